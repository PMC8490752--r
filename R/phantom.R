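#' Tissue-class ground-truth parameters
#'
#' Reference parameter sets for the five brain tissue classes (grey matter,
#' low- and high-FA white matter, oedema and active tumour), as estimated from
#' tissue-class ROI fits of the combined model. Two columns are available:
#' the simultaneous-fit values (default; used as simulation ground truth) and
#' the sequential-fit values.
#'
#' @param fit `"simultaneous"` (default) or `"sequential"`.
#'
#' @return Tibble with columns `tissue`, `f`, `d_star`, `d_app`, `k_app`
#'   (diffusivities in mm^2/s).
#' @examples
#' tissue_truth_table()
#' @export
tissue_truth_table <- function(fit = c("simultaneous", "sequential")) {
  fit <- match.arg(fit)
  if (fit == "simultaneous") {
    tibble::tibble(
      tissue = c("GM", "WM-lowFA", "WM-highFA", "Oedema", "Tumour"),
      f = c(0.13, 0.03, 0.03, 0.03, 0.01),
      d_star = c(8.43e-3, 21.62e-3, 23.02e-3, 28.98e-3, 29.53e-3),
      d_app = c(1.12e-3, 0.94e-3, 0.88e-3, 1.42e-3, 1.38e-3),
      k_app = c(0.83, 1.03, 1.12, 0.74, 0.72))
  } else {
    tibble::tibble(
      tissue = c("GM", "WM-lowFA", "WM-highFA", "Oedema", "Tumour"),
      f = c(0.20, 0.10, 0.10, 0.14, 0.11),
      d_star = c(12.16e-3, 17.63e-3, 17.69e-3, 19.96e-3, 25.92e-3),
      d_app = c(0.86e-3, 0.71e-3, 0.66e-3, 1.05e-3, 1.06e-3),
      k_app = c(0.83, 1.02, 1.11, 0.73, 0.73))
  }
}

default_phantom_layout <- function(dim3 = c(40, 40, 4)) {
  zs <- seq_len(dim3[3])
  list(
    "GM"        = list(x = 7:22,  y = 7:22,  z = zs),
    "WM-lowFA"  = list(x = 25:33, y = 7:15,  z = zs),
    "WM-highFA" = list(x = 25:33, y = 17:25, z = zs),
    "Oedema"    = list(x = 7:15,  y = 25:33, z = zs),
    "Tumour"    = list(x = 18:26, y = 27:33, z = zs)
  )
}

#' Phantom configuration
#'
#' Describes a digital trace-DWI phantom: an axial slab with one rectangular
#' block per tissue class inside an air frame (so the field-of-view corners
#' are signal-free and usable for noise-floor estimation).
#'
#' @param dim 3-D grid dimensions (default `c(40, 40, 4)`; the default layout
#'   gives the grey-matter block 16 x 16 x 4 = 1024 voxels).
#' @param truth Per-class parameter table (default [tissue_truth_table()]).
#' @param layout Named list (one entry per tissue in `truth`) of voxel index
#'   ranges `list(x =, y =, z =)`; blocks must not overlap.
#' @param scheme A [b_scheme()] (default [trace_scheme()]).
#' @param snr SNR of the b = 0 image, or `NULL`/`Inf` for a noiseless
#'   phantom.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param s0 b = 0 magnitude of tissue voxels (single value or one per class).
#' @param jitter_sd Optional named vector of within-class standard deviations
#'   (names among `f`, `d_star`, `d_app`, `k_app`) emulating tissue
#'   heterogeneity; draws are truncated at the default fit bounds.
#'
#' @return List of class `phantom_config`.
#' @export
phantom_config <- function(dim = c(40, 40, 4),
                           truth = tissue_truth_table(),
                           layout = default_phantom_layout(dim),
                           scheme = trace_scheme(),
                           snr = 50,
                           noise_model = c("gaussian", "rician"),
                           s0 = 1,
                           jitter_sd = NULL) {
  noise_model <- match.arg(noise_model)
  if (!all(truth$tissue %in% names(layout))) {
    stop("layout must name every tissue in the truth table", call. = FALSE)
  }
  occupied <- array(0L, dim)
  for (cls in truth$tissue) {
    bl <- layout[[cls]]
    occupied[bl$x, bl$y, bl$z] <- occupied[bl$x, bl$y, bl$z] + 1L
  }
  if (any(occupied > 1L)) stop("phantom layout blocks overlap", call. = FALSE)
  s0 <- rep_len(s0, nrow(truth))
  structure(list(dim = dim, truth = truth, layout = layout, scheme = scheme,
                 snr = snr, noise_model = noise_model, s0 = s0,
                 jitter_sd = jitter_sd),
            class = "phantom_config")
}

truncated_normal <- function(n, mean, sd, lower, upper) {
  x <- stats::rnorm(n, mean, sd)
  for (i in 1:100) {
    bad <- x < lower | x > upper
    if (!any(bad)) break
    x[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  pmin(pmax(x, lower), upper)
}

#' Generate a digital tissue-class phantom
#'
#' Builds the voxelwise noiseless signal `s0 * S(b)/S(0)` from the combined
#' model with each voxel's ground-truth parameters, adds noise according to
#' the configuration and returns the volume together with the class masks and
#' the voxelwise truth maps for recovery scoring. Identical seeds reproduce
#' the noise; the truth maps do not depend on the seed unless within-class
#' jitter is enabled.
#'
#' @param config A [phantom_config()].
#' @param seed Optional RNG seed.
#'
#' @return List with `dwi` ([dwi_volume()]), `masks` ([mask_set()]), `truth`
#'   (named list of 3-D parameter maps, `NaN` outside tissue) and `config`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = NULL) {
  stopifnot(inherits(config, "phantom_config"))
  if (!is.null(seed)) set.seed(seed)
  d3 <- config$dim
  b <- as.numeric(config$scheme)
  nvol <- length(b)
  data <- array(0, c(d3, nvol))
  pnames <- c("f", "d_star", "d_app", "k_app")
  truth_maps <- setNames(lapply(pnames, function(p) array(NaN, d3)), pnames)
  masks <- list()
  bounds <- param_bounds()

  for (ti in seq_len(nrow(config$truth))) {
    row <- config$truth[ti, ]
    bl <- config$layout[[row$tissue]]
    m <- array(0L, d3)
    m[bl$x, bl$y, bl$z] <- 1L
    masks[[row$tissue]] <- m
    vox <- which(m == 1L)
    n <- length(vox)
    pv <- sapply(pnames, function(p) rep(row[[p]], n))
    if (!is.null(config$jitter_sd)) {
      for (p in intersect(names(config$jitter_sd), pnames)) {
        pv[, p] <- truncated_normal(n, row[[p]], config$jitter_sd[[p]],
                                    bounds$lower[[p]], bounds$upper[[p]])
      }
    }
    for (p in pnames) truth_maps[[p]][vox] <- pv[, p]
    sig <- if (is.null(config$jitter_sd)) {
      matrix(config$s0[ti] * predict_signal("full", as.list(pv[1, ]), b),
             nvol, n)
    } else {
      vapply(seq_len(n), function(i) {
        config$s0[ti] * predict_signal("full", as.list(pv[i, ]), b)
      }, numeric(nvol))
    }
    for (v in seq_len(nvol)) {
      vol <- data[, , , v]
      vol[vox] <- sig[v, ]
      data[, , , v] <- vol
    }
  }

  if (!is.null(config$snr) && is.finite(config$snr)) {
    spec <- noise_spec(config$snr, config$noise_model)
    sigma <- max(config$s0) / config$snr
    if (config$noise_model == "gaussian") {
      data <- data + array(stats::rnorm(length(data), 0, sigma), dim(data))
      data[data < 0] <- 0
    } else {
      data <- sqrt((data + array(stats::rnorm(length(data), 0, sigma), dim(data)))^2 +
                     array(stats::rnorm(length(data), 0, sigma), dim(data))^2)
    }
  }

  # classes absent from the truth table get empty masks
  cls_mask <- function(cls) masks[[cls]] %||% array(0L, d3)
  list(dwi = dwi_volume(data, config$scheme),
       masks = mask_set(cls_mask("GM"), cls_mask("WM-lowFA"), cls_mask("WM-highFA"),
                        cls_mask("Oedema"), cls_mask("Tumour")),
       truth = truth_maps,
       config = config)
}

#' Tissue-class mask set
#'
#' The five binary tissue masks on one grid: grey matter, low-FA white
#' matter, high-FA white matter, oedema and tumour.
#'
#' @param gm,wm_low_fa,wm_high_fa,oedema,tumour Binary 3-D arrays, same grid.
#'
#' @return Named list of class `mask_set`.
#' @export
mask_set <- function(gm, wm_low_fa, wm_high_fa, oedema, tumour) {
  ms <- list(gm = gm, wm_low_fa = wm_low_fa, wm_high_fa = wm_high_fa,
             oedema = oedema, tumour = tumour)
  dims <- lapply(ms, dim)
  if (length(unique(dims)) != 1) stop("all masks must share one grid", call. = FALSE)
  ms <- lapply(ms, function(m) array(as.integer(m > 0), dim(m)))
  structure(ms, class = "mask_set")
}

#' Resolve overlaps between tissue masks
#'
#' Applies the mask-exclusivity rules used before tissue-class analysis:
#' a voxel in both the tumour and oedema masks stays tumour only; a voxel in
#' two or more healthy masks (GM, WM-lowFA, WM-highFA) is removed from all of
#' them; a healthy voxel that also belongs to a pathological mask (tumour or
#' oedema) is removed from the healthy mask, so pathology takes priority. The
#' output masks are pairwise disjoint and the operation is idempotent; the
#' tumour mask never loses voxels.
#'
#' @param masks A [mask_set()].
#'
#' @return A disjoint [mask_set()]; attribute `"removed"` counts voxels
#'   dropped per rule.
#' @export
resolve_mask_overlaps <- function(masks) {
  stopifnot(inherits(masks, "mask_set"))
  gm <- masks$gm
  wl <- masks$wm_low_fa
  wh <- masks$wm_high_fa
  oe <- masks$oedema
  tu <- masks$tumour

  tu_oe <- tu & oe
  oe[tu_oe] <- 0L

  healthy_n <- gm + wl + wh
  multi <- healthy_n >= 2L
  gm[multi] <- 0L
  wl[multi] <- 0L
  wh[multi] <- 0L

  path <- (tu | oe) > 0
  healthy_in_path <- (gm | wl | wh) & path
  gm[path] <- 0L
  wl[path] <- 0L
  wh[path] <- 0L

  out <- mask_set(gm, wl, wh, oe, tu)
  attr(out, "removed") <- c(oedema_to_tumour = sum(tu_oe),
                            ambiguous_healthy = sum(multi),
                            healthy_in_pathology = sum(healthy_in_path))
  out
}

#' Mask-construction thresholds
#'
#' @param fa_low_range Open interval of fractional anisotropy defining low-FA
#'   white matter (default `(0.05, 0.3)`, strict on both sides).
#' @param fa_high_min FA at or above which white matter is high-FA
#'   (default 0.3).
#' @param uptake_ratio Tracer-uptake multiple of contralateral white matter at
#'   or above which a voxel is active tumour (default 1.6).
#' @param gm_wm_prob_threshold Probability-map threshold generating GM/WM
#'   masks from a probabilistic segmentation (default 0.98).
#'
#' @return List of class `mask_config`.
#' @export
mask_config <- function(fa_low_range = c(0.05, 0.3), fa_high_min = 0.3,
                        uptake_ratio = 1.6, gm_wm_prob_threshold = 0.98) {
  if (any(fa_low_range <= 0) || any(fa_low_range >= 1) ||
      fa_low_range[1] >= fa_low_range[2]) {
    stop("fa_low_range must be an increasing interval inside (0, 1)", call. = FALSE)
  }
  if (uptake_ratio <= 1) stop("uptake_ratio must exceed 1", call. = FALSE)
  structure(list(fa_low_range = fa_low_range, fa_high_min = fa_high_min,
                 uptake_ratio = uptake_ratio,
                 gm_wm_prob_threshold = gm_wm_prob_threshold),
            class = "mask_config")
}

#' Split a white-matter mask by fractional anisotropy
#'
#' Low-FA white matter satisfies the strict inequalities
#' `fa_low_range[1] < FA < fa_low_range[2]`; high-FA white matter has
#' `FA >= fa_high_min`. Voxels at or below the lower threshold fall in
#' neither class.
#'
#' @param wm_mask Binary white-matter mask.
#' @param fa_map FA values in \[0, 1\], same grid.
#' @param config A [mask_config()].
#'
#' @return List with binary arrays `wm_low_fa` and `wm_high_fa`.
#' @export
split_wm_by_fa <- function(wm_mask, fa_map, config = mask_config()) {
  if (!identical(dim(wm_mask), dim(fa_map))) stop("grid mismatch", call. = FALSE)
  if (any(fa_map < 0 | fa_map > 1, na.rm = TRUE)) {
    stop("FA values must lie in [0, 1]", call. = FALSE)
  }
  lowr <- config$fa_low_range
  low <- (wm_mask > 0) & (fa_map > lowr[1]) & (fa_map < lowr[2])
  high <- (wm_mask > 0) & (fa_map >= config$fa_high_min)
  list(wm_low_fa = array(as.integer(low), dim(wm_mask)),
       wm_high_fa = array(as.integer(high), dim(wm_mask)))
}

#' Tumour mask from tracer uptake
#'
#' Voxels with uptake at or above `uptake_ratio` times the mean uptake in
#' contralateral (normal-appearing) white matter are classed as active tumour.
#'
#' @param uptake_map Scalar uptake volume.
#' @param contralateral_wm_mask Binary reference mask (non-empty).
#' @param config A [mask_config()].
#'
#' @return Binary tumour mask.
#' @export
tumour_from_uptake <- function(uptake_map, contralateral_wm_mask,
                               config = mask_config()) {
  if (!identical(dim(uptake_map), dim(contralateral_wm_mask))) {
    stop("grid mismatch", call. = FALSE)
  }
  ref_vox <- uptake_map[contralateral_wm_mask > 0]
  if (length(ref_vox) == 0) stop("contralateral reference mask is empty", call. = FALSE)
  normal <- mean(ref_vox)
  array(as.integer(uptake_map >= config$uptake_ratio * normal), dim(uptake_map))
}
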