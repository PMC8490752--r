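#' 4-D diffusion-weighted volume
#'
#' Couples a 4-D array (x, y, z, b-volume) with its b-value scheme and voxel
#' geometry; the unit of pipeline input/output.
#'
#' @param data 4-D numeric array; the 4th dimension indexes b-volumes and must
#'   match `length(bvals)`.
#' @param bvals b-values, one per volume (coerced with [b_scheme()]).
#' @param voxel_size Voxel edge lengths in mm (default 2 x 2 x 2).
#' @param slice_gap Slice gap in mm (default 1.4).
#'
#' @return A list of class `dwi_volume`.
#' @export
dwi_volume <- function(data, bvals, voxel_size = c(2, 2, 2), slice_gap = 1.4) {
  if (!is.array(data) || length(dim(data)) != 4) {
    stop("`data` must be a 4-D array (x, y, z, volume)", call. = FALSE)
  }
  bvals <- b_scheme(bvals, require_b0 = FALSE)
  if (dim(data)[4] != length(bvals)) {
    stop("4th dimension (", dim(data)[4], " volumes) must match the scheme (",
         length(bvals), " b-values)", call. = FALSE)
  }
  if (any(data < 0, na.rm = TRUE)) {
    stop("magnitude data must be non-negative", call. = FALSE)
  }
  structure(list(data = data, bvals = bvals,
                 voxel_size = as.numeric(voxel_size),
                 slice_gap = as.numeric(slice_gap)),
            class = "dwi_volume")
}

#' @export
print.dwi_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<dwi_volume> %d x %d x %d voxels, %d b-volumes (b = %g..%g s/mm^2)\n",
              d[1], d[2], d[3], d[4], min(x$bvals), max(x$bvals)))
  invisible(x)
}

check_same_grid <- function(dwi, vol, what = "mask") {
  if (!identical(dim(dwi$data)[1:3], dim(vol)[1:3])) {
    stop(what, " grid ", paste(dim(vol)[1:3], collapse = "x"),
         " does not match the DWI grid ",
         paste(dim(dwi$data)[1:3], collapse = "x"), call. = FALSE)
  }
}

# in-slice kernel mean of the signal around voxel (i, j), truncated at borders
neighbourhood_signal <- function(data, i, j, k, kernel) {
  h <- (kernel - 1) / 2
  xs <- max(1, i - h):min(dim(data)[1], i + h)
  ys <- max(1, j - h):min(dim(data)[2], j + h)
  apply(data[xs, ys, k, , drop = FALSE], 4, mean)
}

#' Fit every masked voxel of a volume
#'
#' Runs the configured fit (sequential or simultaneous; per-voxel signal or
#' the in-slice neighbourhood average assigned to the central voxel) over all
#' voxels with a positive mask value and returns one 3-D map per parameter
#' plus the blood-flow surrogate `f * d_star`. Voxels outside the mask, and
#' voxels whose fit fails, carry `NaN`.
#'
#' @param dwi A [dwi_volume()].
#' @param mask 3-D array on the same grid; voxels with value > 0 are fitted.
#' @param config A [fit_config()]; `method` and `spatial_mode` select the
#'   routine.
#' @param bounds A [param_bounds()].
#'
#' @return Named list of 3-D arrays: `f`, `d_star`, `d_app`, `k_app`,
#'   `f_d_star`.
#' @export
fit_volume <- function(dwi, mask, config = fit_config(), bounds = param_bounds()) {
  stopifnot(inherits(dwi, "dwi_volume"))
  check_same_grid(dwi, mask)
  dims <- dim(dwi$data)[1:3]
  maps <- lapply(1:5, function(i) array(NaN, dims))
  names(maps) <- c("f", "d_star", "d_app", "k_app", "f_d_star")
  idx <- which(mask > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    warning("mask selects no voxels; returning empty maps")
    return(maps)
  }
  b <- as.numeric(dwi$bvals)
  for (r in seq_len(nrow(idx))) {
    i <- idx[r, 1]; j <- idx[r, 2]; k <- idx[r, 3]
    sig <- if (config$spatial_mode == "neighbourhood") {
      neighbourhood_signal(dwi$data, i, j, k, config$kernel)
    } else {
      dwi$data[i, j, k, ]
    }
    fit <- tryCatch({
      d <- tibble::tibble(b = b, signal = sig)
      if (config$method == "sequential") fit_sequential(d, bounds, config)
      else fit_simultaneous(d, bounds, config)
    }, error = function(e) NULL)
    if (!is.null(fit) && !anyNA(fit$params)) {
      maps$f[i, j, k] <- fit$params[["f"]]
      maps$d_star[i, j, k] <- fit$params[["d_star"]]
      maps$d_app[i, j, k] <- fit$params[["d_app"]]
      maps$k_app[i, j, k] <- fit$params[["k_app"]]
      maps$f_d_star[i, j, k] <- fit$params[["f"]] * fit$params[["d_star"]]
    }
  }
  maps
}

#' Region-of-interest fit with model comparison
#'
#' Averages the signal over all ROI voxels per b-volume, then fits each
#' requested nested model to the averaged decay with the simultaneous
#' constrained routine (plus the sequential routine for the full model) and
#' attaches per-model RMSE and corrected AIC.
#'
#' @param dwi A [dwi_volume()].
#' @param roi 3-D mask (> 0 selects ROI voxels); must be non-empty.
#' @param models Subset of `c("mono", "kurtosis", "ivim", "full")`.
#' @param config,bounds See [fit_volume()].
#' @param sequential_full Also run the sequential fit of the full model
#'   (default `TRUE`).
#'
#' @return An object of class `roi_fit`: a list with `fits` (named `dwi_fit`
#'   objects) and `stats` (a tibble of [model_fit_stats()], one row per
#'   model). `tidy()` returns the stats table.
#' @export
fit_roi <- function(dwi, roi, models = c("mono", "kurtosis", "ivim", "full"),
                    config = fit_config(), bounds = param_bounds(),
                    sequential_full = TRUE) {
  stopifnot(inherits(dwi, "dwi_volume"))
  check_same_grid(dwi, roi, "roi")
  models <- match.arg(models, several.ok = TRUE)
  nvox <- sum(roi > 0)
  if (nvox == 0) stop("roi is empty", call. = FALSE)
  mat <- matrix(dwi$data, ncol = dim(dwi$data)[4])
  sig <- colMeans(mat[as.vector(roi > 0), , drop = FALSE])
  decay <- tibble::tibble(b = as.numeric(dwi$bvals), signal = sig)

  fits <- list()
  for (m in models) {
    fits[[m]] <- fit_simultaneous(decay, bounds, config, model = m)
  }
  if (sequential_full && "full" %in% models) {
    fits[["full_sequential"]] <- fit_sequential(decay, bounds, config)
  }
  stats <- purrr::map2(fits, names(fits), function(ft, nm) {
    model_fit_stats(model_id = nm, rss = ft$rss, n = ft$n_points,
                    k = length(model_free_params(ft$model)))
  })
  structure(list(fits = fits, stats = dplyr::bind_rows(stats),
                 n_voxels = nvox, decay = decay),
            class = "roi_fit")
}

#' @export
print.roi_fit <- function(x, ...) {
  cat(sprintf("<roi_fit> %d voxels averaged; %d model fits\n",
              x$n_voxels, length(x$fits)))
  print(x$stats)
  invisible(x)
}
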