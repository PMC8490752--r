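#' Noise specification
#'
#' Noise is parameterised by the signal-to-noise ratio of the b = 0 image:
#' `sigma = s0 / snr`. Gaussian noise adds `N(0, sigma)` to each magnitude;
#' Rician noise takes the magnitude of the complex signal after adding
#' independent `N(0, sigma)` to both quadratures, as appropriate for magnitude
#' MR images.
#'
#' @param snr Positive signal-to-noise ratio S(0)/sigma.
#' @param model `"gaussian"` (default) or `"rician"`.
#'
#' @return List of class `noise_spec`.
#' @export
noise_spec <- function(snr, model = c("gaussian", "rician")) {
  model <- match.arg(model)
  if (!is.numeric(snr) || length(snr) != 1 || is.na(snr) || snr <= 0) {
    stop("snr must be a single positive number", call. = FALSE)
  }
  structure(list(snr = snr, model = model), class = "noise_spec")
}

#' Add noise to a clean decay
#'
#' @param signal Numeric vector of clean signal magnitudes.
#' @param spec A [noise_spec()].
#' @param s0 Reference S(0) defining `sigma = s0 / snr` (default 1, i.e. the
#'   signal is already normalised).
#'
#' @return Numeric vector of noisy magnitudes (same length). Each call draws
#'   fresh noise; set the RNG seed for reproducibility.
#' @examples
#' set.seed(1)
#' add_noise(rep(1, 5), noise_spec(20))
#' @export
add_noise <- function(signal, spec, s0 = 1) {
  stopifnot(inherits(spec, "noise_spec"))
  sigma <- s0 / spec$snr
  n <- length(signal)
  if (spec$model == "gaussian") {
    signal + stats::rnorm(n, 0, sigma)
  } else {
    sqrt((signal + stats::rnorm(n, 0, sigma))^2 + stats::rnorm(n, 0, sigma)^2)
  }
}

#' Averaging-equivalent SNR
#'
#' Averaging the signal of `n` voxels with independent noise raises the
#' effective SNR by `sqrt(n)` (white-noise averaging law). Used to map the
#' in-slice 3 x 3 neighbourhood fit (n = 9) and ROI fits (n = 1000 or more)
#' onto single-signal simulations.
#'
#' @param base_snr Single-voxel SNR.
#' @param n_averaged Number of voxels averaged (>= 1).
#'
#' @return `base_snr * sqrt(n_averaged)`.
#' @examples
#' equivalent_snr(50, 9)     # 150
#' equivalent_snr(50, 1000)  # ~1581
#' @export
equivalent_snr <- function(base_snr, n_averaged) {
  if (any(n_averaged < 1)) stop("n_averaged must be >= 1", call. = FALSE)
  base_snr * sqrt(n_averaged)
}

#' Monte-Carlo parameter-recovery study
#'
#' Generates the noiseless combined-model signal for each tissue-class truth
#' on the given scheme, adds independent noise at each SNR level, fits every
#' realization with the requested fitter(s) and summarises accuracy and
#' precision per (tissue, SNR, fitter, parameter) cell. As in vivo, every
#' realization is normalised by its own noisy b = 0 value before fitting.
#'
#' @param truths A data frame with columns `tissue`, `f`, `d_star`, `d_app`,
#'   `k_app` (see [tissue_truth_table()]), or a single [diffusion_params()]
#'   (then `tissue = "truth"`).
#' @param scheme A [b_scheme()] (default [trace_scheme()]).
#' @param snr_levels Numeric vector of SNR levels (default 20 to 60 by 10).
#' @param n_reps Independent noise draws per cell (default 10000; at least 100
#'   recommended for a stable coefficient of variation).
#' @param fitters Subset of `c("simultaneous", "sequential")`.
#' @param noise_model `"gaussian"` or `"rician"`.
#' @param seed Optional RNG seed; a given seed makes the whole table
#'   reproducible.
#' @param config,bounds Passed to the fitters.
#' @param keep_estimates Keep the per-realization estimates (needed by
#'   [compare_fitters()]); default `TRUE`.
#'
#' @return An object of class `recovery_study`: a list with `summary` (tibble,
#'   one row per tissue/SNR/fitter/parameter with `truth`, `mean`, `sd`, `cv`
#'   (percent), `bias`, `rel_err` (percent), `n_reps`, `n_failed`) and, when
#'   kept, `estimates` (tibble of per-realization estimates with a `rep`
#'   index). `tidy()` returns the summary.
#' @export
run_recovery_study <- function(truths,
                               scheme = trace_scheme(),
                               snr_levels = seq(20, 60, by = 10),
                               n_reps = 10000,
                               fitters = c("simultaneous", "sequential"),
                               noise_model = c("gaussian", "rician"),
                               seed = NULL,
                               config = fit_config(),
                               bounds = param_bounds(),
                               keep_estimates = TRUE) {
  noise_model <- match.arg(noise_model)
  fitters <- match.arg(fitters, several.ok = TRUE)
  if (inherits(truths, "diffusion_params")) {
    truths <- tibble::tibble(tissue = "truth", f = truths$f,
                             d_star = truths$d_star, d_app = truths$d_app,
                             k_app = truths$k_app)
  }
  if (nrow(truths) == 0) stop("empty truth table", call. = FALSE)
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  b <- as.numeric(scheme)
  pnames <- c("f", "d_star", "d_app", "k_app")

  est_rows <- list()
  sum_rows <- list()
  for (ti in seq_len(nrow(truths))) {
    tr <- truths[ti, ]
    truth <- c(f = tr$f, d_star = tr$d_star, d_app = tr$d_app, k_app = tr$k_app)
    clean <- predict_signal("full", as.list(truth), b)
    for (snr in snr_levels) {
      spec <- noise_spec(snr, noise_model)
      for (fitter in fitters) {
        est <- matrix(NA_real_, n_reps, 4, dimnames = list(NULL, pnames))
        for (r in seq_len(n_reps)) {
          noisy <- add_noise(clean, spec)
          dat <- tibble::tibble(b = b, signal = noisy)
          ft <- tryCatch({
            if (fitter == "sequential") fit_sequential(dat, bounds, config)
            else fit_simultaneous(dat, bounds, config)
          }, error = function(e) NULL)
          if (!is.null(ft) && !anyNA(ft$params)) est[r, ] <- ft$params[pnames]
        }
        n_failed <- sum(is.na(est[, 1]))
        if (keep_estimates) {
          est_rows[[length(est_rows) + 1]] <- tibble::tibble(
            tissue = tr$tissue, snr = snr, fitter = fitter,
            rep = seq_len(n_reps),
            f = est[, 1], d_star = est[, 2], d_app = est[, 3], k_app = est[, 4])
        }
        for (p in pnames) {
          x <- est[, p]
          tru <- truth[[p]]
          mu <- mean(x, na.rm = TRUE)
          sdv <- if (sum(!is.na(x)) >= 2) stats::sd(x, na.rm = TRUE) else NA_real_
          sum_rows[[length(sum_rows) + 1]] <- tibble::tibble(
            tissue = tr$tissue, snr = snr, fitter = fitter, parameter = p,
            truth = tru, mean = mu, sd = sdv,
            cv = if (is.na(sdv) || mu == 0) NaN else 100 * sdv / mu,
            bias = mu - tru,
            rel_err = if (tru == 0) NaN else 100 * abs(mu - tru) / tru,
            n_reps = n_reps, n_failed = n_failed)
        }
      }
    }
  }
  structure(list(summary = dplyr::bind_rows(sum_rows),
                 estimates = if (keep_estimates) dplyr::bind_rows(est_rows) else NULL,
                 scheme = scheme, noise_model = noise_model, seed = seed),
            class = "recovery_study")
}

#' @export
print.recovery_study <- function(x, ...) {
  cat("<recovery_study>", nrow(x$summary), "summary cells;",
      x$noise_model, "noise\n")
  print(x$summary)
  invisible(x)
}

#' Paired comparison of two fitters
#'
#' Two-sided Wilcoxon signed-rank tests on the per-realization estimates of
#' two fitters, one test per parameter. Exact p-values for fewer than 25
#' pairs, normal approximation with tie correction otherwise.
#'
#' @param a,b Data frames of paired estimates with columns `f`, `d_star`,
#'   `d_app`, `k_app` (e.g. filtered rows of the `estimates` table of a
#'   [run_recovery_study()] result); equal row counts, paired by row.
#' @param alpha Significance level recorded alongside (default 0.05).
#'
#' @return A tibble with `parameter`, `p_value`, `n`, `significant`.
#' @export
compare_fitters <- function(a, b, alpha = 0.05) {
  pnames <- c("f", "d_star", "d_app", "k_app")
  if (!all(pnames %in% names(a)) || !all(pnames %in% names(b))) {
    stop("`a` and `b` need columns f, d_star, d_app, k_app", call. = FALSE)
  }
  if (nrow(a) != nrow(b)) stop("paired samples must have equal length", call. = FALSE)
  purrr::map_dfr(pnames, function(p) {
    x <- a[[p]]
    y <- b[[p]]
    ok <- !is.na(x) & !is.na(y)
    x <- x[ok]
    y <- y[ok]
    if (all(x == y)) {
      warning("all paired differences are zero for ", p, "; p = 1")
      pv <- 1
    } else {
      exact <- length(x) < 25
      pv <- suppressWarnings(
        stats::wilcox.test(x, y, paired = TRUE, exact = exact,
                           correct = !exact)$p.value)
    }
    tibble::tibble(parameter = p, p_value = pv, n = length(x),
                   significant = pv < alpha)
  })
}
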