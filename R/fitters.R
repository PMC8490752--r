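#' Fitting configuration
#'
#' Controls shared by the sequential and simultaneous fitting routines.
#'
#' @param method `"simultaneous"` (all free parameters estimated jointly by a
#'   constrained Nelder-Mead search) or `"sequential"` (parameters estimated in
#'   the staged order D_app, f, D*, K_app).
#' @param spatial_mode For [fit_volume()]: `"voxel"` fits every masked voxel on
#'   its own signal; `"neighbourhood"` averages the in-slice `kernel` x
#'   `kernel` signal around the central voxel first and assigns the fit of the
#'   averaged signal to that voxel.
#' @param kernel Odd in-slice neighbourhood side length (default 3).
#' @param ivim_cut_b b-value (s/mm^2) below which the IVIM compartment
#'   dominates; the sequential D* step uses only `b <= ivim_cut_b`
#'   (default 200).
#' @param slope_window `c(b_low, b_high)` window of the log-linear slope used
#'   by the sequential D_app step (default 500 to 1000 s/mm^2).
#' @param max_b Optional upper b cut; points above it are discarded before any
#'   fit.
#' @param two_point If `TRUE` the slope step uses only the endpoints of
#'   `slope_window`; by default every acquired b inside the window enters the
#'   regression.
#' @param kurtosis_step Sequential K_app estimation: `"refit"` (default)
#'   divides the high-b signal by `1 - f` and refits the kurtosis exponent
#'   (D_app, K_app) jointly, keeping only K_app; `"frozen"` fits K_app alone
#'   with D_app frozen at the slope estimate. See the methods vignette for why
#'   `"refit"` is the default.
#' @param init Starting point policy of the simultaneous fit: `"sequential"`
#'   (default; the sequential estimates, clipped inside the bounds) or
#'   `"midpoint"` (bound-interval midpoints).
#' @param maxeval Maximum objective evaluations per Nelder-Mead run.
#' @param restarts Number of polish restarts of the simplex from the incumbent
#'   solution (default 1).
#' @param ftol,xtol Nelder-Mead termination tolerances (see [nm_minimize()]).
#'
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(method = c("simultaneous", "sequential"),
                       spatial_mode = c("voxel", "neighbourhood"),
                       kernel = 3,
                       ivim_cut_b = 200,
                       slope_window = c(500, 1000),
                       max_b = NULL,
                       two_point = FALSE,
                       kurtosis_step = c("refit", "frozen"),
                       init = c("sequential", "midpoint"),
                       maxeval = 2000,
                       restarts = 1,
                       ftol = 1e-10,
                       xtol = 1e-8) {
  method <- match.arg(method)
  spatial_mode <- match.arg(spatial_mode)
  kurtosis_step <- match.arg(kurtosis_step)
  init <- match.arg(init)
  if (kernel < 1 || kernel %% 2 != 1) stop("kernel must be odd and >= 1", call. = FALSE)
  if (length(slope_window) != 2 || slope_window[1] >= slope_window[2]) {
    stop("slope_window must be c(b_low, b_high) with b_low < b_high", call. = FALSE)
  }
  if (ivim_cut_b >= slope_window[1]) {
    stop("ivim_cut_b must be below the slope window", call. = FALSE)
  }
  structure(list(method = method, spatial_mode = spatial_mode, kernel = kernel,
                 ivim_cut_b = ivim_cut_b, slope_window = slope_window,
                 max_b = max_b, two_point = two_point,
                 kurtosis_step = kurtosis_step, init = init,
                 maxeval = maxeval, restarts = restarts,
                 ftol = ftol, xtol = xtol),
            class = "fit_config")
}

# free parameters of each nested model (also the parameter count k for AICc)
model_free_params <- function(model) {
  switch(model,
    mono = "d_app",
    kurtosis = c("d_app", "k_app"),
    ivim = c("f", "d_star", "d_app"),
    full = c("f", "d_star", "d_app", "k_app"),
    stop("unknown model: ", model, call. = FALSE)
  )
}

# normalise a (b, signal) data frame by its measured S(0); apply max_b cut
prepare_decay <- function(data, config = fit_config(), s0 = NULL) {
  if (!is.data.frame(data) || !all(c("b", "signal") %in% names(data))) {
    stop("decay data must be a data frame with columns `b` and `signal`", call. = FALSE)
  }
  b <- as.numeric(data$b)
  s <- as.numeric(data$signal)
  if (length(b) != length(s) || anyNA(b) || anyNA(s)) {
    stop("`b` and `signal` must be equal-length and free of NA", call. = FALSE)
  }
  if (any(s < 0)) stop("signal magnitudes must be non-negative", call. = FALSE)
  if (is.null(s0)) {
    if (!any(b == 0)) stop("decay must contain b = 0 (or supply `s0`)", call. = FALSE)
    s0 <- mean(s[b == 0])
  }
  if (s0 <= 0) stop("S(0) must be positive", call. = FALSE)
  if (!is.null(config$max_b)) {
    keep <- b <= config$max_b
    b <- b[keep]
    s <- s[keep]
  }
  list(b = b, s = s / s0, s0 = s0)
}

new_dwi_fit <- function(params, rss, n_points, converged, n_evals, method,
                        model, bounds, clipped = NULL, decay = NULL) {
  structure(list(params = params, rss = rss, n_points = n_points,
                 converged = converged, n_evals = n_evals, method = method,
                 model = model, bounds = bounds,
                 clipped = clipped %||% setNames(rep(FALSE, length(params)), names(params)),
                 decay = decay),
            class = "dwi_fit")
}

failed_fit <- function(method, model, bounds, n_points, decay = NULL) {
  p <- setNames(rep(NA_real_, 4), c("f", "d_star", "d_app", "k_app"))
  new_dwi_fit(p, NA_real_, n_points, converged = FALSE, n_evals = 0L,
              method = method, model = model, bounds = bounds, decay = decay)
}

#' @export
print.dwi_fit <- function(x, ...) {
  cat(sprintf("<dwi_fit> %s fit of the %s model (%d points)%s\n",
              x$method, x$model, x$n_points,
              if (isTRUE(x$converged)) "" else " [NOT CONVERGED]"))
  if (!anyNA(x$params)) {
    cat(sprintf("  f = %.4g  D* = %.4g  D_app = %.4g  K_app = %.4g  (f.D* = %.4g)\n",
                x$params[["f"]], x$params[["d_star"]], x$params[["d_app"]],
                x$params[["k_app"]], x$params[["f"]] * x$params[["d_star"]]))
    cat(sprintf("  RSS = %.4g over %d b-values\n", x$rss, x$n_points))
  }
  invisible(x)
}

full_model_rss <- function(p, b, s) {
  pred <- p[["f"]] * exp(-b * p[["d_star"]]) +
    (1 - p[["f"]]) * exp(-b * p[["d_app"]] + b^2 * p[["d_app"]]^2 * p[["k_app"]] / 6)
  sum((s - pred)^2)
}

#' Sequential (segmented) fit of the combined diffusion model
#'
#' Estimates the four parameters of the combined IVIM/non-Gaussian model in
#' stages, the way segmented IVIM fitting is done in practice:
#'
#' 1. `d_app` is minus the least-squares slope of `log(S/S0)` over the
#'    Gaussian-diffusion window (`slope_window`, default 500-1000 s/mm^2),
#'    where the IVIM compartment has decayed away and the kurtosis term is
#'    still small.
#' 2. `f` is the b = 0 intercept deficit of that line, `1 - exp(intercept)`.
#' 3. `d_star` is found by bounded one-dimensional minimisation of the IVIM
#'    bi-exponential residuals over `b <= ivim_cut_b`, with `f` and `d_app`
#'    frozen.
#' 4. `k_app` is estimated from the high-b points (`b >= slope_window[2]`);
#'    see the `kurtosis_step` argument of [fit_config()].
#'
#' Estimates falling outside the bounds are clipped in and flagged.
#'
#' @param data Data frame with columns `b` (s/mm^2) and `signal`.
#' @param bounds A [param_bounds()] object.
#' @param config A [fit_config()] object.
#' @param s0 Optional reference S(0); by default the measured signal at b = 0.
#'
#' @return A `dwi_fit` object; see [tidy.dwi_fit()] and [glance.dwi_fit()].
#' @examples
#' gm <- diffusion_params(0.13, 8.43e-3, 1.12e-3, 0.83)
#' d <- signal_decay(trace_scheme(), predict_signal("full", gm, trace_scheme()))
#' fit_sequential(d)
#' @export
fit_sequential <- function(data, bounds = param_bounds(), config = fit_config(),
                           s0 = NULL) {
  dec <- prepare_decay(data, config, s0)
  b <- dec$b
  s <- dec$s
  n <- length(b)
  if (n < 4) stop("sequential fit needs at least 4 b-values", call. = FALSE)

  win <- b >= config$slope_window[1] & b <= config$slope_window[2]
  if (config$two_point) {
    win <- b %in% config$slope_window
  }
  if (sum(win) < 2) stop("need at least 2 points inside the slope window", call. = FALSE)
  if (!any(b <= config$ivim_cut_b)) stop("need at least 1 point at b <= ivim_cut_b", call. = FALSE)
  if (any(s[win] <= 0)) {
    # log of a non-positive magnitude is undefined: report failure, not an error
    return(failed_fit("sequential", "full", bounds, n,
                      decay = tibble::tibble(b = b, signal = s)))
  }

  # step 1/2: log-linear slope and intercept over the Gaussian window
  coefs <- stats::lm.fit(cbind(1, b[win]), log(s[win]))$coefficients
  d_app_raw <- -coefs[[2]]
  f_raw <- 1 - exp(coefs[[1]])

  lo <- bounds$lower
  hi <- bounds$upper
  d_app <- min(max(d_app_raw, lo[["d_app"]]), hi[["d_app"]])
  f <- min(max(f_raw, lo[["f"]]), hi[["f"]])

  # step 3: bounded 1-D search for d_star on the IVIM regime, f and d_app frozen
  ivim <- b <= config$ivim_cut_b
  d_star <- stats::optimize(function(ds) {
    pred <- f * exp(-b[ivim] * ds) + (1 - f) * exp(-b[ivim] * d_app)
    sum((s[ivim] - pred)^2)
  }, c(lo[["d_star"]], hi[["d_star"]]))$minimum

  # step 4: apparent kurtosis from the high-b points
  hb <- b >= config$slope_window[2]
  n_evals <- 0L
  if (config$kurtosis_step == "refit") {
    # the tissue compartment at high b is (1 - f) * exp(-b D + b^2 D^2 K / 6):
    # correct the amplitude with the step-2 f, refit the exponent jointly,
    # and keep only K_app (D_app stays the slope estimate)
    sc <- s[hb] / (1 - min(f, 0.999))
    klo <- c(lo[["d_app"]], lo[["k_app"]])
    khi <- c(hi[["d_app"]], hi[["k_app"]])
    obj <- function(t) {
      p <- logit_to_box(t, klo, khi)
      sum((sc - exp(-b[hb] * p[1] + b[hb]^2 * p[1]^2 * p[2] / 6))^2)
    }
    t0 <- box_to_logit(c(d_app, 1), klo, khi)
    o <- nm_minimize(obj, t0, step = 1, maxeval = config$maxeval,
                     ftol = config$ftol, xtol = config$xtol)
    n_evals <- o$evals
    k_app <- logit_to_box(o$par, klo, khi)[2]
  } else {
    k_app <- stats::optimize(function(k) {
      sum((s[hb] - exp(-b[hb] * d_app + b[hb]^2 * d_app^2 * k / 6))^2)
    }, c(lo[["k_app"]], hi[["k_app"]]))$minimum
  }

  params <- c(f = f, d_star = d_star, d_app = d_app, k_app = k_app)
  clipped <- c(f = f != f_raw, d_star = FALSE, d_app = d_app != d_app_raw,
               k_app = FALSE)
  new_dwi_fit(params, full_model_rss(params, b, s), n,
              converged = TRUE, n_evals = n_evals, method = "sequential",
              model = "full", bounds = bounds, clipped = clipped,
              decay = tibble::tibble(b = b, signal = s))
}

#' Simultaneous constrained Nelder-Mead fit
#'
#' Estimates all free parameters of the requested model jointly by minimising
#' the sum of squared residuals between the normalised signal and the model
#' prediction. The search runs on unconstrained coordinates obtained by a
#' logistic transform of each bounded interval, so every iterate (and the
#' returned estimate) respects the box constraints exactly; see
#' [nm_minimize()] for the simplex itself.
#'
#' By default the search starts from the sequential estimates (clipped
#' strictly inside the bounds), falling back to the interval midpoints when
#' the sequential fit fails. Given identical data, start and configuration the
#' result is bitwise reproducible.
#'
#' @inheritParams fit_sequential
#' @param model Which nested model to fit: `"mono"`, `"kurtosis"`, `"ivim"` or
#'   `"full"` (default).
#' @param init Optional [diffusion_params()] (or named vector) start; values
#'   outside the bounds are clipped in.
#'
#' @return A `dwi_fit` object.
#' @examples
#' gm <- diffusion_params(0.13, 8.43e-3, 1.12e-3, 0.83)
#' d <- signal_decay(trace_scheme(), predict_signal("full", gm, trace_scheme()))
#' fit_simultaneous(d)
#' @export
fit_simultaneous <- function(data, bounds = param_bounds(), config = fit_config(),
                             model = "full", init = NULL, s0 = NULL) {
  model <- match.arg(model, c("mono", "ivim", "kurtosis", "full"))
  dec <- prepare_decay(data, config, s0)
  b <- dec$b
  s <- dec$s
  n <- length(b)
  free <- model_free_params(model)
  if (n < length(free) + 1) {
    stop("need more b-values than free parameters", call. = FALSE)
  }
  if (model == "full" &&
      (n < 5 || !any(b <= config$ivim_cut_b & b > 0) || !any(b >= 1500))) {
    stop("full-model fit needs >= 5 b-values spanning the IVIM (<= ",
         config$ivim_cut_b, ") and kurtosis (>= 1500) regimes", call. = FALSE)
  }
  if (stats::sd(s) == 0) {
    return(failed_fit("simultaneous", model, bounds, n,
                      decay = tibble::tibble(b = b, signal = s)))
  }

  # start: user-supplied > sequential estimates > interval midpoints
  mid <- (bounds$lower + bounds$upper) / 2
  start <- mid
  if (!is.null(init)) {
    start <- clip_to_bounds(unlist(init), bounds)
  } else if (config$init == "sequential" && model == "full") {
    sq <- tryCatch(fit_sequential(tibble::tibble(b = b, signal = s),
                                  bounds, config),
                   error = function(e) NULL)
    if (!is.null(sq) && isTRUE(sq$converged)) start <- sq$params
  }

  lo <- bounds$lower[free]
  hi <- bounds$upper[free]
  fixed <- c(f = 0, d_star = mid[["d_star"]], d_app = mid[["d_app"]], k_app = 0)
  obj <- function(t) {
    p <- fixed
    p[free] <- logit_to_box(t, lo, hi)
    full_model_rss(p, b, s)
  }
  t0 <- box_to_logit(start[free], lo, hi)
  o <- nm_minimize(obj, t0, step = 1, maxeval = config$maxeval,
                   ftol = config$ftol, xtol = config$xtol)
  evals <- o$evals
  conv <- o$converged
  for (i in seq_len(config$restarts)) {
    o <- nm_minimize(obj, o$par, step = 0.25, maxeval = config$maxeval,
                     ftol = config$ftol, xtol = config$xtol)
    evals <- evals + o$evals
    conv <- o$converged
  }
  params <- fixed
  params[free] <- logit_to_box(o$par, lo, hi)
  new_dwi_fit(params, o$value, n, converged = conv, n_evals = evals,
              method = "simultaneous", model = model, bounds = bounds,
              decay = tibble::tibble(b = b, signal = s))
}

#' Build a decay data frame
#'
#' Convenience constructor pairing a b-value scheme with signal magnitudes in
#' the tabular form every fitting function accepts.
#'
#' @param b Numeric b-values (s/mm^2), e.g. a [b_scheme()].
#' @param signal Signal magnitudes, same length as `b`.
#'
#' @return A tibble with columns `b` and `signal`.
#' @export
signal_decay <- function(b, signal) {
  b <- as.numeric(b)
  signal <- as.numeric(signal)
  if (length(b) != length(signal)) {
    stop("`b` and `signal` must have equal length", call. = FALSE)
  }
  if (any(signal < 0)) stop("signal magnitudes must be non-negative", call. = FALSE)
  tibble::tibble(b = b, signal = signal)
}

#' Predicted signal of a fitted model
#'
#' @param object A `dwi_fit`.
#' @param b b-values at which to predict (default: those used in the fit).
#' @param ... Unused.
#' @return Numeric vector of normalised predictions.
#' @export
predict.dwi_fit <- function(object, b = NULL, ...) {
  if (is.null(b)) b <- object$decay$b
  p <- object$params
  predict_signal(object$model,
                 list(f = p[["f"]], d_star = p[["d_star"]],
                      d_app = p[["d_app"]], k_app = p[["k_app"]]),
                 b)
}
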