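#' Diffusion model parameters
#'
#' Bundle of the four parameters of the combined IVIM/non-Gaussian-diffusion
#' signal model: the perfusion fraction `f` (dimensionless signal fraction of
#' the fast pseudo-diffusion compartment), the pseudo-diffusion coefficient
#' `d_star` (mm^2/s), the apparent diffusivity `d_app` (mm^2/s) and the
#' apparent kurtosis `k_app` (dimensionless). The derived product
#' `f * d_star` is a blood-flow surrogate.
#'
#' @param f Perfusion fraction, in \[0, 1\].
#' @param d_star Pseudo-diffusion coefficient, mm^2/s, > 0.
#' @param d_app Apparent diffusivity, mm^2/s, > 0.
#' @param k_app Apparent kurtosis, >= 0.
#'
#' @return A named list of class `diffusion_params`.
#' @examples
#' diffusion_params(f = 0.13, d_star = 8.43e-3, d_app = 1.12e-3, k_app = 0.83)
#' @export
diffusion_params <- function(f = 0, d_star = 1e-3, d_app = 1e-3, k_app = 0) {
  vals <- c(f = f, d_star = d_star, d_app = d_app, k_app = k_app)
  if (anyNA(vals) || !is.numeric(vals)) {
    stop("all parameters must be non-missing numbers", call. = FALSE)
  }
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  if (d_star <= 0) stop("d_star must be positive (mm^2/s)", call. = FALSE)
  if (d_app <= 0) stop("d_app must be positive (mm^2/s)", call. = FALSE)
  if (k_app < 0) stop("k_app must be non-negative", call. = FALSE)
  structure(list(f = f, d_star = d_star, d_app = d_app, k_app = k_app),
            class = "diffusion_params")
}

#' @export
print.diffusion_params <- function(x, ...) {
  cat(sprintf("<diffusion_params> f = %.4g, D* = %.4g mm^2/s, D_app = %.4g mm^2/s, K_app = %.4g\n",
              x$f, x$d_star, x$d_app, x$k_app))
  invisible(x)
}

#' @export
as.double.diffusion_params <- function(x, ...) {
  c(f = x$f, d_star = x$d_star, d_app = x$d_app, k_app = x$k_app)
}

#' Box constraints for the constrained fits
#'
#' Default parameter bounds of the constrained fitting routines, chosen as
#' biologically plausible intervals for brain tissue: f in \[0, 0.3\],
#' D* in \[0.004, 0.05\] mm^2/s, D_app in \[0.0001, 0.003\] mm^2/s and
#' K_app in \[0, 3\].
#'
#' @param f,d_star,d_app,k_app Length-2 numeric vectors `c(lower, upper)`.
#'
#' @return A list of class `param_bounds` with elements `lower` and `upper`
#'   (named numeric vectors over `f`, `d_star`, `d_app`, `k_app`).
#' @examples
#' param_bounds()
#' @export
param_bounds <- function(f = c(0, 0.3),
                         d_star = c(0.004, 0.05),
                         d_app = c(1e-4, 3e-3),
                         k_app = c(0, 3)) {
  m <- rbind(f = f, d_star = d_star, d_app = d_app, k_app = k_app)
  if (ncol(m) != 2 || any(m[, 1] >= m[, 2])) {
    stop("each bound must be c(lower, upper) with lower < upper", call. = FALSE)
  }
  structure(list(lower = m[, 1], upper = m[, 2]), class = "param_bounds")
}

#' @export
print.param_bounds <- function(x, ...) {
  cat("<param_bounds>\n")
  for (p in names(x$lower)) {
    cat(sprintf("  %-7s [%g, %g]\n", p, x$lower[[p]], x$upper[[p]]))
  }
  invisible(x)
}

# clip a named parameter vector into [lower, upper]; margin > 0 keeps the
# result strictly inside the box (a fraction of each interval width)
clip_to_bounds <- function(p, bounds, margin = 0) {
  lo <- bounds$lower
  hi <- bounds$upper
  if (margin > 0) {
    w <- hi - lo
    lo <- lo + margin * w
    hi <- hi - margin * w
  }
  pmin(pmax(p[names(bounds$lower)], lo), hi)
}
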