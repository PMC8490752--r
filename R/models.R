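#' Forward diffusion signal models
#'
#' Predicted normalised signal S(b)/S(0) under the four nested representations
#' of the trace diffusion decay:
#'
#' * `mono`: Gaussian diffusion, `exp(-b * d_app)`;
#' * `ivim`: bi-exponential intravoxel incoherent motion,
#'   `f * exp(-b * d_star) + (1 - f) * exp(-b * d_app)`;
#' * `kurtosis`: first-order non-Gaussian cumulant expansion,
#'   `exp(-b * d_app + b^2 * d_app^2 * k_app / 6)`;
#' * `full`: the combined IVIM/non-Gaussian model,
#'   `f * exp(-b * d_star) + (1 - f) * exp(-b * d_app + b^2 * d_app^2 * k_app / 6)`.
#'
#' The models are nested: `full` reduces to `ivim` for `k_app = 0`, to
#' `kurtosis` for `f = 0` and to `mono` for both. Parameters irrelevant to a
#' model (`f`, `d_star` for `mono`/`kurtosis`; `k_app` for `ivim`) are ignored.
#'
#' @param model One of `"mono"`, `"ivim"`, `"kurtosis"`, `"full"`.
#' @param params A [diffusion_params()] object (or a list with the same names).
#' @param b Numeric vector of b-values (s/mm^2), e.g. a [b_scheme()].
#'
#' @return Numeric vector of S(b)/S(0), one value per element of `b`.
#' @examples
#' gm <- diffusion_params(f = 0.13, d_star = 8.43e-3, d_app = 1.12e-3, k_app = 0.83)
#' predict_signal("full", gm, trace_scheme())
#' predict_signal("mono", gm, 1000)  # exp(-1.12)
#' @export
predict_signal <- function(model, params, b) {
  model <- match.arg(model, c("mono", "ivim", "kurtosis", "full"))
  b <- as.numeric(b)
  if (any(b < 0)) stop("b-values must be non-negative", call. = FALSE)
  f <- params$f %||% 0
  d_star <- params$d_star %||% 1e-3
  d_app <- params$d_app
  k_app <- params$k_app %||% 0
  if (is.null(d_app) || d_app < 0 || k_app < 0 || f < 0 || f > 1 || d_star < 0) {
    stop("parameters out of physical range; see ?diffusion_params", call. = FALSE)
  }
  tissue <- switch(model,
    mono = ,
    ivim = exp(-b * d_app),
    kurtosis = ,
    full = exp(-b * d_app + b^2 * d_app^2 * k_app / 6)
  )
  if (model %in% c("mono", "kurtosis")) {
    return(tissue)
  }
  f * exp(-b * d_star) + (1 - f) * tissue
}

#' Upper b-value of kurtosis-model validity
#'
#' The kurtosis expansion has a quadratic exponent in b, so its predicted
#' signal stops decreasing above the vertex `b* = 3 / (d_app * k_app)`.
#' Predictions beyond `b*` are unphysical; the expansion is only applicable
#' up to moderate b-values.
#'
#' @param params A [diffusion_params()] object with `d_app > 0`.
#'
#' @return The bound b* in s/mm^2; `Inf` when `k_app = 0` (Gaussian limit).
#' @examples
#' kurtosis_validity_bound(diffusion_params(d_app = 1e-3, k_app = 3)) # 1000
#' @export
kurtosis_validity_bound <- function(params) {
  if (params$d_app <= 0) stop("d_app must be positive", call. = FALSE)
  if (params$k_app < 0) stop("k_app must be non-negative", call. = FALSE)
  if (params$k_app == 0) {
    return(Inf)
  }
  3 / (params$d_app * params$k_app)
}
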