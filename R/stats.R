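#' Corrected Akaike information criterion
#'
#' `AICc = n * log(rss / n) + 2k + 2k(k + 1) / (n - k - 1)` for a
#' least-squares fit with `k` free parameters over `n` points. Lower values
#' indicate a better trade-off between residual size and model complexity.
#'
#' @param rss Residual sum of squares (> 0; `rss = 0` returns `-Inf` with a
#'   warning).
#' @param n Number of fitted points; must exceed `k + 1`.
#' @param k Number of free model parameters.
#'
#' @return The AICc value.
#' @examples
#' aicc(16, 16, 2)  # 4 + 12/13
#' @export
aicc <- function(rss, n, k) {
  if (n <= k + 1) stop("AICc undefined: need n > k + 1", call. = FALSE)
  if (rss < 0) stop("rss must be non-negative", call. = FALSE)
  if (rss == 0) {
    warning("rss = 0: AICc is -Inf")
    return(-Inf)
  }
  n * log(rss / n) + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

#' Per-model goodness-of-fit statistics
#'
#' @param model_id Model label.
#' @param rss Residual sum of squares of the normalised signal.
#' @param n Number of fitted b-values.
#' @param k Number of free decay parameters (mono 1, kurtosis 2, ivim 3,
#'   full 4; S(0) is measured, not fitted).
#'
#' @return One-row tibble with `model_id`, `rss`, `n`, `k`, `rmse`
#'   (`sqrt(rss/n)`) and `aicc`.
#' @export
model_fit_stats <- function(model_id, rss, n, k) {
  tibble::tibble(model_id = model_id, rss = rss, n = n, k = k,
                 rmse = sqrt(rss / n),
                 aicc = if (is.na(rss)) NA_real_ else suppressWarnings(aicc(rss, n, k)))
}

#' Rank nested models by corrected AIC
#'
#' Orders a set of [model_fit_stats()] rows (all computed on the same data,
#' hence the same `n`) by ascending AICc; exact ties go to the model with
#' fewer parameters.
#'
#' @param stats A data frame of [model_fit_stats()] rows.
#'
#' @return The same rows, reordered, with a `rank` column prepended.
#' @export
rank_models <- function(stats) {
  if (length(unique(stats$n)) != 1) {
    stop("model statistics come from different data (mixed n)", call. = FALSE)
  }
  ord <- order(stats$aicc, stats$k)
  out <- stats[ord, ]
  dplyr::bind_cols(tibble::tibble(rank = seq_len(nrow(out))), out)
}

#' Spearman rank correlation of two scalar maps
#'
#' @param map_a,map_b Numeric arrays on the same grid.
#' @param mask Optional array (> 0 selects voxels).
#'
#' @return A list with `rho` and `n` (paired finite voxels used). Constant
#'   input yields `rho = NA` with a warning.
#' @export
spearman_map_correlation <- function(map_a, map_b, mask = NULL) {
  if (!identical(dim(map_a), dim(map_b))) {
    stop("maps must share one grid", call. = FALSE)
  }
  a <- as.vector(map_a)
  b <- as.vector(map_b)
  keep <- is.finite(a) & is.finite(b)
  if (!is.null(mask)) {
    if (!identical(dim(mask), dim(map_a))) stop("mask grid mismatch", call. = FALSE)
    keep <- keep & as.vector(mask > 0)
  }
  a <- a[keep]
  b <- b[keep]
  if (length(a) < 3) stop("need at least 3 paired finite voxels", call. = FALSE)
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    warning("constant map: Spearman correlation undefined")
    return(list(rho = NA_real_, n = length(a)))
  }
  list(rho = stats::cor(a, b, method = "spearman"), n = length(a))
}

#' Coefficient of variation
#'
#' `100 * sd(x) / mean(x)` with the sample (n - 1) standard deviation; the
#' precision measure of the recovery study.
#'
#' @param x Numeric samples, at least 2.
#'
#' @return CV in percent; `NaN` when the mean is zero.
#' @examples
#' coefficient_of_variation(c(1, 3))  # 70.71
#' @export
coefficient_of_variation <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 2) stop("need at least 2 samples", call. = FALSE)
  m <- mean(x)
  if (m == 0) {
    return(NaN)
  }
  100 * stats::sd(x) / m
}
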