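#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a single-decay fit
#'
#' @param x A `dwi_fit` from [fit_sequential()] or [fit_simultaneous()].
#' @param ... Unused.
#'
#' @return Tibble with one row per parameter: `parameter`, `estimate`,
#'   `lower`, `upper` (the fit bounds), `clipped` and whether the parameter
#'   was free in the fitted model.
#' @export
tidy.dwi_fit <- function(x, ...) {
  free <- model_free_params(x$model)
  tibble::tibble(parameter = names(x$params),
                 estimate = unname(x$params),
                 lower = unname(x$bounds$lower[names(x$params)]),
                 upper = unname(x$bounds$upper[names(x$params)]),
                 clipped = unname(x$clipped[names(x$params)]),
                 free = names(x$params) %in% free)
}

#' One-row fit summary
#'
#' @param x A `dwi_fit`.
#' @param ... Unused.
#'
#' @return Tibble with `method`, `model`, `rss`, `rmse`, `aicc`, `n_points`,
#'   `converged`, `n_evals`.
#' @export
glance.dwi_fit <- function(x, ...) {
  k <- length(model_free_params(x$model))
  tibble::tibble(method = x$method, model = x$model, rss = x$rss,
                 rmse = sqrt(x$rss / x$n_points),
                 aicc = if (is.na(x$rss)) NA_real_
                        else suppressWarnings(aicc(x$rss, x$n_points, k)),
                 n_points = x$n_points, converged = x$converged,
                 n_evals = x$n_evals)
}

#' @export
tidy.roi_fit <- function(x, ...) x$stats

#' @export
glance.roi_fit <- function(x, ...) {
  best <- rank_models(x$stats)
  tibble::tibble(n_voxels = x$n_voxels, n_models = nrow(x$stats),
                 best_model = best$model_id[1], best_aicc = best$aicc[1])
}

#' @export
tidy.recovery_study <- function(x, ...) x$summary

#' Plot a fitted decay
#'
#' Normalised signal (points) with the fitted model curve, on a log scale.
#'
#' @param object A `dwi_fit` carrying its decay data.
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.dwi_fit <- function(object, ...) {
  if (is.null(object$decay)) stop("fit carries no decay data", call. = FALSE)
  bgrid <- seq(min(object$decay$b), max(object$decay$b), length.out = 200)
  curve <- tibble::tibble(b = bgrid, signal = predict(object, bgrid))
  ggplot2::ggplot(object$decay, ggplot2::aes(x = .data$b, y = .data$signal)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "b (s/mm^2)", y = "S(b)/S(0)",
                  title = sprintf("%s fit, %s model", object$method, object$model))
}

#' Plot a recovery study
#'
#' Coefficient of variation versus SNR, one panel per parameter, coloured by
#' fitter and faceted over tissue classes when several are present.
#'
#' @param object A `recovery_study`.
#' @param metric Column of the summary to plot (default `"cv"`).
#' @param ... Unused.
#'
#' @return A ggplot object.
#' @export
autoplot.recovery_study <- function(object, metric = "cv", ...) {
  s <- object$summary
  p <- ggplot2::ggplot(s, ggplot2::aes(x = .data$snr, y = .data[[metric]],
                                       colour = .data$fitter)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "SNR", y = toupper(metric))
  if (length(unique(s$tissue)) > 1) {
    p + ggplot2::facet_grid(ggplot2::vars(.data$tissue),
                            ggplot2::vars(.data$parameter), scales = "free_y")
  } else {
    p + ggplot2::facet_wrap(ggplot2::vars(.data$parameter), scales = "free_y")
  }
}
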