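#' b-value schemes
#'
#' A b-value scheme is the set of diffusion weightings (in s/mm^2) at which a
#' decay curve is sampled. `b_scheme()` validates a numeric vector of
#' weightings; `trace_scheme()` returns the 16-b-value scheme of the fast
#' trace-based protocol (0 to 3000 s/mm^2), which is the default everywhere in
#' the package.
#'
#' @param values Numeric vector of b-values in s/mm^2. Must be non-negative
#'   and free of duplicates. The input ordering is preserved.
#' @param require_b0 If `TRUE` (default), the scheme must contain b = 0 so
#'   that decays can be normalised by S(0).
#'
#' @return A numeric vector of class `b_scheme`.
#' @examples
#' trace_scheme()
#' b_scheme(c(0, 200, 1000))
#' @export
b_scheme <- function(values, require_b0 = TRUE) {
  values <- as.numeric(values)
  if (length(values) == 0 || anyNA(values)) {
    stop("b-values must be a non-empty numeric vector without NA", call. = FALSE)
  }
  if (any(values < 0)) {
    stop("b-values must be non-negative (s/mm^2)", call. = FALSE)
  }
  if (anyDuplicated(values)) {
    stop("duplicate b-values are not allowed in a scheme", call. = FALSE)
  }
  if (require_b0 && !any(values == 0)) {
    stop("scheme must contain b = 0 for S(0) normalisation", call. = FALSE)
  }
  structure(values, class = c("b_scheme", "numeric"))
}

#' @rdname b_scheme
#' @export
trace_scheme <- function() {
  b_scheme(c(0, 50, 100, 200, 300, 500, 700, 1000, 1200, 1500,
             1800, 2000, 2200, 2500, 2700, 3000))
}

#' @export
print.b_scheme <- function(x, ...) {
  cat("<b_scheme>", length(x), "b-values (s/mm^2):", paste(sort(unclass(x)), collapse = ", "), "\n")
  invisible(x)
}
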