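#' Nelder-Mead simplex minimiser with an explicit initial step
#'
#' A plain Nelder-Mead implementation (reflection 1, expansion 2, contraction
#' 0.5, shrink 0.5) used by the constrained fitting routines. Unlike
#' [stats::optim()], the initial simplex is built with an absolute step in
#' every coordinate, so starts at or near zero (which arise naturally on the
#' unconstrained logit scale used by the bounded fits) still span a
#' non-degenerate simplex.
#'
#' Termination requires both the coordinate spread and the function-value
#' spread of the simplex to fall below their tolerances, mirroring the
#' classical simplex stopping rule.
#'
#' @param fn Objective function of a numeric vector.
#' @param x0 Numeric start vector.
#' @param step Absolute initial simplex step added to each coordinate.
#' @param maxeval Maximum number of objective evaluations.
#' @param ftol Function-value spread tolerance (relative to `|f_best|`).
#' @param xtol Coordinate spread tolerance (absolute).
#'
#' @return List with `par`, `value`, `evals` and `converged`.
#' @examples
#' nm_minimize(function(x) sum((x - c(1, 2))^2), c(0, 0))$par
#' @export
nm_minimize <- function(fn, x0, step = 0.5, maxeval = 2000,
                        ftol = 1e-10, xtol = 1e-8) {
  n <- length(x0)
  sx <- matrix(rep(as.numeric(x0), n + 1), nrow = n + 1, byrow = TRUE)
  for (i in seq_len(n)) sx[i + 1, i] <- sx[i + 1, i] + step
  fv <- apply(sx, 1, fn)
  ne <- n + 1
  repeat {
    o <- order(fv)
    sx <- sx[o, , drop = FALSE]
    fv <- fv[o]
    xspread <- max(abs(sweep(sx[-1, , drop = FALSE], 2, sx[1, ])))
    fspread <- fv[n + 1] - fv[1]
    if (xspread < xtol && fspread <= ftol * (abs(fv[1]) + ftol)) {
      return(list(par = sx[1, ], value = fv[1], evals = ne, converged = TRUE))
    }
    if (ne >= maxeval) {
      return(list(par = sx[1, ], value = fv[1], evals = ne, converged = FALSE))
    }
    ctr <- colMeans(sx[seq_len(n), , drop = FALSE])
    xr <- ctr + (ctr - sx[n + 1, ])
    fr <- fn(xr)
    ne <- ne + 1
    if (fr < fv[1]) {
      xe <- ctr + 2 * (ctr - sx[n + 1, ])
      fe <- fn(xe)
      ne <- ne + 1
      if (fe < fr) {
        sx[n + 1, ] <- xe
        fv[n + 1] <- fe
      } else {
        sx[n + 1, ] <- xr
        fv[n + 1] <- fr
      }
    } else if (fr < fv[n]) {
      sx[n + 1, ] <- xr
      fv[n + 1] <- fr
    } else {
      xc <- if (fr < fv[n + 1]) ctr + 0.5 * (xr - ctr) else ctr + 0.5 * (sx[n + 1, ] - ctr)
      fc <- fn(xc)
      ne <- ne + 1
      if (fc < min(fr, fv[n + 1])) {
        sx[n + 1, ] <- xc
        fv[n + 1] <- fc
      } else {
        for (i in 2:(n + 1)) {
          sx[i, ] <- sx[1, ] + 0.5 * (sx[i, ] - sx[1, ])
          fv[i] <- fn(sx[i, ])
        }
        ne <- ne + n
      }
    }
  }
}

# logistic map between the unconstrained optimiser scale and a box
logit_to_box <- function(t, lower, upper) lower + (upper - lower) / (1 + exp(-t))

box_to_logit <- function(p, lower, upper, margin = 0.02) {
  z <- (p - lower) / (upper - lower)
  z <- pmin(pmax(z, margin), 1 - margin)
  log(z / (1 - z))
}
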