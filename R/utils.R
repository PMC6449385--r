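#' Rescale a numeric vector to the unit interval
#'
#' Predictors entering the behavioral GLM and the sliding single-trial
#' regression are standardized to \[0, 1\] so that coefficients are
#' comparable across variables with different natural ranges. A constant
#' vector is returned as all zeros (its range is degenerate and it carries
#' no information for regression).
#'
#' @param x numeric vector.
#' @return list with `x` (rescaled values) and `range` (max - min in
#'   natural units; 1 for constant input), so coefficients can be
#'   back-transformed by dividing by `range`.
#' @keywords internal
standardize01 <- function(x) {
  x <- as.numeric(x)
  rng <- max(x) - min(x)
  if (!is.finite(rng) || rng == 0) {
    return(list(x = rep(0, length(x)), range = 1))
  }
  list(x = (x - min(x)) / rng, range = rng)
}

#' Trapezoidal integral over an irregular grid
#' @param t time axis (s), strictly increasing.
#' @param y values at `t`.
#' @return scalar integral.
#' @keywords internal
trapz_int <- function(t, y) {
  stopifnot(length(t) == length(y), length(t) >= 2)
  sum(diff(t) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
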