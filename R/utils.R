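#' Round half away from zero
#'
#' Commercial ("half-up") rounding, as used for reported percentages.
#' `round()` in R rounds half to even, which would turn 23.5 into 24 or 22.5
#' into 22; reported shares use the conventional half-up rule instead.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places to keep.
#' @return numeric vector rounded half-up.
#' @export
#' @examples
#' round_half_up(c(0.5, 1.5, 2.45), 0)
round_half_up <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Relative abundances of a count vector
#'
#' @param x nonnegative numeric vector with at least one positive entry.
#' @return `x / sum(x)`, names preserved.
#' @export
rel_abund <- function(x) {
  if (any(x < 0)) stop("negative abundances")
  s <- sum(x)
  if (s <= 0) stop("all-zero abundance vector")
  x / s
}

## is q numerically at the Shannon limit?
is_q_one <- function(q) abs(q - 1) < 1e-8

## generalized mean-power backtransform shared by all Hill-type measures:
## value = A^(1/(1-q)) for q != 1, with the caller supplying the Shannon-limit
## branch separately.
pow_back <- function(A, q) A^(1 / (1 - q))
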