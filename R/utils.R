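## Shared numerical helpers and seeding.

#' Derive a child seed from a master seed
#'
#' All stochastic stages of the pipeline are seeded with deterministic
#' children of one master seed, so that a single integer reproduces a full
#' run while stages remain independently re-runnable.
#'
#' @param seed master seed (integer).
#' @param k stage index (small non-negative integer), one per stochastic
#'   component.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
child_seed <- function(seed, k = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  m <- 2147483647 # 2^31 - 1, Mersenne prime modulus
  s <- (abs(as.numeric(seed)) %% m)
  # two rounds of a Lehmer-style mix keep children of nearby masters apart
  s <- (s * 48271 + as.numeric(k) * 2246822519 + 1013904223) %% m
  s <- (s * 48271 + 12345) %% m
  as.integer(s)
}

#' Trapezoidal integral on an arbitrary grid
#' @param x grid (strictly increasing).
#' @param y values at `x`.
#' @return the trapezoidal approximation of the integral.
#' @keywords internal
trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

## Uniform time axis for a sampled trace object (list with values/rate_hz/t0_s)
trace_times <- function(obj) {
  obj$t0_s + (seq_along(obj$values) - 1) / obj$rate_hz
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Contract checks with short classed errors
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
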