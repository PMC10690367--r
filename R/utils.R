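# Shared numerical helpers: discrete convolutions, integration, seeds.

#' Causal discrete convolution on a uniform grid
#'
#' Rectangle-rule discretization of \eqn{(x \ast y)(t) = \int_0^t x(\tau)
#' y(t-\tau) d\tau}: \code{out[i] = dt * sum_j x[j] y[i-j+1]}, truncated to the
#' input length. This is the quadrature used by the tissue forward model,
#' where it keeps the unit-impulse identity exact (an impulse of area 1,
#' i.e. a single sample of value \code{1/dt}, convolves to the other factor
#' unchanged).
#'
#' @param x,y numeric vectors of equal length, samples on a uniform grid.
#' @param dt grid spacing in seconds.
#' @return numeric vector of the same length as \code{x}.
#' @keywords internal
conv_rect <- function(x, y, dt) {
  n <- length(x)
  stopifnot(length(y) == n, dt > 0)
  convolve(x, rev(y), type = "open")[seq_len(n)] * dt
}

#' Trapezoid-corrected causal discrete convolution
#'
#' Same integral as [conv_rect()] but with trapezoidal end-point weights, so
#' that convolution with a constant kernel reproduces [cumtrapz_dt()] exactly.
#' Used throughout the leakage module: the bidirectional kernel
#' \eqn{e^{-K_{ep} t}} then degenerates at \eqn{K_{ep} = 0} to the
#' trapezoidal running integral of the unidirectional model, making the
#' nesting of the two exchange models exact rather than approximate.
#'
#' @inheritParams conv_rect
#' @keywords internal
conv_trapz <- function(x, y, dt) {
  n <- length(x)
  full <- convolve(x, rev(y), type = "open")[seq_len(n)] * dt
  # subtract half of the two end-point rectangle contributions
  full - (dt / 2) * (x[1] * y + x * y[1])
}

#' Cumulative trapezoidal integral on a uniform grid
#' @param x numeric vector of samples.
#' @param dt grid spacing in seconds.
#' @return vector of running integrals, same length, starting at 0.
#' @keywords internal
cumtrapz_dt <- function(x, dt) {
  n <- length(x)
  if (n == 1L) return(0)
  c(0, cumsum((x[-n] + x[-1]) / 2)) * dt
}

#' Trapezoidal integral over an index window
#' @keywords internal
trapz_dt <- function(x, dt) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-n] + x[-1]) / 2) * dt
}

# Run code under a fixed RNG state, restoring the caller's state afterwards.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Derive a stream-specific child seed from a global seed; keeps results
# reproducible per stage while decoupling the streams. Stays below 2^31.
derive_seed <- function(seed, stream) {
  offsets <- c(phantom = 1000L, cohort = 2000L, fold = 3000L, smote = 4000L,
               sampler = 5000L, noise = 6000L)
  stopifnot(stream %in% names(offsets))
  (as.integer(seed) %% 2000000000L) + offsets[[stream]]
}
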