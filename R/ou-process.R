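# Mean-reverting (Ornstein-Uhlenbeck-type) confinement process.
#
# Confined motion of a focus about its home point is modelled as a stationary
# mean-reverting Gaussian process with stationary SD `sigma` and correlation
# time `tau`. The exact discrete update over a step `dt` is
#   x[t+dt] = x[t] * exp(-dt/tau) + N(0, sigma^2 * (1 - exp(-2*dt/tau)))
# which is free of time-step bias at any sampling interval, so the 1-min frame
# grid and the 1-s doublet offsets can be simulated with the same recursion.

#' Stationary mean-reverting displacement SD over a lag
#'
#' For the stationary mean-reverting confinement process with stationary SD
#' `sigma` and correlation time `tau`, the displacement between two samples a
#' lag `dt` apart has SD `sigma * sqrt(2 * (1 - exp(-dt / tau)))`. At
#' `dt >> tau` this saturates at `sqrt(2) * sigma`, which is the RMSD plateau
#' the analysis recovers; at the 1-s doublet lag it is the per-axis
#' short-time-scale step SD.
#'
#' @param sigma Stationary positional SD (um).
#' @param tau Correlation time (min).
#' @param dt Lag (min); the 1-s doublet lag is `1/60`.
#' @return Displacement SD in um.
#' @export
ou_step_sd <- function(sigma, tau, dt) {
  stopifnot(sigma >= 0, tau > 0, dt >= 0)
  sigma * sqrt(2 * (1 - exp(-dt / tau)))
}

# Simulate the process at arbitrary (sorted, possibly irregular) times.
# Starts from stationarity; returns fluctuations about zero.
ou_simulate <- function(times, sigma, tau, x0 = NULL) {
  n <- length(times)
  if (n == 0L) return(numeric(0))
  if (sigma < 0) abort("confinement SD must be >= 0")
  if (tau <= 0) abort("correlation time must be > 0")
  x <- numeric(n)
  x[1] <- if (is.null(x0)) rnorm(1, 0, sigma) else x0
  if (n > 1L) {
    dt <- diff(times)
    if (any(dt < 0)) abort("times must be non-decreasing")
    decay <- exp(-dt / tau)
    innov_sd <- sigma * sqrt(pmax(0, 1 - decay^2))
    eps <- rnorm(n - 1L, 0, 1)
    for (i in seq_len(n - 1L)) {
      x[i + 1L] <- x[i] * decay[i] + innov_sd[i] * eps[i]
    }
  }
  x
}

# One-step offshoot update used for 1-s doublet frames: conditional draw of the
# process a lag dt after a known value, without advancing the main grid.
ou_offshoot <- function(x, sigma, tau, dt) {
  decay <- exp(-dt / tau)
  x * decay + rnorm(length(x), 0, sigma * sqrt(max(0, 1 - decay^2)))
}
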