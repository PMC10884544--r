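#' Rician noise specification
#'
#' Magnitude-MRI noise: the observed signal is the magnitude of a complex
#' Gaussian perturbation of the true signal. The noise scale is anchored to
#' the b = 0, TE = 0 signal: `sigma = s0 / snr`. For the normalised
#' two-compartment model `s0 = 1`.
#'
#' @param snr Signal-to-noise ratio on the b = 0, TE = 0 signal (> 0).
#' @param s0 Reference signal amplitude (default 1, the normalised model).
#' @return An object of class `noise_spec` with fields `snr` and `sigma`.
#' @export
#' @examples
#' noise_spec(100)
noise_spec <- function(snr = 100, s0 = 1) {
  stopifnot(is.numeric(snr), length(snr) == 1L)
  if (snr <= 0) abort("`snr` must be > 0.")
  structure(list(snr = snr, sigma = s0 / snr), class = "noise_spec")
}

#' Add Rician noise to signals
#'
#' Returns `sqrt((S + e1)^2 + e2^2)` with `e1`, `e2` independent zero-mean
#' Gaussians of standard deviation `sigma`. Draws from the current RNG
#' stream; set the seed beforehand for reproducibility.
#'
#' @param signals Non-negative numeric vector of noiseless signals.
#' @param noise A [noise_spec()], or a single non-negative `sigma`.
#' @return Noisy signals (always >= 0, same length as `signals`).
#' @export
#' @examples
#' set.seed(1)
#' add_rician(c(1, 0.5), noise_spec(100))
add_rician <- function(signals, noise) {
  sigma <- if (inherits(noise, "noise_spec")) noise$sigma else noise
  stopifnot(is.numeric(sigma), length(sigma) == 1L)
  if (sigma < 0) abort("`sigma` must be >= 0.")
  if (any(signals < 0)) abort("`signals` must be >= 0.")
  if (sigma == 0) return(signals)
  n <- length(signals)
  sqrt((signals + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}
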