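#' Simulated Wiener process (Brownian path)
#'
#' Cumulative sum of i.i.d. Gaussian increments starting at 0; the standard
#' rough test input for scale-space smoothing, containing structure at all
#' temporal scales.
#'
#' @param length number of samples (>= 1).
#' @param seed integer seed; the generator is a pure function of
#'   `(length, seed, step_sd)`.
#' @param step_sd standard deviation of the increments (default 1).
#' @return A tibble with columns `time` (0-based) and `value`.
#' @export
wiener_process <- function(length, seed = 1L, step_sd = 1) {
  if (length < 1) abort("`length` must be >= 1", class = "tcss_invalid_parameter")
  withr::with_seed(seed, {
    tibble(time = seq_len(length) - 1,
           value = cumsum(c(0, rnorm(length - 1, sd = step_sd))))
  })
}

#' Frequency-varying sine wave
#'
#' \eqn{f(t) = \sin(\exp((b-t)/a))} evaluated at integer t: the wavelength
#' increases with time, sweeping the local frequency downward. The defaults
#' `a = 200`, `b = 1000` give an audio-like chirp over a few thousand
#' samples. The exponent is clamped to avoid overflow far before `b`.
#'
#' @param length number of samples.
#' @param a sweep time constant (> 0).
#' @param b sweep reference time.
#' @return A tibble with columns `time`, `value`.
#' @export
varying_frequency_sine <- function(length, a = 200, b = 1000) {
  if (a <= 0) abort("`a` must be positive", class = "tcss_invalid_parameter")
  t <- seq_len(length) - 1
  tibble(time = t, value = sin(exp(pmin((b - t) / a, 700))))
}

#' Two-peak test signal from limit-kernel events
#'
#' The sum of two discrete limit-kernel approximations (unit mass each) at
#' temporal scales `tau1` and `tau2`, separated by `delay` samples, plus
#' white Gaussian noise: a signal containing one fine-scale and one
#' coarse-scale event, used to exercise scale-normalized derivative
#' responses across scales.
#'
#' @param length number of samples.
#' @param tau1,tau2 scales of the two events (defaults 16 and 256).
#' @param delay onset separation in samples (default 16 standard deviations
#'   of the coarser event, which separates the responses cleanly).
#' @param noise_sd noise standard deviation; default 1 percent of the
#'   noise-free peak height.
#' @param seed integer seed for the noise.
#' @param c distribution parameter of the event kernels (default 2).
#' @param K cascade depth of the kernel approximations.
#' @return A tibble with columns `time`, `value`.
#' @export
two_peak_signal <- function(length = 2048, tau1 = 16, tau2 = 256,
                            delay = NULL, noise_sd = NULL, seed = 1L,
                            c = 2, K = 8L) {
  if (length < 8) abort("`length` too short", class = "tcss_invalid_parameter")
  if (is.null(delay)) delay <- round(16 * sqrt(tau2))
  base <- numeric(length)
  onset <- c(1L, 1L + as.integer(delay))
  for (i in 1:2) {
    tau <- c(tau1, tau2)[i]
    h <- impulse_responses(scale_layout(tau, c = c, K = K),
                           mass_tol = 1e-12)[, K]
    idx <- onset[i]:min(length, onset[i] + base::length(h) - 1L)
    base[idx] <- base[idx] + h[seq_along(idx)]
  }
  if (is.null(noise_sd)) noise_sd <- 0.01 * max(base)
  withr::with_seed(seed, {
    tibble(time = seq_len(length) - 1,
           value = base + rnorm(length, sd = noise_sd))
  })
}

#' Temporal rescaling by integer subsampling
#'
#' Realizes the temporal scaling transformation \eqn{t' = t/S} by keeping
#' every S-th sample. Subsampling (rather than interpolation, which is
#' ill-defined for discrete signals) is the route used for the scale
#' covariance harness: the representation of the subsampled signal at scale
#' \eqn{\tau/S^2} matches the subsampled representation of the original at
#' scale \eqn{\tau}.
#'
#' @param f signal (vector or data frame).
#' @param S integer subsampling factor (>= 2).
#' @return A tibble with columns `time` (new sample index) and `value`.
#' @export
rescale_signal <- function(f, S) {
  if (S < 2 || S != round(S))
    abort("`S` must be an integer >= 2", class = "tcss_invalid_parameter")
  x <- signal_values(f)
  v <- x[seq(1L, length(x), by = as.integer(S))]
  tibble(time = seq_along(v) - 1, value = v)
}
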