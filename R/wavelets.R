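# causal discrete convolution y[t] = sum_{u>=0} ker[u+1] x[t-u], zero-extended
causal_convolve <- function(x, ker) {
  L <- length(ker)
  xp <- c(numeric(L - 1), x)
  y <- stats::filter(xp, ker, method = "convolution", sides = 1)
  as.numeric(y[L:(L + length(x) - 1)])
}

# order-n difference kernel of a smoothing kernel h (backward-aligned, as a
# convolution kernel: delta_t^n h with implicit zeros before the support)
derivative_kernel <- function(h, n) diff(c(numeric(n), h), differences = n)

#' Materialize a time-causal wavelet kernel
#'
#' The order-`n` temporal difference of the discrete limit-kernel
#' approximation (a cascade of `K_trunc` recursive filters), divided by its
#' `l1` or `l2` norm. The result integrates to zero (up to the truncated tail
#' mass) and has finite l1 and l2 norms, so it can serve as a mother wavelet
#' over a time-causal domain; an order-1 kernel has exactly one sign change.
#'
#' @param n derivative order (>= 1; order 0 is not zero-mean).
#' @param tau temporal scale (variance, > 0).
#' @param c distribution parameter (> 1).
#' @param norm `"l1"` (default; the scale-space convention, matching
#'   scale-normalized derivatives with gamma = 1) or `"l2"` (the wavelet
#'   convention).
#' @param K_trunc cascade depth of the limit-kernel approximation.
#' @param mass_tol truncation tolerance of the impulse response.
#' @return Numeric kernel, value at lag u in element u + 1.
#' @export
wavelet_kernel <- function(n, tau, c, norm = c("l1", "l2"),
                           K_trunc = 8L, mass_tol = 1e-12) {
  norm <- match.arg(norm)
  if (n < 1 || n != round(n))
    abort("`n` must be a positive integer (order 0 is not zero-mean)",
          class = "tcss_invalid_parameter")
  layout <- scale_layout(tau, c = c, K = K_trunc)
  h <- impulse_responses(layout, mass_tol = mass_tol)[, K_trunc]
  dk <- derivative_kernel(h, n)
  dk / discrete_lp_norm(dk, if (norm == "l1") 1 else 2)
}

#' Bank of time-causal wavelets on a geometric scale grid
#'
#' Builds the materialized kernels and normalization constants for wavelet
#' scales \eqn{\tau_j = c^{2j} \tau_0}, j = 0..J-1 (child-wavelet scale
#' factors \eqn{a = c^j}). All scales live on one logarithmic cascade layout,
#' so the transform can be computed time-recursively.
#'
#' @param n derivative order of the mother wavelet.
#' @param tau0 finest wavelet scale (> 0).
#' @param c distribution parameter; the scale grid ratio is `c^2`.
#' @param J number of scales.
#' @param norm kernel normalization, `"l1"` or `"l2"`.
#' @param K_base cascade stages below the finest wavelet scale.
#' @param mass_tol impulse-response truncation tolerance.
#' @return An object of class `wavelet_bank`.
#' @export
wavelet_bank <- function(n, tau0, c = 2, J = 4, norm = c("l1", "l2"),
                         K_base = 8L, mass_tol = 1e-12) {
  norm <- match.arg(norm)
  if (n < 1 || n != round(n))
    abort("`n` must be a positive integer", class = "tcss_invalid_parameter")
  scales <- c^(2 * (0:(J - 1))) * tau0
  K <- K_base + J - 1L
  layout <- scale_layout(max(scales), c = c, K = K)
  levels <- (K_base):(K)  # layout levels carrying the bank scales
  stopifnot(max(abs(layout$tau[levels] - scales) / scales) < 1e-9)
  imp <- impulse_responses(layout, mass_tol = mass_tol)
  kernels <- lapply(levels, function(k) derivative_kernel(imp[, k], n))
  norms <- vapply(kernels, discrete_lp_norm, numeric(1),
                  p = if (norm == "l1") 1 else 2)
  structure(list(n = n, scales = scales, c = c, J = J, norm = norm,
                 layout = layout, levels = levels,
                 kernels = Map(`/`, kernels, norms), norms = norms),
            class = "wavelet_bank")
}

#' @export
print.wavelet_bank <- function(x, ...) {
  cat(sprintf("<wavelet_bank: order %d, %d scales tau = %s, c = %g, %s-normalized>\n",
              x$n, x$J, paste(signif(x$scales, 4), collapse = ", "), x$c, x$norm))
  invisible(x)
}

#' Time-causal wavelet transform
#'
#' Expands a signal onto the child wavelets of a [wavelet_bank()]. The
#' `"recursive"` route computes the coefficients inside the scale-space
#' algebra: one pass of the recursive-filter cascade, temporal differences,
#' and division by the per-scale kernel norm — no convolution buffers. The
#' `"direct"` route convolves with the materialized kernels and is the
#' cross-check oracle; the two agree to the kernel truncation error.
#'
#' @param f signal (vector or data frame; zero-extended into the past).
#' @param bank a [wavelet_bank()].
#' @param method `"recursive"` (default) or `"direct"`.
#' @return A tibble with columns `time`, `scale` (tau), `a` (scale factor
#'   \eqn{c^j}) and `coef`.
#' @export
wavelet_transform <- function(f, bank, method = c("recursive", "direct")) {
  stopifnot(inherits(bank, "wavelet_bank"))
  method <- match.arg(method)
  x <- signal_values(f)
  tt <- signal_times(f)
  W <- if (method == "recursive") {
    d <- temporal_derivative(scale_space(x, bank$layout, init = "zero"), bank$n)
    sweep(d$L[, bank$levels, drop = FALSE], 2L, bank$norms, `/`)
  } else {
    vapply(bank$kernels, causal_convolve, x = x, numeric(length(x)))
  }
  tibble(time = rep(tt, bank$J),
         scale = rep(bank$scales, each = length(x)),
         a = rep(bank$c^(0:(bank$J - 1)), each = length(x)),
         coef = as.vector(W))
}

#' Complex-valued extension of the time-causal limit kernel
#'
#' \eqn{\chi(t, \omega) = \Psi(t; \tau, c)\, e^{i\omega t}}: a time-causal
#' analogue of the Gabor function, with the limit kernel as the causal
#' envelope (so \eqn{|\chi| = \Psi} for every frequency, and \eqn{\chi = \Psi}
#' at \eqn{\omega = 0}).
#'
#' @param t evaluation times.
#' @param omega angular frequency (radians per time unit).
#' @inheritParams limit_kernel
#' @return Complex values.
#' @export
complex_kernel <- function(t, omega, tau, c, K_trunc = 24L) {
  limit_kernel(t, tau, c, K_trunc) * exp(1i * omega * t)
}

#' Logarithmically spaced angular-frequency grid
#'
#' @param n number of frequencies.
#' @param omega_min,omega_max grid limits (radians per sample, in (0, pi]).
#' @param spacing `"log"` (default, matching the scale-covariance structure)
#'   or `"linear"`.
#' @return Numeric vector of angular frequencies.
#' @export
omega_grid <- function(n = 16, omega_min = 0.02 * pi, omega_max = 0.9 * pi,
                       spacing = c("log", "linear")) {
  spacing <- match.arg(spacing)
  if (n < 1 || omega_min <= 0 || omega_max <= omega_min)
    abort("invalid frequency grid", class = "tcss_invalid_parameter")
  if (spacing == "log") exp(seq(log(omega_min), log(omega_max), length.out = n))
  else seq(omega_min, omega_max, length.out = n)
}

new_spectrogram <- function(S, omega, tau, c, time, compensated) {
  structure(list(S = S, omega = omega, tau = tau, c = c, time = time,
                 compensated = compensated),
            class = "spectrogram")
}

#' Time-causal windowed Fourier transform (spectrogram)
#'
#' \deqn{S(t, \omega) = \sum_{u \ge 0} f(t-u)\, \Psi(u; \tau, c)\, e^{i\omega u},}
#' with the discrete limit-kernel approximation as the causal window. For a
#' constant signal, \eqn{|S(\cdot, \omega)|} equals the magnitude of the
#' kernel's Fourier transform at \eqn{\omega}.
#'
#' @param f signal (vector or data frame; zero-extended into the past).
#' @param omega angular frequencies (radians per sample), e.g. [omega_grid()].
#' @param tau window scale (variance, > 0).
#' @param c distribution parameter.
#' @param K cascade depth of the window approximation.
#' @param mass_tol window truncation tolerance.
#' @return An object of class `spectrogram` holding the complex T x length(omega)
#'   matrix `S`; see [tidy.spectrogram()].
#' @export
windowed_transform <- function(f, omega, tau, c = 2, K = 8L,
                               mass_tol = 1e-10) {
  if (length(omega) == 0L)
    abort("empty frequency grid", class = "tcss_invalid_parameter")
  x <- signal_values(f)
  psi <- impulse_responses(scale_layout(tau, c = c, K = K),
                           mass_tol = mass_tol)[, K]
  u <- seq_along(psi) - 1
  S <- vapply(omega, function(w) {
    kw <- psi * exp(1i * w * u)
    complex(real = causal_convolve(x, Re(kw)),
            imaginary = causal_convolve(x, Im(kw)))
  }, complex(length(x)))
  new_spectrogram(S, omega, tau, c, signal_times(f), compensated = TRUE)
}

#' Time-recursive spectrogram
#'
#' Computes the time-causal spectrogram by demodulation: the input is
#' multiplied by \eqn{e^{-i\omega t}} and the real and imaginary parts are
#' passed through identical real recursive-filter cascades, so the transform
#' is strictly time-recursive. The magnitudes equal those of
#' [windowed_transform()]; with `compensate = TRUE` the output is multiplied
#' by \eqn{e^{+i\omega t}} a posteriori so the phases match as well.
#'
#' @inheritParams windowed_transform
#' @param compensate apply the a-posteriori phase factor (default `TRUE`).
#' @return A `spectrogram` object.
#' @export
recursive_spectrogram <- function(f, omega, tau, c = 2, K = 8L,
                                  compensate = TRUE) {
  if (length(omega) == 0L)
    abort("empty frequency grid", class = "tcss_invalid_parameter")
  x <- signal_values(f)
  layout <- scale_layout(tau, c = c, K = K)
  t <- seq_along(x) - 1
  S <- vapply(omega, function(w) {
    z <- x * exp(-1i * w * t)
    re <- scale_space(Re(z), layout, init = "zero")$L[, K]
    im <- scale_space(Im(z), layout, init = "zero")$L[, K]
    out <- complex(real = re, imaginary = im)
    if (compensate) out * exp(1i * w * t) else out
  }, complex(length(x)))
  new_spectrogram(S, omega, tau, c, signal_times(f), compensated = compensate)
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram: %d samples x %d frequencies, tau = %g, c = %g, %sphase-compensated>\n",
              nrow(x$S), length(x$omega), x$tau, x$c,
              if (x$compensated) "" else "not "))
  invisible(x)
}

#' Long-format view of a spectrogram
#'
#' @param x a `spectrogram`.
#' @param ... unused.
#' @return A tibble with columns `time`, `omega`, `magnitude`, `phase`.
#' @export
tidy.spectrogram <- function(x, ...) {
  tibble(time = rep(x$time, length(x$omega)),
         omega = rep(x$omega, each = nrow(x$S)),
         magnitude = as.vector(Mod(x$S)),
         phase = as.vector(Arg(x$S)))
}
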