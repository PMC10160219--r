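#' Truncated exponential smoothing kernel
#'
#' The unit-area kernel \eqn{h(t; \mu) = e^{-t/\mu}/\mu} for \eqn{t \ge 0} and
#' 0 for \eqn{t < 0}: the only primitive time-causal smoothing kernel that
#' never increases the number of local extrema of a signal. Physically a
#' first-order integrator with time constant \eqn{\mu}.
#'
#' @param t evaluation times (any sign).
#' @param mu time constant (> 0).
#' @return Kernel values, same length as `t`.
#' @export
truncated_exponential <- function(t, mu) {
  if (mu <= 0) abort("`mu` must be positive", class = "tcss_invalid_parameter")
  ifelse(t >= 0, exp(-t / mu) / mu, 0)
}

#' Composed kernel for uniformly distributed scale levels
#'
#' The cascade of `K` truncated exponentials with equal time constants `mu`
#' has the Gamma-type closed form
#' \eqn{h(t) = t^{K-1} e^{-t/\mu} / (\mu^K \Gamma(K))}, with mean
#' \eqn{K\mu} and variance \eqn{K\mu^2}.
#'
#' @param t evaluation times.
#' @param mu common stage time constant (> 0).
#' @param K number of stages (positive integer).
#' @return Kernel values.
#' @export
compose_uniform_kernel <- function(t, mu, K) {
  if (mu <= 0 || K < 1 || K != round(K))
    abort("need mu > 0 and integer K >= 1", class = "tcss_invalid_parameter")
  ifelse(t >= 0, dgamma(t, shape = K, scale = mu), 0)
}

limit_mu <- function(tau, c, K_trunc) c^(-seq_len(K_trunc)) * sqrt(c^2 - 1) * sqrt(tau)

check_limit_params <- function(tau, c) {
  if (tau <= 0) abort("`tau` must be positive", class = "tcss_invalid_parameter")
  if (c <= 1) abort("`c` must be > 1", class = "tcss_invalid_parameter")
}

#' Fourier transform of the time-causal limit kernel
#'
#' Evaluates the finite-product approximation
#' \deqn{\hat\Psi(\omega) = \prod_{k=1}^{K} \frac{1}{1 + i\, c^{-k}\sqrt{c^2-1}\sqrt{\tau}\,\omega}}
#' of the time-causal limit kernel's Fourier transform. The infinite product
#' converges geometrically, so moderate `K_trunc` (default 32) is accurate to
#' near machine precision for ordinary `c`.
#'
#' @param omega angular frequencies (radians per sample), any sign.
#' @param tau temporal scale (variance, > 0).
#' @param c distribution parameter (> 1).
#' @param K_trunc truncation depth of the product (>= 1).
#' @return Complex values; exactly 1 at `omega = 0`.
#' @export
limit_kernel_fourier <- function(omega, tau, c, K_trunc = 32L) {
  check_limit_params(tau, c)
  if (K_trunc < 1) abort("`K_trunc` must be >= 1", class = "tcss_invalid_parameter")
  mu <- limit_mu(tau, c, K_trunc)
  vapply(omega, function(w) prod(1 / (1 + 1i * mu * w)), complex(1))
}

#' Partial-fraction representation of the limit kernel
#'
#' The Laplace transform of the limit kernel, truncated at `K_trunc` stages,
#' decomposes as \eqn{\sum_k A_k / (1 + \mu_k q)} with
#' \eqn{A_k = \prod_{i \ne k} 1/(1 - \mu_i/\mu_k)}. Because the time constants
#' are geometric, \eqn{\mu_i/\mu_k = c^{k-i}} and the coefficients depend only
#' on `c` and `K_trunc`. The coefficients sum to 1 (unit DC gain).
#'
#' @inheritParams limit_kernel_fourier
#' @return A list with elements `mu` (time constants, decreasing... stored in
#'   stage order k = 1..K, i.e. decreasing magnitude), `A` (coefficients) and
#'   `K_trunc`.
#' @export
limit_kernel_partial_fractions <- function(tau, c, K_trunc = 24L) {
  check_limit_params(tau, c)
  if (K_trunc < 2) abort("`K_trunc` must be >= 2", class = "tcss_invalid_parameter")
  mu <- limit_mu(tau, c, K_trunc)
  if (anyDuplicated(mu))
    abort("degenerate decomposition: duplicate time constants",
          class = "tcss_degenerate_decomposition")
  A <- vapply(seq_len(K_trunc), function(k) {
    i <- setdiff(seq_len(K_trunc), k)
    # factors ordered by |1 - c^(k-i)| ascending for a numerically calm product
    f <- 1 / (1 - c^(k - i))
    prod(f[order(abs(1 - c^(k - i)))])
  }, numeric(1))
  list(mu = mu, A = A, K_trunc = K_trunc)
}

#' Time-causal limit kernel in the temporal domain
#'
#' There is no compact closed form for the limit kernel over time; two
#' numerical routes are provided and agree pointwise:
#' \describe{
#'   \item{partial_fraction}{\eqn{\Psi(t) = \sum_k (A_k/\mu_k) e^{-t/\mu_k}}
#'     from [limit_kernel_partial_fractions()]. Fast and grid-free, but the
#'     decomposition is ill-conditioned for `c` close to 1.}
#'   \item{cascade_fft}{numeric convolution of the `K_trunc` stage kernels on
#'     a fine internal grid, evaluated at `t` by linear interpolation.}
#' }
#' For `c` below 1.2 the partial-fraction route falls back to `cascade_fft`.
#'
#' @param t evaluation times (any sign; the kernel is 0 for `t < 0`).
#' @inheritParams limit_kernel_fourier
#' @param method evaluation route; see Details.
#' @param dt internal grid spacing for the `cascade_fft` route.
#' @return Kernel values at `t`.
#' @export
limit_kernel <- function(t, tau, c, K_trunc = 24L,
                         method = c("partial_fraction", "cascade_fft"),
                         dt = NULL) {
  check_limit_params(tau, c)
  method <- match.arg(method)
  if (method == "partial_fraction" && c < 1.2) method <- "cascade_fft"
  if (method == "partial_fraction") {
    pf <- limit_kernel_partial_fractions(tau, c, K_trunc)
    out <- numeric(length(t))
    pos <- t >= 0
    if (any(pos)) {
      tp <- t[pos]
      out[pos] <- colSums(pf$A / pf$mu * exp(-outer(1 / pf$mu, tp)))
    }
    out
  } else {
    mu <- limit_mu(tau, c, K_trunc)
    if (is.null(dt)) dt <- sqrt(tau) / 1024
    t_max <- max(sum(mu) + 14 * sqrt(tau), max(t, 0) + 4 * dt)
    n <- 2^ceiling(log2(t_max / dt + 1))
    grid <- (seq_len(n) - 1) * dt
    # product of the exact stage transforms at the DFT frequencies; the
    # inverse DFT then yields the periodized kernel sampled on the grid
    wfreq <- 2 * pi * (c(0:(n / 2), -(n / 2 - 1):-1)) / (n * dt)
    Hw <- rep(1 + 0i, n)
    for (m in mu) Hw <- Hw / (1 + 1i * m * wfreq)
    psi <- Re(fft(Hw, inverse = TRUE)) / (n * dt)
    out <- approx(grid, psi, xout = pmax(t, 0), rule = 2)$y
    out[t < 0] <- 0
    out
  }
}

#' Skewness and kurtosis of the time-causal limit kernel
#'
#' Closed-form shape statistics as functions of the distribution parameter:
#' skewness \eqn{\gamma_1 = 2(c+1)\sqrt{c^2-1}/(c^2+c+1)} and excess kurtosis
#' \eqn{\gamma_2 = 6(c^2-1)/(c^2+1)}. Both increase monotonically with `c`;
#' as \eqn{c \to \infty} they approach the single-exponential values 2 and 6.
#'
#' @param c distribution parameter (> 1); vectorized.
#' @return A tibble with columns `c`, `gamma1`, `gamma2`.
#' @export
limit_kernel_shape <- function(c) {
  if (any(c <= 1)) abort("`c` must be > 1", class = "tcss_invalid_parameter")
  tibble(c = c,
         gamma1 = 2 * (c + 1) * sqrt(c^2 - 1) / (c^2 + c + 1),
         gamma2 = 6 * (c^2 - 1) / (c^2 + 1))
}

#' Koenderink scale-time kernel
#'
#' Gaussian smoothing applied over a logarithmically remapped past time axis,
#' normalized to unit area:
#' \deqn{h(t; \sigma, \delta) = \frac{1}{\sqrt{2\pi}\,\sigma\,\delta}
#'   \exp\!\left(-\frac{\log^2(t/\delta)}{2\sigma^2} - \frac{\sigma^2}{2}\right), \quad t > 0,}
#' and 0 for \eqn{t \le 0}. `delta` is the temporal delay of the mapping and
#' `sigma` the dimensionless log-domain width.
#'
#' @param t evaluation times.
#' @param sigma log-domain width (> 0).
#' @param delta temporal delay (> 0).
#' @return Kernel values.
#' @export
koenderink_kernel <- function(t, sigma, delta) {
  if (sigma <= 0 || delta <= 0)
    abort("need sigma > 0 and delta > 0", class = "tcss_invalid_parameter")
  out <- numeric(length(t))
  pos <- t > 0
  out[pos] <- exp(-log(t[pos] / delta)^2 / (2 * sigma^2) - sigma^2 / 2) /
    (sqrt(2 * pi) * sigma * delta)
  out
}

#' Generalized ex-Gaussian kernel
#'
#' The convolution of an unnormalized Gaussian with an unnormalized truncated
#' exponential, plus a DC offset:
#' \deqn{h(t) = a_0 + a_1 \int_0^\infty e^{-(t-m-u)^2/(2\sigma^2)}\, e^{-u/\mu}\, du.}
#' Evaluated in closed form through the complementary error function; relative
#' to the unit-area exponentially modified Gaussian density the integral term
#' is scaled by \eqn{\sqrt{2\pi}\,\sigma\,\mu}. As \eqn{t \to -\infty} the
#' value tends to `a0`.
#'
#' @param t evaluation times.
#' @param mu exponential time constant (> 0).
#' @param sigma Gaussian width (> 0).
#' @param m Gaussian position.
#' @param a0 DC offset (default 0).
#' @param a1 amplitude (> 0, default 1).
#' @return Kernel values.
#' @export
ex_gaussian <- function(t, mu, sigma, m, a0 = 0, a1 = 1) {
  if (mu <= 0 || sigma <= 0 || a1 <= 0)
    abort("need mu > 0, sigma > 0, a1 > 0", class = "tcss_invalid_parameter")
  a0 + a1 * sqrt(pi / 2) * sigma *
    exp((sigma^2 - 2 * mu * (t - m)) / (2 * mu^2)) *
    erfc((sigma^2 - mu * (t - m)) / (sqrt(2) * sigma * mu))
}
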