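#' Lp exponent implied by a scale normalization power
#'
#' Scale-normalized derivatives of order `n` with power `gamma` keep the
#' \eqn{L_p}-norm of the derivative kernel constant over scale, with (for a
#' one-dimensional temporal domain)
#' \deqn{p = \frac{1}{1 + n(1-\gamma)}.}
#' `gamma = 1` corresponds to L1 normalization for all orders.
#'
#' @param n derivative order (>= 1).
#' @param gamma scale normalization power; requires `1 + n*(1-gamma) > 0`.
#' @return The exponent `p` (possibly < 1, a quasi-norm).
#' @export
p_from_gamma <- function(n, gamma) {
  if (n < 1 || n != round(n))
    abort("`n` must be a positive integer", class = "tcss_invalid_parameter")
  den <- 1 + n * (1 - gamma)
  if (den <= 0)
    abort("1 + n(1-gamma) must be positive", class = "tcss_invalid_parameter")
  1 / den
}

#' Variance-based scale normalization factor
#'
#' The factor \eqn{\tau^{n\gamma/2}} multiplying an order-`n` temporal
#' derivative at scale `tau`.
#'
#' @param tau temporal scale (> 0); vectorized.
#' @param n derivative order.
#' @param gamma scale normalization power.
#' @return Numeric factor(s).
#' @export
variance_norm_factor <- function(tau, n, gamma) {
  if (any(tau <= 0)) abort("`tau` must be positive", class = "tcss_invalid_parameter")
  tau^(n * gamma / 2)
}

# probabilists' Hermite polynomial He_n(x), recursion He_{n+1} = x He_n - n He_{n-1}
hermite_He <- function(n, x) {
  if (n == 0L) return(rep(1, length(x)))
  hm1 <- rep(1, length(x)); h <- x
  if (n == 1L) return(h)
  for (k in 1L:(n - 1L)) {
    hnew <- x * h - k * hm1
    hm1 <- h; h <- hnew
  }
  h
}

# n-th derivative of the unit-area Gaussian with variance tau
gaussian_derivative <- function(t, tau, n) {
  s <- sqrt(tau)
  (-1)^n * hermite_He(n, t / s) / s^n * exp(-t^2 / (2 * tau)) / (sqrt(2 * pi) * s)
}

#' Lp-norm of a Gaussian derivative kernel
#'
#' Reference norms \eqn{G_{n,\gamma}(\tau) = \|g_{t^n}(\cdot; \tau)\|_p} with
#' `p` from [p_from_gamma()]. Closed forms are used for `n = 1` (any p) and
#' `n = 2` with `p = 1`; other cases fall back to quadrature of
#' \eqn{|g^{(n)}|^p}.
#'
#' @param tau scale of the Gaussian (variance, > 0).
#' @param n derivative order (>= 1).
#' @param gamma scale normalization power.
#' @return The reference norm (for `p < 1`, the quasi-norm
#'   \eqn{(\int |g^{(n)}|^p)^{1/p}}).
#' @export
gaussian_deriv_norm <- function(tau, n, gamma) {
  p <- p_from_gamma(n, gamma)
  s <- sqrt(tau)
  if (n == 1L) {
    # int |g'|^p = 2 (s^2 sqrt(2 pi s^2))^{-p} * Gamma((p+1)/2)/2 * (2 s^2/p)^{(p+1)/2}
    lognorm <- (log(2) + lgamma((p + 1) / 2) - log(2) +
                  ((p + 1) / 2) * log(2 * s^2 / p) -
                  p * (2 * log(s) + 0.5 * log(2 * pi * s^2))) / p
    return(exp(lognorm))
  }
  if (n == 2L && abs(p - 1) < 1e-12)
    return(4 * exp(-0.5) / (sqrt(2 * pi) * s^2))
  2 * integrate(function(t) abs(gaussian_derivative(t, tau, n))^p,
                0, Inf, rel.tol = 1e-10)$value^(1 / p)
}

discrete_lp_norm <- function(x, p) sum(abs(x)^p)^(1 / p)

#' Lp-norm-based scale normalization factor
#'
#' Determines the factor \eqn{\alpha_{n,\gamma}(\tau)} such that the scale of
#' the discrete order-`n` derivative kernel, measured in the \eqn{l_p}-norm
#' with `p` from [p_from_gamma()], matches the \eqn{L_p}-norm of the order-`n`
#' Gaussian derivative at the same `tau`:
#' \eqn{\alpha = G_{n,\gamma}(\tau) / \|h_{t^n}\|_p}.
#'
#' @param kernel the discrete order-`n` derivative kernel at scale `tau`
#'   (e.g. a differenced column of [impulse_responses()]).
#' @param n derivative order.
#' @param gamma scale normalization power.
#' @param tau the temporal scale the kernel corresponds to.
#' @return The normalization factor.
#' @export
lp_norm_factor <- function(kernel, n, gamma, tau) {
  kernel <- kernel[!is.na(kernel)]
  nrm <- discrete_lp_norm(kernel, p_from_gamma(n, gamma))
  if (nrm == 0) abort("zero derivative kernel", class = "tcss_invalid_input")
  gaussian_deriv_norm(tau, n, gamma) / nrm
}

#' Apply scale normalization to a derivative array
#'
#' Multiplies every scale column of a derivative `scale_space` array by its
#' per-scale normalization factor: \eqn{\tau_k^{n\gamma/2}} for the variance
#' scheme, or the Gaussian-referenced \eqn{l_p} factor of [lp_norm_factor()]
#' for the `lp` scheme (computed on mass-truncated impulse responses). With
#' `gamma = 1` the normalized derivative magnitudes at matching scales are
#' invariant under temporal rescalings by integer powers of the layout's
#' distribution parameter.
#'
#' @param ss a `scale_space` object with `derivative_order >= 1`.
#' @param scheme `"variance"` or `"lp"`.
#' @param gamma scale normalization power (default 1).
#' @param mass_tol impulse-response truncation tolerance for the lp scheme.
#' @return The normalized `scale_space` object.
#' @export
normalize_scale_space <- function(ss, scheme = c("variance", "lp"),
                                  gamma = 1, mass_tol = 1e-10) {
  stopifnot(inherits(ss, "scale_space"))
  scheme <- match.arg(scheme)
  n <- ss$derivative_order
  if (n < 1L)
    abort("normalization applies to derivative arrays (order >= 1)",
          class = "tcss_contract_violation")
  if (ss$normalization != "none")
    abort("array is already normalized", class = "tcss_contract_violation")
  fac <- if (scheme == "variance") {
    variance_norm_factor(ss$layout$tau, n, gamma)
  } else {
    imp <- impulse_responses(ss$layout, mass_tol = mass_tol)
    vapply(seq_len(ss$layout$K), function(k) {
      dk <- derivative_kernel(imp[, k], n)
      lp_norm_factor(dk, n, gamma, ss$layout$tau[k])
    }, numeric(1))
  }
  ss$L <- sweep(ss$L, 2L, fac, `*`)
  ss$normalization <- scheme
  ss$gamma <- gamma
  ss
}
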