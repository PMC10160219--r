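#' Half-line temporal moments of the ex-Gaussian kernel
#'
#' Raw moments \eqn{M_k = \int_0^\infty t^k h(t)\, dt} of the generalized
#' ex-Gaussian [ex_gaussian()] with `a0 = 0`, in closed form. Writing
#' \eqn{h(t) = A e^{-\beta t}\,\mathrm{erfc}(\alpha - \gamma t)}, integration
#' by parts reduces every \eqn{M_k} to an \eqn{\mathrm{erfc}(\alpha)} term
#' plus half-line Gaussian moments, all with error-function closed forms.
#' The moments are the raw half-line moments of the model, which is the
#' convention under which the limit-kernel fit reproduces the moment maps.
#'
#' @inheritParams ex_gaussian
#' @param order_max highest moment order (0..3; default 3).
#' @return A `moment_set`: list with `M` (raw moments `M0..M[order_max]`),
#'   `delta` (mean `M1/M0`) and `V` (variance `M2/M0 - delta^2`).
#' @examples
#' m <- exgauss_moments(4, 0.5, 2)
#' m$delta # about m + mu when little mass sits below t = 0
#' @export
exgauss_moments <- function(mu, sigma, m, a1 = 1, order_max = 3L) {
  if (mu <= 0 || sigma <= 0 || a1 <= 0)
    abort("need mu > 0, sigma > 0, a1 > 0", class = "tcss_invalid_parameter")
  if (order_max < 0 || order_max > 3)
    abort("`order_max` must be in 0..3", class = "tcss_invalid_parameter")
  A  <- a1 * sqrt(pi / 2) * sigma * exp((sigma^2 + 2 * mu * m) / (2 * mu^2))
  be <- 1 / mu
  al <- (sigma^2 + mu * m) / (sqrt(2) * sigma * mu)
  ga <- 1 / (sqrt(2) * sigma)
  ts <- (2 * al * ga - be) / (2 * ga^2)  # centre after completing the square
  Cc <- ga^2 * ts^2 - al^2
  sg <- sigma
  J <- numeric(4)
  E0 <- exp(-ts^2 / (2 * sg^2))
  J[1] <- sg * sqrt(pi / 2) * erfc(-ts / (sqrt(2) * sg))
  J[2] <- ts * J[1] + sg^2 * E0
  J[3] <- ts * J[2] + sg^2 * J[1]
  J[4] <- ts * J[3] + 2 * sg^2 * J[2]
  M <- vapply(0:order_max, function(j) {
    i <- 0:j
    A * (factorial(j) / be^(j + 1) * erfc(al) +
           (2 * ga / sqrt(pi)) * exp(Cc) *
             sum(factorial(j) / factorial(i) * be^(i - j - 1) * J[i + 1]))
  }, numeric(1))
  if (!all(is.finite(M)))
    abort("moment computation did not converge", class = "tcss_numeric_failure")
  new_moment_set(M)
}

new_moment_set <- function(M) {
  delta <- if (length(M) >= 2) M[2] / M[1] else NA_real_
  V <- if (length(M) >= 3) M[3] / M[1] - delta^2 else NA_real_
  structure(list(M = M, delta = delta, V = V), class = "moment_set")
}

#' Temporal moments of a sampled signal
#'
#' Raw moments \eqn{M_k = \int t^k f(t)\, dt} by trapezoidal summation over
#' the sample grid, for use with the moment-map fits.
#'
#' @param f data frame with (time, value) columns, or a numeric vector
#'   (then time is the 0-based sample index).
#' @param order_max highest moment order (default 3).
#' @return A `moment_set`.
#' @export
signal_moments <- function(f, order_max = 3L) {
  x <- signal_values(f)
  t <- signal_times(f)
  if (min(x) < -1e-8 * max(abs(x)))
    abort("signal values must be non-negative", class = "tcss_invalid_input")
  x <- pmax(x, 0)  # clip numerical ringing around zero
  w <- diff(t)
  M <- vapply(0:order_max, function(k) {
    y <- t^k * x
    sum(w * (head(y, -1) + tail(y, -1)) / 2)
  }, numeric(1))
  new_moment_set(M)
}

#' @export
print.moment_set <- function(x, ...) {
  cat("<moment_set>\n")
  for (k in seq_along(x$M)) cat(sprintf("  M%d = %g\n", k - 1, x$M[k]))
  cat(sprintf("  delta = %g, V = %g\n", x$delta, x$V))
  invisible(x)
}

new_limit_kernel_fit <- function(b0, b1, t0, tau, c, diagnostics = list()) {
  structure(list(b0 = b0, b1 = b1, t0 = t0, tau = tau, c = c,
                 diagnostics = diagnostics),
            class = "limit_kernel_fit")
}

# temporal mean of the (infinite) limit kernel: sqrt((c+1)/(c-1)) * sqrt(tau)
limit_kernel_mean <- function(tau, c) sqrt((c + 1) / (c - 1)) * sqrt(tau)

#' Fit a limit-kernel model by second-order moment matching
#'
#' Maps the zero-, first- and second-order temporal moments of a non-negative
#' kernel or signal onto the parameters of the model
#' \eqn{b_0 + b_1 \Psi(t; \tau, c)}: with mean \eqn{\delta = M_1/M_0} and
#' variance \eqn{V = M_2/M_0 - \delta^2},
#' \deqn{b_1 = M_0, \qquad \tau = V, \qquad c = \frac{\delta^2 + V}{\delta^2 - V}.}
#' The fit is feasible only when \eqn{\delta^2 > V} (otherwise `c` would not
#' exceed 1).
#'
#' @param moments a `moment_set` (from [exgauss_moments()] or
#'   [signal_moments()]) with moments up to order 2.
#' @param b0 DC offset, passed through unchanged.
#' @return A `limit_kernel_fit` with `t0 = 0`; see [tidy.limit_kernel_fit()].
#' @examples
#' fit_limit_kernel(exgauss_moments(4, 0.5, 2))
#' @export
fit_limit_kernel <- function(moments, b0 = 0) {
  stopifnot(inherits(moments, "moment_set"))
  if (!(moments$M[1] > 0))
    abort("infeasible fit: M0 must be positive", class = "tcss_infeasible_fit")
  d <- moments$delta; V <- moments$V
  if (!(V > 0) || d^2 <= V)
    abort(sprintf(
      "infeasible fit: need delta^2 > V > 0 (delta^2 = %g, V = %g)", d^2, V),
      class = "tcss_infeasible_fit")
  new_limit_kernel_fit(b0 = b0, b1 = moments$M[1], t0 = 0,
                       tau = V, c = (d^2 + V) / (d^2 - V))
}

#' Fit a limit-kernel model with a temporal offset (third-order moments)
#'
#' Extends [fit_limit_kernel()] to the model
#' \eqn{b_0 + b_1 \Psi(t - t_0; \tau, c)} by matching moments up to order 3.
#' The offset leaves the central moments unchanged, so \eqn{\tau = V} and `c`
#' is recovered from the skewness \eqn{\gamma_1} of the data through the
#' closed-form skewness of the limit kernel ([limit_kernel_shape()]), which
#' increases monotonically from 0 to 2 on \eqn{c \in (1, \infty)}; the offset
#' then follows from the mean: \eqn{t_0 = \delta - \sqrt{(c+1)/(c-1)}\sqrt{\tau}}.
#' Roots are searched on `c` in (1, 100]; the fit is admissible when
#' \eqn{0 < \gamma_1 < 2} and \eqn{t_0 \ge -\delta}.
#'
#' @param moments a `moment_set` with moments up to order 3.
#' @param b0 DC offset, passed through unchanged.
#' @return A `limit_kernel_fit`.
#' @export
fit_limit_kernel_offset <- function(moments, b0 = 0) {
  stopifnot(inherits(moments, "moment_set"))
  if (length(moments$M) < 4)
    abort("third-order moment required", class = "tcss_invalid_parameter")
  if (!(moments$M[1] > 0) || !(moments$V > 0))
    abort("infeasible fit: need M0 > 0 and V > 0", class = "tcss_infeasible_fit")
  d <- moments$delta; V <- moments$V
  mu3 <- moments$M[4] / moments$M[1] - 3 * d * V - d^3  # third central moment
  g1 <- mu3 / V^1.5
  if (!(g1 > 0) || g1 >= limit_kernel_shape(100)$gamma1)
    abort(sprintf("infeasible fit: skewness %g outside the attainable range", g1),
          class = "tcss_infeasible_fit")
  cc <- uniroot(function(c) limit_kernel_shape(c)$gamma1 - g1,
                lower = 1 + 1e-12, upper = 100, tol = 1e-14)$root
  tau <- V
  t0 <- d - limit_kernel_mean(tau, cc)
  if (t0 < -d)
    abort("infeasible fit: no admissible offset root", class = "tcss_infeasible_fit")
  new_limit_kernel_fit(b0 = b0, b1 = moments$M[1], t0 = t0, tau = tau, c = cc,
                       diagnostics = list(skewness = g1))
}

#' Fit a limit-kernel model to a sampled signal
#'
#' Computes trapezoidal moments of a non-negative, roughly unimodal, decaying
#' signal defined for \eqn{t \ge 0} and delegates to the moment-map fits.
#' Goodness of fit is reported as the relative L2 residual between the signal
#' and the fitted model evaluated on the sample grid.
#'
#' @param f data frame with (time, value) columns, or numeric vector.
#' @param with_offset if `TRUE`, use the third-order fit
#'   [fit_limit_kernel_offset()]; otherwise [fit_limit_kernel()].
#' @param b0 DC offset passed through.
#' @return A `limit_kernel_fit` with a `rel_residual` diagnostic.
#' @export
fit_signal <- function(f, with_offset = FALSE, b0 = 0) {
  mom <- signal_moments(f, order_max = if (with_offset) 3L else 2L)
  if (!(mom$M[1] > 0))
    abort("infeasible fit: signal has zero mass", class = "tcss_infeasible_fit")
  fit <- if (with_offset) fit_limit_kernel_offset(mom, b0 = b0)
         else fit_limit_kernel(mom, b0 = b0)
  t <- signal_times(f); x <- signal_values(f)
  pred <- fit$b0 + fit$b1 * limit_kernel(t - fit$t0, fit$tau, fit$c, K_trunc = 32L)
  fit$diagnostics$rel_residual <- sqrt(sum((x - pred)^2) / sum(x^2))
  fit
}

#' @export
print.limit_kernel_fit <- function(x, ...) {
  cat(sprintf("<limit_kernel_fit: tau = %.4g, c = %.4g, b1 = %.4g, t0 = %.4g, b0 = %g>\n",
              x$tau, x$c, x$b1, x$t0, x$b0))
  if (!is.null(x$diagnostics$rel_residual))
    cat(sprintf("  relative L2 residual: %.3g\n", x$diagnostics$rel_residual))
  invisible(x)
}

#' Tidy a limit-kernel fit
#'
#' @param x a `limit_kernel_fit`.
#' @param ... unused.
#' @return `tidy()`: a tibble with columns `term` and `estimate`;
#'   `glance()`: a one-row tibble with the parameters and diagnostics.
#' @export
tidy.limit_kernel_fit <- function(x, ...) {
  tibble(term = c("b0", "b1", "t0", "tau", "c"),
         estimate = c(x$b0, x$b1, x$t0, x$tau, x$c))
}

#' @rdname tidy.limit_kernel_fit
#' @export
glance.limit_kernel_fit <- function(x, ...) {
  tibble(tau = x$tau, c = x$c, b1 = x$b1, t0 = x$t0, b0 = x$b0,
         rel_residual = x$diagnostics$rel_residual %||% NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Map between limit-kernel and Koenderink scale-time parameters
#'
#' Equates first- and second-order moments of the two kernel families.
#' Forward (`koenderink_map`): \eqn{\sigma = \sqrt{\log(2c/(c+1))}} and
#' \eqn{\delta = (c+1)^2\sqrt{\tau} / (2\sqrt{2}\sqrt{(c-1)c^3})}.
#' Inverse (`koenderink_inverse`): \eqn{c = e^{\sigma^2}/(2 - e^{\sigma^2})}
#' and \eqn{\tau = \delta^2 e^{3\sigma^2}(e^{\sigma^2} - 1)}; valid for
#' \eqn{\sigma < \sqrt{\log 2} \approx 0.832}, the supremum of \eqn{\sigma}
#' over all \eqn{c > 1}.
#'
#' @param tau,c limit-kernel parameters (tau > 0, c > 1).
#' @return `koenderink_map()`: list with `sigma`, `delta`.
#' @export
koenderink_map <- function(tau, c) {
  check_limit_params(tau, c)
  list(sigma = sqrt(log(2 * c / (c + 1))),
       delta = (c + 1)^2 * sqrt(tau) / (2 * sqrt(2) * sqrt((c - 1) * c^3)))
}

#' @rdname koenderink_map
#' @param sigma,delta scale-time parameters (sigma in (0, sqrt(log 2)),
#'   delta > 0).
#' @return `koenderink_inverse()`: list with `tau`, `c`.
#' @export
koenderink_inverse <- function(sigma, delta) {
  if (sigma <= 0 || delta <= 0)
    abort("need sigma > 0 and delta > 0", class = "tcss_invalid_parameter")
  if (sigma >= sqrt(log(2)))
    abort("inverse map undefined for sigma >= sqrt(log 2)",
          class = "tcss_out_of_domain")
  es <- exp(sigma^2)
  list(tau = delta^2 * es^3 * (es - 1), c = es / (2 - es))
}

#' Peak-location estimate for the time-causal limit kernel
#'
#' Estimates the location of the maximum of \eqn{\Psi(t; \tau, c)} by the
#' delay parameter of the matched Koenderink kernel,
#' \eqn{t_{max} \approx (c+1)^2\sqrt{\tau}/(2\sqrt{2}\sqrt{(c-1)c^3})}.
#' The estimate scales as \eqn{\sqrt{\tau}} at fixed `c` and tends to
#' overestimate the true peak location; it is a better delay measure than the
#' temporal mean.
#'
#' @inheritParams koenderink_map
#' @return The estimated peak time.
#' @export
tmax_estimate <- function(tau, c) koenderink_map(tau, c)$delta
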