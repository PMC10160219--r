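#' Construct a ladder of temporal scale levels
#'
#' Builds the set of intermediate temporal scale levels \eqn{\tau_k} used by a
#' cascade of first-order recursive filters, together with the continuous time
#' constants \eqn{\mu_k} of the corresponding truncated-exponential kernels and
#' the discrete time constants of the recursive filters.
#'
#' Two distributions of the intermediate levels are supported:
#' \describe{
#'   \item{logarithmic}{\eqn{\tau_k = c^{2(k-K)} \tau_{max}} for a distribution
#'     parameter \eqn{c > 1}. This is the geometric ladder under which the
#'     time-causal limit kernel is scale covariant. The continuous time
#'     constants are \eqn{\mu_1 = c^{1-K}\sqrt{\tau_{max}}} and
#'     \eqn{\mu_k = c^{k-K-1}\sqrt{c^2-1}\sqrt{\tau_{max}}} for \eqn{k \ge 2}.}
#'   \item{uniform}{\eqn{\tau_k = (k/K) \tau_{max}}, all stages sharing the
#'     time constant \eqn{\sqrt{\tau_{max}/K}}. The composed kernel then has
#'     the Gamma-type closed form of [compose_uniform_kernel()].}
#' }
#'
#' The discrete time constants are obtained from the scale increments
#' \eqn{\Delta\tau_k} by [discrete_time_constants()], so that the discrete
#' per-stage variance \eqn{\mu_k^2 + \mu_k} equals \eqn{\Delta\tau_k} exactly
#' and the composed discrete kernel variance matches \eqn{\tau_k} at every
#' level.
#'
#' Scale levels are expressed in squared sample units throughout; convert from
#' physical seconds at the I/O boundary with [sample_scale()].
#'
#' @param tau_max maximum temporal scale (variance, in squared sample units).
#' @param c distribution parameter (> 1); ignored for `kind = "uniform"`.
#'   If `tau_min` is supplied, `c` is derived with [c_from_range()] instead.
#' @param K number of filter stages (positive integer).
#' @param kind `"logarithmic"` (default) or `"uniform"`.
#' @param tau_min optional inner temporal scale; when given (logarithmic kind,
#'   `K >= 2`), the distribution parameter is computed so that
#'   \eqn{\tau_1 = \tau_{min}}.
#' @return An object of class `scale_layout`: a list with elements `kind`,
#'   `c`, `K`, `tau_max`, `tau` (levels, increasing), `mu_cont`, `delta_tau`,
#'   and `mu_disc`.
#' @examples
#' scale_layout(16, c = 2, K = 3)
#' scale_layout(4, K = 4, kind = "uniform")
#' @export
scale_layout <- function(tau_max, c = 2, K = 8,
                         kind = c("logarithmic", "uniform"),
                         tau_min = NULL) {
  kind <- match.arg(kind)
  if (!is.numeric(tau_max) || length(tau_max) != 1L || tau_max <= 0)
    abort("`tau_max` must be a positive number", class = "tcss_invalid_parameter")
  if (K < 1 || K != round(K))
    abort("`K` must be a positive integer", class = "tcss_invalid_parameter")
  K <- as.integer(K)
  if (kind == "logarithmic") {
    if (!is.null(tau_min)) c <- c_from_range(tau_min, tau_max, K)
    if (c <= 1)
      abort("`c` must be > 1", class = "tcss_invalid_parameter")
    k <- seq_len(K)
    tau <- c^(2 * (k - K)) * tau_max
    mu_cont <- c(c^(1 - K) * sqrt(tau_max),
                 if (K >= 2) c^(2:K - K - 1) * sqrt(c^2 - 1) * sqrt(tau_max))
  } else {
    c <- NA_real_
    tau <- (seq_len(K) / K) * tau_max
    mu_cont <- rep(sqrt(tau_max / K), K)
  }
  delta_tau <- diff(c(0, tau))
  structure(
    list(kind = kind, c = c, K = K, tau_max = tau_max,
         tau = tau, mu_cont = mu_cont, delta_tau = delta_tau,
         mu_disc = discrete_time_constants(delta_tau)),
    class = "scale_layout")
}

#' Distribution parameter from a scale range
#'
#' Computes the distribution parameter \eqn{c} such that a logarithmic ladder
#' with `K` levels ending at `tau_max` starts at an a-priori given inner scale
#' `tau_min`: \eqn{c = (\tau_{max}/\tau_{min})^{1/(2(K-1))}}.
#'
#' @param tau_min,tau_max scale bounds with `0 < tau_min < tau_max`.
#' @param K number of levels (>= 2).
#' @return The distribution parameter, a number > 1.
#' @examples
#' c_from_range(1, 16, 3) # 2
#' @export
c_from_range <- function(tau_min, tau_max, K) {
  if (K < 2 || K != round(K))
    abort("`K` must be an integer >= 2", class = "tcss_invalid_parameter")
  if (!(tau_min > 0) || tau_min >= tau_max)
    abort("need 0 < tau_min < tau_max", class = "tcss_invalid_parameter")
  (tau_max / tau_min)^(1 / (2 * (K - 1)))
}

#' Mean and variance of a composed cascade kernel
#'
#' For truncated-exponential kernels with time constants `mu` coupled in
#' cascade, the composed kernel has temporal mean \eqn{\sum_k \mu_k} (a coarse
#' measure of the temporal delay) and temporal variance \eqn{\sum_k \mu_k^2}
#' (the temporal scale).
#'
#' @param mu vector of positive time constants.
#' @return A list with elements `mean` and `variance`.
#' @examples
#' cascade_moments(c(1, 2)) # mean 3, variance 5
#' @export
cascade_moments <- function(mu) {
  if (length(mu) == 0L)
    abort("`mu` must be non-empty", class = "tcss_invalid_parameter")
  if (any(mu <= 0))
    abort("all time constants must be positive", class = "tcss_invalid_parameter")
  list(mean = sum(mu), variance = sum(mu^2))
}

#' Discrete time constants from scale increments
#'
#' A first-order recursive filter with time constant \eqn{\mu} has discrete
#' temporal variance \eqn{\mu^2 + \mu}. Inverting this for a desired scale
#' increment \eqn{\Delta\tau} gives
#' \eqn{\mu = (\sqrt{1 + 4\Delta\tau} - 1)/2}, so that the discrete variances
#' of the composed kernels match the continuous scale levels exactly.
#'
#' @param delta_tau vector of non-negative scale increments.
#' @return Vector of discrete time constants (samples).
#' @examples
#' discrete_time_constants(c(2, 6)) # 1, 2
#' @export
discrete_time_constants <- function(delta_tau) {
  if (any(delta_tau < 0))
    abort("scale increments must be non-negative", class = "tcss_invalid_parameter")
  (sqrt(1 + 4 * delta_tau) - 1) / 2
}

#' Convert a physical temporal scale to sample units
#'
#' For a signal sampled at frame rate `r` (samples per second), a temporal
#' standard deviation `sigma_t` in seconds corresponds to the temporal
#' variance \eqn{\tau = r^2 \sigma_t^2} in squared sample units.
#'
#' @param sigma_t temporal standard deviation in physical time units (>= 0).
#' @param r sampling rate in samples per time unit (> 0).
#' @return Temporal variance in squared sample units.
#' @examples
#' sample_scale(0.1, 100) # 100
#' @export
sample_scale <- function(sigma_t, r) {
  if (r <= 0) abort("`r` must be positive", class = "tcss_invalid_parameter")
  if (any(sigma_t < 0))
    abort("`sigma_t` must be non-negative", class = "tcss_invalid_parameter")
  r^2 * sigma_t^2
}

#' @export
print.scale_layout <- function(x, ...) {
  cat(sprintf("<scale_layout: %s, K = %d, tau_max = %g%s>\n",
              x$kind, x$K, x$tau_max,
              if (!is.na(x$c)) sprintf(", c = %g", x$c) else ""))
  print(as_tibble(x), ...)
  invisible(x)
}

#' @export
as_tibble.scale_layout <- function(x, ...) {
  tibble(level = seq_len(x$K), tau = x$tau, mu_cont = x$mu_cont,
         delta_tau = x$delta_tau, mu_disc = x$mu_disc)
}

#' @rdname scale_layout
#' @param x a `scale_layout` object (for `layout_to_json()`), or a JSON string
#'   or path (for `layout_from_json()`).
#' @export
layout_to_json <- function(x) {
  stopifnot(inherits(x, "scale_layout"))
  jsonlite::toJSON(
    list(kind = x$kind, c = x$c, K = x$K, tau_max = x$tau_max,
         tau_levels = x$tau, mu_cont = x$mu_cont, mu_disc = x$mu_disc),
    auto_unbox = TRUE, digits = NA, na = "null")
}

#' @rdname scale_layout
#' @export
layout_from_json <- function(x) {
  obj <- jsonlite::fromJSON(x)
  scale_layout(obj$tau_max, c = if (is.null(obj$c) || is.na(obj$c)) 2 else obj$c,
               K = obj$K, kind = obj$kind)
}
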