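#' Streaming state of a recursive-filter cascade
#'
#' Creates the per-stage state used by [cascade_step()] for strictly
#' time-recursive processing: one running output value per scale level, which
#' is the only memory of the past the representation needs.
#'
#' @param layout a [scale_layout()].
#' @param init `"zero"` or a numeric value used for all stages (use the first
#'   sample of the signal so that constants are fixed points).
#' @return An object of class `cascade_state` with fields `y` (per-stage
#'   outputs) and `t_index`.
#' @export
cascade_state <- function(layout, init = 0) {
  stopifnot(inherits(layout, "scale_layout"))
  y0 <- if (identical(init, "zero")) 0 else as.numeric(init)
  structure(list(y = rep(y0, layout$K), t_index = 0L),
            class = "cascade_state")
}

#' Advance a recursive-filter cascade by one sample
#'
#' Applies one time step of the normalized first-order recursive filter
#' \deqn{y_k(t) = y_k(t-1) + \frac{1}{1+\mu_k}\,(x_k(t) - y_k(t-1))}
#' at every stage, with the input of stage 1 being the new sample and the
#' input of stage k the updated output of stage k-1. Uses only the current
#' sample and the previous state: no other temporal memory of the past than
#' the scale-space representation itself.
#'
#' @param state a [cascade_state()].
#' @param sample the new input value.
#' @param layout the [scale_layout()] the state was created for.
#' @return The updated `cascade_state`.
#' @export
cascade_step <- function(state, sample, layout) {
  stopifnot(inherits(state, "cascade_state"))
  if (length(state$y) != layout$K)
    abort("state/layout stage count mismatch", class = "tcss_contract_violation")
  alpha <- 1 / (1 + layout$mu_disc)
  x <- sample
  y <- state$y
  for (k in seq_len(layout$K)) {
    # same arithmetic arrangement as the vectorized batch filter
    y[k] <- (alpha[k] * x) + ((1 - alpha[k]) * y[k])
    x <- y[k]
  }
  state$y <- y
  state$t_index <- state$t_index + 1L
  state
}

run_stage <- function(x, mu, y0) {
  alpha <- 1 / (1 + mu)
  as.numeric(stats::filter(alpha * x, 1 - alpha, method = "recursive",
                           init = y0))
}

#' Temporal scale-space representation of a signal
#'
#' Filters a uniformly sampled signal through a cascade (or parallel bank) of
#' first-order recursive filters, producing the temporal scale-space
#' \eqn{L(t; \tau_k)} at every level of the layout. The filtering is
#' time-causal and equals sample-by-sample application of [cascade_step()]
#' bit-identically.
#'
#' In `"cascade"` mode the stages are chained, so every level is a smoothing
#' of the previous one and the number of local extrema is non-increasing from
#' level to level. In `"parallel"` mode each level is produced independently
#' by a single recursive filter whose discrete variance \eqn{\mu^2 + \mu}
#' equals \eqn{\tau_k}; such parallel memory channels are simplifications of
#' the input but not of each other.
#'
#' @param f signal: numeric vector, or data frame with (time, value) columns.
#' @param layout a [scale_layout()], or `NULL` to build one from `...`.
#' @param mode `"cascade"` (default) or `"parallel"`.
#' @param init state initialization: `"first_sample"` (default; constants are
#'   fixed points and there is no DC startup transient) or `"zero"` (use for
#'   impulse-response work).
#' @param ... passed to [scale_layout()] when `layout` is `NULL`
#'   (e.g. `tau_max`, `c`, `K`).
#' @return An object of class `scale_space`: list with `L` (T x K matrix),
#'   `layout`, `time`, `derivative_order` (0), `normalization` (`"none"`),
#'   `gamma`, and `valid_from` (first valid row of each column).
#' @examples
#' f <- wiener_process(256, seed = 1)
#' ss <- scale_space(f, tau_max = 16, c = 2, K = 3)
#' tidy(ss)
#' @export
scale_space <- function(f, layout = NULL,
                        mode = c("cascade", "parallel"),
                        init = c("first_sample", "zero"), ...) {
  mode <- match.arg(mode)
  init <- match.arg(init)
  x <- signal_values(f)
  if (length(x) == 0L) abort("empty signal", class = "tcss_invalid_input")
  if (is.null(layout)) layout <- scale_layout(...)
  y0 <- if (init == "zero") 0 else x[1L]
  L <- matrix(0, nrow = length(x), ncol = layout$K)
  if (mode == "cascade") {
    cur <- x
    for (k in seq_len(layout$K)) {
      cur <- run_stage(cur, layout$mu_disc[k], y0)
      L[, k] <- cur
    }
  } else {
    mu_par <- discrete_time_constants(layout$tau)
    for (k in seq_len(layout$K)) L[, k] <- run_stage(x, mu_par[k], y0)
  }
  colnames(L) <- sprintf("tau_%g", layout$tau)
  structure(list(L = L, layout = layout, time = signal_times(f),
                 input = x, mode = mode, init = init,
                 derivative_order = 0L, normalization = "none",
                 gamma = NA_real_, valid_from = 1L),
            class = "scale_space")
}

#' @export
print.scale_space <- function(x, ...) {
  cat(sprintf(
    "<scale_space: %d samples x %d scales, derivative order %d, normalization %s>\n",
    nrow(x$L), ncol(x$L), x$derivative_order, x$normalization))
  invisible(x)
}

#' Long-format view of a scale-space array
#'
#' @param x a `scale_space` object.
#' @param ... unused.
#' @return A tibble with columns `time`, `tau`, `value` (invalid startup rows
#'   of derivative arrays are dropped).
#' @export
tidy.scale_space <- function(x, ...) {
  tb <- tibble(time = rep(x$time, ncol(x$L)),
               tau = rep(x$layout$tau, each = nrow(x$L)),
               value = as.vector(x$L))
  tb[!is.na(tb$value), ]
}

#' Discrete impulse responses of a cascade
#'
#' Materializes the discrete smoothing kernels implied by the recursive-filter
#' cascade, truncated when the cumulative mass of the coarsest kernel reaches
#' `1 - mass_tol`. Each column k is non-negative, sums to 1 up to the
#' truncated tail mass, and has (mass-renormalized) variance exactly
#' \eqn{\tau_k} up to the truncation error.
#'
#' @param layout a [scale_layout()].
#' @param mass_tol maximum kernel mass allowed to be cut off (0 < mass_tol < 1).
#' @return A matrix with one column per scale level; row u is the kernel value
#'   at lag u - 1.
#' @export
impulse_responses <- function(layout, mass_tol = 1e-12) {
  stopifnot(inherits(layout, "scale_layout"))
  if (!(mass_tol > 0 && mass_tol < 1))
    abort("`mass_tol` must be in (0, 1)", class = "tcss_invalid_parameter")
  mu_max <- max(layout$mu_disc)
  n <- ceiling(sum(layout$mu_disc) + 12 * sqrt(layout$tau_max) +
                 (mu_max + 1) * log(1 / mass_tol)) + 16
  repeat {
    imp <- c(1, numeric(n - 1))
    ss <- scale_space(imp, layout, init = "zero")
    if (min(colSums(ss$L)) >= 1 - mass_tol) return(ss$L)
    n <- 2L * n
  }
}

#' Temporal difference derivatives of a scale-space array
#'
#' Applies the discrete temporal difference operators
#' \eqn{\delta_t = (-1, +1)} and \eqn{\delta_{tt} = (1, -2, 1)} (higher orders
#' by composition) to every column. Differences are aligned to the later
#' sample; the first `order` samples of each column are marked `NA` rather
#' than zero-padded.
#'
#' @param ss a `scale_space` object (any current derivative order).
#' @param order additional derivative order to apply (>= 0).
#' @return A `scale_space` object with updated `derivative_order`.
#' @export
temporal_derivative <- function(ss, order = 1L) {
  stopifnot(inherits(ss, "scale_space"))
  if (order < 0 || order != round(order))
    abort("`order` must be a non-negative integer", class = "tcss_invalid_parameter")
  L <- ss$L
  n <- nrow(L)
  o <- as.integer(order)
  while (o >= 2L) {
    L <- rbind(NA_real_, NA_real_,
               L[3:n, , drop = FALSE] - 2 * L[2:(n - 1), , drop = FALSE] +
                 L[1:(n - 2), , drop = FALSE])
    o <- o - 2L
  }
  if (o == 1L)
    L <- rbind(NA_real_, L[2:n, , drop = FALSE] - L[1:(n - 1), , drop = FALSE])
  ss$L <- L
  ss$derivative_order <- ss$derivative_order + as.integer(order)
  ss$valid_from <- ss$valid_from + as.integer(order)
  ss
}

#' Temporal N-jet of a signal
#'
#' Computes the stack of scale-normalized temporal derivatives of orders
#' 0..`N` of the scale-space representation, supporting a local Taylor
#' description \eqn{L(t_0+\Delta t) \approx L + \Delta t\, L_t +
#' \Delta t^2 L_{tt}/2 + \dots} at every scale.
#'
#' @param ss a smoothed `scale_space` object (derivative order 0).
#' @param N highest derivative order (>= 0).
#' @param gamma scale normalization power (default 1).
#' @param scheme normalization scheme passed to [normalize_scale_space()];
#'   `"none"` leaves plain difference derivatives.
#' @return A list of `N + 1` `scale_space` objects (orders 0..N).
#' @export
temporal_jet <- function(ss, N, gamma = 1,
                         scheme = c("variance", "lp", "none")) {
  stopifnot(inherits(ss, "scale_space"), ss$derivative_order == 0L)
  scheme <- match.arg(scheme)
  if (N < 0) abort("`N` must be >= 0", class = "tcss_invalid_parameter")
  lapply(0:N, function(n) {
    d <- temporal_derivative(ss, n)
    if (scheme == "none" || n == 0L) d
    else normalize_scale_space(d, scheme = scheme, gamma = gamma)
  })
}

#' Count local extrema with plateau collapsing
#'
#' Counts strict sign changes of the first difference after collapsing runs
#' of equal values, so a plateau bounded by descents on both sides counts as
#' a single maximum. This is the structure measure that time-causal smoothing
#' is guaranteed never to increase.
#'
#' @param f signal (vector or data frame).
#' @return Integer count of interior local extrema.
#' @examples
#' count_extrema(c(1, 2, 2, 1)) # 1
#' @export
count_extrema <- function(f) {
  x <- signal_values(f)
  v <- rle(x)$values
  if (length(v) < 3L) return(0L)
  s <- sign(diff(v))
  sum(s[-1] != s[-length(s)])
}
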