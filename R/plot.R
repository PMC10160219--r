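#' Plot a temporal scale-space representation
#'
#' One panel per scale level, finest at the top, echoing the standard way
#' multi-scale smoothing results are displayed.
#'
#' @param object a `scale_space` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.scale_space <- function(object, ...) {
  tb <- tidy(object)
  tb$tau <- factor(sprintf("tau = %g", tb$tau),
                   levels = sprintf("tau = %g", object$layout$tau))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$tau), scales = "free_y") +
    ggplot2::labs(x = "time (samples)", y = NULL)
}

#' Plot a time-causal spectrogram
#'
#' @param object a `spectrogram` object.
#' @param ... unused.
#' @return A ggplot object (log-magnitude raster over time and frequency).
#' @export
autoplot.spectrogram <- function(object, ...) {
  tb <- tidy(object)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$time, y = .data$omega,
                                   fill = log10(.data$magnitude + 1e-12))) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (samples)", y = "angular frequency (rad/sample)",
                  fill = "log10 |S|")
}

#' Plot kernels over a time grid
#'
#' Convenience line plot of one or more kernels evaluated on a shared grid.
#'
#' @param t time grid.
#' @param ... named numeric vectors of kernel values on `t`.
#' @return A ggplot object.
#' @export
plot_kernels <- function(t, ...) {
  ks <- list(...)
  tb <- tibble(t = rep(t, length(ks)),
               kernel = rep(names(ks), each = length(t)),
               value = unlist(ks, use.names = FALSE))
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$t, y = .data$value,
                                   colour = .data$kernel)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time", y = "kernel value", colour = NULL)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
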