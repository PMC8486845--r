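#' Plot conductance traces
#'
#' Overlays G-z traces on a log conductance axis, the standard view of
#' break-junction data.
#'
#' @param data trace tibble or long ensemble.
#' @param alpha line transparency.
#' @return a ggplot.
#' @export
plot_traces <- function(data, alpha = 0.5) {
  if (!"trace" %in% names(data)) data <- dplyr::mutate(data, trace = 1L)
  ggplot2::ggplot(data, ggplot2::aes(.data$z, .data$g,
                                     group = .data$trace)) +
    ggplot2::geom_line(alpha = alpha, linewidth = 0.3) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "displacement (nm)", y = expression(G / G[0]))
}

#' @export
autoplot.zj_hist2d <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$z, .data$log_g, fill = .data$count)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "displacement (nm)",
                  y = expression(log[10] * (G / G[0])), fill = "counts")
}

#' Plot a Fowler-Nordheim spectrum
#'
#' @param spectrum a [fn_transform()] result.
#' @param vtrans optional transition voltage to mark (V).
#' @return a ggplot.
#' @export
plot_fn_spectrum <- function(spectrum, vtrans = NULL) {
  p <- ggplot2::ggplot(spectrum,
                       ggplot2::aes(.data$inv_bias, .data$fn_value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(1 / V ~ (V^-1)),
                  y = expression(log[10] * (I / V^2)))
  if (!is.null(vtrans) && !is.na(vtrans)) {
    p <- p + ggplot2::geom_vline(xintercept = 1 / vtrans, linetype = 2)
  }
  p
}

#' Plot the temporal evolution of dwell lengths
#'
#' @param records a [judge_formation()] result, optionally with a time
#'   axis from [time_axis()].
#' @param threshold_nm formation threshold to mark.
#' @return a ggplot.
#' @export
plot_dwell_series <- function(records, threshold_nm = NULL) {
  xvar <- if ("t" %in% names(records)) "t" else "trace"
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(.data[[xvar]], .data$dwell)) +
    ggplot2::geom_col(width = if (xvar == "t") NULL else 0.8) +
    ggplot2::labs(x = if (xvar == "t") "time (s)" else "trace",
                  y = "dwell length (nm)")
  if (!is.null(threshold_nm)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold_nm, linetype = 2)
  }
  p
}

#' @export
autoplot.zj_trajectory <- function(object, ...) {
  long <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("t", "z_tip", "n_open", "force")],
    -"t", names_to = "panel")
  long$panel <- factor(long$panel,
                       levels = c("z_tip", "n_open", "force"),
                       labels = c("tip height (nm)", "open base pairs",
                                  "force (pN)"))
  ggplot2::ggplot(long, ggplot2::aes(.data$t, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL)
}
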