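#' Tidy methods for zipperjunction result objects
#'
#' Broom-style accessors: `tidy()` returns the per-component or per-bin
#' content of a result as a tibble, `glance()` a one-row summary.
#'
#' @param x a result object.
#' @param ... unused.
#' @return a tibble.
#' @name zj-tidiers
NULL

#' @rdname zj-tidiers
#' @export
tidy.zj_peak <- function(x, ...) {
  tibble::tibble(term = c("center_mG0", "sd_log10", "amplitude"),
                 estimate = c(x$center, x$sd_log10, x$amplitude))
}

#' @rdname zj-tidiers
#' @export
glance.zj_peak <- function(x, ...) {
  tibble::tibble(center = x$center, sd_log10 = x$sd_log10,
                 n_samples = x$n_samples)
}

#' @rdname zj-tidiers
#' @export
tidy.zj_decay <- function(x, ...) {
  tibble::tibble(segment = c("plateau", "post_plateau"),
                 beta = c(x$beta1, x$beta2),
                 window_start = c(x$window1[1], x$window2[1]),
                 window_end = c(x$window1[2], x$window2[2]),
                 r_squared = x$r2)
}

#' @rdname zj-tidiers
#' @export
glance.zj_decay <- function(x, ...) {
  tibble::tibble(beta1 = x$beta1, beta2 = x$beta2)
}

#' @rdname zj-tidiers
#' @export
tidy.zj_hist2d <- function(x, ...) {
  grid <- tidyr::expand_grid(
    iz = seq_len(length(x$z_edges) - 1),
    ig = seq_len(length(x$logg_edges) - 1))
  dplyr::mutate(grid,
                z = (x$z_edges[.data$iz] + x$z_edges[.data$iz + 1]) / 2,
                log_g = (x$logg_edges[.data$ig] +
                           x$logg_edges[.data$ig + 1]) / 2,
                count = as.vector(t(x$counts))[(.data$iz - 1) *
                    (length(x$logg_edges) - 1) + .data$ig]) |>
    dplyr::select("z", "log_g", "count")
}

#' @rdname zj-tidiers
#' @export
tidy.zj_vtrans <- function(x, ...) {
  mids <- x$breaks[-length(x$breaks)] + diff(x$breaks) / 2
  tibble::tibble(vtrans = mids, count = x$counts)
}

#' @rdname zj-tidiers
#' @export
glance.zj_vtrans <- function(x, ...) {
  tibble::tibble(mean = x$mean, sd = x$sd, n = x$n)
}

#' @rdname zj-tidiers
#' @export
glance.zj_restoration <- function(x, ...) {
  tibble::tibble(p_form = x$p_form, p_joint_adjacent = x$p_joint_adjacent,
                 independence_ratio = x$independence_ratio,
                 p_value = x$p_value, max_run = x$max_run, n = x$n)
}

#' @rdname zj-tidiers
#' @export
glance.zj_trajectory <- function(x, ...) {
  tibble::tibble(n_bp = attr(x, "n_bp"),
                 termination = attr(x, "termination"),
                 max_n_open = max(x$n_open),
                 final_intact = final_intact_bp(x),
                 max_force = max(x$force))
}

#' @rdname zj-tidiers
#' @export
tidy.zj_filter <- function(x, ...) x$report
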