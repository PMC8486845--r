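#' Dwell length of a trace in a conductance band
#'
#' Sum of the displacement increments whose conductance lies inside
#' `[band_low, band_high]` (mG0); non-contiguous visits accumulate. Each
#' increment `z[k+1] - z[k]` is attributed to the conductance at its left
#' endpoint. The result is invariant to displacement-origin shifts and
#' additive under trace concatenation.
#'
#' @param data one trace (`z`, `g`).
#' @param cfg a [dwell_config()].
#' @return dwell length in nm (0 when the band is never visited).
#' @export
#' @examples
#' tr <- tibble::tibble(z = seq(0, 0.5, 1e-3), g = rep(1.9e-3, 501))
#' dwell_length(tr, dwell_config("90mer"))  # 0.5
dwell_length <- function(data, cfg = dwell_config("90mer")) {
  if (nrow(data) < 2) return(0)
  g_mG0 <- data$g * 1e3
  inband <- g_mG0 >= cfg$band_low & g_mG0 <= cfg$band_high
  sum(diff(data$z)[inband[-length(inband)]])
}

#' Dwell lengths across a consecutive-trace series
#'
#' @param data long trace series (`trace`, `z`, `g`).
#' @param cfg a [dwell_config()].
#' @return tibble `trace`, `dwell` (nm), ordered by trace index.
#' @export
dwell_table <- function(data, cfg = dwell_config("90mer")) {
  parts <- split(data, data$trace)
  tibble::tibble(
    trace = as.integer(names(parts)),
    dwell = purrr::map_dbl(parts, dwell_length, cfg = cfg)
  ) |> dplyr::arrange(.data$trace)
}

#' Judge junction formation from dwell lengths
#'
#' A junction is judged formed when the dwell length reaches the
#' plateau-length threshold (inclusive comparison; the thresholds are
#' 0.060 nm for the 90-mer band and 0.028 nm for the 10-mer band).
#'
#' @param records a [dwell_table()] result (`trace`, `dwell`), ordered by
#'   trace index.
#' @param cfg a [dwell_config()].
#' @return `records` with a logical `formed` column appended.
#' @export
judge_formation <- function(records, cfg = dwell_config("90mer")) {
  dplyr::mutate(records, formed = .data$dwell >= cfg$threshold_nm)
}

longest_run <- function(x) {
  if (!length(x) || !any(x)) return(0L)
  r <- rle(x)
  max(r$lengths[r$values])
}

#' Joint-probability statistics of repeated junction formation
#'
#' Quantifies whether consecutive junction formations are correlated
#' (self-restoration) or independent (fresh formation each cycle):
#' `p_form` is the formation fraction, `p_joint_adjacent` the fraction of
#' adjacent trace pairs that are both formed, and `independence_ratio =
#' p_joint / p_form^2` equals 1 for independent formation and exceeds it
#' for persistent junctions. Significance is assessed with a permutation
#' null: the series is shuffled `n_perm` times and a two-sided p-value is
#' computed from the absolute deviation of `p_joint_adjacent` from its
#' permutation mean. `max_run` is the longest uninterrupted run of
#' formations.
#'
#' @param series logical vector of formation states, or a tibble with a
#'   `formed` column (e.g. from [judge_formation()]).
#' @param n_perm number of permutations.
#' @param seed optional integer seed for the permutation draw.
#' @return object of class `zj_restoration` with fields `p_form`,
#'   `p_joint_adjacent`, `independence_ratio` (NA when `p_form` is 0),
#'   `p_value`, `max_run`, `n`.
#' @export
#' @examples
#' restoration_stats(rep(TRUE, 10), n_perm = 99, seed = 1)
restoration_stats <- function(series, n_perm = 1000, seed = NULL) {
  if (is.data.frame(series)) series <- series$formed
  stopifnot(is.logical(series), length(series) >= 2)
  if (!is.null(seed)) withr::local_seed(seed)
  n <- length(series)
  p_form <- mean(series)
  joint <- function(x) mean(x[-length(x)] & x[-1])
  p_joint <- joint(series)
  ratio <- if (p_form > 0) p_joint / p_form^2 else NA_real_
  perm <- vapply(seq_len(n_perm), function(k) joint(sample(series)),
                 numeric(1))
  dev <- abs(p_joint - mean(perm))
  p_value <- (1 + sum(abs(perm - mean(perm)) >= dev - 1e-12)) / (n_perm + 1)
  structure(list(p_form = p_form, p_joint_adjacent = p_joint,
                 independence_ratio = ratio, p_value = p_value,
                 max_run = longest_run(series), n = n),
            class = "zj_restoration")
}

#' @export
print.zj_restoration <- function(x, ...) {
  cat(sprintf(paste0("<zj_restoration> p_form %.3f, p_joint %.3f, ",
                     "ratio %.3f, p = %.3g, max run %d of %d\n"),
              x$p_form, x$p_joint_adjacent, x$independence_ratio,
              x$p_value, x$max_run, x$n))
  invisible(x)
}

#' Attach a time axis to a consecutive-trace series
#'
#' Each pull cycle takes a constant period (pull time plus approach and
#' hybridisation wait); trace `k` is stamped `t = k * period`. The default
#' period, 30 nm / (31 nm/s) + 0.3 s of wait, makes a run of 78
#' consecutive formations last about 100 s.
#'
#' @param records per-trace tibble with a `trace` column.
#' @param trace_period_s seconds per pull cycle.
#' @return `records` with a `t` column (s) appended.
#' @export
time_axis <- function(records, trace_period_s = 30 / 31 + 0.3) {
  if (trace_period_s <= 0) abort("trace period must be positive")
  dplyr::mutate(records, t = .data$trace * trace_period_s)
}
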