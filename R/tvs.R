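#' Classify I-V sweeps into high- and low-conductance states
#'
#' Sweep ensembles recorded with DNA-modified tips are bimodal: a
#' high-conductance molecular state and a low-conductance state common to
#' the control experiments (the empty gap). Each sweep is summarised by
#' its low-bias conductance, `mean(|I/V|)` over `window`, log-transformed,
#' and the ensemble is split by two-means clustering in log space with the
#' extreme observations as fixed starting centres (deterministic for a
#' given input).
#'
#' @param data long sweep ensemble (`sweep`, `v`, `i`).
#' @param window absolute-bias window (V) for the low-bias conductance.
#' @param fallback label used when the ensemble forms a single cluster.
#' @param min_separation minimum distance (decades) between the two
#'   cluster centres for the split to be accepted; below it the ensemble
#'   is treated as a single population (the control-experiment case) and
#'   labelled `fallback` throughout.
#' @return tibble with `sweep`, `log_g` (log10 S) and `state`
#'   (`"high"`/`"low"`).
#' @export
classify_iv <- function(data, window = c(0.05, 0.15), fallback = "low",
                        min_separation = 0.5) {
  feat <- data |>
    dplyr::filter(abs(.data$v) >= window[1], abs(.data$v) <= window[2]) |>
    dplyr::summarise(log_g = log10(mean(abs(.data$i / .data$v))),
                     .by = "sweep")
  if (diff(range(feat$log_g)) == 0) {
    return(dplyr::mutate(feat, state = fallback))
  }
  km <- kmeans(feat$log_g, centers = matrix(range(feat$log_g), ncol = 1))
  if (abs(diff(range(km$centers))) < min_separation) {
    return(dplyr::mutate(feat, state = fallback))
  }
  hi <- which.max(km$centers)
  dplyr::mutate(feat, state = ifelse(km$cluster == hi, "high", "low"))
}

#' Fowler-Nordheim transform of an I-V sweep
#'
#' For the chosen bias polarity, emits `log10(|I|/V^2)` against `1/|V|`
#' over `v_min <= |V| <= max(|V|)`. Points too close to zero bias are
#' excluded (1/V singularity) and non-positive currents are dropped.
#'
#' @param data one sweep (`v`, `i`).
#' @param polarity `"positive"` or `"negative"`.
#' @param v_min minimum absolute bias retained, V.
#' @return tibble `inv_bias` (1/V, increasing), `fn_value`
#'   (log10(A/V^2)); empty input or all-dropped points raise an error.
#' @export
#' @examples
#' sw <- gen_iv_sweep("low", iv_params(noise_sd_logI = 0), seed = 1)
#' fn <- fn_transform(sw, "positive")
fn_transform <- function(data, polarity = c("positive", "negative"),
                         v_min = 0.1) {
  polarity <- match.arg(polarity)
  sgn <- if (polarity == "positive") 1 else -1
  d <- dplyr::filter(data, sign(.data$v) == sgn, abs(.data$v) >= v_min,
                     abs(.data$i) > 0)
  if (!nrow(d)) abort("sweep has no usable points at the requested polarity")
  d |>
    dplyr::transmute(inv_bias = 1 / abs(.data$v),
                     fn_value = log10(abs(.data$i) / .data$v^2)) |>
    dplyr::arrange(.data$inv_bias)
}

#' Locate the transition voltage in a Fowler-Nordheim spectrum
#'
#' Smooths `fn_value` with a centred moving average of `smooth_points`
#' samples and returns the absolute bias at the interior minimum.
#' A minimum sitting on the boundary of the smoothed range means the
#' spectrum is monotone over the sweep (e.g. an ohmic gap) and yields
#' `NA`: no transition voltage is defined there.
#'
#' @param spectrum a [fn_transform()] result.
#' @param smooth_points moving-average width (samples).
#' @return transition voltage in V, or `NA`.
#' @export
find_vtrans <- function(spectrum, smooth_points = 5) {
  n <- nrow(spectrum)
  if (n < smooth_points + 2) abort("spectrum shorter than the smoothing window")
  h <- floor(smooth_points / 2)
  sm <- stats::filter(spectrum$fn_value, rep(1 / smooth_points, smooth_points),
                      sides = 2)
  valid <- which(!is.na(sm))
  k <- valid[which.min(sm[valid])]
  if (k <= min(valid) || k >= max(valid)) return(NA_real_)
  1 / spectrum$inv_bias[k]
}

#' Extract transition voltages across a sweep ensemble
#'
#' Runs [fn_transform()] and [find_vtrans()] per sweep and polarity.
#'
#' @param data long sweep ensemble (`sweep`, `v`, `i`).
#' @param polarities polarities analysed (pooled downstream by absolute
#'   value).
#' @inheritParams fn_transform
#' @inheritParams find_vtrans
#' @return tibble `sweep`, `polarity`, `vtrans` (V, `NA` when undefined).
#' @export
extract_vtrans <- function(data, polarities = c("positive", "negative"),
                           v_min = 0.1, smooth_points = 5) {
  grid <- tidyr::expand_grid(sweep = unique(data$sweep),
                             polarity = polarities)
  purrr::pmap(grid, function(sweep, polarity) {
    d <- dplyr::filter(data, .data$sweep == !!sweep)
    vt <- tryCatch(
      find_vtrans(fn_transform(d, polarity, v_min), smooth_points),
      error = function(e) NA_real_
    )
    tibble::tibble(sweep = sweep, polarity = polarity, vtrans = vt)
  }) |> dplyr::bind_rows()
}

#' Transition-voltage histogram and summary
#'
#' Pools the defined transition voltages of an ensemble (both polarities,
#' by absolute value), histograms them and reports mean and sd.
#'
#' @param vtrans_tbl an [extract_vtrans()] result (or any tibble with a
#'   `vtrans` column).
#' @param binwidth histogram bin width, V.
#' @return object of class `zj_vtrans` with `mean`, `sd`, `n`, and the
#'   histogram (`breaks`, `counts`).
#' @export
vtrans_summary <- function(vtrans_tbl, binwidth = 0.02) {
  v <- vtrans_tbl$vtrans
  v <- v[!is.na(v)]
  if (!length(v)) abort("no defined transition voltages")
  breaks <- seq(floor(min(v) / binwidth) * binwidth,
                ceiling(max(v) / binwidth) * binwidth + binwidth,
                by = binwidth)
  counts <- tabulate(findInterval(v, breaks, rightmost.closed = TRUE),
                     nbins = length(breaks) - 1)
  structure(list(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
                 n = length(v), breaks = breaks, counts = counts,
                 values = v),
            class = "zj_vtrans")
}

#' @export
print.zj_vtrans <- function(x, ...) {
  cat(sprintf("<zj_vtrans> mean %.3f V, sd %.3f V (n = %d)\n",
              x$mean, x$sd, x$n))
  invisible(x)
}
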