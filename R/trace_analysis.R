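#' Set the displacement origin of conductance traces
#'
#' Applies the experimental origin convention: the displacement axis of
#' each trace is shifted so that the first sample with conductance below
#' `threshold` (50 mG0) sits at z = 0. Samples before the crossing keep
#' negative displacements and are retained. Traces that never drop below
#' the threshold cannot be originated; they are flagged (`originated =
#' FALSE`) and left unshifted, to be excluded from downstream histograms.
#'
#' The operation is idempotent: re-applying it shifts by zero.
#'
#' @param data a trace tibble (`z`, `g`) or long ensemble (`trace`, `z`,
#'   `g`).
#' @param threshold origin threshold in G0 (default 0.05, i.e. 50 mG0).
#' @return the input with `z` shifted per trace and a logical `originated`
#'   column.
#' @export
#' @examples
#' tr <- gen_bj_trace(trace_params("90mer"), seed = 1)
#' tr0 <- set_displacement_origin(tr)
#' tr0$z[which(tr0$g < 0.05)[1]]  # exactly 0
set_displacement_origin <- function(data, threshold = 0.05) {
  one <- function(d) {
    k <- which(d$g < threshold)[1]
    if (is.na(k)) {
      d$originated <- FALSE
    } else {
      d$z <- d$z - d$z[k]
      d$originated <- TRUE
    }
    d
  }
  apply_per_trace(data, one)
}

# run f per trace for single-trace or long-ensemble tibbles, keeping attrs
apply_per_trace <- function(data, f) {
  att <- attributes(data)[c("meta", "truth")]
  out <- if (!"trace" %in% names(data)) {
    f(data)
  } else {
    dplyr::bind_rows(purrr::map(split(data, data$trace), f))
  }
  for (a in names(att)) if (!is.null(att[[a]])) attr(out, a) <- att[[a]]
  out
}

trace_step <- function(d) {
  m <- attr(d, "meta")
  if (!is.null(m) && !is.null(m$tip_velocity)) {
    m$tip_velocity / m$sample_rate
  } else {
    median(diff(d$z))
  }
}

#' Plateau-filter configuration
#'
#' Parameters of the per-trace-histogram plateau judgement used to remove
#' traces with a simple exponential decay: a log10-conductance histogram
#' with bins of `bin_decades` over `range` (log10 G/G0) is built for each
#' trace, bin counts are converted to displacement through the sampling
#' step, and a plateau is declared when the fullest bin holds at least
#' `min_plateau_nm` of displacement. `max_gap` (samples) controls how the
#' contiguous plateau window is grown around the modal bin.
#'
#' @param bin_decades histogram bin width, decades.
#' @param range log10(G/G0) range of the histogram.
#' @param min_plateau_nm occupancy threshold, nm.
#' @param max_gap maximum in-window sample gap when clustering modal-bin
#'   samples.
#' @return object of class `zj_plateau_config`.
#' @export
plateau_config <- function(bin_decades = 0.2, range = c(-7, -1),
                           min_plateau_nm = 0.05, max_gap = 10) {
  stopifnot(bin_decades > 0, length(range) == 2, range[1] < range[2],
            min_plateau_nm > 0, max_gap >= 0)
  structure(list(bin_decades = bin_decades, range = range,
                 min_plateau_nm = min_plateau_nm, max_gap = max_gap),
            class = "zj_plateau_config")
}

plateau_judge_one <- function(d, cfg, step) {
  lg <- log10(d$g)
  edges <- seq(cfg$range[1], cfg$range[2], by = cfg$bin_decades)
  bin <- findInterval(lg, edges, rightmost.closed = TRUE)
  inr <- bin >= 1 & bin <= length(edges) - 1
  if (!any(inr)) {
    return(tibble::tibble(present = FALSE, z_start = NA_real_,
                          z_end = NA_real_, band_center = NA_real_,
                          occupancy_nm = 0))
  }
  counts <- tabulate(bin[inr], nbins = length(edges) - 1)
  mode_bin <- which.max(counts)
  occ <- counts[mode_bin] * step
  present <- occ >= cfg$min_plateau_nm
  idx <- which(bin == mode_bin)
  # keep the largest near-contiguous cluster of modal-bin samples
  br <- which(diff(idx) > cfg$max_gap + 1)
  grp <- cumsum(c(1, as.integer(seq_along(idx)[-1] %in% (br + 1))))
  best <- which.max(tabulate(grp))
  idx <- idx[grp == best]
  tibble::tibble(
    present = present,
    z_start = d$z[min(idx)],
    z_end = d$z[max(idx)],
    band_center = 10^((edges[mode_bin] + edges[mode_bin + 1]) / 2) * 1e3,
    occupancy_nm = occ
  )
}

#' Filter trace ensembles by per-trace plateau judgement
#'
#' Implements the automated removal of traces showing only a simple
#' exponential decay: each trace's log-conductance histogram is examined
#' and the trace is retained only when some bin's occupancy, converted to
#' displacement, reaches the plateau threshold (see [plateau_config()]).
#' The modal bin also yields the plateau band centre and the plateau
#' window `[z_start, z_end]` used by [fit_decay_constants()].
#'
#' @param data an originated long ensemble (`trace`, `z`, `g`,
#'   `originated`).
#' @param cfg a [plateau_config()].
#' @return a list of class `zj_filter` with elements `retained` (the
#'   plateau-bearing subset of `data`) and `report` (per-trace tibble:
#'   `trace`, `present`, `z_start`, `z_end`, `band_center` in mG0,
#'   `occupancy_nm`).
#' @export
filter_plateau_traces <- function(data, cfg = plateau_config()) {
  if (!nrow(data)) abort("empty ensemble")
  if (!"trace" %in% names(data)) data <- dplyr::mutate(data, trace = 1L)
  if ("originated" %in% names(data)) {
    data <- dplyr::filter(data, .data$originated)
  }
  parts <- split(data, data$trace)
  report <- dplyr::bind_rows(purrr::map(parts, function(d) {
    dplyr::mutate(plateau_judge_one(d, cfg, trace_step(data)),
                  trace = d$trace[1], .before = 1)
  }))
  keep <- report$trace[report$present]
  retained <- dplyr::filter(data, .data$trace %in% keep)
  attr(retained, "meta") <- attr(data, "meta")
  structure(list(retained = retained, report = report), class = "zj_filter")
}

#' @export
print.zj_filter <- function(x, ...) {
  cat(sprintf("<zj_filter> %d / %d traces retained\n",
              sum(x$report$present), nrow(x$report)))
  invisible(x)
}

#' Two-dimensional conductance-displacement histogram
#'
#' Overlays all originated traces of an ensemble on a common
#' (z, log10 G) grid, as used to visualise plateau populations across
#' thousands of traces. Counts are summed over traces; the total equals
#' the number of in-range samples.
#'
#' @param data originated long ensemble.
#' @param z_edges displacement bin edges, nm.
#' @param logg_edges log10(G/G0) bin edges.
#' @return object of class `zj_hist2d`: list with `z_edges`, `logg_edges`
#'   and the `counts` matrix (rows = z bins, columns = log10 G bins).
#' @export
trace_histogram2d <- function(data,
                              z_edges = seq(-0.1, 1, by = 0.01),
                              logg_edges = seq(-7, -1, by = 0.05)) {
  if (any(diff(z_edges) <= 0) || any(diff(logg_edges) <= 0)) {
    abort("histogram edges must be strictly increasing")
  }
  if ("originated" %in% names(data)) {
    data <- dplyr::filter(data, .data$originated)
  }
  iz <- findInterval(data$z, z_edges, rightmost.closed = TRUE)
  ig <- findInterval(log10(data$g), logg_edges, rightmost.closed = TRUE)
  ok <- iz >= 1 & iz <= length(z_edges) - 1 & ig >= 1 & ig <= length(logg_edges) - 1
  counts <- matrix(0L, length(z_edges) - 1, length(logg_edges) - 1)
  tab <- table(factor(iz[ok], levels = seq_len(nrow(counts))),
               factor(ig[ok], levels = seq_len(ncol(counts))))
  counts[] <- as.integer(tab)
  structure(list(z_edges = z_edges, logg_edges = logg_edges, counts = counts),
            class = "zj_hist2d")
}

#' Gaussian peak of the plateau-conductance histogram
#'
#' Pools the log10-conductance samples of a retained ensemble inside
#' `fit_range`, histograms them, and fits a single Gaussian in log space.
#' The centre is back-transformed to mG0; the width is reported in
#' decades. Degenerate histograms (fewer than three occupied bins) fall
#' back to weighted moments, so an ensemble of constant traces yields the
#' constant with zero width.
#'
#' @param data retained ensemble (e.g. `filter_plateau_traces(...)$retained`).
#' @param fit_range conductance window in mG0 over which to fit.
#' @param bin_decades histogram bin width.
#' @return object of class `zj_peak` with fields `center` (mG0),
#'   `sd_log10` (decades), `amplitude` (counts), `n_samples`.
#' @export
conductance_peak <- function(data, fit_range = c(1.0, 3.6),
                             bin_decades = 0.02) {
  stopifnot(length(fit_range) == 2, fit_range[1] > 0,
            fit_range[2] > fit_range[1])
  lo <- log10(fit_range[1] * 1e-3)
  hi <- log10(fit_range[2] * 1e-3)
  lg <- log10(data$g)
  lg <- lg[lg >= lo & lg <= hi]
  if (!length(lg)) abort("no samples inside fit_range")
  edges <- seq(lo, hi + bin_decades, by = bin_decades)
  mids <- edges[-length(edges)] + bin_decades / 2
  counts <- tabulate(findInterval(lg, edges, rightmost.closed = TRUE),
                     nbins = length(mids))
  occupied <- sum(counts > 0)
  if (occupied < 3) {
    mu <- sum(mids * counts) / sum(counts)
    s <- sqrt(max(0, sum(counts * (mids - mu)^2) / sum(counts)))
    fit <- NULL
    amp <- max(counts)
  } else {
    mu0 <- mids[which.max(counts)]
    s0 <- max(sd(lg), bin_decades)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        counts ~ A * exp(-(mids - mu)^2 / (2 * s^2)),
        start = list(A = max(counts), mu = mu0, s = s0),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) abort("Gaussian peak fit failed (degenerate histogram)")
    cf <- coef(fit)
    mu <- cf[["mu"]]; s <- abs(cf[["s"]]); amp <- cf[["A"]]
  }
  structure(list(center = 10^mu * 1e3, sd_log10 = s, amplitude = amp,
                 n_samples = length(lg), fit = fit,
                 fit_range = fit_range),
            class = "zj_peak")
}

#' @export
print.zj_peak <- function(x, ...) {
  cat(sprintf("<zj_peak> center %.3g mG0, sd %.3g decades (%d samples)\n",
              x$center, x$sd_log10, x$n_samples))
  invisible(x)
}

#' Decay-fit configuration
#'
#' @param noise_floor_G0 lower conductance bound of the post-plateau fit
#'   window (default 10^-6.5 G0).
#' @param min_points minimum samples per fit window.
#' @param refine iteratively trim window endpoints whose residuals are
#'   inconsistent with the fitted segment (removes the few samples where
#'   the detected window overhangs a neighbouring decay segment; inactive
#'   on noisy data because the criterion is scaled to the residual sd).
#' @param guard_frac fraction of samples excluded from each end of the
#'   plateau window before the `beta1` fit. The window is detected in
#'   conductance space, so its extremes always contain the samples where
#'   the steep flanking decays cross the plateau band; guarding them keeps
#'   the in-plateau slope unbiased under noise while leaving noise-free
#'   (collinear) windows unaffected.
#' @return object of class `zj_decay_config`.
#' @export
decay_config <- function(noise_floor_G0 = 10^-6.5, min_points = 5,
                         refine = TRUE, guard_frac = 0.15) {
  stopifnot(noise_floor_G0 > 0, min_points >= 3,
            guard_frac >= 0, guard_frac < 0.5)
  structure(list(noise_floor_G0 = noise_floor_G0, min_points = min_points,
                 refine = refine, guard_frac = guard_frac),
            class = "zj_decay_config")
}

# least squares of y ~ x with optional endpoint trimming; the robust
# (MAD-based) residual scale makes the trim insensitive to a few gross
# window-overhang points while leaving noisy-but-consistent windows alone
trim_fit <- function(x, y, min_points, refine, abs_tol = 1e-10) {
  repeat {
    ft <- lm(y ~ x)
    r <- stats::resid(ft)
    if (!refine || length(x) <= min_points) break
    s <- max(stats::mad(r), abs_tol)
    ends <- c(1, length(x))
    worst <- ends[which.max(abs(r[ends]))]
    if (abs(r[worst]) <= 3 * s) break
    x <- x[-worst]; y <- y[-worst]
  }
  sst <- sum((y - mean(y))^2)
  list(slope = coef(ft)[[2]], r2 = if (sst > 0) 1 - sum(r^2) / sst else 1,
       n = length(x), window = range(x), resid_sd = sd(r))
}

#' Fit the two tunnelling decay constants of a trace
#'
#' Least-squares fit of ln G versus z (in Angstrom) within the plateau
#' window (`beta1`) and between the plateau end and the noise floor
#' (`beta2`). For a bare trace (no plateau, `plateau = NULL`) a single
#' decay constant is fitted over the full post-origin range down to the
#' noise floor and returned as `beta2` with `beta1 = NA`.
#'
#' @param data one originated trace (`z`, `g`).
#' @param plateau the trace's row of a [filter_plateau_traces()] report
#'   (needs `z_start`, `z_end`), or `NULL` for a single-decay fit.
#' @param cfg a [decay_config()].
#' @return object of class `zj_decay` with `beta1`, `beta2` (1/Angstrom),
#'   the fitted windows (nm) and per-segment R^2.
#' @export
#' @examples
#' tr <- set_displacement_origin(
#'   gen_bj_trace(trace_params("bare"), noise_sd_log10G = 0, seed = 1))
#' fit_decay_constants(tr, plateau = NULL)$beta2  # 2.2
fit_decay_constants <- function(data, plateau, cfg = decay_config()) {
  lg <- log10(data$g)
  if (is.null(plateau)) {
    k_end <- which(data$g <= cfg$noise_floor_G0)[1]
    if (is.na(k_end)) k_end <- nrow(data)
    w2 <- which(data$z >= 0 & seq_len(nrow(data)) < k_end)
    if (length(w2) < cfg$min_points) abort("too few samples for decay fit")
    f2 <- trim_fit(data$z[w2], lg[w2], cfg$min_points, cfg$refine)
    return(structure(list(beta1 = NA_real_, beta2 = dec_per_nm_to_beta_A(f2$slope),
                          window1 = c(NA_real_, NA_real_), window2 = f2$window,
                          r2 = c(NA_real_, f2$r2)), class = "zj_decay"))
  }
  if (!isTRUE(plateau$present)) abort("trace has no detected plateau")
  w1 <- which(data$z >= plateau$z_start & data$z <= plateau$z_end)
  ng <- floor(length(w1) * cfg$guard_frac)
  if (length(w1) - 2 * ng >= cfg$min_points && ng > 0) {
    w1 <- w1[(ng + 1):(length(w1) - ng)]
  }
  if (length(w1) < cfg$min_points) abort("too few samples in a fit window")
  f1 <- trim_fit(data$z[w1], lg[w1], cfg$min_points, cfg$refine)
  # the post-plateau window opens where the trace departs downward from the
  # extrapolated plateau line (beyond the in-plateau residual scale), so a
  # plateau wider than the modal histogram bin cannot leak into the beta2 fit
  line1 <- lg[w1[1]] - f1$slope * data$z[w1[1]] + f1$slope * data$z
  dev_tol <- max(5 * f1$resid_sd, 0.01)
  cand <- which(data$z > plateau$z_end & lg < line1 - dev_tol)
  k_start <- if (length(cand)) cand[1] else NA_integer_
  k_end <- which(data$g <= cfg$noise_floor_G0 & data$z > plateau$z_end)[1]
  if (is.na(k_end)) k_end <- nrow(data)
  if (is.na(k_start) || k_end - k_start < cfg$min_points) {
    abort("too few samples in a fit window")
  }
  w2 <- seq(k_start, k_end - 1)
  f2 <- trim_fit(data$z[w2], lg[w2], cfg$min_points, cfg$refine)
  structure(list(beta1 = dec_per_nm_to_beta_A(f1$slope),
                 beta2 = dec_per_nm_to_beta_A(f2$slope),
                 window1 = f1$window, window2 = f2$window,
                 r2 = c(f1$r2, f2$r2)), class = "zj_decay")
}

#' @export
print.zj_decay <- function(x, ...) {
  cat(sprintf("<zj_decay> beta1 %.4g, beta2 %.4g 1/Angstrom\n",
              x$beta1, x$beta2))
  invisible(x)
}

#' Fit decay constants across a retained ensemble
#'
#' @param flt a `zj_filter` result.
#' @param cfg a [decay_config()].
#' @return tibble with one row per retained trace: `trace`, `beta1`,
#'   `beta2`, `r2_1`, `r2_2`.
#' @export
fit_decay_ensemble <- function(flt, cfg = decay_config()) {
  stopifnot(inherits(flt, "zj_filter"))
  rep_ok <- dplyr::filter(flt$report, .data$present)
  parts <- split(flt$retained, flt$retained$trace)
  dplyr::bind_rows(purrr::map(seq_len(nrow(rep_ok)), function(k) {
    tr <- as.character(rep_ok$trace[k])
    ft <- tryCatch(fit_decay_constants(parts[[tr]], rep_ok[k, ], cfg),
                   error = function(e) NULL)
    if (is.null(ft)) return(NULL)
    tibble::tibble(trace = rep_ok$trace[k], beta1 = ft$beta1,
                   beta2 = ft$beta2, r2_1 = ft$r2[1], r2_2 = ft$r2[2])
  }))
}
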