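#' Generate the formation record of a consecutive-trace series
#'
#' Lightweight generator of the per-trace junction formation state and the
#' associated dwell lengths, without synthesising full G-z traces.
#' `"persistent"` mode runs a two-state Markov chain with self-transition
#' `p_persist` from the formed state and entry probability chosen so the
#' stationary formation fraction is `p_form`; `"independent"` mode draws
#' i.i.d. Bernoulli(`p_form`). Dwells for formed traces are log-normal with
#' the configured mean/sd; unformed traces have dwell
#' `dwell_given_unformed_mean` (0 by default).
#'
#' @param params a [series_params()] object.
#' @param seed optional integer seed.
#' @return tibble with columns `trace`, `formed`, `dwell` (nm).
#' @export
#' @examples
#' gen_formation_series(series_params("independent", n_traces = 10), seed = 1)
gen_formation_series <- function(params, seed = NULL) {
  stopifnot(inherits(params, "zj_series_params"))
  if (params$mode == "simulator") {
    abort("use gen_simulated_series() for simulator-driven series")
  }
  if (!is.null(seed)) withr::local_seed(seed)
  n <- params$n_traces
  formed <- logical(n)
  if (params$mode == "independent") {
    formed <- runif(n) < params$p_form
  } else {
    p11 <- params$p_persist
    p01 <- if (params$p_form >= 1) 1 else {
      params$p_form * (1 - p11) / (1 - params$p_form)
    }
    if (params$p_form >= 1) p11 <- 1
    formed[1] <- runif(1) < params$p_form   # start from stationarity
    for (k in seq_len(n)[-1]) {
      p <- if (formed[k - 1]) p11 else p01
      formed[k] <- runif(1) < p
    }
  }
  dwell <- ifelse(
    formed,
    draw_lognormal(n, params$dwell_given_formed_mean,
                   params$dwell_given_formed_sd),
    params$dwell_given_unformed_mean
  )
  tibble::tibble(trace = seq_len(n), formed = formed, dwell = dwell)
}

#' Generate a consecutive series of conductance traces
#'
#' Expands a formation record (persistent or independent mode) into full
#' synthetic G-z traces: formed traces receive a plateau whose length is
#' the drawn dwell, unformed traces are bare tunnelling decays.
#'
#' @param params a [series_params()] object.
#' @param trace_params a [trace_params()] object for the trace shapes.
#' @param seed optional integer seed.
#' @return long tibble `trace`, `z`, `g` with the formation record in the
#'   `truth` attribute.
#' @export
gen_consecutive_series <- function(params, trace_params = trace_params("90mer"),
                                   seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  rec <- gen_formation_series(params)
  out <- dplyr::bind_rows(purrr::map(seq_len(nrow(rec)), function(k) {
    tr <- gen_bj_trace(trace_params,
                       with_plateau = rec$formed[k] && rec$dwell[k] > 0,
                       plateau_length = if (rec$formed[k]) rec$dwell[k])
    dplyr::mutate(tr, trace = k, .before = 1)
  }))
  attr(out, "truth") <- rec
  attr(out, "meta") <- list(tip_velocity = trace_params$tip_velocity,
                            sample_rate = trace_params$sample_rate,
                            preset = trace_params$preset)
  out
}

#' Simulator-driven consecutive-trace series
#'
#' Delegates the formation state to the zipper model: for each trace a
#' [kmc_run()] is performed on the given duplex, the pull phase is mapped
#' to a conductance trace through [junction_conductance()], and the next
#' cycle starts from the duplex state the previous one left behind
#' (fully reannealed after a return protocol, separated otherwise, in
#' which case a fresh duplex forms with probability `p_rebind`).
#'
#' @param n_traces number of consecutive pull cycles.
#' @param sequence duplex base string (one strand).
#' @param zipper a [zipper_params()] object.
#' @param protocol a [pull_protocol()] object (return protocol advised).
#' @param mapping a [junction_conductance()] mapping config, see
#'   [conductance_mapping()].
#' @param p_rebind probability a separated duplex re-forms before the next
#'   cycle (in-solution rehybridisation is outside the zipper model).
#' @param seed optional integer seed.
#' @return long tibble `trace`, `z`, `g`; `truth` attribute records the
#'   per-cycle formation state (duplex intact at the start of the pull).
#' @export
gen_simulated_series <- function(n_traces, sequence, zipper = zipper_params(),
                                 protocol = pull_protocol(),
                                 mapping = conductance_mapping(),
                                 p_rebind = 0.3, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  intact <- TRUE
  rows <- vector("list", n_traces)
  formed <- logical(n_traces)
  for (k in seq_len(n_traces)) {
    if (!intact && runif(1) < p_rebind) intact <- TRUE
    formed[k] <- intact
    if (intact) {
      traj <- kmc_run(sequence, zipper, protocol)
      tr <- trajectory_trace(traj, mapping)
      intact <- attr(traj, "termination") == "completed" &&
        final_open_bp(traj) < nchar(sequence)
    } else {
      tr <- gen_bj_trace(trace_params("bare"), with_plateau = FALSE)
    }
    rows[[k]] <- dplyr::mutate(tr, trace = k, .before = 1)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- tibble::tibble(trace = seq_len(n_traces),
                                       formed = formed)
  out
}
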