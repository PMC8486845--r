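#' Break-junction trace generator parameters
#'
#' Bundles the parameters of the two-segment exponential trace model used by
#' [gen_bj_trace()]. The presets mirror the experimental conditions of the
#' STM break-junction measurements on zipper-configured DNA duplexes:
#'
#' * `"90mer"`: plateau at 1.9 mG0, in-plateau decay `beta1 = 0.27` 1/A,
#'   post-plateau decay `beta2 = 2.0` 1/A;
#' * `"10mer"`: plateau at 0.15 mG0 (decay constants as for the 90-mer;
#'   the short-duplex decay analysis is not separately parameterised);
#' * `"bare"`: no molecular plateau, single direct-tunnelling decay of
#'   2.2 1/A.
#'
#' Tip velocity (31 nm/s) and sampling rate (20 kHz) follow the experiment,
#' giving a displacement step of 1.55 pm per sample. Plateau lengths are
#' drawn log-normal; the defaults (mean 0.15 nm / 0.07 nm, sd 50% of the
#' mean) are generator choices, as is the 0.1-decade multiplicative noise.
#'
#' @param preset one of `"90mer"`, `"10mer"`, `"bare"`.
#' @param ... named overrides for any listed field.
#' @return an object of class `zj_trace_params` (a named list) with fields
#'   `plateau_conductance` (mG0), `plateau_length_mean`, `plateau_length_sd`
#'   (nm), `beta1`, `beta2`, `beta_bare` (1/A), `start_conductance` (mG0),
#'   `noise_sd_log10G` (decades), `sample_rate` (Hz), `tip_velocity` (nm/s),
#'   `noise_floor` (G0), `plateau_probability`, `tail_nm`.
#' @export
#' @examples
#' trace_params("90mer")
#' trace_params("10mer", noise_sd_log10G = 0)
trace_params <- function(preset = c("90mer", "10mer", "bare"), ...) {
  preset <- match.arg(preset)
  p <- list(
    preset              = preset,
    plateau_conductance = 1.9,      # mG0
    plateau_length_mean = 0.15,     # nm
    plateau_length_sd   = 0.075,    # nm
    beta1               = 0.27,     # 1/Angstrom
    beta2               = 2.0,      # 1/Angstrom
    beta_bare           = 2.2,      # 1/Angstrom
    start_conductance   = 100,      # mG0
    noise_sd_log10G     = 0.1,      # decades
    sample_rate         = 20000,    # Hz
    tip_velocity        = 31,       # nm/s
    noise_floor         = 1e-7,     # G0
    plateau_probability = 0.8,
    tail_nm             = 0.02      # flat noise-floor tail appended
  )
  if (preset == "10mer") {
    p$plateau_conductance <- 0.15
    p$plateau_length_mean <- 0.07
    p$plateau_length_sd   <- 0.035
  }
  if (preset == "bare") {
    p$plateau_probability <- 0
  }
  p <- utils::modifyList(p, list(...))
  validate_trace_params(p)
  structure(p, class = "zj_trace_params")
}

validate_trace_params <- function(p) {
  stopifnot(
    p$tip_velocity > 0, p$sample_rate > 0,
    p$plateau_length_mean >= 0, p$plateau_length_sd >= 0,
    p$beta1 > 0, p$beta2 > 0, p$beta_bare > 0,
    p$noise_sd_log10G >= 0, p$noise_floor > 0,
    p$plateau_probability >= 0, p$plateau_probability <= 1
  )
  if (!(p$start_conductance * 1e-3 > p$plateau_conductance * 1e-3 &&
        p$plateau_conductance * 1e-3 > p$noise_floor)) {
    abort("need start_conductance > plateau_conductance > noise_floor (in G0)")
  }
  invisible(p)
}

#' Current-voltage sweep generator parameters
#'
#' The high-conductance (molecular) state follows the symmetric single-level
#' transmission model with level energy `level_energy` (eV above the Fermi
#' level) and level broadening `coupling` (eV); this guarantees an interior
#' Fowler-Nordheim minimum whose position is tunable via
#' [tune_level_energy()]. The low (empty-gap tunnelling) state is a weakly
#' non-linear polynomial `I = a V + b V^3` whose Fowler-Nordheim minimum
#' `sqrt(a/b)` sits outside the swept range by default.
#'
#' The sweep spans -1.1 V to 1.1 V; at the experimental 5 ms sweep and
#' 20 kHz sampling this is ~100 samples, so `n_points = 101`.
#'
#' @param ... named overrides.
#' @return object of class `zj_iv_params`.
#' @export
iv_params <- function(...) {
  p <- list(
    level_energy        = 0.344,    # eV; tuned so the FN minimum sits at 0.4 V
    coupling            = 0.02,     # eV
    low_state_linear    = 1e-8,     # A/V
    low_state_cubic     = 2.5e-9,   # A/V^3 -> FN minimum at 2 V, outside sweep
    sweep_min           = -1.1,     # V
    sweep_max           = 1.1,      # V
    n_points            = 101,
    high_state_fraction = 0.5,
    noise_sd_logI       = 0.05      # decades
  )
  p <- utils::modifyList(p, list(...))
  stopifnot(
    p$sweep_min < 0, p$sweep_max > 0, p$coupling > 0, p$n_points >= 5,
    p$high_state_fraction >= 0, p$high_state_fraction <= 1,
    p$noise_sd_logI >= 0
  )
  structure(p, class = "zj_iv_params")
}

#' Consecutive-trace series generator parameters
#'
#' Emulates series of consecutive pull-ups (700 traces in the experiment).
#' In `"persistent"` mode the junction formation state is a two-state Markov
#' chain whose stationary formation probability is `p_form` and whose
#' self-transition probability from the formed state is `p_persist`
#' (90-mer-like self-restoration). In `"independent"` mode formation is
#' i.i.d. Bernoulli(`p_form`) (10-mer-like). `"simulator"` mode derives the
#' formation state from zipper-model trajectories via [gen_simulated_series()].
#'
#' @param mode `"persistent"`, `"independent"` or `"simulator"`.
#' @param ... named overrides.
#' @return object of class `zj_series_params`.
#' @export
series_params <- function(mode = c("persistent", "independent", "simulator"), ...) {
  mode <- match.arg(mode)
  p <- list(
    n_traces                = 700,
    mode                    = mode,
    p_form                  = if (mode == "independent") 0.3 else 0.8,
    p_persist               = 0.95,
    dwell_given_formed_mean = 0.15,  # nm
    dwell_given_formed_sd   = 0.075, # nm
    dwell_given_unformed_mean = 0    # nm; unformed traces carry no plateau
  )
  p <- utils::modifyList(p, list(...))
  stopifnot(
    p$n_traces >= 1,
    p$p_form >= 0, p$p_form <= 1, p$p_persist >= 0, p$p_persist <= 1
  )
  if (p$mode == "persistent" && p$p_form < 1) {
    # entry probability giving the requested stationary formation fraction
    q <- p$p_form * (1 - p$p_persist) / (1 - p$p_form)
    if (q > 1) abort("no two-state chain with this (p_form, p_persist); reduce p_form")
  }
  structure(p, class = "zj_series_params")
}

#' Dwell-band configuration for formation judgement
#'
#' The dwell length of a trace is its displacement spent inside a
#' conductance band around the plateau; formation is judged by comparing it
#' to a plateau-length threshold. The experimental bands and thresholds are
#' 1.4-2.4 mG0 / 0.060 nm for the 90-mer and 0.14-0.16 mG0 / 0.028 nm for
#' the 10-mer duplex.
#'
#' @param preset `"90mer"` or `"10mer"`.
#' @param band_low,band_high band edges in mG0.
#' @param threshold_nm formation threshold (inclusive) in nm.
#' @return object of class `zj_dwell_config`.
#' @export
dwell_config <- function(preset = c("90mer", "10mer"),
                         band_low = NULL, band_high = NULL, threshold_nm = NULL) {
  preset <- match.arg(preset)
  d <- if (preset == "90mer") {
    list(band_low = 1.4, band_high = 2.4, threshold_nm = 0.060)
  } else {
    list(band_low = 0.14, band_high = 0.16, threshold_nm = 0.028)
  }
  if (!is.null(band_low)) d$band_low <- band_low
  if (!is.null(band_high)) d$band_high <- band_high
  if (!is.null(threshold_nm)) d$threshold_nm <- threshold_nm
  stopifnot(d$band_low > 0, d$band_high > d$band_low, d$threshold_nm > 0)
  structure(d, class = "zj_dwell_config")
}

#' Zipper-model physical parameters
#'
#' Parameters of the one-dimensional tethered-duplex zipper model: two
#' linker springs of stiffness `k_spring` (8.5 N/m each, the Au-Au bond
#' stiffness) in series with the freely-jointed-chain single-stranded DNA
#' released by the fork, at `temperature` (300 K). `rupture_force` is the
#' Au-S/Au-Au mechanical failure threshold (1-2 nN), far above unzipping
#' forces, and serves as a termination guard.
#'
#' @param ... named overrides.
#' @return object of class `zj_zipper_params`.
#' @export
zipper_params <- function(...) {
  p <- list(
    k_spring       = 8.5,    # N/m per spring
    temperature    = 300,    # K
    contour_per_nt = 0.63,   # nm per nucleotide (ssDNA contour)
    kuhn_length    = 1.5,    # nm
    attempt_rate   = 1e6,    # 1/s
    rupture_force  = 1.5,    # nN
    duplex_rise    = 0.34    # nm per bp
  )
  p <- utils::modifyList(p, list(...))
  stopifnot(
    p$k_spring > 0, p$temperature > 0, p$contour_per_nt > 0,
    p$kuhn_length > 0, p$attempt_rate > 0, p$rupture_force > 0,
    p$duplex_rise > 0
  )
  structure(p, class = "zj_zipper_params")
}

#' Pulling protocol for zipper simulations
#'
#' Pull the tethered end up by `pull_distance` at `pull_velocity`, hold for
#' `hold_time`, then either move back to the origin at the same velocity
#' (`return = TRUE`) or detach the springs (`release_after_pull = TRUE`),
#' and finally dwell for `settle_time` so reannealing can complete.
#' Defaults follow the experiment: 30 nm pull at 31 nm/s, 0.3 s wait.
#'
#' @param pull_distance nm.
#' @param pull_velocity nm/s.
#' @param hold_time s.
#' @param return move the end back to the origin after the hold.
#' @param release_after_pull detach the springs after the pull instead.
#' @param settle_time s of additional zero-drive dwell at the end.
#' @return object of class `zj_protocol`.
#' @export
pull_protocol <- function(pull_distance = 30, pull_velocity = 31,
                          hold_time = 0.3, return = TRUE,
                          release_after_pull = FALSE, settle_time = 0.5) {
  stopifnot(pull_distance >= 0, pull_velocity > 0, hold_time >= 0,
            settle_time >= 0)
  if (return && release_after_pull) {
    abort("choose either `return` or `release_after_pull`, not both")
  }
  structure(
    list(pull_distance = pull_distance, pull_velocity = pull_velocity,
         hold_time = hold_time, return = return,
         release_after_pull = release_after_pull, settle_time = settle_time),
    class = "zj_protocol"
  )
}
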