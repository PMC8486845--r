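#' Single-level model current
#'
#' Zero-temperature Landauer current through one molecular level with a
#' Lorentzian transmission centred at `level_energy` (eV relative to the
#' electrode Fermi energy) and broadening `coupling` (eV), with the bias
#' dropping symmetrically across the two contacts:
#' \deqn{I(V) = G_0 \Gamma [\arctan((V/2-\epsilon_0)/\Gamma) +
#'   \arctan((V/2+\epsilon_0)/\Gamma)].}
#' The current is odd in `V` and exhibits an interior Fowler-Nordheim
#' minimum whose position is set by `level_energy`/`coupling`.
#'
#' @param v bias voltage(s), V.
#' @param level_energy level position, eV.
#' @param coupling level broadening, eV.
#' @return current in A.
#' @export
single_level_current <- function(v, level_energy, coupling) {
  stopifnot(coupling > 0)
  G0_SIEMENS * coupling *
    (atan((v / 2 - level_energy) / coupling) +
     atan((v / 2 + level_energy) / coupling))
}

#' Low-state (empty gap) polynomial current
#'
#' `I = a V + b V^3`, the weakly non-linear tunnelling characteristic of
#' the gap without a molecular bridge. Its Fowler-Nordheim minimum sits at
#' `sqrt(a/b)`, outside the sweep for the defaults.
#'
#' @param v bias, V.
#' @param a linear coefficient, A/V.
#' @param b cubic coefficient, A/V^3.
#' @return current in A.
#' @export
low_state_current <- function(v, a, b) a * v + b * v^3

#' Generate one current-voltage sweep
#'
#' @param state `"high"` (molecular junction, single-level model) or
#'   `"low"` (empty gap, cubic polynomial).
#' @param params an [iv_params()] object.
#' @param seed optional integer seed.
#' @return tibble with columns `v` (V) and `i` (A); attribute `state`.
#'   `I(0)` is exactly zero; noise is multiplicative in the log domain and
#'   sign-preserving.
#' @export
#' @examples
#' sw <- gen_iv_sweep("high", iv_params(), seed = 1)
gen_iv_sweep <- function(state = c("high", "low"), params = iv_params(),
                         seed = NULL) {
  state <- match.arg(state)
  stopifnot(inherits(params, "zj_iv_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  v <- seq(params$sweep_min, params$sweep_max, length.out = params$n_points)
  i <- if (state == "high") {
    single_level_current(v, params$level_energy, params$coupling)
  } else {
    low_state_current(v, params$low_state_linear, params$low_state_cubic)
  }
  if (params$noise_sd_logI > 0) {
    i <- i * 10^rnorm(length(i), 0, params$noise_sd_logI)
  }
  out <- tibble::tibble(v = v, i = i)
  attr(out, "state") <- state
  out
}

#' Generate an ensemble of I-V sweeps
#'
#' Each sweep is drawn from the high (molecular) state with probability
#' `params$high_state_fraction`, otherwise from the low (empty gap) state,
#' emulating the bimodal sweep ensembles observed with DNA-modified tips.
#'
#' @param n number of sweeps.
#' @inheritParams gen_iv_sweep
#' @return tibble with columns `sweep`, `v`, `i`; ground-truth state labels
#'   in the `truth` attribute.
#' @export
gen_iv_ensemble <- function(n, params = iv_params(), seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  states <- ifelse(runif(n) < params$high_state_fraction, "high", "low")
  out <- dplyr::bind_rows(purrr::map(seq_len(n), function(k) {
    dplyr::mutate(gen_iv_sweep(states[k], params), sweep = k, .before = 1)
  }))
  attr(out, "truth") <- tibble::tibble(sweep = seq_len(n), state = states)
  out
}

#' Tune the single-level energy for a target transition voltage
#'
#' Scans the level energy at fixed coupling so that the noise-free
#' Fowler-Nordheim spectrum of the single-level model attains its interior
#' minimum at `target_vtrans`. Used to parameterise the high-state sweep
#' generator (default target 0.4 V).
#'
#' @param target_vtrans desired transition voltage, V.
#' @param coupling level broadening, eV.
#' @param v_range bias range searched for the minimum, V.
#' @return the level energy in eV.
#' @export
#' @examples
#' tune_level_energy(0.4)
tune_level_energy <- function(target_vtrans = 0.4, coupling = 0.02,
                              v_range = c(0.1, 1.1)) {
  stopifnot(target_vtrans > v_range[1], target_vtrans < v_range[2])
  vgrid <- seq(v_range[1], v_range[2], by = 5e-4)
  vmin_of <- function(eps0) {
    vgrid[which.min(log10(single_level_current(vgrid, eps0, coupling) /
                            vgrid^2))]
  }
  egrid <- seq(coupling, 2 * target_vtrans, by = 1e-3)
  vm <- vapply(egrid, vmin_of, numeric(1))
  interior <- vm < v_range[2] - 2 * coupling
  if (!any(interior)) abort("no interior Fowler-Nordheim minimum in scan range")
  best <- which.min(abs(vm - target_vtrans) + ifelse(interior, 0, Inf))
  egrid[best]
}
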