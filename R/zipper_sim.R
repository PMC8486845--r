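#' Freely-jointed-chain extension per nucleotide
#'
#' Entropic elasticity of the single-stranded DNA released by the fork:
#' extension per nucleotide is the contour length times the Langevin
#' function of `f * kuhn_length / kT`. Strictly increasing in force, 0 at
#' zero force, saturating at the contour length.
#'
#' @param force pN (vectorised).
#' @param params a [zipper_params()].
#' @return extension in nm per nucleotide.
#' @export
#' @examples
#' fjc_extension(c(0, 5, 50), zipper_params())
fjc_extension <- function(force, params = zipper_params()) {
  stopifnot(all(force >= 0))
  kT <- kT_pN_nm(params$temperature)
  xi <- force * params$kuhn_length / kT
  L <- function(x) {
    ifelse(x < 1e-4, x / 3 - x^3 / 45, 1 / tanh(pmax(x, 1e-12)) - 1 / x)
  }
  params$contour_per_nt * L(xi)
}

#' Force balance of the tethered zipper at fixed tip height
#'
#' Solves for the unique tension `f` at which the total extension -- two
#' linker springs in series (compliance `2/k_spring`) plus `2 * n_open`
#' nucleotides of freely-jointed-chain ssDNA -- equals the tip height
#' `z_tip`. Returns 0 when the chain is slack (`z_tip <= 0`).
#'
#' @param n_open open base pairs (vectorised with `z_tip`).
#' @param z_tip tip height above the rest position, nm.
#' @param params a [zipper_params()].
#' @return force in pN.
#' @export
#' @examples
#' force_balance(10, 5, zipper_params())
force_balance <- function(n_open, z_tip, params = zipper_params()) {
  stopifnot(all(n_open >= 0), length(n_open) == length(z_tip) ||
              length(n_open) == 1 || length(z_tip) == 1)
  kT <- kT_pN_nm(params$temperature)
  n <- pmax(length(n_open), length(z_tip))
  n_open <- rep_len(n_open, n); z_tip <- rep_len(z_tip, n)
  vapply(seq_len(n), function(k) {
    solve_force_r(n_open[k], z_tip[k], params, kT)
  }, numeric(1))
}

# reference R root-finder (uniroot + Newton polish); the KMC core uses an
# independent C++ implementation of the same balance
solve_force_r <- function(n_open, z, params, kT) {
  if (z <= 0) return(0)
  k <- params$k_spring * 1000  # pN/nm
  ext <- function(f) 2 * f / k + 2 * n_open * fjc_extension(f, params)
  hi <- k * z / 2 + 1
  f <- uniroot(function(f) ext(f) - z, lower = 0, upper = hi,
               tol = 1e-12)$root
  for (i in 1:50) {
    r <- ext(f) - z
    if (abs(r) < 1e-12) break
    dl <- function(x) ifelse(x < 1e-4, 1 / 3 - x^2 / 15,
                             1 / x^2 - 1 / sinh(pmin(x, 30))^2)
    xi <- f * params$kuhn_length / kT
    d <- 2 / k + 2 * n_open * params$contour_per_nt * dl(xi) *
      params$kuhn_length / kT
    f <- max(0, f - r / d)
  }
  f
}

#' Elastic free energy of the tether at fixed tip height
#'
#' Spring energy `f^2 / k_spring` plus the Helmholtz free energy of the
#' released ssDNA (Legendre transform of the FJC Gibbs branch), evaluated
#' at the balanced force. This is the mechanical part of the zipper-state
#' energy used by the kinetic Monte Carlo acceptance rule.
#'
#' @inheritParams force_balance
#' @return energy in pN nm.
#' @export
elastic_energy <- function(n_open, z_tip, params = zipper_params()) {
  kT <- kT_pN_nm(params$temperature)
  f <- force_balance(n_open, z_tip, params)
  xi <- f * params$kuhn_length / kT
  lsc <- ifelse(xi < 1e-4, xi^2 / 6,
                ifelse(xi > 30, xi - log(2 * xi), log(sinh(xi) / xi)))
  per_nt <- f * fjc_extension(f, params) -
    (params$contour_per_nt / params$kuhn_length) * kT * lsc
  f^2 / (params$k_spring * 1000) + 2 * n_open * per_nt
}

#' Exact Boltzmann distribution of the fork coordinate
#'
#' Enumerates all fork states `n_open = 0..n_bp` of a duplex at fixed tip
#' height and returns their Boltzmann weights,
#' `E(n) = sum(opening costs up to n) + elastic energy(n, z)`. The fully
#' open state carries no elastic term (the strands are mechanically
#' decoupled). Used as the exact oracle for the KMC sampler on small
#' duplexes.
#'
#' @param sequence duplex base string.
#' @param z_tip tip height, nm.
#' @param params a [zipper_params()].
#' @return tibble `n_open`, `energy_kT`, `prob`.
#' @export
exact_zipper_distribution <- function(sequence, z_tip,
                                      params = zipper_params()) {
  kT <- kT_pN_nm(params$temperature)
  costs <- nn_step_free_energies(sequence, params$temperature)$dg_open
  costs_kT <- kcal_to_kT(costs, params$temperature)
  n_bp <- length(costs_kT)
  e_open <- cumsum(c(0, costs_kT))
  e_el <- c(vapply(0:(n_bp - 1), function(n) {
    elastic_energy(n, z_tip, params) / kT
  }, numeric(1)), 0)
  e <- e_open + e_el
  w <- exp(-(e - min(e)))
  tibble::tibble(n_open = 0:n_bp, energy_kT = e, prob = w / sum(w))
}

#' Run a kinetic Monte Carlo zipper simulation
#'
#' Metropolis KMC over the fork coordinate of a tethered duplex under a
#' pull-hold-return (or pull-release) protocol. Candidate moves open or
#' close one base pair at the fork at `attempt_rate`; acceptance uses the
#' nearest-neighbour opening cost plus the change in elastic free energy
#' at the instantaneous tip height. The run terminates early on strand
#' separation under tension or if the tether force exceeds the Au-S
#' rupture threshold; the cause is recorded.
#'
#' @param sequence duplex base string (tethered, fork-side end first).
#' @param params a [zipper_params()].
#' @param protocol a [pull_protocol()].
#' @param seed optional integer seed (trajectories are bit-reproducible
#'   for a fixed seed and stride).
#' @param sample_dt trajectory sampling interval, s.
#' @param terminate_on_separation set `FALSE` to keep sampling the fully
#'   open state (used for equilibrium validation runs).
#' @return a tibble of class `zj_trajectory` with columns `t` (s), `z_tip`
#'   (nm), `n_open`, `force` (pN); attributes `termination`, `sequence`,
#'   `n_bp`, `params`, `protocol`.
#' @export
#' @examples
#' traj <- kmc_run(gen_sequence(10, seed = 1), zipper_params(),
#'                 pull_protocol(pull_distance = 2, hold_time = 0.01,
#'                               settle_time = 0.01), seed = 1)
kmc_run <- function(sequence, params = zipper_params(),
                    protocol = pull_protocol(), seed = NULL,
                    sample_dt = 1e-3, terminate_on_separation = TRUE) {
  stopifnot(inherits(params, "zj_zipper_params"),
            inherits(protocol, "zj_protocol"))
  if (!is.null(seed)) withr::local_seed(seed)
  kT <- kT_pN_nm(params$temperature)
  costs <- nn_step_free_energies(sequence, params$temperature)$dg_open
  costs_kT <- kcal_to_kT(costs, params$temperature)

  v <- protocol$pull_velocity
  t1 <- protocol$pull_distance / v
  ph <- list(c(0, t1, 0, v),
             c(t1, t1 + protocol$hold_time, protocol$pull_distance, 0))
  t2 <- t1 + protocol$hold_time
  if (protocol$return) {
    t3 <- t2 + t1
    ph <- c(ph, list(c(t2, t3, protocol$pull_distance, -v),
                     c(t3, t3 + protocol$settle_time, 0, 0)))
  } else {
    ph <- c(ph, list(c(t2, t2 + protocol$settle_time,
                       protocol$pull_distance, 0)))
  }
  phases <- do.call(rbind, ph[vapply(ph, function(p) p[2] > p[1], logical(1))])
  if (is.null(phases) || !nrow(phases)) abort("protocol has zero duration")

  stride <- max(1L, as.integer(round(params$attempt_rate * sample_dt)))
  res <- kmc_core(costs_kT, params$k_spring * 1000, kT,
                  params$contour_per_nt, params$kuhn_length,
                  params$attempt_rate, phases,
                  protocol$release_after_pull, t1,
                  params$rupture_force * 1000, 0.5,
                  stride, terminate_on_separation)
  out <- tibble::tibble(t = res$t, z_tip = res$z_tip,
                        n_open = res$n_open, force = res$force)
  class(out) <- c("zj_trajectory", class(out))
  attr(out, "termination") <- res$termination
  attr(out, "sequence") <- sequence
  attr(out, "n_bp") <- length(costs_kT)
  attr(out, "params") <- params
  attr(out, "protocol") <- protocol
  out
}

#' @export
print.zj_trajectory <- function(x, ...) {
  cat(sprintf("<zj_trajectory> %d bp, %d frames, termination: %s\n",
              attr(x, "n_bp"), nrow(x), attr(x, "termination")))
  NextMethod()
}

#' Per-pair open/closed record at a trajectory frame
#'
#' In the fork-coordinate model pair `i` is open exactly when
#' `i <= n_open` (pairs are counted from the tethered end).
#'
#' @param traj a [kmc_run()] trajectory.
#' @param frame frame index (default: last frame).
#' @return tibble `pair`, `open`.
#' @export
pair_state_at <- function(traj, frame = nrow(traj)) {
  n_bp <- attr(traj, "n_bp")
  tibble::tibble(pair = seq_len(n_bp),
                 open = seq_len(n_bp) <= traj$n_open[frame])
}

#' Mean force during the unzipping phase
#'
#' Averages the tether force over sampled frames in which the open-pair
#' count increased within the preceding sampling stride -- the force at
#' which base pairs actually unzip.
#'
#' @param traj a [kmc_run()] trajectory.
#' @return force in pN.
#' @export
unzip_force_plateau <- function(traj) {
  opening <- which(diff(traj$n_open) > 0) + 1
  if (!length(opening)) abort("trajectory contains no unzipping phase")
  mean(traj$force[opening])
}

#' Stationary open-pair count at the end of a trajectory
#'
#' The modal `n_open` over the last `tail_frac` of the sampled frames:
#' after reannealing completes the chain fluctuates around its equilibrium
#' fork position (mostly 0 with transient single-pair breathing), and the
#' mode reads off the stationary value.
#'
#' @param traj a [kmc_run()] trajectory.
#' @param tail_frac fraction of frames (from the end) examined.
#' @return integer open-pair count.
#' @export
final_open_bp <- function(traj, tail_frac = 0.25) {
  k <- max(1, ceiling(nrow(traj) * (1 - tail_frac)))
  tail_n <- traj$n_open[k:nrow(traj)]
  as.integer(names(which.max(table(tail_n))))
}

#' @rdname final_open_bp
#' @return `final_intact_bp()`: the number of intact (paired) base pairs,
#'   `n_bp - final_open_bp`.
#' @export
final_intact_bp <- function(traj, tail_frac = 0.25) {
  attr(traj, "n_bp") - final_open_bp(traj, tail_frac)
}

#' Conductance mapping for simulator-driven traces
#'
#' @param plateau_mG0 junction conductance while the duplex bridges the
#'   gap (default the 90-mer plateau, 1.9 mG0).
#' @param beta_bare direct-tunnelling decay constant, 1/Angstrom.
#' @param start_mG0 conductance at zero displacement for the tunnelling
#'   branch.
#' @param noise_sd_log10G log-domain noise added to the emitted trace.
#' @return object of class `zj_cond_mapping`.
#' @export
conductance_mapping <- function(plateau_mG0 = 1.9, beta_bare = 2.2,
                                start_mG0 = 100, noise_sd_log10G = 0.1) {
  stopifnot(plateau_mG0 > 0, beta_bare > 0, start_mG0 > plateau_mG0)
  structure(list(plateau_mG0 = plateau_mG0, beta_bare = beta_bare,
                 start_mG0 = start_mG0, noise_sd_log10G = noise_sd_log10G),
            class = "zj_cond_mapping")
}

#' Junction conductance of a trajectory frame
#'
#' Couples the simulator to the trace pipeline: while the junction is
#' intact (springs attached and a duplex region remains, i.e.
#' `n_open < n_bp`) the conductance sits at the plateau value, reflecting
#' transport mediated by the linker-proximal base pairs; once the duplex
#' has separated or the springs are detached, the bare tunnelling decay
#' law at the same displacement applies.
#'
#' @param traj a [kmc_run()] trajectory.
#' @param frame frame index (default: last frame).
#' @param mapping a [conductance_mapping()].
#' @return conductance in mG0.
#' @export
junction_conductance <- function(traj, frame = nrow(traj),
                                 mapping = conductance_mapping()) {
  junction_conductance_vec(traj, mapping)[frame]
}

# noise-free conductance (mG0) of every frame of a trajectory
junction_conductance_vec <- function(traj, mapping) {
  prot <- attr(traj, "protocol")
  n_bp <- attr(traj, "n_bp")
  released <- if (!is.null(prot) && isTRUE(prot$release_after_pull)) {
    traj$t >= prot$pull_distance / prot$pull_velocity
  } else {
    rep(FALSE, nrow(traj))
  }
  intact <- !released & traj$n_open < n_bp
  ifelse(intact, mapping$plateau_mG0,
         mapping$start_mG0 *
           10^(-beta_A_to_dec_per_nm(mapping$beta_bare) * traj$z_tip))
}

#' Map a zipper trajectory to a conductance-displacement trace
#'
#' Applies [junction_conductance()] to every frame of the pull phase and
#' adds optional log-domain noise, so simulator output can be fed to the
#' trace-analysis pipeline.
#'
#' @param traj a [kmc_run()] trajectory.
#' @param mapping a [conductance_mapping()].
#' @return trace tibble (`z`, `g`) over the pull phase.
#' @export
trajectory_trace <- function(traj, mapping = conductance_mapping()) {
  prot <- attr(traj, "protocol")
  t1 <- prot$pull_distance / prot$pull_velocity
  keep <- traj$t <= t1
  d <- traj[keep, ]
  lg <- log10(junction_conductance_vec(traj, mapping)[keep] * 1e-3)
  if (mapping$noise_sd_log10G > 0) {
    lg <- lg + rnorm(length(lg), 0, mapping$noise_sd_log10G)
  }
  out <- tibble::tibble(z = d$z_tip, g = 10^lg)
  attr(out, "meta") <- list(tip_velocity = prot$pull_velocity,
                            sample_rate = 1 / diff(d$t[1:2]),
                            preset = "simulated")
  out
}
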