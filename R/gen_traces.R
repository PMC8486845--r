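#' Generate a synthetic break-junction conductance trace
#'
#' Produces one conductance-displacement (G-z) trace of the retraction
#' process. The noise-free trace is piecewise linear in
#' (z, log10 G): a direct-tunnelling approach segment decaying at `beta2`
#' from `start_conductance` down to the plateau, a molecular plateau of
#' drawn length `L` whose log-conductance is centred on
#' `plateau_conductance` with slope `-beta1`, a post-plateau decay at
#' `beta2` down to the noise floor, and a short flat tail at the floor.
#' Without a plateau the trace is a single exponential at `beta_bare`.
#' Gaussian noise of sd `noise_sd_log10G` decades is added pointwise in the
#' log domain; conductance is clamped to `[noise_floor, start_conductance]`.
#'
#' Displacement starts at 0 at the first sample and advances by
#' `tip_velocity / sample_rate` per sample; the experimental origin
#' convention (z = 0 where G first drops below 50 mG0) is applied
#' downstream by [set_displacement_origin()].
#'
#' @param params a [trace_params()] object.
#' @param with_plateau logical; include a molecular plateau. Default draws
#'   from `params$plateau_probability`.
#' @param plateau_length plateau length in nm; default draws log-normal
#'   with the configured mean/sd.
#' @param seed optional integer seed (restores the RNG state afterwards).
#' @return a tibble with columns `z` (nm) and `g` (conductance in G0),
#'   carrying a `meta` attribute (bias mV, tip velocity, sample rate,
#'   preset, `with_plateau`, `plateau_length`).
#' @export
#' @examples
#' tr <- gen_bj_trace(trace_params("90mer"), seed = 1)
#' head(tr)
gen_bj_trace <- function(params, with_plateau = NULL, plateau_length = NULL,
                         seed = NULL) {
  stopifnot(inherits(params, "zj_trace_params"))
  if (!is.null(seed)) withr::local_seed(seed)
  if (is.null(with_plateau)) with_plateau <- runif(1) < params$plateau_probability
  if (with_plateau && is.null(plateau_length)) {
    plateau_length <- draw_lognormal(1, params$plateau_length_mean,
                                     params$plateau_length_sd)
  }
  if (!with_plateau) plateau_length <- 0

  step <- params$tip_velocity / params$sample_rate
  l0 <- log10(params$start_conductance * 1e-3)
  lf <- log10(params$noise_floor)

  if (with_plateau && plateau_length > 0) {
    b1 <- beta_A_to_dec_per_nm(params$beta1)
    b2 <- beta_A_to_dec_per_nm(params$beta2)
    lp <- log10(params$plateau_conductance * 1e-3)
    top <- lp + b1 * plateau_length / 2
    bottom <- lp - b1 * plateau_length / 2
    if (top >= l0) abort("drawn plateau reaches start_conductance; shorten it")
    z1 <- (l0 - top) / b2
    z2 <- z1 + plateau_length
    z3 <- z2 + (bottom - lf) / b2
    mu <- function(z) {
      ifelse(z < z1, l0 - b2 * z,
      ifelse(z < z2, top - b1 * (z - z1),
      ifelse(z < z3, bottom - b2 * (z - z2), lf)))
    }
  } else {
    bb <- beta_A_to_dec_per_nm(if (params$preset == "bare") params$beta_bare
                               else params$beta2)
    z3 <- (l0 - lf) / bb
    mu <- function(z) pmax(l0 - bb * z, lf)
  }

  z <- seq(0, z3 + params$tail_nm, by = step)
  lg <- mu(z)
  if (params$noise_sd_log10G > 0) {
    lg <- lg + rnorm(length(z), 0, params$noise_sd_log10G)
  }
  g <- pmin(pmax(10^lg, params$noise_floor), params$start_conductance * 1e-3)

  out <- tibble::tibble(z = z, g = g)
  attr(out, "meta") <- list(
    bias_mV = 20, tip_velocity = params$tip_velocity,
    sample_rate = params$sample_rate, preset = params$preset,
    with_plateau = with_plateau, plateau_length = plateau_length
  )
  out
}

# log-normal draws parameterised by arithmetic mean and sd
draw_lognormal <- function(n, mean, sd) {
  if (mean <= 0) return(rep(0, n))
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

#' Generate an ensemble of break-junction traces
#'
#' Draws `n` traces from [gen_bj_trace()]; each trace carries a plateau
#' with probability `params$plateau_probability`. The returned long tibble
#' stacks all traces with a `trace` index; the generator ground truth
#' (plateau presence and drawn length per trace) is attached as the
#' `truth` attribute for round-trip validation.
#'
#' @param n number of traces.
#' @inheritParams gen_bj_trace
#' @return tibble with columns `trace`, `z`, `g` and attribute `truth`.
#' @export
#' @examples
#' ens <- gen_bj_ensemble(5, trace_params("90mer"), seed = 1)
#' dplyr::count(ens, trace)
gen_bj_ensemble <- function(n, params, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  formed <- runif(n) < params$plateau_probability
  lens <- ifelse(formed,
                 draw_lognormal(n, params$plateau_length_mean,
                                params$plateau_length_sd), 0)
  traces <- purrr::map(seq_len(n), function(i) {
    tr <- gen_bj_trace(params, with_plateau = formed[i],
                       plateau_length = if (formed[i]) lens[i] else NULL)
    dplyr::mutate(tr, trace = i, .before = 1)
  })
  out <- dplyr::bind_rows(traces)
  attr(out, "truth") <- tibble::tibble(trace = seq_len(n),
                                       with_plateau = formed,
                                       plateau_length = lens)
  attr(out, "meta") <- list(tip_velocity = params$tip_velocity,
                            sample_rate = params$sample_rate,
                            preset = params$preset)
  out
}

#' Generate a random duplex sequence
#'
#' Uniform random base string of length `n_bp` with expected GC content
#' `gc_fraction`, standing in for the experimental duplex sequences (one
#' strand, 5' to 3').
#'
#' @param n_bp number of base pairs (>= 2).
#' @param gc_fraction expected GC fraction in `[0, 1]`.
#' @param seed optional integer seed.
#' @return a single character string over `A`, `C`, `G`, `T`.
#' @export
#' @examples
#' gen_sequence(10, gc_fraction = 0, seed = 1)
gen_sequence <- function(n_bp, gc_fraction = 0.5, seed = NULL) {
  if (n_bp < 2) abort("n_bp must be at least 2")
  stopifnot(gc_fraction >= 0, gc_fraction <= 1)
  if (!is.null(seed)) withr::local_seed(seed)
  prob <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
            G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  paste(sample(names(prob), n_bp, replace = TRUE, prob = prob), collapse = "")
}
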