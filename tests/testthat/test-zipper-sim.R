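test_that("FJC extension has the right limits and the Langevin value at kT/b", {
  zp <- zipper_params()
  expect_equal(fjc_extension(0, zp), 0)
  expect_equal(fjc_extension(1e6, zp), zp$contour_per_nt, tolerance = 1e-4)
  kT <- 1.380649e-2 * zp$temperature
  f1 <- kT / zp$kuhn_length
  want <- zp$contour_per_nt * (1 / tanh(1) - 1)
  expect_equal(fjc_extension(f1, zp), want, tolerance = 1e-12)
  f <- seq(0, 100, by = 0.5)
  expect_true(all(diff(fjc_extension(f, zp)) > 0))
})

test_that("force balance is exact in the Hookean and slack limits", {
  zp <- zipper_params()
  expect_equal(force_balance(0, 0, zp), 0)
  expect_equal(force_balance(50, -1, zp), 0)
  # n_open = 0: springs only, f = (k/2) z
  z <- 0.003
  expect_equal(force_balance(0, z, zp), zp$k_spring * 1000 * z / 2,
               tolerance = 1e-9)
})

test_that("force-balance residuals are below 1e-9 nm on random cases", {
  zp <- zipper_params()
  withr::local_seed(2)
  n <- 10000
  no <- sample(0:90, n, replace = TRUE)
  z <- runif(n, 0.001, 40)
  f <- zipperjunction:::solve_force_vec_cpp(
    no, z, zp$k_spring * 1000, 1.380649e-2 * zp$temperature,
    zp$contour_per_nt, zp$kuhn_length)
  resid <- abs(2 * f / (zp$k_spring * 1000) + 2 * no * fjc_extension(f, zp) - z)
  expect_lt(max(resid), 1e-9)
  # the reference R solver agrees with the compiled one
  idx <- sample(n, 50)
  expect_equal(force_balance(no[idx], z[idx], zp), f[idx], tolerance = 1e-6)
})

test_that("force is monotone in tip height and open-pair count", {
  zp <- zipper_params()
  z <- seq(0, 20, by = 0.5)
  f_z <- force_balance(rep(15, length(z)), z, zp)
  expect_true(all(diff(f_z) >= -1e-9))
  ns <- 5:40
  f_n <- force_balance(ns, rep(10, length(ns)), zp)
  expect_true(all(diff(f_n) <= 1e-9))
})

test_that("an undriven duplex stays closed", {
  traj <- kmc_run(gen_sequence(30, 0.5, seed = 2), zipper_params(),
                  pull_protocol(pull_distance = 0, hold_time = 0.2,
                                return = FALSE, settle_time = 0),
                  seed = 3, sample_dt = 1e-4)
  expect_lt(mean(traj$n_open), 0.5)
  expect_lt(max(traj$n_open), 5)
  expect_equal(final_open_bp(traj), 0L)
})

test_that("KMC occupancy matches exact Boltzmann enumeration on a small duplex", {
  zp <- zipper_params(k_spring = 0.005)  # soft springs: visible tension states
  s5 <- "GCATG"
  z0 <- 1.5
  ex <- exact_zipper_distribution(s5, z0, zp)
  traj <- kmc_run(s5, zp,
                  pull_protocol(pull_distance = z0, pull_velocity = 1e6,
                                hold_time = 1, return = FALSE,
                                settle_time = 0),
                  seed = 7, sample_dt = 2e-4, terminate_on_separation = FALSE)
  obs <- as.vector(table(factor(traj$n_open, levels = 0:5)))
  nz <- ex$prob * sum(obs) >= 5
  chi <- chisq.test(obs[nz], p = ex$prob[nz] / sum(ex$prob[nz]))
  expect_gt(chi$p.value, 0.001)
})

test_that("trajectories are bit-reproducible for a fixed seed", {
  s <- gen_sequence(20, 0.5, seed = 1)
  pr <- pull_protocol(pull_distance = 3, hold_time = 0.05, settle_time = 0.05)
  t1 <- kmc_run(s, zipper_params(), pr, seed = 5)
  t2 <- kmc_run(s, zipper_params(), pr, seed = 5)
  expect_identical(t1$n_open, t2$n_open)
  expect_identical(t1$force, t2$force)
})

test_that("a 30 nm pull partially unzips a 90-bp duplex which then fully reanneals", {
  traj <- kmc_run(gen_sequence(90, 0.5, seed = 42), zipper_params(),
                  pull_protocol(), seed = 1)
  expect_identical(attr(traj, "termination"), "completed")
  expect_gt(max(traj$n_open), 0)          # it unzips
  expect_lt(max(traj$n_open), 90)         # but never fully
  expect_equal(final_open_bp(traj), 0L)   # and reanneals after return
  # intact pair count at max pull matches the n_bp - n_open bookkeeping
  k <- which.max(traj$z_tip)
  expect_equal(90 - traj$n_open[k],
               sum(!pair_state_at(traj, k)$open))
})

test_that("the same pull separates a 10-bp duplex", {
  seps <- vapply(1:5, function(sd) {
    attr(kmc_run(gen_sequence(10, 0.5, seed = 5), zipper_params(),
                 pull_protocol(), seed = sd), "termination")
  }, character(1))
  expect_true(all(seps == "separated"))
})

test_that("release after pull also ends in a fully reannealed duplex", {
  traj <- kmc_run(gen_sequence(90, 0.5, seed = 42), zipper_params(),
                  pull_protocol(return = FALSE, release_after_pull = TRUE,
                                settle_time = 1), seed = 3)
  expect_equal(final_open_bp(traj), 0L)
  # with the springs detached no force acts
  post <- traj$force[traj$t > 30 / 31]
  expect_true(all(post == 0))
})

test_that("unzipping force sits at the analytic coexistence point for a uniform duplex", {
  zp <- zipper_params()
  sA <- strrep("A", 90)
  dg <- nn_step_free_energies(sA, 300)$dg_open[1] * 6.947695  # pN nm
  fstar <- uniroot(function(f) f - dg / (2 * fjc_extension(f, zp)),
                   c(1, 100))$root
  fs <- vapply(1:3, function(sd) {
    unzip_force_plateau(kmc_run(sA, zp, pull_protocol(), seed = sd))
  }, numeric(1))
  expect_lt(abs(mean(fs) - fstar) / fstar, 0.15)
})

test_that("trajectories without opening events refuse a plateau estimate", {
  flat <- tibble::tibble(t = seq(0, 1, 0.01), z_tip = 0,
                         n_open = 0L, force = 0)
  expect_error(unzip_force_plateau(flat), "no unzipping")
})

test_that("simulated junction conductance feeds back into the trace pipeline", {
  traj <- kmc_run(gen_sequence(90, 0.5, seed = 42), zipper_params(),
                  pull_protocol(), seed = 2)
  tr <- trajectory_trace(traj, conductance_mapping(noise_sd_log10G = 0))
  # intact junction throughout the pull: plateau at 1.9 mG0
  expect_true(all(abs(tr$g - 1.9e-3) < 1e-12))
  sep <- kmc_run(gen_sequence(10, 0.5, seed = 5), zipper_params(),
                 pull_protocol(), seed = 1)
  tr10 <- trajectory_trace(sep, conductance_mapping(noise_sd_log10G = 0))
  # after separation the conductance follows the bare tunnelling law
  z_post <- tr10$z[nrow(tr10)]
  expect_equal(tr10$g[nrow(tr10)],
               0.1 * 10^(-beta_A_to_dec_per_nm(2.2) * z_post),
               tolerance = 1e-9)
  # the per-frame mapping agrees: intact frame at the plateau, separated
  # frame on the tunnelling branch (in mG0)
  expect_equal(junction_conductance(traj, 1), 1.9)
  expect_equal(junction_conductance(sep),
               100 * 10^(-beta_A_to_dec_per_nm(2.2) * z_post),
               tolerance = 1e-9)
})

test_that("simulator-driven series pass the plateau filter round trip", {
  ser <- gen_simulated_series(3, gen_sequence(90, 0.5, seed = 42),
                              protocol = pull_protocol(settle_time = 0.1),
                              seed = 4)
  ser <- set_displacement_origin(ser)
  fl <- filter_plateau_traces(ser)
  expect_true(any(fl$report$present))
})
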