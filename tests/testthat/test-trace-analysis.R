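test_that("origin convention puts the first sub-50 mG0 sample exactly at zero", {
  tr <- gen_bj_trace(trace_params("90mer"), seed = 2)
  out <- set_displacement_origin(tr)
  k <- which(out$g < 0.05)[1]
  expect_identical(out$z[k], 0)
  # crossing index agrees with an independent linear scan on the raw trace
  k_scan <- 0L
  for (i in seq_len(nrow(tr))) if (tr$g[i] < 0.05) { k_scan <- i; break }
  expect_identical(k, k_scan)
})

test_that("origin handles boundary cases and is idempotent", {
  below <- tibble::tibble(z = c(1, 2, 3), g = c(0.01, 0.005, 0.001))
  out <- set_displacement_origin(below)
  expect_equal(out$z[1], 0)  # entirely below threshold: origin at first sample
  never <- tibble::tibble(z = c(1, 2), g = c(0.3, 0.2))
  out2 <- set_displacement_origin(never)
  expect_false(out2$originated[1])
  expect_equal(out2$z, never$z)  # left unshifted
  tr <- set_displacement_origin(gen_bj_trace(trace_params("90mer"), seed = 2))
  expect_equal(set_displacement_origin(tr)$z, tr$z)
})

test_that("a mathematically exact single exponential is never retained", {
  p <- trace_params("bare", noise_sd_log10G = 0)
  tr <- originated_trace(p, with_plateau = FALSE)
  fl <- filter_plateau_traces(tr)
  expect_false(fl$report$present)
  # the same holds at the molecular beta2 rate
  p2 <- trace_params("90mer", noise_sd_log10G = 0, plateau_length_mean = 0,
                     plateau_length_sd = 0)
  tr2 <- originated_trace(p2, with_plateau = TRUE, plateau_length = 0)
  expect_false(filter_plateau_traces(tr2)$report$present)
})

test_that("a noiseless flat segment longer than the threshold is retained with the right band", {
  step <- 31 / 20000
  n_flat <- ceiling(0.1 / step)
  z <- seq(0, by = step, length.out = 200 + n_flat)
  g <- c(10^seq(-1.31, -2.72, length.out = 100), rep(1.9e-3, n_flat),
         10^seq(-2.75, -5, length.out = 100))
  tr <- tibble::tibble(z = z, g = g, trace = 1L, originated = TRUE)
  fl <- filter_plateau_traces(tr, plateau_config(min_plateau_nm = 0.05))
  expect_true(fl$report$present)
  bin <- plateau_config()$bin_decades
  expect_lt(abs(log10(fl$report$band_center) - log10(1.9)), bin / 2 + 1e-9)
})

test_that("the plateau filter retains most formed traces of a default 90-mer ensemble", {
  ens <- set_displacement_origin(
    gen_bj_ensemble(500, trace_params("90mer"), seed = 1))
  fl <- filter_plateau_traces(ens)
  p_true <- trace_params("90mer")$plateau_probability
  expect_gte(mean(fl$report$present), p_true - 0.1)
  # and never mislabels bare traces in the ensemble
  truth <- attr(ens, "truth")
  rep2 <- dplyr::left_join(fl$report, truth, by = "trace")
  expect_lt(mean(rep2$present[!rep2$with_plateau]), 0.05)
})

test_that("2D histograms concentrate mass and are additive under partition", {
  const <- tibble::tibble(trace = 1L, z = seq(0, 0.5, 31 / 20000),
                          g = 1.9e-3, originated = TRUE)
  h <- trace_histogram2d(const)
  expect_equal(sum(colSums(h$counts) > 0), 1)  # one log-G row occupied
  two <- dplyr::bind_rows(const, dplyr::mutate(const, trace = 2L))
  h2 <- trace_histogram2d(two)
  expect_equal(h2$counts, h$counts * 2L)
  ens <- set_displacement_origin(
    gen_bj_ensemble(40, trace_params("90mer"), seed = 3))
  ha <- trace_histogram2d(dplyr::filter(ens, trace <= 20))
  hb <- trace_histogram2d(dplyr::filter(ens, trace > 20))
  hall <- trace_histogram2d(ens)
  expect_equal(hall$counts, ha$counts + hb$counts)
  expect_error(trace_histogram2d(ens, z_edges = c(0, 0, 1)), "increasing")
})

test_that("the plateau region of a 90-mer ensemble peaks at the plateau conductance", {
  ens <- set_displacement_origin(
    gen_bj_ensemble(300, trace_params("90mer"), seed = 4))
  h <- trace_histogram2d(ens, z_edges = seq(-0.05, 0.6, 0.01),
                         logg_edges = seq(-7, -1, 0.05))
  marg <- colSums(h$counts)
  # restrict to the molecular region below the origin threshold
  mids <- h$logg_edges[-length(h$logg_edges)] + 0.025
  mol <- mids > -4 & mids < -2
  peak_logg <- mids[mol][which.max(marg[mol])]
  expect_lt(abs(peak_logg - log10(1.9e-3)), 0.1)
})

test_that("conductance peak fitting recovers constant, preset and mixture centres", {
  const <- tibble::tibble(trace = 1L, z = seq(0, 0.3, 31 / 20000), g = 1e-3)
  pk <- conductance_peak(const, fit_range = c(0.5, 2))
  expect_equal(pk$center, 1.0, tolerance = 0.03)
  expect_lt(pk$sd_log10, 0.02)
  ens90 <- set_displacement_origin(
    gen_bj_ensemble(400, trace_params("90mer"), seed = 5))
  r90 <- filter_plateau_traces(ens90)$retained
  ens10 <- set_displacement_origin(
    gen_bj_ensemble(400, trace_params("10mer"), seed = 5))
  r10 <- filter_plateau_traces(ens10)$retained
  mix <- dplyr::bind_rows(r90, dplyr::mutate(r10, trace = trace + 1000L))
  pk90 <- conductance_peak(mix, fit_range = c(1.0, 3.6))
  pk10 <- conductance_peak(mix, fit_range = c(0.08, 0.30))
  expect_equal(pk90$center, 1.9, tolerance = 0.1)
  expect_equal(pk10$center, 0.15, tolerance = 0.1)
})

test_that("decay fits are exact on noise-free traces and flat segments give zero", {
  tr <- originated_trace(noisefree_90mer(), TRUE, plateau_length = 0.15)
  fl <- filter_plateau_traces(tr)
  ft <- fit_decay_constants(fl$retained, fl$report[1, ])
  expect_equal(ft$beta1, 0.27, tolerance = 1e-9)
  expect_equal(ft$beta2, 2.0, tolerance = 1e-9)
  bare <- originated_trace(trace_params("bare", noise_sd_log10G = 0), FALSE)
  expect_equal(fit_decay_constants(bare, NULL)$beta2, 2.2, tolerance = 1e-9)
  # an exactly constant plateau segment fits beta1 = 0
  step <- 31 / 20000
  zc <- seq(0, by = step, length.out = 400)
  gc_ <- c(10^seq(-1.31, -2.72, length.out = 100), rep(1.9e-3, 100),
           10^seq(-2.73, -6.9, length.out = 200))
  trc <- tibble::tibble(z = zc, g = gc_, trace = 1L, originated = TRUE)
  flc <- filter_plateau_traces(trc)
  ftc <- fit_decay_constants(trc, flc$report[1, ])
  expect_equal(ftc$beta1, 0, tolerance = 1e-9)
})

test_that("a constructed segment with ln G dropping 2.0 per Angstrom fits that slope", {
  step <- 31 / 20000
  z <- seq(0, 0.4, by = step)
  g <- 0.05 * exp(-20 * z)  # 2.0 per Angstrom = 20 per nm
  tr <- tibble::tibble(z = z, g = g)
  ft <- fit_decay_constants(tr, NULL,
                            decay_config(noise_floor_G0 = 1e-10))
  expect_equal(ft$beta2, 2.0, tolerance = 1e-9)
})

test_that("fitted betas recover the generator medians under default noise", {
  ens <- set_displacement_origin(
    gen_bj_ensemble(500, trace_params("90mer"), seed = 2))
  bt <- fit_decay_ensemble(filter_plateau_traces(ens))
  expect_gt(nrow(bt), 250)
  expect_lt(abs(median(bt$beta1) - 0.27) / 0.27, 0.05)
  expect_lt(abs(median(bt$beta2) - 2.0) / 2.0, 0.05)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(filter_plateau_traces(tibble::tibble()), "empty")
  tiny <- tibble::tibble(z = c(0, 1), g = c(1e-3, 1e-4))
  expect_error(fit_decay_constants(tiny, NULL), "too few")
})
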