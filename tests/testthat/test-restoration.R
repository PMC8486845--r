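test_that("dwell length accumulates band visits and handles misses", {
  cfg <- dwell_config("90mer")
  const <- tibble::tibble(z = seq(0, 0.5, length.out = 501), g = 1.9e-3)
  expect_equal(dwell_length(const, cfg), 0.5, tolerance = 1e-12)
  out <- tibble::tibble(z = seq(0, 0.5, length.out = 501), g = 1e-4)
  expect_equal(dwell_length(out, cfg), 0)
  # two separate visits of 0.03 and 0.02 nm, counted by hand
  step <- 0.001
  g <- rep(1e-4, 100)
  g[11:40] <- 1.9e-3   # 30 increments of 0.001 = 0.03 nm
  g[61:80] <- 2.0e-3   # 20 increments of 0.001 = 0.02 nm
  tr <- tibble::tibble(z = seq(0, by = step, length.out = 100), g = g)
  expect_equal(dwell_length(tr, cfg), 0.05, tolerance = 1e-12)
})

test_that("dwell length is origin-shift invariant and additive under concatenation", {
  cfg <- dwell_config("90mer")
  tr <- gen_bj_trace(trace_params("90mer"), seed = 9)
  shifted <- dplyr::mutate(tr, z = z - 0.123)
  expect_equal(dwell_length(tr, cfg), dwell_length(shifted, cfg))
  full <- gen_bj_trace(trace_params("90mer"), seed = 10)
  k <- nrow(full) %/% 3
  expect_equal(dwell_length(full, cfg),
               dwell_length(full[1:k, ], cfg) +
                 dwell_length(full[k:nrow(full), ], cfg), tolerance = 1e-12)
})

test_that("formation judgement uses an inclusive threshold", {
  cfg <- dwell_config("90mer")
  rec <- tibble::tibble(trace = 1:3, dwell = c(0, cfg$threshold_nm, 0.1))
  out <- judge_formation(rec, cfg)
  expect_equal(out$formed, c(FALSE, TRUE, TRUE))
  allz <- judge_formation(tibble::tibble(trace = 1:5, dwell = rep(0, 5)), cfg)
  expect_true(all(!allz$formed))
})

test_that("formation fraction of a persistent series sits at the chain's stationary value", {
  sp <- series_params("persistent", n_traces = 700)
  fs <- gen_formation_series(sp, seed = 3)
  # binomial bound inflated by the chain's autocorrelation factor
  rho <- sp$p_persist - sp$p_form * (1 - sp$p_persist) / (1 - sp$p_form)
  neff <- 700 * (1 - rho) / (1 + rho)
  se <- sqrt(sp$p_form * (1 - sp$p_form) / neff)
  expect_lt(abs(mean(fs$formed) - sp$p_form), 3 * se)
})

test_that("restoration statistics handle degenerate series exactly", {
  all_true <- restoration_stats(rep(TRUE, 20), n_perm = 99, seed = 1)
  expect_equal(all_true$p_form, 1)
  expect_equal(all_true$independence_ratio, 1)
  expect_equal(all_true$max_run, 20)
  alt <- restoration_stats(rep(c(TRUE, FALSE), 25), n_perm = 99, seed = 1)
  expect_equal(alt$p_joint_adjacent, 0)
  none <- restoration_stats(rep(FALSE, 10), n_perm = 99, seed = 1)
  expect_true(is.na(none$independence_ratio))
})

test_that("the independence ratio is calibrated on i.i.d. series", {
  n <- 10000
  fs <- gen_formation_series(series_params("independent", n_traces = n,
                                           p_form = 0.5), seed = 12)
  st <- restoration_stats(fs$formed, n_perm = 200, seed = 12)
  se_joint <- sqrt(st$p_joint_adjacent * (1 - st$p_joint_adjacent) / (n - 1))
  expect_lt(abs(st$independence_ratio - 1),
            3 * se_joint / st$p_form^2 + 0.01)
  # permutation p-values are not systematically extreme on null data
  ps <- vapply(1:40, function(s) {
    f <- gen_formation_series(series_params("independent", n_traces = 300,
                                            p_form = 0.5), seed = 100 + s)
    restoration_stats(f$formed, n_perm = 99, seed = s)$p_value
  }, numeric(1))
  expect_gt(mean(ps), 0.25)
  expect_lt(mean(ps < 0.05), 0.2)
})

test_that("persistent series show a significant excess of repeated formation at n = 700", {
  fs <- gen_formation_series(series_params("persistent", n_traces = 700),
                             seed = 21)
  st <- restoration_stats(fs$formed, n_perm = 999, seed = 21)
  expect_gt(st$independence_ratio, 1)
  expect_lt(st$p_value, 0.01)
  ind <- gen_formation_series(series_params("independent", n_traces = 700,
                                            p_form = 0.8), seed = 21)
  st2 <- restoration_stats(ind$formed, n_perm = 999, seed = 21)
  expect_lt(abs(st2$independence_ratio - 1), 0.1)
})

test_that("longest runs of permuted series follow the exact fixed-composition law", {
  withr::local_seed(31)
  n <- 100; n1 <- 50
  base <- c(rep(TRUE, n1), rep(FALSE, n - n1))
  maxruns <- vapply(1:10000, function(k) {
    x <- sample(base)
    r <- rle(x)
    max(r$lengths[r$values])
  }, numeric(1))
  for (k in c(4, 6, 8)) {
    emp <- mean(maxruns <= k)
    thr <- longest_run_cdf(n, n1, k)
    se <- sqrt(thr * (1 - thr) / 10000)
    expect_lt(abs(emp - thr), 4 * se + 1e-3)
  }
})

test_that("the time axis reproduces the ~100 s run duration and constant spacing", {
  rec <- tibble::tibble(trace = 1:78)
  out <- time_axis(rec, trace_period_s = 1.3)
  expect_equal(diff(out$t), rep(1.3, 77))
  expect_equal(max(out$t), 101.4)  # 78 cycles at 1.3 s
  out1 <- time_axis(rec, trace_period_s = 1)
  expect_equal(out1$t, as.numeric(rec$trace))
  expect_error(time_axis(rec, trace_period_s = 0), "positive")
  # default period: 30 nm pull at 31 nm/s plus 0.3 s wait
  def <- time_axis(rec)
  expect_equal(def$t[1], 30 / 31 + 0.3)
  expect_equal(78 * (30 / 31 + 0.3), 98.8, tolerance = 0.01)
})

test_that("the full dwell pipeline separates persistent and independent series", {
  tp <- trace_params("90mer")
  ser <- gen_consecutive_series(
    series_params("persistent", n_traces = 120), tp, seed = 5)
  truth <- attr(ser, "truth")
  dt <- dwell_table(set_displacement_origin(ser), dwell_config("90mer"))
  fj <- judge_formation(dt, dwell_config("90mer"))
  # dwell-based formation largely agrees with the generator state
  expect_gt(mean(fj$formed == truth$formed), 0.8)
})
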