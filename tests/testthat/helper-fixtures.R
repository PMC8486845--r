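# shared fixtures and small independent oracles used across test files

noisefree_90mer <- function(...) trace_params("90mer", noise_sd_log10G = 0, ...)

# originated single trace wrapped as a 1-trace ensemble
originated_trace <- function(params, with_plateau, plateau_length = NULL,
                             seed = NULL) {
  tr <- gen_bj_trace(params, with_plateau = with_plateau,
                     plateau_length = plateau_length, seed = seed)
  tr <- set_displacement_origin(tr)
  tr$trace <- 1L
  tr
}

# closed-form dwell length of a noise-free plateau trace inside a band,
# from the generator's piecewise-linear geometry (independent of
# dwell_length())
dwell_closed_form <- function(params, L, band_mG0) {
  b1 <- params$beta1 * 10 / log(10)
  b2 <- params$beta2 * 10 / log(10)
  lp <- log10(params$plateau_conductance * 1e-3)
  top <- lp + b1 * L / 2
  bottom <- lp - b1 * L / 2
  l0 <- log10(params$start_conductance * 1e-3)
  lf <- log10(params$noise_floor)
  band <- sort(log10(band_mG0 * 1e-3))
  ov <- function(a, b) max(0, min(b[2], a[2]) - max(b[1], a[1]))
  ov(c(top, l0), band) / b2 + ov(c(bottom, top), band) / b1 +
    ov(c(lf, bottom), band) / b2
}

# Wald-Wolfowitz runs test p-value (normal approximation)
runs_test_p <- function(x) {
  n1 <- sum(x); n0 <- sum(!x); n <- n1 + n0
  r <- length(rle(x)$lengths)
  mu <- 2 * n1 * n0 / n + 1
  s2 <- 2 * n1 * n0 * (2 * n1 * n0 - n) / (n^2 * (n - 1))
  2 * stats::pnorm(-abs((r - mu) / sqrt(s2)))
}

# exact P(longest success-run <= k) for a uniformly random arrangement of
# n1 successes among n trials, by dynamic programming over positions
longest_run_cdf <- function(n, n1, k) {
  # state: successes used so far x current terminal run length (0..k)
  # count arrangements position by position
  f <- matrix(0, nrow = n1 + 1, ncol = k + 1)
  f[1, 1] <- 1
  for (pos in seq_len(n)) {
    g <- matrix(0, nrow = n1 + 1, ncol = k + 1)
    for (u in 0:n1) {
      for (r in 0:k) {
        c0 <- f[u + 1, r + 1]
        if (c0 == 0) next
        g[u + 1, 1] <- g[u + 1, 1] + c0            # place a failure
        if (u < n1 && r < k) {                      # place a success
          g[u + 2, r + 2] <- g[u + 2, r + 2] + c0
        }
      }
    }
    f <- g
  }
  sum(f[n1 + 1, ]) / choose(n, n1)
}
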