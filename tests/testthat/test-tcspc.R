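delta_irf <- function(n, period) {
  dt <- period / n
  t <- (seq_len(n) - 0.5) * dt
  tcspc_irf(t, c(1, rep(0, n - 1)))
}

test_that("convolution with a delta IRF reduces to the pure wrapped decay", {
  period <- 50                      # tau = 2 ns << 50 ns window
  irf <- delta_irf(1024, period)
  m <- convolve_irf(data.frame(amplitude = 1, lifetime_ns = 2), irf,
                    rep_period_ns = period)
  t <- irf$time_ns
  ref <- exp(-(t - t[1]) / 2)
  expect_lt(max(abs(m / m[1] - ref)), 1e-6)
})

test_that("convolution is linear in the amplitudes", {
  g <- simulate_decay(noise = FALSE)
  comp <- g$truth$components
  m1 <- convolve_irf(comp, g$irf, 12.5, offset = 3)
  comp2 <- transform(comp, amplitude = 2 * amplitude)
  m2 <- convolve_irf(comp2, g$irf, 12.5, offset = 3)
  expect_equal(m2 - 3, 2 * (m1 - 3), tolerance = 1e-12)
})

test_that("FFT reconvolution matches the direct-summation oracle binwise", {
  g <- simulate_decay(noise = FALSE, n_bins = 256)
  comp <- data.frame(amplitude = c(0.6, 0.4), lifetime_ns = c(0.5, 2.0))
  m <- convolve_irf(comp, g$irf, 12.5)
  oracle <- oracle_reconvolution(comp, g$irf$counts, g$irf$time_ns, 12.5)
  expect_lt(max(abs(m - oracle) / max(oracle)), 1e-3)
})

test_that("model counts over one period obey the analytic integral", {
  period <- 12.5
  irf <- delta_irf(4096, period)
  dt <- period / 4096
  comp <- data.frame(amplitude = c(0.6, 0.4), lifetime_ns = c(0.5, 2.0))
  m <- convolve_irf(comp, irf, period)
  # integral of a_i e^{-t/tau_i} over [0, T), wrapped, is a_i tau_i / dt counts
  closed <- sum(comp$amplitude * comp$lifetime_ns) / dt
  expect_equal(sum(m), closed, tolerance = 1e-3)
})

test_that("amplitude-weighted lifetime is the amplitude-weighted mean", {
  expect_equal(amplitude_weighted_lifetime(
    data.frame(amplitude = 1, lifetime_ns = 3.14)), 3.14)
  expect_equal(amplitude_weighted_lifetime(
    data.frame(amplitude = c(0.7, 0.3), lifetime_ns = c(1, 3))), 1.6)
  expect_equal(amplitude_weighted_lifetime(
    data.frame(amplitude = c(0.5, 0.5), lifetime_ns = c(2, 4))), 3)
  expect_error(amplitude_weighted_lifetime(
    data.frame(amplitude = c(0, 0), lifetime_ns = c(1, 2))), "undefined")
})

test_that("noise-free monoexponential decays are recovered near-exactly", {
  g <- simulate_decay(components = data.frame(amplitude = 1, lifetime_ns = 3),
                      noise = FALSE)
  fit <- fit_reconvolution(g$decay, g$irf, 1)
  expect_equal(fit$components$lifetime_ns, 3, tolerance = 1e-3)
})

test_that("biexponential fits at standard peak counts recover both lifetimes", {
  g <- simulate_decay(seed = 7)    # 0.6/0.5 ns + 0.4/2.0 ns, 1e4 peak counts
  fit <- fit_reconvolution(g$decay, g$irf, 2)
  expect_equal(fit$components$lifetime_ns[1], 0.5, tolerance = 0.10)
  expect_equal(fit$components$lifetime_ns[2], 2.0, tolerance = 0.10)
  expect_equal(fit$tau_av_ns, g$truth$tau_av_ns, tolerance = 0.03)
  expect_true(fit$tau_av_ns >= min(fit$components$lifetime_ns) &&
                fit$tau_av_ns <= max(fit$components$lifetime_ns))
  expect_lt(fit$chi2_reduced, 1.5)

  # label-permutation symmetry: swapped starting order, same sorted result
  fit_sw <- fit_reconvolution(g$decay, g$irf, 2,
                              start = list(amplitude = c(4000, 6000),
                                           lifetime_ns = c(2.2, 0.45)))
  expect_equal(fit_sw$components$lifetime_ns, fit$components$lifetime_ns,
               tolerance = 0.02)
})

test_that("indistinguishable lifetimes are merged into a reduced model", {
  g <- simulate_decay(components = data.frame(amplitude = 1, lifetime_ns = 3),
                      seed = 5)
  fit <- fit_reconvolution(g$decay, g$irf, 2)
  expect_lte(nrow(fit$components), 2)
  if (nrow(fit$components) == 1) expect_gte(fit$n_merged, 1)
  expect_equal(fit$tau_av_ns, 3, tolerance = 0.03)
})

test_that("fit configuration is validated", {
  g <- simulate_decay(seed = 1, n_bins = 64)
  expect_error(fit_reconvolution(g$decay, g$irf, 5), "1..4")
  g_small <- simulate_decay(seed = 1, n_bins = 32)
  expect_error(fit_reconvolution(g_small$decay, g_small$irf, 4), "too few bins")
  other <- simulate_decay(seed = 1, n_bins = 128)
  expect_error(fit_reconvolution(g$decay, other$irf, 2), "share the time grid")
  expect_error(tcspc_irf(g$irf$time_ns, rep(0, 64)), "sums to 0")
})

test_that("fitted mean lifetime tracks a decreasing true-lifetime series", {
  tau2 <- c(2.4, 2.0, 1.6, 1.2)
  tau_av <- vapply(seq_along(tau2), function(i) {
    g <- simulate_decay(components = data.frame(amplitude = c(0.6, 0.4),
                                                lifetime_ns = c(0.5, tau2[i])),
                        seed = 100 + i)
    fit_reconvolution(g$decay, g$irf, 2)$tau_av_ns
  }, numeric(1))
  expect_true(all(diff(tau_av) < 0))
})

test_that("bootstrap collapses in the high-count limit and is seed-deterministic", {
  g <- simulate_decay(peak_counts = 1e7, noise = FALSE)
  bs <- bootstrap_lifetimes(g$decay, g$irf, 2, n_boot = 20, seed = 3)
  widths <- bs$intervals["97.5%", c("tau1", "tau2")] -
    bs$intervals["2.5%", c("tau1", "tau2")]
  expect_true(all(widths < 1e-2))

  g2 <- simulate_decay(seed = 7)
  a <- bootstrap_lifetimes(g2$decay, g2$irf, 2, n_boot = 10, seed = 21)
  b <- bootstrap_lifetimes(g2$decay, g2$irf, 2, n_boot = 10, seed = 21)
  expect_identical(a$replicates, b$replicates)
  expect_error(bootstrap_lifetimes(g2$decay, g2$irf, 2, n_boot = 1), ">= 2")
})

test_that("decay CSV round trip preserves counts and repetition period", {
  path <- tempfile(fileext = ".csv")
  g <- simulate_decay(seed = 9, rep_period_ns = 50)
  write_decay_csv(g$decay, path)
  d2 <- read_decay_csv(path)
  expect_equal(d2$rep_period_ns, 50)
  expect_equal(d2$counts, g$decay$counts)
  unlink(path)
})
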