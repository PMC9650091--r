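test_that("every generator is bit-identical under a fixed seed", {
  expect_identical(simulate_spectrum(0.5, noise_sd = 5, seed = 3),
                   simulate_spectrum(0.5, noise_sd = 5, seed = 3))
  expect_identical(simulate_decay(seed = 3), simulate_decay(seed = 3))
  expect_identical(simulate_correlogram(227, noise_sd = 0.01, seed = 3),
                   simulate_correlogram(227, noise_sd = 0.01, seed = 3))
  expect_identical(simulate_diameters(100, seed = 3),
                   simulate_diameters(100, seed = 3))
  expect_identical(simulate_vesicle_field(c(10, 10), seed = 3),
                   simulate_vesicle_field(c(10, 10), seed = 3))
  f <- simulate_vesicle_field(c(8, 8), seed = 3)
  expect_identical(simulate_movie(f, 0.5, n_frames = 3, seed = 3),
                   simulate_movie(f, 0.5, n_frames = 3, seed = 3))
})

test_that("generators leave the caller's RNG stream untouched", {
  set.seed(123)
  ref <- runif(3)
  set.seed(123)
  invisible(simulate_decay(seed = 9))
  invisible(simulate_spectrum(0.5, noise_sd = 1, seed = 9))
  expect_identical(runif(3), ref)
})

test_that("noise-free spectra round-trip the true efficiency", {
  for (e in c(0.4, 0.5, 0.6)) {
    s <- simulate_spectrum(e)
    pair <- integrate_bands(s$spectrum)
    expect_equal(fret_efficiency(pair$donor, pair$acceptor), e,
                 tolerance = 0.005 / e)
  }
})

test_that("decay generator honors the peak-count acquisition criterion", {
  g <- simulate_decay(noise = FALSE, peak_counts = 1e4)
  expect_equal(max(g$decay$counts), 1e4)
  g2 <- simulate_decay(noise = FALSE, peak_counts = 5000, background = 20)
  expect_equal(max(g2$decay$counts), 5000)
  expect_error(simulate_decay(peak_counts = 50), "peak_counts")
})

test_that("decay noise is Poisson: per-bin variance tracks the mean", {
  base <- simulate_decay(noise = FALSE, n_bins = 64)
  mu <- base$decay$counts
  reps <- vapply(1:500, function(s) {
    simulate_decay(noise = TRUE, n_bins = 64, seed = s)$decay$counts
  }, numeric(64))
  sel <- mu > 500        # high-count bins where 500 replicates resolve 10%
  ratio <- apply(reps, 1, var)[sel] / mu[sel]
  expect_true(all(abs(ratio - 1) < 0.30))
  expect_lt(abs(mean(ratio) - 1), 0.05)
})

test_that("correlogram generator places the half-life at ln2 / (2 D q^2)", {
  g <- simulate_correlogram(227)
  tr <- g$truth
  q <- scattering_vector(1.33, 633, 178)
  t_half <- log(2) / (2 * tr$D_m2_s * q^2)
  z <- (g$correlogram$g2 - tr$A) / (tr$A * tr$B)
  expect_equal(exp(stats::approx(g$correlogram$lag_s, log(z),
                                 xout = t_half)$y), 0.5, tolerance = 1e-6)
})

test_that("vesicle counts follow the tethering surface density", {
  area <- 50 * 50
  counts <- vapply(1:100, function(s) {
    nrow(simulate_vesicle_field(c(50, 50), seed = s))
  }, numeric(1))
  expected <- 195 / (25 * 50) * area       # 2x the per-half-field count
  se <- sqrt(expected / 100)
  expect_lt(abs(mean(counts) - expected), 4 * se)
  expect_error(simulate_vesicle_field(c(3, 3), density_per_um2 = 10,
                                      min_separation_um = 1.5),
               "packing")
})

test_that("per-vesicle total brightness is conserved across conditions", {
  f <- simulate_vesicle_field(c(10, 10), seed = 7)
  lo <- simulate_movie(f, 0.40, n_frames = 3, seed = 7)
  hi <- simulate_movie(f, 0.60, n_frames = 3, seed = 7)
  expect_identical(lo$truth$vesicles$brightness, hi$truth$vesicles$brightness)
  expect_identical(lo$truth$vesicles[c("x_um", "y_um")],
                   hi$truth$vesicles[c("x_um", "y_um")])

  # symmetric split at E = 0.5: channel-summed signal above offset matches
  sym <- simulate_movie(f, 0.5, n_frames = 6, channel_shift_px = c(dx = 0, dy = 0),
                        seed = 8)
  img <- colMeans(sym$movie$frames, dims = 1)
  h <- ncol(img) / 2
  d_sig <- sum(img[, 1:h] - 100)
  a_sig <- sum(img[, (h + 1):(2 * h)] - 100)
  expect_equal(d_sig / a_sig, 1, tolerance = 0.02)
})

test_that("synthetic datasets serialize with a ground-truth sidecar", {
  dir <- tempfile(); dir.create(dir)
  p1 <- write_synthetic(simulate_spectrum(0.5, seed = 1),
                        file.path(dir, "spec.csv"))
  p2 <- write_synthetic(simulate_decay(seed = 1, n_bins = 64),
                        file.path(dir, "decay.csv"))
  p3 <- write_synthetic(simulate_correlogram(227, seed = 1),
                        file.path(dir, "corr.csv"))
  expect_true(all(file.exists(p1, p2, p3,
                              paste0(c(p1, p2, p3), ".truth.json"),
                              file.path(dir, "decay.irf.csv"))))
  truth <- jsonlite::read_json(paste0(p3, ".truth.json"))
  expect_equal(truth$d_H_true_nm, 227)
  unlink(dir, recursive = TRUE)
})
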