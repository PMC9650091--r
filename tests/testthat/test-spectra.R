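make_spectrum <- function(intensity, wl = seq(500, 800, by = 1)) {
  emission_spectrum(wl, intensity)
}

test_that("band integration cancels the baseline and integrates exactly", {
  wl <- seq(500, 800, by = 1)
  flat <- make_spectrum(rep(7, length(wl)))
  pair <- integrate_bands(flat, baseline = flat)
  expect_equal(pair$donor, 0)
  expect_equal(pair$acceptor, 0)

  # unit-height rectangle exactly filling a 10-nm donor band
  rect <- make_spectrum(ifelse(wl >= 550 & wl <= 560, 1, 0))
  pair <- integrate_bands(rect, donor_band = c(550, 560),
                          acceptor_band = c(650, 750), baseline = 0)
  expect_equal(pair$donor, 10)
  expect_equal(pair$acceptor, 0)
})

test_that("quadrature recovers analytic Gaussian band areas within 1%", {
  wl <- seq(500, 800, by = 1)
  spec <- make_spectrum(70 * dnorm(wl, 570, 8) + 30 * dnorm(wl, 690, 10))
  pair <- integrate_bands(spec, baseline = 0)
  expect_equal(pair$donor, 70, tolerance = 0.01)
  expect_equal(pair$acceptor, 30, tolerance = 0.01)
})

test_that("band configuration is validated", {
  wl <- seq(540, 760, by = 1)
  s <- make_spectrum(rep(1, length(wl)), wl)
  expect_error(integrate_bands(s, donor_band = c(500, 610)), "outside")
  expect_error(integrate_bands(s, donor_band = c(545, 660),
                               acceptor_band = c(650, 750)), "overlap")
  expect_error(emission_spectrum(c(1, 1, 2), c(0, 0, 0)), "increasing")
})

test_that("titration series recovers generator efficiencies and separations", {
  e_true <- c(0.50, 0.55, 0.60)
  specs <- lapply(seq_along(e_true), function(i) {
    simulate_spectrum(e_true[i], seed = i)$spectrum
  })
  series <- titration_series(c(0, 1, 3), specs)
  tab <- series_to_efret(series)
  expect_equal(tab$efret, e_true, tolerance = 0.01)
  expect_equal(tab$r_nm[1], 5.3, tolerance = 0.02)  # E = 0.5 sits at R0

  # a ratio quantity: invariant under global rescaling of any spectrum
  scaled <- specs
  scaled[[2]]$intensity <- scaled[[2]]$intensity * 17
  tab2 <- series_to_efret(titration_series(c(0, 1, 3), scaled))
  expect_equal(tab2$efret, tab$efret, tolerance = 1e-12)

  # identical spectra across the titration give a constant E
  same <- titration_series(c(0, 1, 3), rep(specs[2], 3))
  expect_equal(diff(range(series_to_efret(same)$efret)), 0)
})

test_that("zero-signal spectra are flagged, not propagated as NaN", {
  wl <- seq(500, 800, by = 1)
  blank <- make_spectrum(rep(3, length(wl)))
  good <- simulate_spectrum(0.5, seed = 4)$spectrum
  series <- titration_series(c(0, 1, 2, 3), list(blank, good, good, good))
  tab <- series_to_efret(series)
  expect_equal(tab$flagged, c(1, 0, 0, 0))
  expect_true(is.na(tab$efret[1]))
  trend <- fit_titration_quadratic(tab$concentration, tab$efret)
  expect_true(all(is.finite(trend$coefficients)))
})

test_that("quadratic trend fit is exact on polynomial data and sane on noise", {
  x <- c(0, 0.5, 1, 2, 3)
  expect_equal(unname(fit_titration_quadratic(x, rep(2, 5))$coefficients),
               c(2, 0, 0), tolerance = 1e-12)
  y <- 1 + 0.1 * x - 0.01 * x^2
  expect_equal(unname(fit_titration_quadratic(x, y)$coefficients),
               c(1, 0.1, -0.01), tolerance = 1e-10)

  set.seed(42)
  x7 <- seq(0, 3, length.out = 7)
  yn <- 1 + 0.1 * x7 - 0.01 * x7^2 + rnorm(7, sd = 0.005)
  fit <- fit_titration_quadratic(x7, yn)
  se <- summary(fit$lm)$coefficients[, "Std. Error"]
  expect_true(all(abs(fit$coefficients - c(1, 0.1, -0.01)) < 3 * se))

  expect_error(fit_titration_quadratic(c(0, 1), c(1, 2)), ">= 3")
})

test_that("spectrum CSV round trip preserves the data", {
  path <- tempfile(fileext = ".csv")
  s <- simulate_spectrum(0.45, noise_sd = 2, seed = 8)$spectrum
  write_spectrum_csv(s, path)
  s2 <- read_spectrum_csv(path)
  expect_equal(s2$wavelength_nm, s$wavelength_nm)
  expect_equal(s2$intensity, s$intensity, tolerance = 1e-12)
  unlink(path)
})
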