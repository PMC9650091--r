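# deterministic spotty image used for registration fixtures
spot_image <- function(nr = 64, nc = 64, n = 12, seed = 3) {
  set.seed(seed)
  img <- matrix(10, nr, nc)
  for (i in seq_len(n)) {
    r0 <- runif(1, 12, nr - 12); c0 <- runif(1, 12, nc - 12)
    p <- luvfret:::render_psf_patch(r0, c0, 1.2, 6)
    img[p$rows, p$cols] <- img[p$rows, p$cols] + 800 * p$patch
  }
  img
}

test_that("integer inter-channel shifts are recovered and identity is exact", {
  img <- spot_image()
  shifted <- luvfret:::shift_image(img, -3, 2)    # displaces features by (+3, -2)
  movie <- vesicle_movie(array(cbind(img, shifted), c(1, 64, 128)))
  reg <- split_and_register(movie)
  expect_equal(unname(reg$transform), c(3, -2), tolerance = 0.05)

  same <- vesicle_movie(array(cbind(img, img), c(1, 64, 128)))
  expect_equal(unname(split_and_register(same)$transform), c(0, 0))
})

test_that("sub-pixel shifts are recovered within 0.2 px under noise", {
  sim <- tiny_movie(efret = 0.5, shift = c(dx = 1.5, dy = 0.25), seed = 21)
  reg <- split_and_register(sim$movie)
  expect_lt(max(abs(reg$transform - c(1.5, 0.25))), 0.2)
})

test_that("featureless channels raise a registration error carrying identity", {
  set.seed(8)
  flat <- array(100 + rnorm(1 * 40 * 80), c(1, 40, 80))
  err <- tryCatch(split_and_register(vesicle_movie(flat)),
                  luvfret_registration_error = function(e) e)
  expect_s3_class(err, "luvfret_registration_error")
  expect_equal(unname(err$transform), c(0, 0))
})

test_that("spot detection finds planted PSFs and respects the threshold", {
  set.seed(12)
  blank <- matrix(100 + rnorm(80 * 80, sd = 3), 80, 80)
  expect_equal(nrow(detect_spots(blank)), 0)

  img <- matrix(100 + rnorm(80 * 80, sd = 3), 80, 80)
  truth <- expand.grid(r = seq(12, 72, by = 15), c = seq(12, 72, by = 15))[1:20, ]
  for (i in 1:20) {
    p <- luvfret:::render_psf_patch(truth$r[i], truth$c[i], 1.2, 6)
    img[p$rows, p$cols] <- img[p$rows, p$cols] + 1000 * p$patch
  }
  spots <- detect_spots(img, k = 5, min_separation_px = 4)
  expect_equal(nrow(spots), 20)
  for (i in 1:20) {
    d <- sqrt((spots$y + 1 - truth$r[i])^2 + (spots$x + 1 - truth$c[i])^2)
    expect_lt(min(d), 1)
  }
  expect_equal(nrow(detect_spots(img, k = 1e6)), 0)
})

test_that("trace extraction cancels flat background and is linear", {
  flat <- array(37, c(5, 40, 40))
  spots <- data.frame(id = 1, x = 19, y = 19, quality = 1)
  tr <- extract_traces(flat, flat, spots)
  expect_equal(max(abs(tr$donor)), 0)

  set.seed(6)
  img <- matrix(50, 48, 48)
  p <- luvfret:::render_psf_patch(24, 24, 1.0, 6)
  img[p$rows, p$cols] <- img[p$rows, p$cols] + 1000 * p$patch
  stack <- array(rep(img, 3), c(48, 48, 3))
  stack <- aperm(stack, c(3, 1, 2))
  tr2 <- extract_traces(stack, stack, data.frame(id = 1, x = 23, y = 23,
                                                 quality = 1))
  expect_equal(tr2$donor[1, 1], 1000, tolerance = 0.05)
  tr3 <- extract_traces(2 * stack, 2 * stack,
                        data.frame(id = 1, x = 23, y = 23, quality = 1))
  expect_equal(tr3$donor, 2 * tr2$donor, tolerance = 1e-12)

  edge <- data.frame(id = 1:2, x = c(2, 23), y = c(2, 23), quality = 1)
  expect_warning(tr4 <- extract_traces(stack, stack, edge), "dropped")
  expect_equal(tr4$dropped, 1)
  expect_equal(nrow(tr4$spots), 1)
})

test_that("per-vesicle efficiency is the ratio of trace means", {
  mk <- function(d, a) {
    structure(list(donor = matrix(d, 1, length(d)),
                   acceptor = matrix(a, 1, length(a)),
                   spots = data.frame(id = 1), dropped = integer(),
                   transform = c(dx = 0, dy = 0)), class = "trace_set")
  }
  expect_equal(trace_efret(mk(rep(30, 10), rep(70, 10)))$efret, 0.7)
  set.seed(2); noisy <- rlnorm(20)
  expect_equal(trace_efret(mk(noisy, noisy))$efret, 0.5)
  neg <- trace_efret(mk(rep(-5, 10), rep(2, 10)))
  expect_true(neg$flagged)
  expect_true(is.na(neg$efret))
  expect_error(trace_efret(mk(1:5, 1:5), frame_range = c(4, 99)), "frame range")
})

test_that("simulated vesicles at known efficiency recover E within shot noise", {
  sim <- tiny_movie(efret = 0.45, n_frames = 60, seed = 31)
  res <- analyze_movie(sim$movie)
  ok <- !res$efret$flagged
  expect_gt(sum(ok), 5)
  expect_equal(mean(res$efret$efret[ok]), 0.45, tolerance = 0.02 / 0.45)
})

test_that("efficiency histograms use 0.01 bins, count every vesicle and fit peaks", {
  h <- build_histogram(rep(0.45, 50))
  expect_equal(diff(h$mids[1:2]), 0.01)
  expect_equal(sum(h$counts > 0), 1)
  expect_equal(sum(h$counts), 50)
  expect_true(h$fit$mean >= 0.44 && h$fit$mean <= 0.46)

  set.seed(9)
  e <- pmin(pmax(rnorm(2000, 0.45, 0.05), 0), 1)
  h2 <- build_histogram(e)
  expect_equal(sum(h2$counts), 2000)
  expect_equal(h2$fit$mean, 0.45, tolerance = 0.01 / 0.45)

  h3 <- build_histogram(c(rep(0.4, 30)))
  expect_equal(round(h3$mean_separation_nm, 1), 5.7)

  few <- build_histogram(rep(0.3, 5))
  expect_null(few$fit)
  expect_equal(sum(few$counts), 5)

  mixed <- build_histogram(c(e, NA, 1.4, -0.2))
  expect_equal(mixed$n_excluded, 3)
  expect_equal(sum(mixed$counts), mixed$n_vesicles)
})

test_that("condition comparison classifies reversibility from peak shifts", {
  set.seed(4)
  mk_hist <- function(mu) build_histogram(pmin(pmax(rnorm(1200, mu, 0.05), 0), 1))
  h40 <- mk_hist(0.40); h42 <- mk_hist(0.42); h53 <- mk_hist(0.53)
  h53b <- mk_hist(0.53); h60 <- mk_hist(0.60); h40b <- mk_hist(0.40)

  same <- compare_conditions(h40, h40, h40, shift_threshold = 0.03)
  expect_equal(same$verdict, "no effect")
  expect_equal(same$delta_after, 0)

  irr <- compare_conditions(h42, h53, h53b, shift_threshold = 0.03)
  expect_equal(irr$verdict, "irreversible")

  rev <- compare_conditions(h40, h60, h40b, shift_threshold = 0.03,
                            total_intensity = c(1000, 990, 1010))
  expect_equal(rev$verdict, "reversible")
  expect_false(rev$intensity_flag)

  leaky <- compare_conditions(h40, h60, h40b,
                              total_intensity = c(1000, 600, 1000))
  expect_true(leaky$intensity_flag)

  nofit <- build_histogram(rep(0.3, 5))
  expect_error(compare_conditions(nofit, h53, h53), "lacks a Gaussian fit")
})

test_that("whole-movie integer translation leaves extracted traces unchanged", {
  sim <- tiny_movie(efret = 0.5, n_frames = 12, seed = 41)
  f <- sim$movie$frames
  # shift content by (+2 rows, +3 cols); fill the revealed edges with
  # background drawn from the same camera model so no step edge appears
  set.seed(99)
  g <- array(as.integer(100 + rpois(length(f), 5) + round(rnorm(length(f), sd = 2))),
             dim(f))
  g[, 3:dim(f)[2], 4:dim(f)[3]] <- f[, 1:(dim(f)[2] - 2), 1:(dim(f)[3] - 3)]
  res_a <- analyze_movie(sim$movie)
  res_b <- analyze_movie(vesicle_movie(g))
  key_a <- order(round(res_a$spots$x), round(res_a$spots$y))
  key_b <- order(round(res_b$spots$x), round(res_b$spots$y))
  expect_equal(nrow(res_a$spots), nrow(res_b$spots))
  expect_equal(res_b$traces$donor[key_b, ], res_a$traces$donor[key_a, ],
               tolerance = 0.01)
  expect_equal(res_b$traces$acceptor[key_b, ], res_a$traces$acceptor[key_a, ],
               tolerance = 0.01)
})

test_that("movie TIFF round trip preserves counts and metadata", {
  path <- tempfile(fileext = ".tif")
  sim <- tiny_movie(n_frames = 4, seed = 51)
  write_movie_tiff(sim$movie, path)
  m2 <- read_movie_tiff(path)
  expect_equal(m2$frames, sim$movie$frames, ignore_attr = TRUE)
  expect_equal(m2$exposure_s, 0.05)
  unlink(c(path, paste0(path, ".meta.json")))
})
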