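#' Synthetic emission spectrum with known FRET efficiency
#'
#' Renders donor (peak near 565 nm) and acceptor (peak near 670 nm)
#' emission lines as skew-normal templates whose band areas are in the
#' ratio (1 - E):E, scaled to `total_area`, with optional additive Gaussian
#' noise. The templates place essentially all donor area inside the default
#' 545--610 nm band and all acceptor area inside 650--750 nm, so band
#' integration recovers E up to quadrature error.
#'
#' @param efret_true True apparent FRET efficiency in (0, 1).
#' @param total_area Total (donor + acceptor) band area, counts x nm.
#' @param noise_sd Additive Gaussian noise per grid point (counts).
#' @param wavelength_nm Wavelength grid.
#' @param donor_shape,acceptor_shape Skew-normal template parameters
#'   `c(location, scale, shape)` in nm.
#' @param seed Integer seed; same seed, same spectrum.
#' @return List: `spectrum` ([emission_spectrum()]), `truth` (parameters
#'   incl. seed).
#' @export
simulate_spectrum <- function(efret_true, total_area = 1e4, noise_sd = 0,
                              wavelength_nm = seq(500, 800, by = 1),
                              donor_shape = c(556, 12, 4),
                              acceptor_shape = c(661, 14, 4),
                              seed = 1) {
  stopifnot(efret_true > 0, efret_true < 1, total_area > 0)
  skew_normal <- function(x, p) {
    z <- (x - p[1]) / p[2]
    2 / p[2] * stats::dnorm(z) * stats::pnorm(p[3] * z)
  }
  clean <- total_area * ((1 - efret_true) * skew_normal(wavelength_nm, donor_shape) +
                           efret_true * skew_normal(wavelength_nm, acceptor_shape))
  intensity <- with_preserved_seed(seed, {
    clean + if (noise_sd > 0) stats::rnorm(length(clean), sd = noise_sd) else 0
  })
  list(spectrum = emission_spectrum(wavelength_nm, intensity),
       truth = list(modality = "spectrum", efret_true = efret_true,
                    total_area = total_area, noise_sd = noise_sd,
                    donor_shape = donor_shape, acceptor_shape = acceptor_shape,
                    seed = seed))
}

#' Synthetic TCSPC decay with IRF
#'
#' Builds a Gaussian IRF and the wrapped reconvolution model for the given
#' components over one repetition period, scales it so the expected count
#' at the decay maximum equals `peak_counts` (the standard acquisition
#' stop criterion), and draws independent Poisson counts per bin.
#'
#' @param components Data.frame `amplitude`, `lifetime_ns`; amplitudes are
#'   fractional (relative weights).
#' @param irf_fwhm_ns IRF full width at half maximum (ns).
#' @param irf_center_ns IRF peak position within the window (ns).
#' @param rep_period_ns Repetition period: 12.5 ns (80 MHz) by default.
#' @param n_bins Bins across one period.
#' @param peak_counts Expected counts at the decay maximum (default 1e4).
#' @param background Expected background counts per bin.
#' @param noise If `FALSE`, return the exact expected counts.
#' @param seed Integer seed.
#' @return List: `decay` ([decay_histogram()]), `irf` ([tcspc_irf()]),
#'   `truth`.
#' @export
simulate_decay <- function(components = data.frame(amplitude = c(0.6, 0.4),
                                                   lifetime_ns = c(0.5, 2.0)),
                           irf_fwhm_ns = 0.2, irf_center_ns = 1.0,
                           rep_period_ns = 12.5, n_bins = 512,
                           peak_counts = 1e4, background = 0,
                           noise = TRUE, seed = 1) {
  stopifnot(peak_counts >= 100, n_bins >= 32)
  dt <- rep_period_ns / n_bins
  t <- (seq_len(n_bins) - 0.5) * dt
  sigma <- irf_fwhm_ns / (2 * sqrt(2 * log(2)))
  irf_counts <- stats::dnorm(t, mean = irf_center_ns, sd = sigma)
  irf <- tcspc_irf(t, irf_counts / max(irf_counts) * 1e4)

  m <- convolve_irf(components, irf, rep_period_ns = rep_period_ns)
  expected <- m / max(m) * (peak_counts - background) + background
  counts <- if (noise) {
    with_preserved_seed(seed, stats::rpois(n_bins, expected))
  } else expected
  list(decay = decay_histogram(t, counts, rep_period_ns),
       irf = irf,
       truth = list(modality = "decay",
                    components = as.data.frame(components),
                    tau_av_ns = amplitude_weighted_lifetime(components),
                    irf_fwhm_ns = irf_fwhm_ns, irf_center_ns = irf_center_ns,
                    rep_period_ns = rep_period_ns, peak_counts = peak_counts,
                    background = background, noise = noise, seed = seed))
}

#' Synthetic DLS correlogram for a known hydrodynamic diameter
#'
#' Converts the true diameter to a diffusion coefficient (inverse
#' Stokes--Einstein), lays out log-spaced lags spanning the decay
#' (0.01/(D q^2) to 10/(D q^2)), evaluates
#' \eqn{G(\tau) = A[1 + B e^{-2 D q^2 \tau}]} and adds Gaussian noise.
#'
#' @param d_H_true_nm True hydrodynamic diameter (nm).
#' @param instrument A [dls_instrument()].
#' @param A,B Baseline and intercept amplitude of the model.
#' @param n_lags Number of lag points.
#' @param noise_sd Additive Gaussian noise (same units as g2; A = 1 makes
#'   this a relative amplitude).
#' @param seed Integer seed.
#' @return List: `correlogram`, `truth`.
#' @export
simulate_correlogram <- function(d_H_true_nm, instrument = dls_instrument(),
                                 A = 1, B = 0.9, n_lags = 100,
                                 noise_sd = 0, seed = 1) {
  stopifnot(d_H_true_nm > 0, n_lags >= 10)
  D <- diffusion_from_diameter(d_H_true_nm, instrument$temperature_K,
                               instrument$viscosity_Pa_s)
  q <- scattering_vector(instrument$refractive_index, instrument$wavelength_nm,
                         instrument$angle_deg)
  lag <- exp(seq(log(0.01 / (D * q^2)), log(10 / (D * q^2)),
                 length.out = n_lags))
  g2 <- A * (1 + B * exp(-2 * D * q^2 * lag))
  g2 <- with_preserved_seed(seed, {
    g2 + if (noise_sd > 0) stats::rnorm(n_lags, sd = noise_sd) else 0
  })
  list(correlogram = correlogram(lag, g2, instrument),
       truth = list(modality = "dls", d_H_true_nm = d_H_true_nm,
                    D_m2_s = D, A = A, B = B, noise_sd = noise_sd,
                    seed = seed))
}

#' Synthetic log-normal diameter sample
#'
#' Draws diameters from the log-normal with a given density mode and FWHM
#' (the parameters electron-microscopy size histograms are reported in).
#'
#' @param n Number of diameters.
#' @param mode_nm Mode of the density (nm).
#' @param fwhm_nm Full width at half maximum of the density (nm).
#' @param seed Integer seed.
#' @return List: `diameters_nm`, `truth`.
#' @export
simulate_diameters <- function(n, mode_nm = 132, fwhm_nm = 125, seed = 1) {
  p <- lognormal_from_mode_fwhm(mode_nm, fwhm_nm)
  d <- with_preserved_seed(seed, stats::rlnorm(n, p["meanlog"], p["sdlog"]))
  list(diameters_nm = d,
       truth = list(modality = "diameters", mode_nm = mode_nm,
                    fwhm_nm = fwhm_nm, meanlog = unname(p["meanlog"]),
                    sdlog = unname(p["sdlog"]), seed = seed))
}

#' Synthetic field of surface-tethered vesicles
#'
#' Draws the vesicle layout a movie is rendered from: a Poisson number of
#' vesicles at the observed surface density (195 per 25 x 50 um by
#' default), uniform positions with a minimum-separation rejection step
#' (tethered vesicles sit ~1 um apart), and log-normal per-vesicle total
#' brightness. The layout is independent of any FRET efficiency, so the
#' same field can be re-rendered under different conditions with
#' per-vesicle total intensity conserved by construction.
#'
#' @param field_um `c(width, height)` of the field of view (um).
#' @param density_per_um2 Vesicle surface density (um^-2).
#' @param min_separation_um Minimum center-to-center distance.
#' @param brightness_meanlog,brightness_sdlog Log-normal parameters of the
#'   per-vesicle total signal (photons per frame in the aperture).
#' @param seed Integer seed.
#' @return A data.frame `id`, `x_um`, `y_um`, `brightness` with the field
#'   geometry in attributes.
#' @export
simulate_vesicle_field <- function(field_um = c(50, 50),
                                   density_per_um2 = 195 / (25 * 50),
                                   min_separation_um = 1,
                                   brightness_meanlog = log(1500),
                                   brightness_sdlog = 0.4,
                                   seed = 1) {
  stopifnot(density_per_um2 > 0, all(field_um > 0))
  with_preserved_seed(seed, {
    n <- stats::rpois(1, density_per_um2 * prod(field_um))
    xs <- numeric(0); ys <- numeric(0)
    tries <- 0L
    max_tries <- 200L * max(n, 1L)
    while (length(xs) < n) {
      if (tries > max_tries) {
        stop("packing error: cannot place ", n, " vesicles at min separation ",
             min_separation_um, " um in a ", field_um[1], " x ", field_um[2],
             " um field")
      }
      tries <- tries + 1L
      cx <- stats::runif(1, 0, field_um[1])
      cy <- stats::runif(1, 0, field_um[2])
      if (length(xs) == 0 ||
          min((xs - cx)^2 + (ys - cy)^2) >= min_separation_um^2) {
        xs <- c(xs, cx); ys <- c(ys, cy)
      }
    }
    brightness <- stats::rlnorm(n, brightness_meanlog, brightness_sdlog)
    out <- data.frame(id = seq_len(n), x_um = xs, y_um = ys,
                      brightness = brightness)
    attr(out, "field_um") <- field_um
    attr(out, "seed") <- seed
    out
  })
}

# integrate a unit-flux pixelated Gaussian PSF into a patch around
# (row0, col0) (fractional, 1-based pixel centers)
render_psf_patch <- function(row0, col0, sigma, half) {
  r <- (round(row0) - half):(round(row0) + half)
  c <- (round(col0) - half):(round(col0) + half)
  fr <- stats::pnorm(r + 0.5, row0, sigma) - stats::pnorm(r - 0.5, row0, sigma)
  fc <- stats::pnorm(c + 0.5, col0, sigma) - stats::pnorm(c - 0.5, col0, sigma)
  list(rows = r, cols = c, patch = outer(fr, fc))
}

#' Synthetic dual-view TIRF movie with known per-vesicle FRET
#'
#' Renders a vesicle field into a donor/acceptor dual-view stack: each
#' vesicle's total brightness is split (1 - E):E between the two channels,
#' drawn as a pixel-integrated Gaussian PSF (acceptor positions offset by
#' the true inter-channel shift), overlaid on a uniform fluorescence
#' background, and read out with per-pixel Poisson shot noise plus a
#' camera model (offset + Gaussian read noise, rounded to integer counts).
#'
#' @param field A layout from [simulate_vesicle_field()], or `NULL` to draw
#'   one from `seed`.
#' @param efret True efficiency: scalar, one value per vesicle, or a
#'   function(n) drawing n values.
#' @param n_frames Number of frames (500 as standard).
#' @param exposure_s Exposure metadata (s).
#' @param pixel_size_um Pixel size (um).
#' @param psf_sigma_px PSF standard deviation (px).
#' @param channel_shift_px True acceptor-vs-donor shift `c(dx, dy)` (px).
#' @param background_photons Background photons per pixel per frame.
#' @param camera List `offset`, `read_noise_sd`, `gain`.
#' @param seed Integer seed (noise stream; layout comes from `field` or is
#'   drawn from this seed too).
#' @return List: `movie` ([vesicle_movie()]), `truth` (per-vesicle table
#'   with positions in donor-channel px, brightness, efret; plus shift,
#'   camera and geometry).
#' @export
simulate_movie <- function(field = NULL, efret = 0.45, n_frames = 500,
                           exposure_s = 0.05, pixel_size_um = 0.11,
                           psf_sigma_px = 1.2,
                           channel_shift_px = c(dx = 2.3, dy = -1.6),
                           background_photons = 5,
                           camera = list(offset = 100, read_noise_sd = 2,
                                         gain = 1),
                           seed = 1) {
  if (is.null(field)) field <- simulate_vesicle_field(seed = seed)
  field_um <- attr(field, "field_um")
  n_ves <- nrow(field)
  e <- if (is.function(efret)) {
    with_preserved_seed(seed + 1L, efret(n_ves))
  } else if (length(efret) == 1L) {
    rep(efret, n_ves)
  } else {
    stopifnot(length(efret) == n_ves)
    efret
  }
  stopifnot(all(e >= 0), all(e <= 1), psf_sigma_px > 0)

  nc_half <- ceiling(field_um[1] / pixel_size_um)
  nr <- ceiling(field_um[2] / pixel_size_um)
  margin <- 10L                       # keep PSFs and annuli inside the frame
  nr <- nr + 2L * margin; nc_half <- nc_half + 2L * margin
  if (nc_half %% 2L != 0L) nc_half <- nc_half + 1L

  row_px <- field$y_um / pixel_size_um + margin + 0.5  # 1-based pixel centers
  col_px <- field$x_um / pixel_size_um + margin + 0.5
  half <- ceiling(4 * psf_sigma_px) + 2L

  base_d <- matrix(background_photons, nr, nc_half)
  base_a <- matrix(background_photons, nr, nc_half)
  for (i in seq_len(n_ves)) {
    pd <- render_psf_patch(row_px[i], col_px[i], psf_sigma_px, half)
    base_d[pd$rows, pd$cols] <- base_d[pd$rows, pd$cols] +
      field$brightness[i] * (1 - e[i]) * pd$patch
    pa <- render_psf_patch(row_px[i] + channel_shift_px[["dy"]],
                           col_px[i] + channel_shift_px[["dx"]],
                           psf_sigma_px, half)
    base_a[pa$rows, pa$cols] <- base_a[pa$rows, pa$cols] +
      field$brightness[i] * e[i] * pa$patch
  }
  base <- cbind(base_d, base_a)
  npix <- length(base)

  frames <- array(0L, dim = c(n_frames, nr, 2L * nc_half))
  with_preserved_seed(seed, {
    for (f in seq_len(n_frames)) {
      px <- camera$offset + camera$gain * stats::rpois(npix, base) +
        round(stats::rnorm(npix, sd = camera$read_noise_sd))
      frames[f, , ] <- as.integer(pmax(px, 0))
    }
  })
  truth <- field
  truth$row_px0 <- row_px - 1   # 0-based pixel-center coordinates
  truth$col_px0 <- col_px - 1
  truth$efret_true <- e
  list(movie = vesicle_movie(frames, exposure_s, pixel_size_um, "col"),
       truth = list(modality = "movie", vesicles = truth,
                    channel_shift_px = channel_shift_px,
                    psf_sigma_px = psf_sigma_px,
                    background_photons = background_photons,
                    camera = camera, margin_px = margin,
                    field_um = field_um, seed = seed))
}

#' Write a generated dataset with its ground-truth sidecar
#'
#' Serializes any generator result to disk in the same formats the
#' analysis functions read (CSV or TIFF), with the ground-truth record as
#' a JSON sidecar (`<path>.truth.json`).
#'
#' @param generated A list returned by one of the `simulate_*()` functions.
#' @param path Output file path (extension chooses nothing; the modality
#'   does).
#' @return `path`, invisibly.
#' @export
write_synthetic <- function(generated, path) {
  truth <- generated$truth
  if (!is.null(generated$spectrum)) {
    write_spectrum_csv(generated$spectrum, path)
  } else if (!is.null(generated$decay)) {
    write_decay_csv(generated$decay, path)
    write_decay_csv(
      decay_histogram(generated$irf$time_ns,
                      generated$irf$counts,
                      generated$decay$rep_period_ns),
      sub("(\\.[^.]+)?$", ".irf\\1", path))
  } else if (!is.null(generated$correlogram)) {
    write_correlogram_csv(generated$correlogram, path)
  } else if (!is.null(generated$movie)) {
    write_movie_tiff(generated$movie, path)
    truth$vesicles <- as.data.frame(truth$vesicles)
  } else if (!is.null(generated$diameters_nm)) {
    utils::write.csv(data.frame(diameter_nm = generated$diameters_nm), path,
                     row.names = FALSE)
  } else {
    stop("unrecognized generated dataset")
  }
  jsonlite::write_json(truth, paste0(path, ".truth.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
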