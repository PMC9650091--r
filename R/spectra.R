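#' Emission spectrum container
#'
#' A bulk fluorescence emission spectrum as a wavelength/intensity table.
#'
#' @param wavelength_nm Strictly increasing wavelength grid (nm).
#' @param intensity Nonnegative intensities (counts), same length.
#' @param excitation_nm Excitation wavelength metadata (532 nm for the
#'   DiI--DiD pair).
#' @return An object of class `emission_spectrum` (a data.frame with
#'   attributes).
#' @export
emission_spectrum <- function(wavelength_nm, intensity, excitation_nm = 532) {
  wavelength_nm <- as.numeric(wavelength_nm)
  intensity <- as.numeric(intensity)
  if (length(wavelength_nm) != length(intensity)) {
    stop("wavelength and intensity grids must have equal length")
  }
  if (length(wavelength_nm) < 2L || any(diff(wavelength_nm) <= 0)) {
    stop("'wavelength_nm' must be strictly increasing with >= 2 points")
  }
  if (any(!is.finite(intensity))) stop("intensities must be finite")
  out <- data.frame(wavelength_nm = wavelength_nm, intensity = intensity)
  attr(out, "excitation_nm") <- excitation_nm
  class(out) <- c("emission_spectrum", "data.frame")
  out
}

#' Integrate donor and acceptor emission bands
#'
#' Background-corrects a spectrum and integrates it over the donor and
#' acceptor emission bands by trapezoidal quadrature on the native
#' wavelength grid (no resampling). Band integrals are clipped at zero so
#' noise around a blank cannot produce negative intensities.
#'
#' The baseline may be a measured blank spectrum (same grid), a constant, or
#' `NULL`, in which case the median intensity over `baseline_window`
#' (default 750--780 nm, beyond the acceptor emission) is used.
#'
#' @param spectrum An [emission_spectrum()].
#' @param donor_band,acceptor_band Length-2 numeric wavelength intervals
#'   (nm). Defaults 545--610 (donor, DiI) and 650--750 (acceptor, DiD),
#'   consistent with the 640 nm dichroic separating the two emission lines.
#' @param baseline Blank `emission_spectrum`, a single number, or `NULL`.
#' @param baseline_window Window used when `baseline` is `NULL`.
#' @return A list with `donor`, `acceptor` (band integrals, counts x nm) of
#'   class `intensity_pair`.
#' @export
integrate_bands <- function(spectrum,
                            donor_band = c(545, 610),
                            acceptor_band = c(650, 750),
                            baseline = NULL,
                            baseline_window = c(750, 780)) {
  stopifnot(inherits(spectrum, "emission_spectrum"))
  wl <- spectrum$wavelength_nm
  check_band <- function(b, name) {
    if (length(b) != 2L || b[1] >= b[2]) stop("'", name, "' must be an increasing interval")
    if (b[1] < min(wl) || b[2] > max(wl)) {
      stop("'", name, "' lies outside the spectrum's wavelength range")
    }
  }
  check_band(donor_band, "donor_band")
  check_band(acceptor_band, "acceptor_band")
  if (max(donor_band[1], acceptor_band[1]) < min(donor_band[2], acceptor_band[2])) {
    stop("donor and acceptor bands overlap")
  }

  if (is.null(baseline)) {
    in_win <- wl >= baseline_window[1] & wl <= baseline_window[2]
    base <- if (any(in_win)) stats::median(spectrum$intensity[in_win]) else 0
  } else if (inherits(baseline, "emission_spectrum")) {
    if (!isTRUE(all.equal(baseline$wavelength_nm, wl))) {
      stop("blank spectrum must share the wavelength grid")
    }
    base <- baseline$intensity
  } else if (is.numeric(baseline) && length(baseline) == 1L) {
    base <- baseline
  } else {
    stop("'baseline' must be a blank emission_spectrum, a scalar, or NULL")
  }

  corrected <- spectrum$intensity - base
  band_integral <- function(band) {
    keep <- wl >= band[1] & wl <= band[2]
    if (sum(keep) < 2L) stop("band contains fewer than 2 grid points")
    max(trapz(wl[keep], corrected[keep]), 0)
  }
  structure(list(donor = band_integral(donor_band),
                 acceptor = band_integral(acceptor_band)),
            class = "intensity_pair")
}

# trapezoidal quadrature on an arbitrary increasing grid
trapz <- function(x, y) {
  n <- length(x)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

#' Titration series of emission spectra
#'
#' Bundles one emission spectrum per crowder concentration (optionally with
#' replicates) for conversion into an E_FRET / separation trend.
#'
#' @param concentration Crowder concentrations (M or \% w/w), one per
#'   spectrum; need not be unique (replicates share a concentration).
#' @param spectra List of [emission_spectrum()] objects, same length.
#' @param replicate_id Optional replicate labels (defaults to 1).
#' @return An object of class `titration_series`.
#' @export
titration_series <- function(concentration, spectra, replicate_id = NULL) {
  if (!is.list(spectra) || !all(vapply(spectra, inherits, TRUE, "emission_spectrum"))) {
    stop("'spectra' must be a list of emission_spectrum objects")
  }
  if (length(concentration) != length(spectra)) {
    stop("one concentration per spectrum required")
  }
  if (length(unique(concentration)) < 2L) {
    stop("a titration needs >= 2 distinct concentrations")
  }
  if (is.null(replicate_id)) replicate_id <- rep(1L, length(spectra))
  ord <- order(concentration, replicate_id)
  structure(list(concentration = concentration[ord],
                 spectra = spectra[ord],
                 replicate_id = replicate_id[ord]),
            class = "titration_series")
}

#' E_FRET and mean separation across a crowder titration
#'
#' Integrates each spectrum's donor/acceptor bands, forms the apparent
#' efficiency \eqn{I_A/(I_A+I_D)} and the mean dye separation via the
#' Forster relation, and averages replicates per concentration. Spectra with
#' zero total band signal are flagged and excluded from the summary rather
#' than propagating NaN.
#'
#' @param series A [titration_series()].
#' @param params A [fret_params()].
#' @inheritParams integrate_bands
#' @return A data.frame with one row per concentration:
#'   `concentration`, `n_replicates`, `efret`, `efret_sd`, `r_nm`, `r_sd`,
#'   `flagged` (number of excluded replicates). Per-replicate values are in
#'   `attr(, "replicates")`.
#' @export
series_to_efret <- function(series, params = fret_params(),
                            donor_band = c(545, 610),
                            acceptor_band = c(650, 750),
                            baseline = NULL) {
  stopifnot(inherits(series, "titration_series"))
  per <- lapply(seq_along(series$spectra), function(i) {
    pair <- integrate_bands(series$spectra[[i]], donor_band, acceptor_band,
                            baseline = baseline)
    tot <- pair$donor + pair$acceptor
    if (tot <= 0) {
      data.frame(concentration = series$concentration[i],
                 replicate_id = series$replicate_id[i],
                 efret = NA_real_, r_nm = NA_real_, flagged = TRUE)
    } else {
      e <- fret_efficiency(pair$donor, pair$acceptor, params)
      r <- if (e > 0 && e < 1) efficiency_to_distance(e, params) else NA_real_
      data.frame(concentration = series$concentration[i],
                 replicate_id = series$replicate_id[i],
                 efret = e, r_nm = r, flagged = FALSE)
    }
  })
  per <- do.call(rbind, per)

  agg <- lapply(split(per, per$concentration), function(d) {
    ok <- d[!d$flagged, , drop = FALSE]
    data.frame(concentration = d$concentration[1],
               n_replicates = nrow(ok),
               efret = if (nrow(ok)) mean(ok$efret) else NA_real_,
               efret_sd = if (nrow(ok) > 1) stats::sd(ok$efret) else NA_real_,
               r_nm = if (nrow(ok)) mean(ok$r_nm) else NA_real_,
               r_sd = if (nrow(ok) > 1) stats::sd(ok$r_nm) else NA_real_,
               flagged = sum(d$flagged))
  })
  out <- do.call(rbind, agg)
  out <- out[order(out$concentration), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "replicates") <- per
  out
}

#' Quadratic trend fit to a titration response
#'
#' Least-squares degree-2 polynomial \eqn{y = c_0 + c_1 x + c_2 x^2},
#' the heuristic trend model used for E_FRET and separation vs crowder
#' concentration. Rows with missing response (flagged spectra) are dropped.
#'
#' @param concentration,response Numeric vectors; >= 3 complete points.
#' @return List with `coefficients` (c0, c1, c2), `fitted`, `residuals`,
#'   and the underlying `lm` fit.
#' @export
fit_titration_quadratic <- function(concentration, response) {
  keep <- is.finite(concentration) & is.finite(response)
  x <- concentration[keep]; y <- response[keep]
  if (length(x) < 3L) stop("quadratic trend fit needs >= 3 complete points")
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- unname(stats::coef(fit))
  list(coefficients = c(c0 = cf[1], c1 = cf[2], c2 = cf[3]),
       fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::residuals(fit)),
       lm = fit)
}

#' Read an emission spectrum from CSV
#'
#' Expects two columns, `wavelength_nm` and `intensity`.
#'
#' @param path CSV path.
#' @param excitation_nm Excitation wavelength metadata.
#' @return An [emission_spectrum()].
#' @export
read_spectrum_csv <- function(path, excitation_nm = 532) {
  d <- utils::read.csv(path)
  emission_spectrum(d$wavelength_nm, d$intensity, excitation_nm)
}

#' @rdname read_spectrum_csv
#' @param spectrum Spectrum to write.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  utils::write.csv(as.data.frame(spectrum), path, row.names = FALSE)
  invisible(path)
}
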