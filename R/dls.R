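#' Physical constants and instrument defaults for backscatter DLS
#'
#' The sizing instrument collects backscattered light at 178 degrees from a
#' 633 nm line in aqueous buffer (n = 1.33); the environment defaults to
#' water at 25 C (298.15 K, 8.9e-4 Pa s).
#'
#' @param wavelength_nm Laser wavelength in vacuo.
#' @param angle_deg Scattering angle.
#' @param refractive_index Solution refractive index.
#' @param temperature_K Absolute temperature.
#' @param viscosity_Pa_s Dynamic viscosity.
#' @return A list of class `dls_instrument`.
#' @export
dls_instrument <- function(wavelength_nm = 633, angle_deg = 178,
                           refractive_index = 1.33,
                           temperature_K = 298.15, viscosity_Pa_s = 8.9e-4) {
  stopifnot(wavelength_nm > 0, angle_deg > 0, angle_deg <= 180,
            refractive_index > 0, temperature_K > 0, viscosity_Pa_s > 0)
  structure(list(wavelength_nm = wavelength_nm, angle_deg = angle_deg,
                 refractive_index = refractive_index,
                 temperature_K = temperature_K,
                 viscosity_Pa_s = viscosity_Pa_s),
            class = "dls_instrument")
}

BOLTZMANN_J_PER_K <- 1.380649e-23

#' Scattering vector magnitude
#'
#' \deqn{q = \frac{4 \pi n}{\lambda_0} \sin(\theta / 2)}
#' with the wavelength converted to metres, so q is in 1/m.
#'
#' @param refractive_index Solution refractive index (n = 1.33 for water).
#' @param wavelength_nm Laser wavelength in vacuo (nm).
#' @param angle_deg Scattering angle (0, 180].
#' @return q in 1/m.
#' @examples
#' scattering_vector(1.33, 633, 178)  # ~2.64e7 m^-1
#' @export
scattering_vector <- function(refractive_index, wavelength_nm, angle_deg) {
  if (wavelength_nm <= 0) stop("wavelength must be positive")
  if (angle_deg < 0 || angle_deg > 180) stop("angle must be in [0, 180] degrees")
  4 * pi * refractive_index / (wavelength_nm * 1e-9) * sin(angle_deg * pi / 360)
}

#' Stokes--Einstein hydrodynamic diameter
#'
#' \deqn{d_H = \frac{k_B T}{3 \pi \eta D}}
#' returned in nm. Exactly inverse-proportional to D.
#'
#' @param D Diffusion coefficient (m^2/s).
#' @param temperature_K Absolute temperature (K).
#' @param viscosity_Pa_s Dynamic viscosity (Pa s).
#' @return Hydrodynamic diameter in nm.
#' @export
stokes_einstein_diameter <- function(D, temperature_K = 298.15,
                                     viscosity_Pa_s = 8.9e-4) {
  if (any(D <= 0) || temperature_K <= 0 || viscosity_Pa_s <= 0) {
    stop("D, temperature and viscosity must be positive")
  }
  BOLTZMANN_J_PER_K * temperature_K / (3 * pi * viscosity_Pa_s * D) * 1e9
}

#' @rdname stokes_einstein_diameter
#' @param d_H_nm Hydrodynamic diameter in nm.
#' @return `diffusion_from_diameter()`: D in m^2/s (algebraic inverse).
#' @export
diffusion_from_diameter <- function(d_H_nm, temperature_K = 298.15,
                                    viscosity_Pa_s = 8.9e-4) {
  if (any(d_H_nm <= 0)) stop("diameter must be positive")
  BOLTZMANN_J_PER_K * temperature_K / (3 * pi * viscosity_Pa_s * (d_H_nm * 1e-9))
}

#' Autocorrelation curve container
#'
#' @param lag_s Strictly increasing positive lag times (s).
#' @param g2 Correlation values, same length.
#' @param instrument A [dls_instrument()].
#' @return An object of class `correlogram`.
#' @export
correlogram <- function(lag_s, g2, instrument = dls_instrument()) {
  lag_s <- as.numeric(lag_s); g2 <- as.numeric(g2)
  if (length(lag_s) != length(g2)) stop("lag and g2 must have equal length")
  if (any(lag_s <= 0) || any(diff(lag_s) <= 0)) {
    stop("lags must be positive and strictly increasing")
  }
  if (any(!is.finite(g2))) stop("g2 must be finite")
  structure(list(lag_s = lag_s, g2 = g2, instrument = instrument),
            class = "correlogram")
}

#' Fit a DLS correlogram to the single-exponential model
#'
#' Nonlinear least squares for
#' \deqn{G(\tau) = A [1 + B e^{-2 D q^2 \tau}]}
#' with positivity constraints on A, B and D. q comes from the instrument
#' geometry; the fitted diffusion coefficient is converted to a
#' hydrodynamic diameter via [stokes_einstein_diameter()].
#'
#' Initialization follows the curve's own geometry: A from the tail mean, B
#' from the intercept, D from a log-linear fit of the early decay.
#'
#' @param corr A [correlogram()].
#' @return A `dls_fit`: `A`, `B`, `D_m2_s`, `d_H_nm`, `q_per_m`, `fitted`,
#'   `residuals`, `chi2`.
#' @export
fit_correlogram <- function(corr) {
  stopifnot(inherits(corr, "correlogram"))
  if (length(corr$lag_s) < 10L) stop("need >= 10 lag points spanning the decay")
  ins <- corr$instrument
  q <- scattering_vector(ins$refractive_index, ins$wavelength_nm, ins$angle_deg)
  tau <- corr$lag_s
  y <- corr$g2

  n <- length(tau)
  tail_idx <- max(1L, n - max(5L, n %/% 5) + 1L):n
  A0 <- mean(y[tail_idx])
  if (A0 <= 0) A0 <- mean(y)
  B0 <- y[1] / A0 - 1
  if (!is.finite(B0) || B0 <= 0) {
    stop("degenerate fit: curve shows no decay above its baseline")
  }
  # log-linear early-decay slope: log((g2 - A)/(A B)) = -2 D q^2 tau
  z <- (y - A0) / (A0 * B0)
  early <- which(z > 0.2 & z < 0.95)
  if (length(early) >= 3) {
    slope <- stats::coef(stats::lm(log(z[early]) ~ tau[early]))[2]
    D0 <- max(-slope / (2 * q^2), 1e-16)
  } else {
    i_half <- which(z < 0.5)[1]
    D0 <- if (is.na(i_half)) 1e-12 else log(2) / (2 * q^2 * tau[i_half])
  }

  fit <- minpack.lm::nls.lm(
    par = c(A = A0, B = min(B0, 1.2), D = D0),
    lower = c(1e-12, 1e-6, 1e-18), upper = c(Inf, 1.2, Inf),
    fn = function(p) p[1] * (1 + p[2] * exp(-2 * p[3] * q^2 * tau)) - y,
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  p <- unname(fit$par)
  if (p[3] <= 0) stop("constraint violation: fitted D is nonpositive")
  fitted <- p[1] * (1 + p[2] * exp(-2 * p[3] * q^2 * tau))
  structure(list(A = p[1], B = p[2], D_m2_s = p[3],
                 d_H_nm = stokes_einstein_diameter(p[3], ins$temperature_K,
                                                   ins$viscosity_Pa_s),
                 q_per_m = q, fitted = fitted, residuals = y - fitted,
                 chi2 = sum((y - fitted)^2), instrument = ins),
            class = "dls_fit")
}

#' @export
print.dls_fit <- function(x, ...) {
  cat(sprintf("DLS fit: A = %.4g, B = %.4g, D = %.4g m^2/s, d_H = %.1f nm\n",
              x$A, x$B, x$D_m2_s, x$d_H_nm))
  invisible(x)
}

#' Size-distribution statistics for diameter tables
#'
#' Histograms a set of particle diameters at a fixed bin width (25 nm for
#' electron-microscopy tables), fits a log-normal by maximum likelihood
#' (closed form: mean and sd of log diameters), and reports the fitted mode
#' and full width at half maximum of the fitted density.
#'
#' @param diameters_nm Positive diameters (nm), >= 10 values.
#' @param bin_width_nm Histogram bin width (nm).
#' @return List: `histogram` (data.frame mid/counts), `peak_nm` (fitted
#'   mode), `fwhm_nm`, `meanlog`, `sdlog`, `n`.
#' @export
size_distribution_stats <- function(diameters_nm, bin_width_nm = 25) {
  d <- as.numeric(diameters_nm)
  if (length(d) < 10L) stop("need >= 10 diameters")
  if (any(!is.finite(d)) || any(d <= 0)) stop("diameters must be positive")
  if (bin_width_nm <= 0) stop("bin width must be positive")

  breaks <- seq(floor(min(d) / bin_width_nm) * bin_width_nm,
                ceiling(max(d) / bin_width_nm) * bin_width_nm + bin_width_nm / 2,
                by = bin_width_nm)
  h <- graphics::hist(d, breaks = breaks, plot = FALSE)

  mu <- mean(log(d))
  sdl <- sqrt(mean((log(d) - mu)^2))   # MLE (n denominator)
  if (sdl < 1e-12) {
    peak <- exp(mu); fwhm <- 0
  } else {
    peak <- exp(mu - sdl^2)
    fwhm <- lognormal_fwhm(mu, sdl)
  }
  list(histogram = data.frame(mid_nm = h$mids, counts = h$counts),
       peak_nm = peak, fwhm_nm = fwhm, meanlog = mu, sdlog = sdl,
       n = length(d))
}

# FWHM of a log-normal density, found numerically on either side of the mode
lognormal_fwhm <- function(meanlog, sdlog) {
  mode <- exp(meanlog - sdlog^2)
  half <- stats::dlnorm(mode, meanlog, sdlog) / 2
  f <- function(x) stats::dlnorm(x, meanlog, sdlog) - half
  lo <- stats::uniroot(f, lower = mode * 1e-6, upper = mode, tol = 1e-12 * mode)$root
  hi_upper <- mode
  while (f(hi_upper) > 0) hi_upper <- hi_upper * 2
  hi <- stats::uniroot(f, lower = mode, upper = hi_upper, tol = 1e-12 * mode)$root
  hi - lo
}

# (meanlog, sdlog) of the log-normal with a given mode and FWHM;
# FWHM/mode depends on sdlog alone, so invert that ratio first
lognormal_from_mode_fwhm <- function(mode_nm, fwhm_nm) {
  ratio <- fwhm_nm / mode_nm
  g <- function(s) lognormal_fwhm(s^2, s) / exp(0) - ratio  # mode=1 when meanlog=s^2
  sdl <- stats::uniroot(g, lower = 1e-4, upper = 3, tol = 1e-10)$root
  c(meanlog = log(mode_nm) + sdl^2, sdlog = sdl)
}

#' Read / write correlogram CSV
#'
#' Columns `lag_s`, `g2`; instrument and environment fields travel in `#`
#' comment header lines (`key=value`).
#'
#' @param path CSV path.
#' @return A [correlogram()] (reader).
#' @export
read_correlogram_csv <- function(path) {
  hdr <- grep("^#", readLines(path, n = 10L), value = TRUE)
  get <- function(key, default) {
    m <- regmatches(hdr, regexec(paste0(key, "=([0-9.eE+-]+)"), hdr))
    v <- unlist(lapply(m, function(x) if (length(x) == 2) as.numeric(x[2]) else NULL))
    if (length(v)) v[1] else default
  }
  ins <- dls_instrument(wavelength_nm = get("wavelength_nm", 633),
                        angle_deg = get("angle_deg", 178),
                        refractive_index = get("refractive_index", 1.33),
                        temperature_K = get("temperature_K", 298.15),
                        viscosity_Pa_s = get("viscosity_Pa_s", 8.9e-4))
  d <- utils::read.csv(path, comment.char = "#")
  correlogram(d$lag_s, d$g2, ins)
}

#' @rdname read_correlogram_csv
#' @param corr Correlogram to write.
#' @export
write_correlogram_csv <- function(corr, path) {
  ins <- corr$instrument
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# wavelength_nm=%g angle_deg=%g refractive_index=%g temperature_K=%g viscosity_Pa_s=%g",
    ins$wavelength_nm, ins$angle_deg, ins$refractive_index,
    ins$temperature_K, ins$viscosity_Pa_s), con)
  utils::write.csv(data.frame(lag_s = corr$lag_s, g2 = corr$g2),
                   con, row.names = FALSE)
  invisible(path)
}
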