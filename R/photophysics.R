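#' FRET parameters
#'
#' Container for the photophysical constants governing intensity-to-distance
#' conversion. The only required constant is the Forster radius \eqn{R_0},
#' the donor--acceptor separation at which transfer efficiency is 50\%;
#' for the DiI--DiD membrane stain pair used throughout, \eqn{R_0 = 5.3} nm.
#'
#' Optional correction hooks (`donor_correction`, `acceptor_correction`) are
#' applied to background-corrected intensities before the efficiency ratio is
#' formed. They default to the identity, i.e. efficiencies are *apparent*
#' (proxy) efficiencies with no gamma-factor, spectral-leakage or
#' direct-excitation correction.
#'
#' @param forster_radius_nm Forster radius in nm (> 0). Default 5.3.
#' @param donor_correction,acceptor_correction Functions applied to the donor
#'   and acceptor intensities before computing efficiencies. Default identity.
#' @return An object of class `fret_params`.
#' @examples
#' fret_params()                      # DiI-DiD defaults
#' fret_params(forster_radius_nm = 6)
#' @export
fret_params <- function(forster_radius_nm = 5.3,
                        donor_correction = identity,
                        acceptor_correction = identity) {
  if (!is.numeric(forster_radius_nm) || length(forster_radius_nm) != 1L ||
      !is.finite(forster_radius_nm) || forster_radius_nm <= 0) {
    stop("'forster_radius_nm' must be a single positive number")
  }
  stopifnot(is.function(donor_correction), is.function(acceptor_correction))
  structure(
    list(forster_radius_nm = forster_radius_nm,
         donor_correction = donor_correction,
         acceptor_correction = acceptor_correction),
    class = "fret_params"
  )
}

#' @export
print.fret_params <- function(x, ...) {
  cat("FRET parameters: R0 =", x$forster_radius_nm, "nm\n")
  invisible(x)
}

#' Apparent FRET efficiency from donor/acceptor intensities
#'
#' Computes the apparent (proxy) FRET efficiency
#' \deqn{E = I_A / (I_A + I_D)}
#' from background-corrected donor and acceptor intensities. Both arguments
#' are vectorised; negative intensities are rejected and pairs summing to
#' zero are an error (the ratio is undefined).
#'
#' @param donor,acceptor Nonnegative background-corrected intensities
#'   (arbitrary but common units).
#' @param params A [fret_params()] object supplying optional intensity
#'   correction hooks (identity by default).
#' @return Efficiencies in \[0, 1\], same length as the inputs.
#' @examples
#' fret_efficiency(40, 60)   # 0.6
#' @export
fret_efficiency <- function(donor, acceptor, params = fret_params()) {
  if (any(!is.finite(donor)) || any(!is.finite(acceptor))) {
    stop("intensities must be finite")
  }
  if (any(donor < 0) || any(acceptor < 0)) {
    stop("intensities must be nonnegative (background-corrected)")
  }
  d <- params$donor_correction(donor)
  a <- params$acceptor_correction(acceptor)
  tot <- d + a
  if (any(tot <= 0)) {
    stop("donor + acceptor must be positive: efficiency ratio undefined")
  }
  a / tot
}

#' Convert FRET efficiency to mean dye separation
#'
#' Inverts the Forster relation \eqn{E = R_0^6 / (R_0^6 + R^6)} to
#' \deqn{R = R_0 \left(\frac{1 - E}{E}\right)^{1/6}.}
#' The separation diverges as \eqn{E \to 0} and collapses to zero as
#' \eqn{E \to 1}, so only the open interval is accepted.
#'
#' @param efficiency Efficiencies strictly inside (0, 1); vectorised.
#' @param params A [fret_params()] object carrying \eqn{R_0}.
#' @return Separations in nm.
#' @examples
#' efficiency_to_distance(0.5)   # equals R0: 5.3 nm
#' efficiency_to_distance(0.4)   # 5.7 nm to one decimal
#' @export
efficiency_to_distance <- function(efficiency, params = fret_params()) {
  if (any(!is.finite(efficiency)) || any(efficiency <= 0) || any(efficiency >= 1)) {
    stop("'efficiency' must lie strictly in (0, 1)")
  }
  params$forster_radius_nm * ((1 - efficiency) / efficiency)^(1 / 6)
}

#' Convert dye separation to FRET efficiency
#'
#' Forward Forster relation \eqn{E = R_0^6 / (R_0^6 + R^6)}; the exact
#' algebraic inverse of [efficiency_to_distance()].
#'
#' @param distance_nm Separations in nm (> 0); vectorised.
#' @param params A [fret_params()] object carrying \eqn{R_0}.
#' @return Efficiencies in (0, 1).
#' @examples
#' distance_to_efficiency(5.3)   # 0.5
#' @export
distance_to_efficiency <- function(distance_nm, params = fret_params()) {
  if (any(!is.finite(distance_nm)) || any(distance_nm <= 0)) {
    stop("'distance_nm' must be positive")
  }
  r0_6 <- params$forster_radius_nm^6
  r0_6 / (r0_6 + distance_nm^6)
}
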