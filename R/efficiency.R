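#' Spectral overlap efficiency of a broadband source relative to a laser line
#'
#' A broadband LED source excites a photosensitizer less efficiently per unit
#' of delivered fluence than a laser tuned to the absorption peak, because
#' part of the emission falls where the absorber is weaker. The spectral
#' efficiency quantifies this as the absorption-weighted mean of the source
#' spectrum, normalized to the absorption at the reference laser wavelength:
#'
#' \deqn{\epsilon = \frac{\int S(\lambda) A(\lambda)\,d\lambda}
#'                       {\int S(\lambda)\,d\lambda \; A(\lambda_{ref})}}
#'
#' A power meter with non-flat responsivity R(lambda) similarly misreads a
#' broadband source relative to the laser line it was referenced at; the
#' analogous detector correction factor
#' \eqn{\int S R d\lambda / \int S d\lambda / R(\lambda_{ref})} converts a
#' meter reading into true irradiance (divide the reading by this factor)
#' before any fluence is accumulated.
#'
#' Both integrals use the trapezoid rule on the union grid of the input
#' spectra (exact for the piecewise-linear sampled data). Spectra are zero
#' outside their own support. With `weighting = "photon"` the integrands are
#' additionally weighted by lambda, counting photons rather than energy; the
#' default is energy weighting.
#'
#' @param source Source emission spectrum S(lambda).
#' @param absorber Photosensitizer absorption spectrum A(lambda).
#' @param reference_nm Reference laser wavelength (nm), treated as an exact
#'   line; the absorber must be positive there.
#' @param detector Power-meter responsivity spectrum R(lambda), or `NULL`
#'   for a flat (already-corrected) detector.
#' @param weighting `"energy"` (default) or `"photon"`.
#' @return An object of class `pdt_efficiency`: a list with `epsilon`,
#'   `detector_correction`, `reference_nm`, `weighting`, and a
#'   `correction_order` note recording that the detector correction applies
#'   to the irradiance reading before dose accumulation.
#' @examples
#' led <- gaussian_spectrum(689, fwhm_nm = 26)
#' bpd <- gaussian_spectrum(690, fwhm_nm = 10)
#' spectral_efficiency(led, bpd, reference_nm = 690)
#' @export
spectral_efficiency <- function(source, absorber, reference_nm = 690,
                                detector = NULL,
                                weighting = c("energy", "photon")) {
  weighting <- match.arg(weighting)
  source <- as_spectrum(source, "source")
  absorber <- as_spectrum(absorber, "absorber")
  if (!is.null(detector)) detector <- as_spectrum(detector, "detector")

  a_ref <- spectrum_value_at(absorber, reference_nm)
  if (a_ref <= 0) {
    abort("absorber is zero at the reference wavelength")
  }
  grid <- sort(unique(c(source$wavelength_nm, absorber$wavelength_nm,
                        if (!is.null(detector)) detector$wavelength_nm,
                        reference_nm)))
  s <- resample_spectrum(source, grid)$value
  a <- resample_spectrum(absorber, grid)$value
  if (all(s * a == 0)) {
    abort("source and absorber supports are disjoint: overlap integral is zero")
  }
  wgt <- if (weighting == "photon") grid else rep(1, length(grid))
  s_int <- pracma::trapz(grid, s * wgt)
  epsilon <- pracma::trapz(grid, s * a * wgt) / s_int / a_ref

  detector_correction <- 1
  if (!is.null(detector)) {
    r_ref <- spectrum_value_at(detector, reference_nm)
    if (r_ref <= 0) abort("detector responsivity is zero at the reference wavelength")
    r <- resample_spectrum(detector, grid)$value
    detector_correction <- pracma::trapz(grid, s * r * wgt) / s_int / r_ref
  }

  structure(
    list(
      epsilon = epsilon,
      detector_correction = detector_correction,
      reference_nm = reference_nm,
      weighting = weighting,
      correction_order = "detector correction divides the meter irradiance reading before fluence integration; epsilon then scales accumulated fluence to effective dose"
    ),
    class = "pdt_efficiency"
  )
}

#' @export
print.pdt_efficiency <- function(x, ...) {
  cat(sprintf(
    "<spectral efficiency vs %.6g nm line (%s-weighted)>\n  epsilon: %.4f (%.2f%%)\n  detector correction: %.4f\n",
    x$reference_nm, x$weighting, x$epsilon, 100 * x$epsilon,
    x$detector_correction
  ))
  invisible(x)
}

#' @export
tidy.pdt_efficiency <- function(x, ...) {
  tibble(
    epsilon = x$epsilon,
    detector_correction = x$detector_correction,
    reference_nm = x$reference_nm,
    weighting = x$weighting
  )
}

#' Convert a delivered fluence to an effective light dose
#'
#' Scales a (detector-corrected) fluence by the spectral efficiency so that
#' broadband-LED doses are comparable with doses from the reference laser
#' line. An epsilon of 1 (the laser itself) leaves the dose unchanged.
#'
#' @param dose_Jcm2 Delivered fluence in J/cm2, >= 0. The irradiance reading
#'   behind it is assumed already divided by `eff$detector_correction`.
#' @param eff A `pdt_efficiency`, or a bare numeric epsilon.
#' @return Effective dose in J/cm2.
#' @examples
#' effective_dose(10, 0.6198)  # 6.198
#' @export
effective_dose <- function(dose_Jcm2, eff) {
  if (any(dose_Jcm2 < 0)) abort("dose must be non-negative")
  epsilon <- if (inherits(eff, "pdt_efficiency")) eff$epsilon else as.numeric(eff)
  dose_Jcm2 * epsilon
}

#' Correct a power-meter irradiance reading for detector responsivity
#'
#' @param reading_mWcm2 Meter reading(s) in mW/cm2.
#' @param eff A `pdt_efficiency` (or numeric correction factor).
#' @return True irradiance: reading / detector_correction.
#' @export
correct_meter_reading <- function(reading_mWcm2, eff) {
  k <- if (inherits(eff, "pdt_efficiency")) eff$detector_correction else as.numeric(eff)
  reading_mWcm2 / k
}
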