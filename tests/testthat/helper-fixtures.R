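# shared fixtures, all built in code

linear_calib_400 <- function() {
  irradiance_calibration(
    tibble::tibble(duty = (1:20) / 20, irradiance_mWcm2 = 400 * (1:20) / 20)
  )
}

# slope 1000: makes 50 mW/cm2 exactly representable (duty 0.05)
linear_calib_1000 <- function() {
  irradiance_calibration(
    tibble::tibble(duty = (1:20) / 20, irradiance_mWcm2 = 1000 * (1:20) / 20)
  )
}

# independent dense midpoint-Riemann oracle for the overlap efficiency;
# deliberately avoids the package's trapezoid path
riemann_efficiency <- function(source, absorber, ref_nm, detector = NULL,
                               step = 0.002) {
  rng <- range(c(source$wavelength_nm, absorber$wavelength_nm,
                 if (!is.null(detector)) detector$wavelength_nm))
  edges <- seq(rng[1], rng[2], by = step)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  interp <- function(s, x) {
    y <- approx(s$wavelength_nm, s$value, xout = x, rule = 1)$y
    y[is.na(y)] <- 0
    y
  }
  s <- interp(source, mid)
  a <- interp(absorber, mid)
  a_ref <- approx(absorber$wavelength_nm, absorber$value, xout = ref_nm)$y
  eps <- sum(s * a * step) / sum(s * step) / a_ref
  det_k <- 1
  if (!is.null(detector)) {
    r <- interp(detector, mid)
    r_ref <- approx(detector$wavelength_nm, detector$value, xout = ref_nm)$y
    det_k <- sum(s * r * step) / sum(s * step) / r_ref
  }
  list(epsilon = eps, detector_correction = det_k)
}

# minimal valid layout: one treatment group plus the four controls
# (controls live in rows E-H so custom treatment footprints in rows A-C
# cannot collide with them)
tiny_layout <- function(dose = 8, footprint_wells = c("A1", "A2", "A3",
                                                      "B1", "B2", "B3")) {
  plate_layout(
    tibble::tibble(
      group = c("PDT", "DNL", "LND", "NDNL", "MO"),
      role = c("treatment", "DNL", "LND", "NDNL", "MO"),
      wells = list(footprint_wells,
                   paste0("E", 1:6), paste0("F", 1:6),
                   paste0("G", 1:6), paste0("H", 1:6)),
      dose_Jcm2 = c(dose, 0, 0, 0, 0)
    ),
    replicates = if (length(footprint_wells) == 6L) 6L else NA_integer_
  )
}
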