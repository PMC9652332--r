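#' Generate a synthetic viability table
#'
#' Simulates one plate's raw luminescence readings from a known 4PL ground
#' truth: treatment wells respond to their group dose through
#' v(d) = bottom + (top - bottom)/(1 + (d/ec50)^hill); NDNL and DNL sit at
#' the top, LND at its delivered dose's response, MO at the media-only
#' background. Multiplicative Gaussian noise with the given CV is applied to
#' the cell-derived signal. Defaults mirror the standard dose-response
#' experiment: the 2-12 J/cm2 dose ladder, six replicates, 5% CV.
#'
#' @param layout A [plate_layout()] (default [canonical_layout_96()]).
#' @param truth Named list with `top`, `bottom`, `ec50`, `hill` (defaults
#'   100, 0, 6, 2).
#' @param cv Coefficient of variation of the luminescence noise (default
#'   0.05).
#' @param lum_ndnl,lum_mo Mean luminescence of the NDNL (100%) and MO (0%)
#'   anchors (defaults 1e6 and 5e4 counts).
#' @param seed Integer seed; the table is deterministic given it.
#' @return A tibble with columns `well`, `group`, `role`, `dose_Jcm2`,
#'   `luminescence`.
#' @export
generate_viability_table <- function(layout = canonical_layout_96(),
                                     truth = list(top = 100, bottom = 0,
                                                  ec50 = 6, hill = 2),
                                     cv = 0.05,
                                     lum_ndnl = 1e6, lum_mo = 5e4,
                                     seed = 1L) {
  tbl <- as_tibble(layout)[, c("well", "group", "role", "dose_Jcm2")]
  max_dose <- max(c(0, tbl$dose_Jcm2[tbl$role == "treatment"]))
  with_preserved_seed(seed, {
    v <- dplyr::case_when(
      tbl$role == "treatment" ~ pl4_predict(tbl$dose_Jcm2, truth$top,
                                            truth$bottom,
                                            log10(truth$ec50), truth$hill),
      tbl$role == "LND" ~ pl4_predict(max_dose, truth$top, truth$bottom,
                                      log10(truth$ec50), truth$hill),
      tbl$role %in% c("DNL", "NDNL") ~ truth$top,
      tbl$role == "MO" ~ 0
    )
    # LND carries no drug, so light alone leaves viability at the top
    v[tbl$role == "LND"] <- truth$top
    signal <- lum_mo + v / 100 * (lum_ndnl - lum_mo)
    noise <- 1 + stats::rnorm(nrow(tbl), 0, cv)
    lum <- lum_mo + (signal - lum_mo) * noise
    tbl$luminescence <- pmax(lum, 0)
  })
  tbl
}

# evaluate expr under set.seed(seed) without disturbing the caller's RNG
with_preserved_seed <- function(seed, expr) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else {
    NULL
  }
  on.exit(
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    },
    add = TRUE
  )
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Generate the full synthetic fixture set
#'
#' Builds every input the package's pipelines need, without hardware or
#' downloads: an LED emission spectrum (Gaussian, centre 689 nm, half-max
#' crossings at 676 and 702 nm), a photosensitizer Q-band absorption
#' spectrum (Gaussian, peak 690 nm, 10 nm FWHM), a smooth near-flat
#' power-meter responsivity, a 20-point linear duty-to-irradiance
#' calibration reaching 400 mW/cm2, the canonical 96-well layout and a
#' noisy viability table. Deterministic per seed; `write_dir` optionally
#' serializes everything to plain-text files (spectra/calibration CSV,
#' layout JSON).
#'
#' @param seed Integer seed for the noisy components.
#' @param write_dir Optional directory to write the fixture files into.
#' @param step_nm Spectral grid step (default 0.02 nm).
#' @return A list of class `pdt_fixtures`: `led`, `absorber`, `detector`
#'   (spectra), `calibration`, `layout`, `viability`, `thermal`, `seed`.
#' @export
generate_fixtures <- function(seed = 1L, write_dir = NULL, step_nm = 0.02) {
  led <- gaussian_spectrum(689, fwhm_nm = 26, range_nm = c(640, 740),
                           step_nm = step_nm)
  absorber <- gaussian_spectrum(690, fwhm_nm = 10, range_nm = c(640, 740),
                                step_nm = step_nm)
  # near-flat detector: a gentle linear tilt of 0.05%/nm around 690
  w <- seq(640, 740, by = step_nm)
  detector <- spectrum_tbl(w, 1 + 5e-4 * (w - 690))
  calib <- irradiance_calibration(
    tibble(duty = (1:20) / 20, irradiance_mWcm2 = 400 * (1:20) / 20)
  )
  layout <- canonical_layout_96()
  viability <- generate_viability_table(layout, seed = seed)
  out <- structure(
    list(led = led, absorber = absorber, detector = detector,
         calibration = calib, layout = layout, viability = viability,
         thermal = thermal_params(), seed = as.integer(seed)),
    class = "pdt_fixtures"
  )
  if (!is.null(write_dir)) {
    if (!dir.exists(write_dir)) dir.create(write_dir, recursive = TRUE)
    write_spectrum_csv(led, file.path(write_dir, "led_spectrum.csv"),
                       comments = "synthetic LED emission, FWHM 676-702 nm")
    write_spectrum_csv(absorber, file.path(write_dir, "absorber_spectrum.csv"),
                       comments = "synthetic photosensitizer Q-band, 690/10 nm")
    write_spectrum_csv(detector, file.path(write_dir, "detector_response.csv"),
                       comments = "synthetic near-flat power-meter responsivity")
    readr::write_csv(calib$points, file.path(write_dir, "calibration.csv"))
    write_layout_json(layout, file.path(write_dir, "layout.json"))
    readr::write_csv(viability, file.path(write_dir, "viability.csv"))
  }
  out
}

#' @export
print.pdt_fixtures <- function(x, ...) {
  cat(sprintf(
    "<synthetic fixture set (seed %d): LED %d pts, absorber %d pts, %d-well layout, %d viability rows>\n",
    x$seed, nrow(x$led), nrow(x$absorber), nrow(as_tibble(x$layout)),
    nrow(x$viability)
  ))
  invisible(x)
}
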