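#' PWM configuration
#'
#' The LED array is driven by a square wave synthesized sample-by-sample on
#' a DAQ analog output: a carrier (default 250 Hz) built from a fixed
#' sampling rate (default 5 kHz), giving an integer number of samples per
#' period and hence a finite set of representable duty cycles.
#'
#' @param carrier_hz Square-wave frequency (Hz), default 250.
#' @param sample_hz DAQ sampling rate (Hz), default 5000. Must be an integer
#'   multiple of `carrier_hz`.
#' @param high_level_V,low_level_V Pulse levels (V), default 10 and 0.
#' @return A list of class `pdt_pwm_config`.
#' @export
pwm_config <- function(carrier_hz = 250, sample_hz = 5000,
                       high_level_V = 10, low_level_V = 0) {
  if (carrier_hz <= 0 || sample_hz <= 0) abort("rates must be positive")
  if (high_level_V <= low_level_V) abort("high level must exceed low level")
  cfg <- structure(
    list(carrier_hz = carrier_hz, sample_hz = sample_hz,
         high_level_V = high_level_V, low_level_V = low_level_V),
    class = "pdt_pwm_config"
  )
  samples_per_period(cfg)  # validates divisibility
  cfg
}

#' Samples per PWM period
#'
#' @param cfg A [pwm_config()].
#' @return Integer sample count per carrier period (sample_hz / carrier_hz).
#' @examples
#' samples_per_period(pwm_config(250, 5000))  # 20
#' @export
samples_per_period <- function(cfg) {
  ratio <- cfg$sample_hz / cfg$carrier_hz
  if (abs(ratio - round(ratio)) > 1e-9) {
    abort(sprintf(
      "sample rate %g Hz is not an integer multiple of carrier %g Hz (ratio %.4g)",
      cfg$sample_hz, cfg$carrier_hz, ratio
    ))
  }
  as.integer(round(ratio))
}

#' Representable nonzero duty cycles
#'
#' With N samples per period the duty cycle can only change in steps of 1/N;
#' the nonzero levels are k/N for k = 1..N (the default 250 Hz / 5 kHz
#' configuration gives 20 levels in 5% steps).
#'
#' @param cfg A [pwm_config()].
#' @return Increasing numeric vector of N duty fractions.
#' @export
available_duties <- function(cfg) {
  n <- samples_per_period(cfg)
  seq_len(n) / n
}

#' One period of the PWM sample waveform
#'
#' @param duty Duty fraction; must be representable (`k/N`) or 0.
#' @param cfg A [pwm_config()].
#' @return Numeric vector of N sample levels (V): the on-samples first, then
#'   the off-samples. Its mean is `low + duty * (high - low)`.
#' @export
build_waveform <- function(duty, cfg) {
  n <- samples_per_period(cfg)
  k <- duty * n
  if (abs(k - round(k)) > 1e-9 || duty < 0 || duty > 1) {
    abort(sprintf("duty %.4g is not representable with %d samples per period",
                  duty, n))
  }
  k <- as.integer(round(k))
  c(rep(cfg$high_level_V, k), rep(cfg$low_level_V, n - k))
}

#' Duty-cycle to irradiance calibration
#'
#' The time-averaged irradiance at the sample plane is linear in the PWM
#' duty cycle (the LEDs switch in under 100 ns, so the average power is the
#' duty-weighted on-power). The calibration is a least-squares line through
#' measured (duty, irradiance) points with a free intercept; a lookup-table
#' mode (monotone linear interpolation through the points) is available for
#' calibrations where high-duty saturation matters.
#'
#' @param points Data frame with columns `duty` (fractions in \[0, 1\]) and
#'   `irradiance_mWcm2`; irradiance must be non-decreasing in duty.
#' @param mode `"linear"` (default) or `"lookup"`.
#' @param max_irradiance_mWcm2 Hard ceiling of the system (default: largest
#'   calibrated irradiance). The full-power system reaches 400 mW/cm2.
#' @return A list of class `pdt_calibration` with `slope`, `intercept`,
#'   `max_irradiance_mWcm2`, `residual_bound_mWcm2` (max absolute fit
#'   residual over the points) and the points themselves.
#' @examples
#' pts <- tibble::tibble(duty = (1:20) / 20, irradiance_mWcm2 = 400 * (1:20) / 20)
#' calib <- irradiance_calibration(pts)
#' @export
irradiance_calibration <- function(points, mode = c("linear", "lookup"),
                                   max_irradiance_mWcm2 = NULL) {
  mode <- match.arg(mode)
  if (!all(c("duty", "irradiance_mWcm2") %in% names(points))) {
    abort("calibration points need columns duty and irradiance_mWcm2")
  }
  points <- dplyr::arrange(as_tibble(points), .data$duty)
  if (any(points$duty < 0 | points$duty > 1)) abort("duties must lie in [0, 1]")
  if (any(points$irradiance_mWcm2 < 0)) abort("irradiance must be non-negative")
  if (is.unsorted(points$irradiance_mWcm2)) {
    abort("irradiance must be non-decreasing in duty")
  }
  if (nrow(points) < 2) abort("need at least two calibration points")
  fit <- lm(irradiance_mWcm2 ~ duty, data = points)
  structure(
    list(
      points = points,
      mode = mode,
      slope = unname(coef(fit)[["duty"]]),
      intercept = unname(coef(fit)[["(Intercept)"]]),
      residual_bound_mWcm2 = max(abs(stats::residuals(fit))),
      max_irradiance_mWcm2 = max_irradiance_mWcm2 %||% max(points$irradiance_mWcm2)
    ),
    class = "pdt_calibration"
  )
}

#' @export
print.pdt_calibration <- function(x, ...) {
  cat(sprintf(
    "<irradiance calibration (%s): %.4g mW/cm2 per unit duty %+.4g, max %.4g mW/cm2, fit residual <= %.3g mW/cm2, %d points>\n",
    x$mode, x$slope, x$intercept, x$max_irradiance_mWcm2,
    x$residual_bound_mWcm2, nrow(x$points)
  ))
  invisible(x)
}

#' Read a calibration CSV (duty, irradiance_mWcm2)
#'
#' @param path CSV path with columns `duty` and `irradiance_mWcm2`.
#' @param ... Passed to [irradiance_calibration()].
#' @export
read_calibration_csv <- function(path, ...) {
  df <- readr::read_csv(path, comment = "#", show_col_types = FALSE,
                        progress = FALSE)
  irradiance_calibration(df, ...)
}

#' Calibrated irradiance for a duty cycle
#'
#' @param duty Duty fraction(s).
#' @param calib A [irradiance_calibration()].
#' @return Irradiance in mW/cm2 (clamped at 0 from below).
#' @export
irradiance_for_duty <- function(duty, calib) {
  out <- switch(calib$mode,
    linear = calib$intercept + calib$slope * duty,
    lookup = approx(calib$points$duty, calib$points$irradiance_mWcm2,
                    xout = duty, rule = 2)$y
  )
  pmax(out, 0)
}

#' Nearest representable duty for a target irradiance
#'
#' Picks, among the representable duty levels, the one whose calibrated
#' irradiance is closest to the target. Ties break toward the lower duty:
#' under-dosing is the safer failure mode in a cytotoxicity assay.
#'
#' @param target_mWcm2 Requested irradiance, 0 < target <= calibration max.
#' @param calib A [irradiance_calibration()].
#' @param cfg A [pwm_config()].
#' @return A tibble with one row: `duty`, `achieved_mWcm2`.
#' @examples
#' pts <- tibble::tibble(duty = (1:20) / 20, irradiance_mWcm2 = 400 * (1:20) / 20)
#' duty_for_irradiance(100, irradiance_calibration(pts), pwm_config())
#' @export
duty_for_irradiance <- function(target_mWcm2, calib, cfg = pwm_config()) {
  if (target_mWcm2 <= 0) abort("target irradiance must be positive")
  if (target_mWcm2 > calib$max_irradiance_mWcm2) {
    abort(sprintf("target %.4g mW/cm2 exceeds calibrated maximum %.4g mW/cm2",
                  target_mWcm2, calib$max_irradiance_mWcm2))
  }
  duties <- available_duties(cfg)
  achieved <- irradiance_for_duty(duties, calib)
  err <- abs(achieved - target_mWcm2)
  # near-ties (within numerical noise of the calibration fit) break toward
  # the lower duty; duties are sorted ascending
  tol <- 1e-9 * max(1, target_mWcm2)
  i <- which(err <= min(err) + tol)[1]
  tibble(duty = duties[i], achieved_mWcm2 = achieved[i])
}

#' Exposure time for a target fluence at a given irradiance
#'
#' fluence (J/cm2) = irradiance (W/cm2) x time (s), so
#' t = dose / (irradiance / 1000).
#'
#' @param dose_Jcm2 Target fluence (J/cm2), > 0.
#' @param irradiance_mWcm2 Delivered irradiance (mW/cm2), > 0.
#' @return Exposure time in seconds.
#' @examples
#' exposure_time(156, 200)  # 780 s = 13 min
#' @export
exposure_time <- function(dose_Jcm2, irradiance_mWcm2) {
  if (any(dose_Jcm2 <= 0)) abort("dose must be positive")
  if (any(irradiance_mWcm2 <= 0)) abort("irradiance must be positive")
  dose_Jcm2 / (irradiance_mWcm2 / 1000)
}
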