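#' Voltage-divider sensor circuit
#'
#' The on-board thermistor and phototransistor are each read through a
#' resistive divider across the 12 V supply: a fixed resistor (5 kOhm for the
#' thermistor, 10 kOhm for the phototransistor) in series with the sensor.
#' With the sensor on top (default) the output is taken across the fixed
#' resistor, so the output voltage rises as the sensor resistance falls -
#' i.e. rises with temperature for an NTC thermistor and with light for the
#' phototransistor.
#'
#' @param supply_V Supply voltage (V), default 12.
#' @param fixed_ohm Fixed resistor (Ohm).
#' @param sensor_on_top If TRUE (default) the sensor sits between supply and
#'   the output node; if FALSE the fixed resistor does.
#' @return A list of class `pdt_divider`.
#' @export
divider_circuit <- function(supply_V = 12, fixed_ohm = 5000,
                            sensor_on_top = TRUE) {
  if (supply_V <= 0 || fixed_ohm <= 0) abort("supply and resistance must be positive")
  structure(
    list(supply_V = supply_V, fixed_ohm = fixed_ohm,
         sensor_on_top = sensor_on_top),
    class = "pdt_divider"
  )
}

#' Divider output voltage for a sensor resistance
#'
#' @param circuit A [divider_circuit()].
#' @param sensor_ohm Sensor resistance (Ohm), > 0.
#' @return Output voltage in V, strictly between 0 and the supply.
#' @examples
#' divider_output(divider_circuit(12, 5000), 5000)  # 6 V
#' @export
divider_output <- function(circuit, sensor_ohm) {
  if (any(sensor_ohm <= 0)) abort("sensor resistance must be positive")
  if (circuit$sensor_on_top) {
    circuit$supply_V * circuit$fixed_ohm / (circuit$fixed_ohm + sensor_ohm)
  } else {
    circuit$supply_V * sensor_ohm / (circuit$fixed_ohm + sensor_ohm)
  }
}

#' Invert a divider reading to the sensor resistance
#'
#' @param circuit A [divider_circuit()].
#' @param v Output voltage, strictly inside (0, supply).
#' @return Sensor resistance (Ohm).
#' @export
sensor_resistance <- function(circuit, v) {
  if (any(v <= 0) || any(v >= circuit$supply_V)) {
    abort("voltage must lie strictly between 0 and the supply voltage")
  }
  if (circuit$sensor_on_top) {
    circuit$fixed_ohm * (circuit$supply_V - v) / v
  } else {
    circuit$fixed_ohm * v / (circuit$supply_V - v)
  }
}

#' NTC thermistor beta model
#'
#' R(T) = r0 * exp(beta * (1/T - 1/T0)) with T in kelvin: resistance falls
#' monotonically with temperature. Defaults are the common 10 kOhm @ 25 C,
#' beta = 3950 K bead; all constants are configuration, to be replaced by
#' the values from your own part's calibration.
#'
#' @param r0_ohm Resistance at the reference temperature (Ohm).
#' @param t0_C Reference temperature (Celsius), default 25.
#' @param beta_K Beta constant (K), default 3950.
#' @return A list of class `pdt_ntc`.
#' @export
ntc_model <- function(r0_ohm = 10000, t0_C = 25, beta_K = 3950) {
  if (r0_ohm <= 0 || beta_K <= 0) abort("r0 and beta must be positive")
  structure(list(r0_ohm = r0_ohm, t0_K = t0_C + 273.15, beta_K = beta_K),
            class = "pdt_ntc")
}

#' @rdname ntc_model
#' @param ntc A `pdt_ntc`.
#' @param temp_C Temperature(s) in Celsius.
#' @return `ntc_resistance()`: resistance in Ohm.
#' @export
ntc_resistance <- function(ntc, temp_C) {
  t_K <- temp_C + 273.15
  if (any(t_K <= 0)) abort("temperature below absolute zero")
  ntc$r0_ohm * exp(ntc$beta_K * (1 / t_K - 1 / ntc$t0_K))
}

#' @rdname ntc_model
#' @param resistance_ohm Resistance(s) in Ohm, > 0.
#' @return `ntc_temperature()`: temperature in Celsius.
#' @export
ntc_temperature <- function(ntc, resistance_ohm) {
  if (any(resistance_ohm <= 0)) abort("resistance must be positive")
  1 / (1 / ntc$t0_K + log(resistance_ohm / ntc$r0_ohm) / ntc$beta_K) - 273.15
}

#' Temperature from a thermistor divider voltage
#'
#' Inverts the divider for the sensor resistance, then inverts the beta
#' model. Exactly reverses [voltage_from_temperature()].
#'
#' @param v Divider output voltage, inside (0, supply).
#' @param circuit A [divider_circuit()].
#' @param ntc A [ntc_model()].
#' @return Temperature in Celsius.
#' @export
temperature_from_voltage <- function(v, circuit, ntc) {
  ntc_temperature(ntc, sensor_resistance(circuit, v))
}

#' @rdname temperature_from_voltage
#' @param temp_C Temperature in Celsius.
#' @export
voltage_from_temperature <- function(temp_C, circuit, ntc) {
  divider_output(circuit, ntc_resistance(ntc, temp_C))
}

#' Fit a beta model from calibration points
#'
#' Least-squares fit of log-resistance against inverse temperature: the beta
#' model is linear in those coordinates, so three or more (temperature,
#' resistance) points determine r0 and beta.
#'
#' @param points Data frame with columns `temp_C`, `resistance_ohm`.
#' @param t0_C Reference temperature for the reported r0 (default 25).
#' @return A [ntc_model()].
#' @export
fit_ntc_beta <- function(points, t0_C = 25) {
  if (nrow(points) < 2) abort("need at least two calibration points")
  x <- 1 / (points$temp_C + 273.15)
  fit <- lm(log(points$resistance_ohm) ~ x)
  beta <- unname(coef(fit)[["x"]])
  r0 <- exp(unname(coef(fit)[["(Intercept)"]]) + beta / (t0_C + 273.15))
  ntc_model(r0_ohm = r0, t0_C = t0_C, beta_K = beta)
}

#' Phototransistor linear calibration with residual bound
#'
#' Linear least-squares fit of divider output voltage against optical power,
#' reporting the maximum absolute residual. Phototransistors saturate mildly
#' at high power; the residual bound documents how far the linear model
#' strays from the calibration points.
#'
#' @param points Data frame with columns `power_mW`, `voltage_V`.
#' @return A list of class `pdt_photo_fit`: `slope` (V/mW), `intercept` (V),
#'   `max_residual_mW` (worst-case power error of the inverted fit).
#' @export
fit_phototransistor <- function(points) {
  if (nrow(points) < 2) abort("need at least two calibration points")
  fit <- lm(voltage_V ~ power_mW, data = points)
  slope <- unname(coef(fit)[["power_mW"]])
  if (slope == 0) abort("flat response: no usable calibration")
  pred_power <- (points$voltage_V - unname(coef(fit)[["(Intercept)"]])) / slope
  structure(
    list(slope = slope, intercept = unname(coef(fit)[["(Intercept)"]]),
         max_residual_mW = max(abs(pred_power - points$power_mW))),
    class = "pdt_photo_fit"
  )
}

#' @rdname fit_phototransistor
#' @param fit A `pdt_photo_fit`.
#' @param voltage_V Measured divider voltage(s).
#' @return `power_from_voltage()`: optical power in mW.
#' @export
power_from_voltage <- function(fit, voltage_V) {
  (voltage_V - fit$intercept) / fit$slope
}

# AWG diameters follow the standard geometric progression
awg_area_mm2 <- function(gauge) {
  d_mm <- 0.127 * 92^((36 - gauge) / 39)
  pi * d_mm^2 / 4
}

#' Nearest standard AWG gauge for a conductor cross-section
#'
#' @param area_mm2 Cross-sectional area (mm2), > 0.
#' @return Integer AWG gauge (0-40) whose standard area is nearest; ties go
#'   to the thinner (higher-number) gauge.
#' @examples
#' awg_from_area(4 * 0.07)  # PCB lead 4 mm x 0.07 mm -> AWG 23
#' @export
awg_from_area <- function(area_mm2) {
  if (area_mm2 <= 0) abort("area must be positive")
  gauges <- 0:40
  err <- abs(awg_area_mm2(gauges) - area_mm2)
  # ties toward the thinner gauge = larger gauge number = later index
  candidates <- which(err == min(err))
  gauges[max(candidates)]
}

#' LED-array electrical budget
#'
#' The array wires groups of `n_series` LEDs in series and `n_parallel` such
#' branches in parallel. The budget reports the total supply current, the
#' voltage across one series branch, the resistance and voltage drop of the
#' PCB power lead (drop = I * rho * L / (w * h)), the drop as a percentage of
#' the branch voltage, and the nearest AWG wire equivalent to the lead's
#' cross-section.
#'
#' @param n_series LEDs per series branch (default 5).
#' @param n_parallel Parallel branches (default 5).
#' @param v_led_V Forward voltage per LED (V, default 2.4).
#' @param i_led_A Forward current per branch (A, default 0.6).
#' @param lead_width_mm PCB lead width (mm, default 4).
#' @param copper_height_mm Copper layer height (mm, default 0.07).
#' @param resistivity_ohm_m Copper resistivity (Ohm m, default 1.68e-8 at
#'   20 C).
#' @param lead_length_mm Power-lead length (mm); board-specific, no default
#'   in the electrical standard - measure your own trace.
#' @return A tibble with one row: `total_A`, `series_V`, `lead_ohm`,
#'   `drop_V`, `drop_pct`, `awg_equiv`.
#' @examples
#' electrical_budget(lead_length_mm = 220)
#' @export
electrical_budget <- function(n_series = 5, n_parallel = 5, v_led_V = 2.4,
                              i_led_A = 0.6, lead_width_mm = 4,
                              copper_height_mm = 0.07,
                              resistivity_ohm_m = 1.68e-8,
                              lead_length_mm = 100) {
  area_mm2 <- lead_width_mm * copper_height_mm
  if (area_mm2 <= 0) abort("lead cross-section must be positive")
  if (lead_length_mm <= 0) abort("lead length must be positive")
  total_A <- n_parallel * i_led_A
  series_V <- n_series * v_led_V
  lead_ohm <- resistivity_ohm_m * (lead_length_mm / 1000) / (area_mm2 * 1e-6)
  drop_V <- total_A * lead_ohm
  tibble(
    total_A = total_A,
    series_V = series_V,
    lead_ohm = lead_ohm,
    drop_V = drop_V,
    drop_pct = 100 * drop_V / series_V,
    awg_equiv = awg_from_area(area_mm2)
  )
}
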