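#' Generate a treatment plan from a layout
#'
#' Turns a validated plate layout into an ordered schedule of stage moves
#' and illuminations. Every group with a nonzero dose is visited exactly
#' once; the LND (light, no drug) control is always illuminated with the
#' maximum treatment dose. Per visit, the PWM layer picks the representable
#' duty closest to the requested irradiance and the exposure time delivers
#' the requested fluence at the achieved irradiance. Control groups that
#' receive no light (DNL, NDNL, MO) are carried as zero-illumination rows so
#' the plan documents the whole plate.
#'
#' Exposure times are not re-quantized to whole PWM periods; the worst-case
#' sub-period dose error this leaves is reported per visit
#' (`subperiod_dose_err_Jcm2`). Set `quantize_periods = TRUE` to round each
#' exposure to whole carrier periods instead.
#'
#' @param layout A [plate_layout()]; must validate cleanly.
#' @param irradiance_mWcm2 Requested irradiance for every illuminated visit.
#' @param calib A [irradiance_calibration()].
#' @param pwm_cfg A [pwm_config()].
#' @param motion_cfg A [motion_config()].
#' @param order Visit order, currently `"row-major"` (by group centroid,
#'   top-left to bottom-right) or `"as-is"` (layout group order).
#' @param home_mm Stage home position (mm), start of the motion chain.
#' @param quantize_periods Round exposures to whole PWM periods.
#' @return A tibble of class `pdt_plan`, one row per visit: `visit`,
#'   `group`, `role`, `dose_Jcm2`, `x_mm`, `y_mm`, `steps_x`, `steps_y`,
#'   `duty`, `irradiance_mWcm2` (achieved), `seconds`,
#'   `subperiod_dose_err_Jcm2`. Totals (illumination time, move count) are
#'   attached as attributes and shown by `print()`.
#' @examples
#' calib <- irradiance_calibration(
#'   tibble::tibble(duty = (1:20) / 20, irradiance_mWcm2 = 1000 * (1:20) / 20)
#' )
#' plan <- plan_experiment(canonical_layout_96(), 50, calib)
#' @export
plan_experiment <- function(layout, irradiance_mWcm2, calib,
                            pwm_cfg = pwm_config(),
                            motion_cfg = motion_config(),
                            order = c("row-major", "as-is"),
                            home_mm = c(0, 0),
                            quantize_periods = FALSE) {
  order <- match.arg(order)
  violations <- validate_layout(layout)
  if (length(violations) > 0) {
    abort(paste0("layout is invalid:\n", paste("-", violations, collapse = "\n")))
  }
  fmt <- attr(layout, "format") %||% plate_format_96()

  groups <- dplyr::group_by(as_tibble(layout), .data$group, .data$role,
                            .data$dose_Jcm2) |>
    dplyr::summarise(wells = list(.data$well), .groups = "drop")
  # centroid of each group's wells = stage target
  cent <- purrr::map_dfr(groups$wells, function(w) {
    pos <- well_position(w, fmt)
    tibble(x_mm = mean(pos$x_mm), y_mm = mean(pos$y_mm))
  })
  groups <- dplyr::bind_cols(groups, cent)

  # LND is illuminated with the maximum treatment dose
  max_dose <- max(c(0, groups$dose_Jcm2[groups$role == "treatment"]))
  groups$dose_Jcm2[groups$role == "LND"] <- max_dose

  lit <- groups[groups$dose_Jcm2 > 0, ]
  dark <- groups[groups$dose_Jcm2 <= 0, ]
  if (order == "row-major") {
    lit <- dplyr::arrange(lit, .data$y_mm, .data$x_mm)
  }

  pick <- if (nrow(lit) > 0) {
    tryCatch(
      duty_for_irradiance(irradiance_mWcm2, calib, pwm_cfg),
      error = function(e) {
        abort(sprintf("irradiance %g mW/cm2 unachievable for plan: %s",
                      irradiance_mWcm2, conditionMessage(e)))
      }
    )
  } else {
    tibble(duty = 0, achieved_mWcm2 = 0)
  }

  period_s <- 1 / pwm_cfg$carrier_hz
  mk_visit <- function(g, from) {
    steps <- motion_steps(from, c(g$x_mm, g$y_mm), motion_cfg)
    secs <- if (g$dose_Jcm2 > 0) {
      exposure_time(g$dose_Jcm2, pick$achieved_mWcm2)
    } else {
      0
    }
    # work in whole-period units to keep exact multiples exact
    n_periods <- secs * pwm_cfg$carrier_hz
    if (quantize_periods && secs > 0) {
      n_periods <- round(n_periods)
      secs <- n_periods / pwm_cfg$carrier_hz
    }
    frac_period <- n_periods - round(n_periods)
    frac_period <- if (abs(frac_period) < 1e-9) 0 else
      n_periods - floor(n_periods)
    tibble(
      group = g$group, role = g$role, dose_Jcm2 = g$dose_Jcm2,
      x_mm = g$x_mm, y_mm = g$y_mm,
      steps_x = steps$steps[1] * steps$direction[1],
      steps_y = steps$steps[2] * steps$direction[2],
      duty = if (g$dose_Jcm2 > 0) pick$duty else 0,
      irradiance_mWcm2 = if (g$dose_Jcm2 > 0) pick$achieved_mWcm2 else 0,
      seconds = secs,
      subperiod_dose_err_Jcm2 = if (quantize_periods || secs == 0) 0 else
        pick$achieved_mWcm2 / 1000 * frac_period * period_s
    )
  }

  pos <- as.numeric(home_mm)
  visits <- vector("list", nrow(lit) + nrow(dark))
  ordered <- dplyr::bind_rows(lit, dark)
  for (i in seq_len(nrow(ordered))) {
    g <- ordered[i, ]
    visits[[i]] <- mk_visit(g, pos)
    if (g$dose_Jcm2 > 0) pos <- c(g$x_mm, g$y_mm)  # dark groups: no move
  }
  plan <- dplyr::bind_cols(
    tibble(visit = seq_len(nrow(ordered))),
    dplyr::bind_rows(visits)
  )
  plan$steps_x[plan$dose_Jcm2 <= 0] <- 0L
  plan$steps_y[plan$dose_Jcm2 <= 0] <- 0L

  structure(
    plan,
    layout = layout,
    pwm_cfg = pwm_cfg,
    motion_cfg = motion_cfg,
    requested_mWcm2 = irradiance_mWcm2,
    total_illumination_s = sum(plan$seconds),
    n_moves = sum(plan$dose_Jcm2 > 0),
    class = c("pdt_plan", class(plan))
  )
}

#' @export
print.pdt_plan <- function(x, ...) {
  cat(sprintf(
    "<treatment plan: %d visits (%d illuminated), total illumination %.4g s>\n",
    nrow(x), attr(x, "n_moves"), attr(x, "total_illumination_s")
  ))
  NextMethod()
}

#' Write a treatment plan CSV
#'
#' Columns: visit, group, x_mm, y_mm, steps_x, steps_y, duty, seconds.
#'
#' @param plan A [plan_experiment()] result.
#' @param path Output path.
#' @export
write_plan_csv <- function(plan, path) {
  readr::write_csv(
    dplyr::select(as_tibble(plan), "visit", "group", "x_mm", "y_mm",
                  "steps_x", "steps_y", "duty", "seconds"),
    path
  )
  invisible(path)
}
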