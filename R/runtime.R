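#' Virtual hardware rig
#'
#' A software stand-in for the physical instrument: PWM channel, two stepper
#' axes, the thermistor/phototransistor sensor models and a virtual clock.
#' Executing a plan against it produces the same event stream and per-well
#' fluence bookkeeping the real controller would, in milliseconds of compute
#' (no wall-clock sleeps). All sensor noise is seeded, so identical seeds
#' and plans give identical logs.
#'
#' @param pwm_cfg A [pwm_config()].
#' @param motion_cfg A [motion_config()].
#' @param thermal A [thermal_params()] for the simulated sample temperature.
#' @param divider,ntc Thermistor readout models ([divider_circuit()],
#'   [ntc_model()]).
#' @param seed Integer noise seed.
#' @param home_mm Stage home position (mm).
#' @param travel_mm Per-axis travel limits, length-2 (min, max) in mm.
#' @param step_rate_hz Motor step rate for move timing (default 500 steps/s).
#' @param sensor_rate_hz Sensor sampling rate during illumination (default
#'   1 Hz).
#' @param temp_noise_C,photo_noise_mW Gaussian sensor noise SDs (default
#'   0.1 degC and 1 mW).
#' @param t_thresh_C Thermal-interlock ceiling (Celsius, default 37).
#' @param dwell_s Settling dwell after each move (s, default 0).
#' @param port_map Opaque DAQ port names carried into the log for fidelity.
#' @return A list of class `pdt_rig`.
#' @export
virtual_rig <- function(pwm_cfg = pwm_config(),
                        motion_cfg = motion_config(),
                        thermal = thermal_params(),
                        divider = divider_circuit(12, 5000),
                        ntc = ntc_model(),
                        seed = 1L,
                        home_mm = c(0, 0),
                        travel_mm = c(-150, 150),
                        step_rate_hz = 500,
                        sensor_rate_hz = 1,
                        temp_noise_C = 0.1,
                        photo_noise_mW = 1,
                        t_thresh_C = 37,
                        dwell_s = 0,
                        port_map = c(pwm = "AO0", thermistor = "AI0",
                                     phototransistor = "AI1",
                                     pul_x = "p0.1", dir_x = "p0.2",
                                     pul_y = "p0.3", dir_y = "p0.4")) {
  structure(
    list(pwm_cfg = pwm_cfg, motion_cfg = motion_cfg, thermal = thermal,
         divider = divider, ntc = ntc, seed = as.integer(seed),
         home_mm = home_mm, travel_mm = travel_mm,
         step_rate_hz = step_rate_hz, sensor_rate_hz = sensor_rate_hz,
         temp_noise_C = temp_noise_C, photo_noise_mW = photo_noise_mW,
         t_thresh_C = t_thresh_C, dwell_s = dwell_s, port_map = port_map),
    class = "pdt_rig"
  )
}

#' Execute a treatment plan on the virtual rig
#'
#' Replays the plan visit by visit on a virtual clock: move (both axes
#' stepped independently), optional dwell, then illuminate. Per-well fluence
#' accrues as achieved irradiance x on-time for every well inside the
#' visit's open aperture; no light is emitted during motion. A thermal
#' interlock projects each exposure's end temperature with the rig's lumped
#' thermal model and refuses the plan up front if any visit would cross the
#' configured threshold (set `override_thermal = TRUE` to run anyway). A
#' move beyond the travel range aborts execution, returning the partial log.
#'
#' @param plan A [plan_experiment()] result.
#' @param rig A [virtual_rig()].
#' @param override_thermal Run even if the thermal projection crosses the
#'   rig's threshold.
#' @return A list of class `pdt_eventlog`: `events` (tibble: `t_s`, `event`,
#'   `group`, `detail`, `value`), `fluence` (tibble: `well`, `group`,
#'   `dose_Jcm2` requested, `fluence_Jcm2` delivered), `aborted` flag and
#'   the final clock time.
#' @export
run_plan <- function(plan, rig = virtual_rig(), override_thermal = FALSE) {
  if (!inherits(plan, "pdt_plan")) abort("plan must come from plan_experiment()")
  layout <- attr(plan, "layout")
  fmt <- attr(layout, "format") %||% plate_format_96()

  # duty representability is checked before any execution
  duties <- c(0, available_duties(rig$pwm_cfg))
  bad <- setdiff(unique(plan$duty), duties)
  if (length(bad) > 0) {
    abort(sprintf("plan duty %.4g not representable on this rig",
                  bad[1]))
  }

  # thermal interlock: project every illuminated visit before starting
  lit <- plan[plan$seconds > 0, ]
  if (nrow(lit) > 0 && !override_thermal) {
    peak <- temperature_at(lit$seconds, lit$irradiance_mWcm2, rig$thermal)
    if (any(peak >= rig$t_thresh_C)) {
      v <- lit$group[which(peak >= rig$t_thresh_C)[1]]
      abort(sprintf(
        "thermal interlock: visit %s projects %.1f C >= %.1f C threshold (override_thermal = TRUE to force)",
        v, max(peak), rig$t_thresh_C
      ))
    }
  }

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
  set.seed(rig$seed)

  fluence <- dplyr::mutate(
    as_tibble(layout)[, c("well", "group", "dose_Jcm2")],
    fluence_Jcm2 = 0
  )
  events <- list()
  emit <- function(t, event, group = NA_character_, detail = NA_character_,
                   value = NA_real_) {
    events[[length(events) + 1L]] <<- tibble(
      t_s = t, event = event, group = group, detail = detail, value = value
    )
  }

  clock <- 0
  pos <- as.numeric(rig$home_mm)
  aborted <- FALSE
  step_mm <- rig$motion_cfg$step_size_um / 1000

  for (i in seq_len(nrow(plan))) {
    visit <- plan[i, ]
    if (visit$dose_Jcm2 <= 0) next  # dark controls: no motion, no light

    target <- c(visit$x_mm, visit$y_mm)
    if (any(target < rig$travel_mm[1]) || any(target > rig$travel_mm[2])) {
      emit(clock, "abort", visit$group,
           sprintf("target (%.4g, %.4g) mm outside travel range", target[1],
                   target[2]))
      aborted <- TRUE
      break
    }
    steps <- motion_steps(pos, target, rig$motion_cfg)
    emit(clock, "move_start", visit$group,
         sprintf("steps x=%d y=%d", steps$steps[1] * steps$direction[1],
                 steps$steps[2] * steps$direction[2]))
    move_s <- max(steps$steps) / rig$step_rate_hz
    clock <- clock + move_s
    # landed position = commanded steps, not the exact target
    pos <- pos + steps$direction * steps$steps * step_mm
    emit(clock, "move_end", visit$group)
    clock <- clock + rig$dwell_s

    emit(clock, "illuminate_start", visit$group,
         sprintf("duty %.3g on %s", visit$duty, rig$port_map[["pwm"]]),
         visit$irradiance_mWcm2)
    # sensor samples during the exposure
    n_samp <- floor(visit$seconds * rig$sensor_rate_hz)
    if (n_samp > 0) {
      t_rel <- seq_len(n_samp) / rig$sensor_rate_hz
      temp <- temperature_at(t_rel, visit$irradiance_mWcm2, rig$thermal) +
        stats::rnorm(n_samp, 0, rig$temp_noise_C)
      volt <- voltage_from_temperature(
        pmax(temp, rig$thermal$t_env_C - 5), rig$divider, rig$ntc
      )
      photo <- visit$irradiance_mWcm2 +
        stats::rnorm(n_samp, 0, rig$photo_noise_mW)
      for (k in seq_len(n_samp)) {
        emit(clock + t_rel[k], "sensor_sample", visit$group,
             sprintf("%s=%.4g V; %s=%.4g mW/cm2",
                     rig$port_map[["thermistor"]], volt[k],
                     rig$port_map[["phototransistor"]], photo[k]),
             temp[k])
      }
    }
    clock <- clock + visit$seconds
    emit(clock, "illuminate_end", visit$group)

    in_group <- fluence$group == visit$group
    fluence$fluence_Jcm2[in_group] <- fluence$fluence_Jcm2[in_group] +
      visit$irradiance_mWcm2 / 1000 * visit$seconds
  }

  structure(
    list(
      events = if (length(events) > 0) dplyr::bind_rows(events) else
        tibble(t_s = numeric(), event = character(), group = character(),
               detail = character(), value = numeric()),
      fluence = fluence,
      aborted = aborted,
      final_t_s = clock
    ),
    class = "pdt_eventlog"
  )
}

#' @export
print.pdt_eventlog <- function(x, ...) {
  cat(sprintf(
    "<event log: %d events over %.4g virtual s, %d wells dosed%s>\n",
    nrow(x$events), x$final_t_s, sum(x$fluence$fluence_Jcm2 > 0),
    if (x$aborted) ", ABORTED" else ""
  ))
  invisible(x)
}

#' Serialize an event log
#'
#' `write_eventlog_jsonl()` writes one JSON object per event (JSON-lines);
#' `write_fluence_csv()` writes the per-well fluence summary, optionally
#' adding an effective-dose column for a given spectral efficiency.
#'
#' @param log A [run_plan()] result.
#' @param path Output path.
#' @export
write_eventlog_jsonl <- function(log, path) {
  lines <- vapply(seq_len(nrow(log$events)), function(i) {
    jsonlite::toJSON(as.list(log$events[i, ]), auto_unbox = TRUE,
                     digits = NA, na = "null")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_eventlog_jsonl
#' @param eff Optional [spectral_efficiency()] (or numeric epsilon) to add
#'   an `effective_Jcm2` column.
#' @export
write_fluence_csv <- function(log, path, eff = NULL) {
  out <- log$fluence
  if (!is.null(eff)) {
    out$effective_Jcm2 <- effective_dose(out$fluence_Jcm2, eff)
  }
  readr::write_csv(out, path)
  invisible(path)
}
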