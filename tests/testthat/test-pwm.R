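test_that("samples per period follows the rate ratio and rejects non-integers", {
  expect_identical(samples_per_period(pwm_config(250, 5000)), 20L)
  expect_identical(samples_per_period(pwm_config(100, 1000)), 10L)
  expect_error(pwm_config(300, 5000), "not an integer multiple")
})

test_that("available duties are k/N including full power", {
  expect_equal(available_duties(pwm_config(250, 5000)), seq(0.05, 1, by = 0.05))
  expect_length(available_duties(pwm_config(250, 5000)), 20)
  expect_equal(available_duties(pwm_config(100, 100)), 1)
  expect_equal(available_duties(pwm_config(250, 1000)), c(0.25, 0.5, 0.75, 1))
})

test_that("waveforms put the on-samples first and average to the duty", {
  cfg <- pwm_config()
  w <- build_waveform(0.25, cfg)
  expect_equal(w, c(rep(10, 5), rep(0, 15)))
  expect_equal(build_waveform(1, cfg), rep(10, 20))
  expect_equal(build_waveform(0, cfg), rep(0, 20))
  for (duty in available_duties(cfg)) {
    expect_equal(mean(build_waveform(duty, cfg)) / cfg$high_level_V, duty)
  }
  expect_error(build_waveform(0.13, cfg), "not representable")
})

test_that("calibration fit records slope, intercept and residual bound", {
  pts <- tibble::tibble(duty = (1:20) / 20,
                        irradiance_mWcm2 = 400 * (1:20) / 20)
  calib <- irradiance_calibration(pts)
  expect_equal(calib$slope, 400, tolerance = 1e-9)
  expect_equal(calib$intercept, 0, tolerance = 1e-9)
  expect_lt(calib$residual_bound_mWcm2, 1e-9)
  expect_equal(calib$max_irradiance_mWcm2, 400)
  expect_error(
    irradiance_calibration(
      tibble::tibble(duty = c(0.2, 0.4), irradiance_mWcm2 = c(100, 50))
    ),
    "non-decreasing"
  )
})

test_that("lookup mode follows saturation that the linear fit smooths over", {
  # saturating high end
  pts <- tibble::tibble(duty = (1:10) / 10,
                        irradiance_mWcm2 = 400 * tanh(1.2 * (1:10) / 10))
  lut <- irradiance_calibration(pts, mode = "lookup")
  expect_equal(irradiance_for_duty(0.5, lut),
               pts$irradiance_mWcm2[5], tolerance = 1e-12)
  lin <- irradiance_calibration(pts, mode = "linear")
  expect_gt(lin$residual_bound_mWcm2, 1)
})

test_that("duty selection is nearest-with-low-tie and enforces bounds", {
  calib <- linear_calib_400()
  cfg <- pwm_config()
  hit <- duty_for_irradiance(100, calib, cfg)
  expect_equal(hit$duty, 0.25)
  expect_equal(hit$achieved_mWcm2, 100)
  # 90 sits exactly between 80 (duty .20) and 100 (duty .25): lower wins
  tie <- duty_for_irradiance(90, calib, cfg)
  expect_equal(tie$duty, 0.20)
  expect_equal(tie$achieved_mWcm2, 80)
  expect_error(duty_for_irradiance(500, calib, cfg), "exceeds")
  expect_error(duty_for_irradiance(0, calib, cfg), "positive")
  expect_error(duty_for_irradiance(-5, calib, cfg), "positive")
})

test_that("duty -> irradiance -> duty round-trips to the achieved value", {
  calib <- linear_calib_400()
  cfg <- pwm_config()
  for (duty in available_duties(cfg)) {
    irr <- irradiance_for_duty(duty, calib)
    back <- duty_for_irradiance(irr, calib, cfg)
    expect_equal(back$duty, duty)
    expect_equal(back$achieved_mWcm2, irr)
  }
})

test_that("exposure time implements dose = irradiance x time", {
  expect_equal(exposure_time(156, 200), 780)   # 13 min
  expect_equal(exposure_time(8, 100), 80)
  expect_equal(exposure_time(12, 50), 240)
  expect_error(exposure_time(0, 100), "positive")
  expect_error(exposure_time(8, 0), "positive")
})

test_that("calibration CSV round-trips", {
  path <- withr::local_tempfile(fileext = ".csv")
  pts <- tibble::tibble(duty = (1:4) / 4, irradiance_mWcm2 = c(90, 180, 270, 360))
  readr::write_csv(pts, path)
  calib <- read_calibration_csv(path)
  expect_equal(calib$points$irradiance_mWcm2, pts$irradiance_mWcm2)
})
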