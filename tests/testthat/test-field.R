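test_that("on-axis irradiance of a single emitter falls with height", {
  one <- emitter_array(n_side = 1)
  irr <- vapply(c(10, 20, 40, 80), function(z) {
    f <- simulate_field(one, z_mm = z, grid_mm = list(x = 0, y = 0))
    f$irradiance_mWcm2[1, 1]
  }, numeric(1))
  expect_true(all(diff(irr) < 0))
})

test_that("the symmetric 5x5 array field is invariant under 90-degree rotation", {
  arr <- emitter_array()
  f <- simulate_field(arr, z_mm = 25.4, grid_mm = 1, window_mm = 30)
  m <- f$irradiance_mWcm2
  rot <- t(m[nrow(m):1, ])  # 90-degree rotation of a square matrix
  expect_lt(max(abs(m - rot)) / max(m), 1e-9)
})

test_that("plane-integrated power conserves the emitted power within 2%", {
  one <- emitter_array(n_side = 1, power_mW = 520)
  f <- simulate_field(one, z_mm = 25.4, grid_mm = 1, window_mm = 80)
  expect_equal(field_power_mW(f), 520, tolerance = 0.02)
})

test_that("per-well means respect uniform fields, masks and radial falloff", {
  fmt <- plate_format_96()
  wells3x3 <- as.vector(outer(c("A", "B", "C"), 1:3, paste0))
  # uniform synthetic field
  uni <- structure(
    list(irradiance_mWcm2 = matrix(7.5, 81, 81),
         x_mm = seq(-20, 20, 0.5), y_mm = seq(-20, 20, 0.5), z_mm = 25),
    class = "pdt_field"
  )
  fmt_c <- plate_format(8, 12, 9, a1_offset_mm = c(-9, -9))
  means <- per_well_irradiance(uni, wells3x3, fmt_c)
  expect_true(all(means$mean_mWcm2 == 7.5))
  # fully closed mask -> all zeros
  masked <- per_well_irradiance(uni, wells3x3, fmt_c, mask = closed_mask())
  expect_true(all(masked$mean_mWcm2 == 0))
  # centred Gaussian: centre well beats corner wells
  g <- gaussian_laser_field(waist_mm = 15, peak_mWcm2 = 100, grid_mm = 0.5,
                            window_mm = 20)
  gm <- per_well_irradiance(g, wells3x3, fmt_c)
  expect_gt(gm$mean_mWcm2[5], max(gm$mean_mWcm2[c(1, 3, 7, 9)]))
  # well outside the grid errors
  expect_error(per_well_irradiance(g, "H12", fmt_c), "outside")
})

test_that("the uniformity metric is centre-vs-worst-corner percent difference", {
  expect_equal(uniformity_metric(rep(5, 9)), 0)
  v <- c(90, 95, 92, 95, 100, 95, 91, 95, 93)
  expect_equal(uniformity_metric(v), 10)
  expect_error(uniformity_metric(c(1, 1, 1, 1, 0, 1, 1, 1, 1)), "positive")
  expect_error(uniformity_metric(1:4), "9 well")
})

test_that("the LED array illuminates a 3x3 group more evenly than the laser", {
  fmt_c <- plate_format(8, 12, 9, a1_offset_mm = c(-9, -9))
  wells3x3 <- as.vector(outer(c("A", "B", "C"), 1:3, paste0))
  arr <- calibrate_transmission(emitter_array(), 400, grid_mm = 1)
  led_f <- simulate_field(arr, z_mm = 25.4, grid_mm = 0.5, window_mm = 25)
  led_w <- per_well_irradiance(led_f, wells3x3, fmt_c)
  laser_f <- gaussian_laser_field(waist_mm = 25.4, peak_mWcm2 = 100,
                                  grid_mm = 0.5, window_mm = 25)
  laser_w <- per_well_irradiance(laser_f, wells3x3, fmt_c)
  u_led <- uniformity_metric(led_w$mean_mWcm2)
  u_laser <- uniformity_metric(laser_w$mean_mWcm2)
  expect_lt(u_led, u_laser)
  expect_gt(u_led, 0)
})

test_that("masking can only remove power and calibration hits the target peak", {
  arr <- emitter_array()
  f <- simulate_field(arr, grid_mm = 1, window_mm = 40)
  open_p <- field_power_mW(f)
  masked <- mask_field(f, aperture_mask(tibble::tibble(
    x0_mm = -10, x1_mm = 10, y0_mm = -10, y1_mm = 10
  )))
  expect_lt(field_power_mW(masked), open_p)
  cal <- calibrate_transmission(arr, 400, grid_mm = 1)
  f400 <- simulate_field(cal, grid_mm = 1)
  expect_equal(max(f400$irradiance_mWcm2), 400, tolerance = 1e-6)
})

test_that("3x3 uniformity has an interior optimum in emitter half-angle", {
  # too narrow leaves per-emitter ripple across the group; too wide domes
  # the superposed field toward the centre - the best uniformity sits at an
  # intermediate beam width on the default geometry
  fmt_c <- plate_format(8, 12, 9, a1_offset_mm = c(-9, -9))
  wells3x3 <- as.vector(outer(c("A", "B", "C"), 1:3, paste0))
  u <- vapply(c(6, 10, 25), function(half) {
    arr <- emitter_array(half_angle_deg = half)
    f <- simulate_field(arr, z_mm = 25.4, grid_mm = 1, window_mm = 25)
    uniformity_metric(per_well_irradiance(f, wells3x3, fmt_c)$mean_mWcm2)
  }, numeric(1))
  expect_lt(u[2], u[1])
  expect_lt(u[2], u[3])
})
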