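test_that("well names parse, convert and reject malformed input", {
  idx <- parse_wells(c("A1", "H12"))
  expect_equal(idx$row, c(0L, 7L))
  expect_equal(idx$col, c(0L, 11L))
  expect_equal(well_name(0, 0), "A1")
  expect_error(parse_wells("1A"), "malformed")
  expect_error(parse_wells("A13"), "outside")
  pos <- well_position(c("A1", "B4"), plate_format_96())
  expect_equal(pos$x_mm, c(0, 27))
  expect_equal(pos$y_mm, c(0, 9))
})

test_that("the canonical 96-well layout is valid, staggered included", {
  layout <- canonical_layout_96()
  expect_equal(nrow(tibble::as_tibble(layout)), 96)
  expect_equal(length(unique(layout$group)), 16)
  expect_true(all(table(layout$group) == 6))
  expect_length(validate_layout(layout, staggered = TRUE), 0)
})

test_that("layout violations are reported, not silently fixed", {
  layout <- canonical_layout_96()
  no_mo <- plate_layout(
    dplyr::group_by(tibble::as_tibble(layout), group, role, dose_Jcm2) |>
      dplyr::summarise(wells = list(well), .groups = "drop") |>
      dplyr::filter(role != "MO"),
    replicates = 6L
  )
  expect_match(validate_layout(no_mo), "missing control: MO", all = FALSE)

  dup <- tibble::tibble(
    group = c("A", "B", "DNL", "LND", "NDNL", "MO"),
    role = c("treatment", "treatment", "DNL", "LND", "NDNL", "MO"),
    wells = list("A1", "A1", "B1", "B2", "B3", "B4"),
    dose_Jcm2 = c(2, 4, 0, 0, 0, 0)
  )
  v <- validate_layout(plate_layout(dup, replicates = 1L))
  expect_match(v, "assigned twice", all = FALSE)

  # a same-dose pair in edge-adjacent footprints trips the stagger check
  clash <- tibble::tibble(
    group = c("P1", "P2", "DNL", "LND", "NDNL", "MO"),
    role = c("treatment", "treatment", "DNL", "LND", "NDNL", "MO"),
    wells = list(c("A1", "A2"), c("B1", "B2"), "D1", "D2", "D3", "D4"),
    dose_Jcm2 = c(6, 6, 0, 0, 0, 0)
  )
  v <- validate_layout(plate_layout(clash, replicates = NULL),
                       staggered = TRUE)
  expect_match(v, "staggering violated", all = FALSE)
})

test_that("layout JSON round-trips", {
  layout <- canonical_layout_96()
  path <- withr::local_tempfile(fileext = ".json")
  write_layout_json(layout, path)
  back <- read_layout_json(path)
  a <- dplyr::arrange(tibble::as_tibble(layout), well)
  b <- dplyr::arrange(tibble::as_tibble(back), well)
  expect_equal(b$group, a$group)
  expect_equal(b$dose_Jcm2, a$dose_Jcm2)
  expect_length(validate_layout(back), 0)
})

test_that("motion planning converts displacements to steps with bounded residual", {
  cfg <- motion_config(25)
  three_pitches <- motion_steps(c(0, 0), c(27, 0), cfg)
  expect_equal(three_pitches$steps, c(1080L, 0L))
  expect_equal(three_pitches$direction[1], 1L)

  still <- motion_steps(c(5, 5), c(5, 5), cfg)
  expect_equal(still$steps, c(0L, 0L))

  back <- motion_steps(c(9, 0), c(0, 0), cfg)
  expect_equal(back$steps[1], 360L)
  expect_equal(back$direction[1], -1L)

  set.seed(42)
  for (i in 1:50) {
    mv <- motion_steps(runif(2, -50, 50), runif(2, -50, 50), cfg)
    expect_true(all(abs(mv$residual_mm) <= 0.025 / 2 + 1e-12))
  }
})

test_that("plan_experiment reproduces the dose-ladder illumination total", {
  # two series over 2..12 J/cm2 at 50 mW/cm2: sum = 2 x 42 / 0.05 = 1680 s,
  # plus the LND control at the 12 J/cm2 maximum (240 s)
  plan <- plan_experiment(canonical_layout_96(), 50, linear_calib_1000())
  tr <- plan[plan$role == "treatment", ]
  expect_equal(sum(tr$seconds), 1680)
  lnd <- plan[plan$role == "LND", ]
  expect_equal(lnd$dose_Jcm2, 12)
  expect_equal(lnd$seconds, 240)
  expect_equal(attr(plan, "total_illumination_s"), 1920)
  expect_equal(attr(plan, "n_moves"), 13)
  # illuminated visits come in row-major centroid order
  lit <- plan[plan$seconds > 0, ]
  expect_true(all(diff(order(lit$y_mm, lit$x_mm)) > 0))
})

test_that("a single-group plan exposes for dose/irradiance seconds", {
  plan <- plan_experiment(tiny_layout(dose = 8), 100, linear_calib_400())
  expect_equal(plan$seconds[plan$role == "treatment"], 80)
  expect_equal(plan$duty[plan$role == "treatment"], 0.25)
})

test_that("an all-zero dose map yields a controls-only plan with no illumination", {
  layout <- tiny_layout(dose = 0)
  plan <- plan_experiment(layout, 100, linear_calib_400())
  expect_equal(attr(plan, "total_illumination_s"), 0)
  expect_true(all(plan$seconds == 0))
  expect_setequal(plan$role, c("treatment", "DNL", "LND", "NDNL", "MO"))
})

test_that("plans surface PWM errors with context and report sub-period error", {
  expect_error(
    plan_experiment(tiny_layout(8), 900, linear_calib_400()),
    "unachievable"
  )
  # 7 J/cm2 at 80 mW/cm2 -> 87.5 s = 21875 periods exactly: zero residual
  plan <- plan_experiment(tiny_layout(7), 80, linear_calib_400())
  expect_equal(plan$subperiod_dose_err_Jcm2[plan$role == "treatment"], 0)
  # quantization mode rounds to whole periods
  plan_q <- plan_experiment(tiny_layout(8.0001), 100, linear_calib_400(),
                            quantize_periods = TRUE)
  secs <- plan_q$seconds[plan_q$role == "treatment"]
  n_periods <- secs * 250
  expect_equal(n_periods, round(n_periods), tolerance = 1e-9)
})
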