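test_that("a single-visit plan deposits the requested dose on all nine wells", {
  layout <- tiny_layout(dose = 8, footprint_wells = as.vector(
    outer(c("A", "B", "C"), 1:3, paste0)
  ))
  plan <- plan_experiment(layout, 100, linear_calib_400())
  log <- run_plan(plan, virtual_rig(seed = 2))
  dosed <- log$fluence[log$fluence$group == "PDT", ]
  expect_equal(nrow(dosed), 9)
  # within one duty-quantization step of the request (here: exact)
  duty_step_Jcm2 <- 400 / 20 / 1000 * 80
  expect_true(all(abs(dosed$fluence_Jcm2 - 8) <= duty_step_Jcm2))
  expect_equal(dosed$fluence_Jcm2, rep(8, 9))
  # LND is illuminated at the maximum treatment dose; the dark controls stay dark
  expect_equal(log$fluence$fluence_Jcm2[log$fluence$group == "LND"], rep(8, 6))
  dark <- log$fluence$group %in% c("DNL", "NDNL", "MO")
  expect_true(all(log$fluence$fluence_Jcm2[dark] == 0))
  expect_false(log$aborted)
})

test_that("an all-controls plan produces no illumination events", {
  plan <- plan_experiment(tiny_layout(dose = 0), 100, linear_calib_400())
  log <- run_plan(plan, virtual_rig())
  expect_equal(sum(log$events$event == "illuminate_start"), 0)
  expect_true(all(log$fluence$fluence_Jcm2 == 0))
})

test_that("disjoint groups never share fluence and totals are conserved", {
  plan <- plan_experiment(canonical_layout_96(), 50, linear_calib_1000())
  log <- run_plan(plan, virtual_rig(seed = 9))
  fl <- log$fluence
  # each well gets exactly its group's dose (LND at the 12 J/cm2 maximum)
  expect_equal(fl$fluence_Jcm2[fl$group == "MO"], rep(0, 6))
  lit <- plan[plan$seconds > 0, ]
  wells_per_group <- table(fl$group)
  expected_total <- sum(
    lit$irradiance_mWcm2 / 1000 * lit$seconds *
      as.numeric(wells_per_group[lit$group])
  )
  expect_equal(sum(fl$fluence_Jcm2), expected_total, tolerance = 1e-12)
  # every illuminated visit dosed only its own 6 wells
  for (g in lit$group) {
    expect_equal(sum(fl$group == g & fl$fluence_Jcm2 > 0), 6)
  }
})

test_that("event logs are deterministic given the seed and ordered in time", {
  plan <- plan_experiment(tiny_layout(6), 100, linear_calib_400())
  log1 <- run_plan(plan, virtual_rig(seed = 123))
  log2 <- run_plan(plan, virtual_rig(seed = 123))
  expect_identical(log1$events, log2$events)
  log3 <- run_plan(plan, virtual_rig(seed = 124))
  expect_false(identical(log3$events$value, log1$events$value))
  expect_true(all(diff(log1$events$t_s) >= 0))
  # no illumination during motion: every move_end precedes the next
  # illuminate_start at a strictly later-or-equal clock time
  ev <- log1$events
  ill <- ev$t_s[ev$event == "illuminate_start"]
  mv <- ev$t_s[ev$event == "move_end"]
  expect_true(all(vapply(ill, function(t) any(mv <= t), logical(1))))
})

test_that("the thermal interlock refuses overheating plans unless overridden", {
  # 160 J/cm2 at 200 mW/cm2 -> 800 s, past the 779 s crossing of 37 C
  plan <- plan_experiment(tiny_layout(160), 200, linear_calib_400())
  expect_error(run_plan(plan, virtual_rig()), "thermal interlock")
  log <- run_plan(plan, virtual_rig(), override_thermal = TRUE)
  expect_false(log$aborted)
  # a cooler plan passes untouched
  ok <- plan_experiment(tiny_layout(8), 100, linear_calib_400())
  expect_silent(run_plan(ok, virtual_rig()))
})

test_that("moves outside the travel range abort with a partial log", {
  layout <- tiny_layout(8)
  plan <- plan_experiment(layout, 100, linear_calib_400())
  rig <- virtual_rig(travel_mm = c(-1, 1))
  log <- run_plan(plan, rig)
  expect_true(log$aborted)
  expect_equal(log$events$event[nrow(log$events)], "abort")
  expect_true(all(log$fluence$fluence_Jcm2 == 0))
})

test_that("logs serialize to JSON-lines and fluence to CSV", {
  plan <- plan_experiment(tiny_layout(8), 100, linear_calib_400())
  log <- run_plan(plan, virtual_rig(seed = 4))
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_eventlog_jsonl(log, jl)
  lines <- readLines(jl)
  expect_equal(length(lines), nrow(log$events))
  first <- jsonlite::fromJSON(lines[1])
  expect_equal(first$event, "move_start")
  cs <- withr::local_tempfile(fileext = ".csv")
  write_fluence_csv(log, cs, eff = 0.62)
  back <- readr::read_csv(cs, show_col_types = FALSE)
  expect_equal(back$effective_Jcm2, back$fluence_Jcm2 * 0.62)
})

test_that("fixture generation is deterministic and meets its contracts", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  fx1 <- generate_fixtures(42, write_dir = dir1)
  fx2 <- generate_fixtures(42, write_dir = dir2)
  for (f in list.files(dir1)) {
    expect_identical(readLines(file.path(dir1, f)),
                     readLines(file.path(dir2, f)))
  }
  # LED fixture honours the half-maximum band edges
  expect_equal(unname(fwhm_interval(fx1$led)), c(676, 702), tolerance = 1e-4)
  # viability at the 100% anchors averages ~100
  norm <- normalize_viability(fx1$viability)
  ndnl <- norm$viability_pct[norm$role == "NDNL"]
  expect_equal(mean(ndnl), 100, tolerance = 0.05)
  # different seeds change the noisy parts only
  fx3 <- generate_fixtures(43)
  expect_identical(fx3$led, fx1$led)
  expect_false(identical(fx3$viability$luminescence,
                         fx1$viability$luminescence))
})
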