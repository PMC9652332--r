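test_that("viability normalization anchors controls at 100% and 0%", {
  tbl <- tibble::tibble(
    well = paste0("A", 1:8),
    group = c("T", "T", "NDNL", "NDNL", "MO", "MO", "T", "T"),
    role = c("treatment", "treatment", "NDNL", "NDNL", "MO", "MO",
             "treatment", "treatment"),
    dose_Jcm2 = c(2, 4, 0, 0, 0, 0, 6, 8),
    luminescence = c(900, 700, 1000, 1000, 100, 100, 550, 325)
  )
  norm <- normalize_viability(tbl)
  expect_equal(norm$viability_pct[3], 100)               # raw = NDNL mean
  expect_equal(norm$viability_pct[5], 0)                 # raw = MO mean
  expect_equal(norm$viability_pct[7], 50)                # midway
  bad <- tbl
  bad$luminescence[bad$role == "NDNL"] <- 50
  expect_error(normalize_viability(bad), "exceed")
  expect_error(normalize_viability(tbl[tbl$role != "MO", ]), "at least 2")
})

test_that("a noise-free 4PL is recovered to machine precision", {
  truth <- list(top = 100, bottom = 0, ec50 = 4.2, hill = 2)
  d <- rep(c(0.5, 1, 2, 4, 8, 16, 32), each = 2)
  v <- truth$bottom + (truth$top - truth$bottom) /
    (1 + (d / truth$ec50)^truth$hill)
  fit <- fit_4pl(d, v)
  expect_equal(fit$top, truth$top, tolerance = 1e-6)
  expect_equal(fit$bottom, truth$bottom, tolerance = 1e-6)
  expect_equal(fit$ec50, truth$ec50, tolerance = 1e-6)
  expect_equal(fit$hill, truth$hill, tolerance = 1e-6)
  # the fitted curve passes through (ec50, (top+bottom)/2) exactly
  expect_equal(predict(fit, fit$ec50), (fit$top + fit$bottom) / 2,
               tolerance = 1e-9)
})

test_that("degenerate dose-response inputs are refused", {
  expect_error(fit_4pl(c(1, 2, 4, 8), rep(50, 4)), "no dose effect")
  expect_error(fit_4pl(c(1, 2, 2, 1), c(90, 60, 61, 89)), "4 distinct")
})

test_that("constrained fits pin top and bottom", {
  d <- rep(c(1, 2, 4, 8, 16, 32), each = 3)
  withr::with_seed(11, {
    v <- 97 / (1 + (d / 6)^1.8) + 2 + rnorm(length(d), 0, 2)
  })
  fit <- fit_4pl(d, v, constrain_top = 100, constrain_bottom = 0)
  expect_equal(fit$top, 100)
  expect_equal(fit$bottom, 0)
  expect_equal(fit$ec50, 6, tolerance = 0.2)
})

test_that("normalization then refit is invariant to affine luminescence rescaling", {
  fx_tbl <- generate_viability_table(seed = 5)
  fit_a <- fit_dose_response(fx_tbl)
  rescaled <- dplyr::mutate(fx_tbl, luminescence = 3.7 * luminescence + 1e5)
  fit_b <- fit_dose_response(rescaled)
  # identical up to optimizer numerical noise
  expect_equal(fit_b$ec50, fit_a$ec50, tolerance = 1e-5)
  expect_equal(fit_b$hill, fit_a$hill, tolerance = 1e-5)
  expect_equal(fit_b$top, fit_a$top, tolerance = 1e-5)
})

test_that("replicate spread peaks where the dose-response slope is steepest", {
  # light-dose jitter maps to viability spread through |dv/dd|: simulate
  # replicates with 3% dose noise and compare the SD profile to the slope
  truth <- list(top = 100, bottom = 0, ec50 = 6, hill = 2)
  doses <- c(1, 2, 4, 6, 8, 12, 24)
  withr::with_seed(13, {
    sds <- vapply(doses, function(d) {
      jitter <- d * (1 + rnorm(400, 0, 0.03))
      sd(truth$top / (1 + (jitter / truth$ec50)^truth$hill))
    }, numeric(1))
  })
  slope <- abs(
    -truth$top * truth$hill * (doses / truth$ec50)^truth$hill /
      (doses * (1 + (doses / truth$ec50)^truth$hill)^2)
  ) * doses * 0.03
  expect_equal(doses[which.max(sds)], doses[which.max(slope)])
})

test_that("effective EC50 scales by epsilon and preserves ordering", {
  expect_equal(effective_ec50(10, 0.6198), 6.198)
  expect_equal(effective_ec50(10, 1), 10)
  d <- rep(c(1, 2, 4, 8, 16, 32), each = 2)
  fit1 <- fit_4pl(d, 100 / (1 + (d / 5)^2))
  fit2 <- fit_4pl(d, 100 / (1 + (d / 9)^2))
  eps <- 0.62
  expect_lt(effective_ec50(fit1, eps), effective_ec50(fit2, eps))
})

test_that("tidy and glance expose the coefficient table and fit summary", {
  fx_tbl <- generate_viability_table(seed = 3)
  fit <- fit_dose_response(fx_tbl)
  td <- tidy(fit)
  expect_setequal(td$term, c("top", "bottom", "ec50", "hill"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, 72)  # 12 treatment groups x 6 replicates
  expect_gt(gl$ec50, 0)
})
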