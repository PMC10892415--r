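# national 2018/2021 printed inputs, reused across blocks
POP_2018 <- 10276617
POP_2021 <- 10344802

test_that("weight_factor matches its closed form and limits", {
  expect_equal(weight_factor(0, 0, 0), 1)
  expect_equal(weight_factor(1, 0, 0), 0.5)
  expect_equal(weight_factor(0.28, 0.19, 0.07), 1 / 1.87)
  expect_error(weight_factor(-0.1, 0, 0), "non-negative")
  expect_error(weight_factor(0.6, 0.3, 0.2), "exceed 1")
})

test_that("the individual steps do the printed arithmetic", {
  p1 <- patients_from_did(75.4, POP_2018)
  expect_equal(p1, 75.4 * POP_2018 / 1000)

  p2 <- adjust_adherence(p1, 0.60)
  expect_equal(p2, p1 / 0.60)
  expect_identical(adjust_adherence(1234.5, 1.0), 1234.5)
  expect_gt(adjust_adherence(p1, 0.5), adjust_adherence(p1, 0.92))

  p3 <- apply_concomitance(p2, 0.608)
  expect_equal(p3, p2 * 0.608)
  expect_identical(apply_concomitance(p2, 1.0), p2)

  ins <- patients_from_did(15.5, POP_2018)
  # printed patient-count totals carry a rounded-DID-input residual below 0.1%
  expect_equal(t2dm_treated(p3, ins, 0.075), 797307, tolerance = 1e-3)
  expect_equal(patients_dm_total(p3, ins), 945090, tolerance = 1e-3)
  expect_identical(t2dm_treated(100, 50, 0), 100)
  expect_identical(t2dm_treated(0, 50, 1), 50)

  prev <- prevalence_treated(t2dm_treated(p3, ins, 0.075), POP_2018)
  expect_equal(round_half_up(prev, 1), 7.8)
  expect_equal(round_half_up(prevalence_overall(prev, 0.44), 1), 13.9)
  expect_identical(prevalence_overall(7.5, 0), 7.5)
  expect_error(prevalence_overall(7.5, 1), "\\[0, 1\\)")
})

test_that("adherence division and concomitance weighting commute", {
  x <- c(0, 1, 1234.5, 7e5)
  expect_equal(
    apply_concomitance(adjust_adherence(x, 0.6), 0.608),
    adjust_adherence(apply_concomitance(x, 0.608), 0.6)
  )
})

test_that("run_model reproduces the national estimates for both years", {
  est <- run_model(national_consumption(3), national_population(),
                   model_params())
  expect_s3_class(est, "prevalence_estimate")
  e18 <- dplyr::filter(est, year == 2018)
  e21 <- dplyr::filter(est, year == 2021)
  expect_equal(e18$prev_treated_report, 7.8)
  expect_equal(e18$prev_overall_report, 13.9)
  expect_equal(e21$prev_treated_report, 9.1)
  expect_equal(e21$prev_overall_report, 14.2)
  # full-precision patient counts against printed (rounded-input residual)
  expect_equal(e18$patients_dm, 945090, tolerance = 2e-3)
  expect_equal(e18$patients_t2dm, 797307, tolerance = 2e-3)
  expect_equal(e21$patients_dm, 1096864, tolerance = 2e-3)
  expect_equal(e21$patients_t2dm, 944187, tolerance = 2e-3)
})

test_that("zero consumption gives an all-zero estimate", {
  cons <- tibble::tibble(region = "TOTAL", year = 2018,
                         atc_class = c("A10A", "A10B"), did = c(0, 0))
  pop <- tibble::tibble(region = "PT", year = 2018, inhabitants = 1000)
  est <- run_model(cons, pop, model_params())
  expect_equal(est$patients_dm, 0)
  expect_equal(est$prev_treated_pct, 0)
  expect_equal(est$prev_overall_pct, 0)
})

test_that("neutral parameters reduce the model to the DID identity", {
  cons <- tibble::tibble(region = "TOTAL", year = 2018,
                         atc_class = c("A10A", "A10B"), did = c(12, 80))
  pop <- tibble::tibble(region = "PT", year = 2018, inhabitants = 54321)
  params <- model_params(adherence_nad = 1, adherence_insulin = 1,
                         w = NULL, pis = c(0, 0, 0),
                         insulin_t2dm_fraction = 0,
                         undiagnosed_fraction = 0)
  est <- run_model(cons, pop, params)
  expect_equal(est$prev_treated_pct, 100 * 80 / 1000)
  expect_equal(est$prev_overall_pct, est$prev_treated_pct)
})

test_that("prevalence responds monotonically to each parameter", {
  cons <- national_consumption(3)
  pop <- national_population()
  treated <- function(params) {
    dplyr::filter(run_model(cons, pop, params), year == 2018)$prev_treated_pct
  }
  overall <- function(params) {
    dplyr::filter(run_model(cons, pop, params), year == 2018)$prev_overall_pct
  }
  adh <- vapply(c(0.5, 0.6, 0.75, 0.92, 1.0),
                function(a) treated(model_params(adherence_nad = a)),
                numeric(1))
  expect_true(all(diff(adh) < 0))
  ws <- vapply(c(0.5, 0.596, 0.608, 0.8, 1.0),
               function(w) treated(model_params(w = w)), numeric(1))
  expect_true(all(diff(ws) > 0))
  fs <- vapply(c(0, 0.06, 0.075, 0.158, 1),
               function(f) treated(model_params(insulin_t2dm_fraction = f)),
               numeric(1))
  expect_true(all(diff(fs) > 0))
  us <- vapply(c(0, 0.098, 0.357, 0.44, 0.5),
               function(u) overall(model_params(undiagnosed_fraction = u)),
               numeric(1))
  expect_true(all(diff(us) > 0))
})

test_that("prevalence is invariant to joint scaling of people and drugs", {
  reg <- mini_registry()
  rec <- tibble::tibble(atc = c("A10BA02", "A10AE04"),
                        n_units = c(5e5, 4e4), strength = c(2000, 40),
                        region = "PT", year = 2018)
  pop <- tibble::tibble(region = "PT", year = 2018, inhabitants = 1e5)
  params <- model_params(undiagnosed_fraction = 0.44)
  base <- run_model(aggregate_consumption(rec, reg, pop, level = 3),
                    pop, params, scopes = "TOTAL")
  k <- 7.3
  scaled <- run_model(
    aggregate_consumption(dplyr::mutate(rec, n_units = n_units * k), reg,
                          dplyr::mutate(pop, inhabitants = inhabitants * k),
                          level = 3),
    dplyr::mutate(pop, inhabitants = inhabitants * k),
    params, scopes = "TOTAL"
  )
  expect_equal(scaled$prev_treated_pct, base$prev_treated_pct)
  expect_equal(scaled$prev_overall_pct, base$prev_overall_pct)
  expect_equal(scaled$patients_dm, k * base$patients_dm)
})

test_that("model_params validates its inputs", {
  expect_error(model_params(adherence_nad = 0), "adherence_nad")
  expect_error(model_params(w = 1.2), "`w`")
  expect_error(model_params(undiagnosed_fraction = 1), "undiagnosed_fraction")
  expect_error(model_params(w = 0.5, pis = c(0.1, 0.1, 0.1)), "exactly one")
  # pis route computes w through the closed form
  p <- model_params(w = NULL, pis = c(0.28, 0.19, 0.07))
  expect_equal(p$w, 1 / 1.87)
})

test_that("run_model demands both drug classes and a known population", {
  pop <- tibble::tibble(region = "PT", year = 2018, inhabitants = 1000)
  only_nad <- tibble::tibble(region = "TOTAL", year = 2018,
                             atc_class = "A10B", did = 10)
  expect_error(run_model(only_nad, pop, model_params()), "Missing insulin")
  both <- tibble::tibble(region = "Elsewhere", year = 2018,
                         atc_class = c("A10A", "A10B"), did = c(1, 2))
  expect_error(run_model(both, pop, model_params()), "Elsewhere/2018")
  cons <- tibble::tibble(region = "TOTAL", year = 1999,
                         atc_class = c("A10A", "A10B"), did = c(1, 2))
  pop99 <- tibble::tibble(region = "PT", year = 1999, inhabitants = 1000)
  expect_error(run_model(cons, pop99, model_params()), "year 1999")
})

test_that("tidy and glance expose the estimate in broom shapes", {
  est <- run_model(national_consumption(3), national_population(),
                   model_params())
  td <- tidy(est)
  expect_true(all(c("scope", "year", "quantity", "estimate") %in% names(td)))
  expect_equal(nrow(td), nrow(est) * 4)
  gl <- glance(est)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$w, 0.608)
  expect_equal(gl$n_years, 2)
})

test_that("autoplot returns a ggplot without evaluation errors", {
  est <- run_model(national_consumption(3), national_population(),
                   model_params())
  p <- ggplot2::autoplot(est)
  expect_s3_class(p, "ggplot")
  built <- ggplot2::ggplot_build(p)
  expect_gt(nrow(built$data[[1]]), 0)
})
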