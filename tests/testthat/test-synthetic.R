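# recovery-test configuration: t1dm prevalence calibrated so the realized
# T2DM share of insulin users equals the model's retained fraction f
recovery_config <- function(n_pop, mode, f = 0.075, prev = 0.10, u = 0.40) {
  n_ins_t2 <- prev * (1 - u) * f         # T2DM insulin users (share of pop)
  t1 <- n_ins_t2 * (1 - f) / f           # then n_ins_t2 / (n_ins_t2+t1) = f
  cohort_config(
    n_pop = n_pop, true_prevalence = prev, undiagnosed_fraction = u,
    insulin_t2dm_fraction = f, t1dm_prevalence = t1, mode = mode
  )
}

single_region_pop <- function(config) {
  tibble::tibble(region = names(config$regions), year = config$year,
                 inhabitants = config$n_pop * unname(config$regions))
}

run_recovery <- function(config, registry, params) {
  persons <- generate_cohort(config, registry)
  records <- simulate_dispensing(persons, registry, config)
  cons <- aggregate_consumption(records, registry, single_region_pop(config),
                                level = 3)
  est <- run_model(cons, single_region_pop(config), params, scopes = "TOTAL")
  truth <- true_summary(persons)
  list(est = est, truth = truth[truth$region == "TOTAL", ])
}

test_that("deterministic apportionment hits the stated counts exactly", {
  cfg <- cohort_config(n_pop = 100000, true_prevalence = 0.10,
                       undiagnosed_fraction = 0.40,
                       insulin_t2dm_fraction = 0.075,
                       t1dm_prevalence = 0.005, mode = "deterministic")
  persons <- generate_cohort(cfg, load_registry())
  counts <- table(persons$status)
  expect_equal(unname(counts[["t2dm_nad"]]), 6000)
  expect_equal(unname(counts[["t2dm_insulin"]]), 450)
  expect_equal(unname(counts[["t2dm_undiagnosed"]]), 3550)
  expect_equal(unname(counts[["t1dm"]]), 500)
  truth <- true_summary(persons)
  tot <- truth[truth$region == "TOTAL", ]
  expect_equal(tot$n_t2dm, 10000)
  expect_equal(tot$prev_treated_pct, 6.45)
  expect_equal(tot$prev_overall_pct, 10.0)
})

test_that("zero prevalence produces no diabetic persons and no records", {
  cfg <- cohort_config(n_pop = 1000, true_prevalence = 0,
                       t1dm_prevalence = 0, mode = "deterministic")
  persons <- generate_cohort(cfg, load_registry())
  expect_true(all(persons$status == "healthy"))
  recs <- simulate_dispensing(persons, load_registry(), cfg)
  expect_equal(nrow(recs), 0)
  truth <- true_summary(persons)
  expect_equal(truth$prev_treated_pct, c(0, 0))
})

test_that("the stochastic generator is reproducible under a fixed seed", {
  cfg <- cohort_config(n_pop = 5000, mode = "stochastic")
  reg <- load_registry()
  set.seed(123); a <- generate_cohort(cfg, reg)
  set.seed(123); b <- generate_cohort(cfg, reg)
  expect_identical(a, b)
  set.seed(123); ra <- simulate_dispensing(a, reg, cfg)
  set.seed(123); rb <- simulate_dispensing(b, reg, cfg)
  expect_identical(ra, rb)
})

test_that("per-person consumption follows the generative rule", {
  reg <- load_registry()
  # one monotherapy person at full adherence: exactly one patient-year
  p1 <- tibble::tibble(id = 1L, status = "t2dm_nad", region = "PT",
                       n_drugs = 1L, regimen = list("A10BA02"))
  cfg1 <- cohort_config(n_pop = 1, true_prevalence = 0.5, adherence_nad = 1,
                        mode = "deterministic")
  recs <- simulate_dispensing(p1, reg, cfg1)
  cons <- record_total_ddd(recs, reg)
  expect_equal(sum(cons$total_ddd), 365)

  # triple therapy at 60% adherence: 3 x 0.6 x 365 DDDs
  p3 <- tibble::tibble(id = 1L, status = "t2dm_nad", region = "PT",
                       n_drugs = 3L,
                       regimen = list(c("A10BA02", "A10BB09", "A10BK01")))
  cfg6 <- cohort_config(n_pop = 1, true_prevalence = 0.5, adherence_nad = 0.6,
                        mode = "deterministic")
  recs3 <- simulate_dispensing(p3, reg, cfg6)
  expect_equal(sum(record_total_ddd(recs3, reg)$total_ddd), 3 * 0.6 * 365)

  # a type 1 person only ever generates insulin-class records
  pt1 <- tibble::tibble(id = 1L, status = "t1dm", region = "PT",
                        n_drugs = 1L, regimen = list("A10AE04"))
  rt1 <- simulate_dispensing(pt1, reg, cfg1)
  expect_true(all(classify_ad(rt1$atc) == "insulin"))
})

test_that("insulin statuses never carry NAD codes in generated cohorts", {
  cfg <- cohort_config(n_pop = 20000, mode = "stochastic")
  set.seed(7)
  persons <- generate_cohort(cfg, load_registry())
  ins <- dplyr::filter(persons, status %in% c("t2dm_insulin", "t1dm"))
  codes <- unlist(ins$regimen)
  expect_true(all(classify_ad(codes) == "insulin"))
  expect_true(all(ins$n_drugs == 1))
  nad <- dplyr::filter(persons, status == "t2dm_nad")
  expect_true(all(classify_ad(unlist(nad$regimen)) == "nad"))
  # a regimen never holds two drugs of the same level-4 class
  dup <- vapply(nad$regimen,
                function(r) anyDuplicated(atc_level(r, 4)) > 0, logical(1))
  expect_false(any(dup))
})

test_that("regional counts are conserved in the truth summary", {
  cfg <- cohort_config(n_pop = 10000, mode = "deterministic",
                       regions = c(North = 0.3, South = 0.7))
  persons <- generate_cohort(cfg, load_registry())
  truth <- true_summary(persons)
  tot <- truth[truth$region == "TOTAL", ]
  reg <- truth[truth$region != "TOTAL", ]
  for (col in c("n_pop", "n_t2dm", "n_treated", "n_t1dm")) {
    expect_equal(sum(reg[[col]]), tot[[col]])
  }
})

test_that("deterministic-mode parameter recovery is exact", {
  reg <- load_registry()
  cfg <- recovery_config(100000, "deterministic")
  persons <- generate_cohort(cfg, reg)
  truth <- true_summary(persons)
  out <- run_recovery(cfg, reg, effective_params(truth, cfg))
  expect_equal(out$est$prev_treated_pct, out$truth$prev_treated_pct,
               tolerance = 1e-12)
  expect_equal(out$est$prev_overall_pct, out$truth$prev_overall_pct,
               tolerance = 1e-12)
})

test_that("misspecified adherence biases prevalence in the known direction", {
  reg <- load_registry()
  cfg <- recovery_config(50000, "deterministic")
  truth <- true_summary(generate_cohort(cfg, reg))
  base <- effective_params(truth, cfg)
  over <- model_params(adherence_nad = 0.9, w = base$w,
                       insulin_t2dm_fraction = base$insulin_t2dm_fraction,
                       undiagnosed_fraction = base$undiagnosed_fraction)
  under <- model_params(adherence_nad = 0.4, w = base$w,
                        insulin_t2dm_fraction = base$insulin_t2dm_fraction,
                        undiagnosed_fraction = base$undiagnosed_fraction)
  est_over <- run_recovery(cfg, reg, over)$est$prev_treated_pct
  est_under <- run_recovery(cfg, reg, under)$est$prev_treated_pct
  true_prev <- truth$prev_treated_pct[truth$region == "TOTAL"]
  expect_lt(est_over, true_prev)   # assuming better adherence than real
  expect_gt(est_under, true_prev)  # assuming worse adherence than real
})

test_that("pack quantization only ever rounds units up", {
  reg <- load_registry()
  cfg <- recovery_config(2000, "deterministic")
  persons <- generate_cohort(cfg, reg)
  plain <- simulate_dispensing(persons, reg, cfg)
  cfg_pack <- cfg
  cfg_pack$pack_size <- 56L
  packed <- simulate_dispensing(persons, reg, cfg_pack)
  j <- dplyr::left_join(plain, packed, by = c("atc", "region", "strength",
                                              "year"))
  expect_true(all(j$n_units.y >= j$n_units.x))
  expect_true(all(j$n_units.y %% 56 == 0))
})
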