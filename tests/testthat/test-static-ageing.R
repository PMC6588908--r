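# A small weighted file spanning two age bands and both employment
# states, used by several calibration tests.
cal_fixture <- function() {
  dplyr::bind_rows(
    person_row("P1", age = 46L, sex = "male", weight = 100,
               labour_force_status = "employed_ft"),
    person_row("P2", age = 47L, sex = "male", weight = 120,
               labour_force_status = "employed_pt",
               hours_per_week = 20),
    person_row("P3", age = 48L, sex = "male", weight = 80,
               labour_force_status = "nilf",
               nilf_reason = "other", hours_per_week = 0),
    person_row("P4", age = 52L, sex = "male", weight = 150,
               labour_force_status = "employed_ft"))
}

test_that("benchmark sets validate their inputs", {
  pops <- tibble::tibble(age_group = c("45-49", "50-54"),
                         sex = "male", target = c(300, 150))
  b <- benchmark_set(2015, pops)
  expect_equal(nrow(b), 2)
  expect_error(benchmark_set(2015, dplyr::mutate(pops, target = -1)),
               "positive")
  bad_rates <- tibble::tibble(age_group = "45-49", sex = "male",
                              rate = 1.2)
  expect_error(benchmark_set(2015, pops, ft_rates = bad_rates),
               "\\[0, 1\\]")
  ft <- tibble::tibble(age_group = c("45-49", "50-54"), sex = "male",
                       rate = 0.7)
  pt <- tibble::tibble(age_group = c("45-49", "50-54"), sex = "male",
                       rate = 0.5)
  expect_error(benchmark_set(2015, pops, ft, pt), "exceed")
})

test_that("weights already on target are a calibration fixed point", {
  recs <- cal_fixture()
  b <- benchmark_set(2015, tibble::tibble(
    age_group = c("45-49", "50-54"), sex = "male",
    target = c(300, 150)))
  res <- gregwt_calibrate(recs, b)
  expect_true(res$converged)
  expect_equal(res$iterations, 0L)
  expect_equal(res$weights, recs$weight)
})

test_that("a single grand-total margin rescales all weights by T/S", {
  recs <- cal_fixture()[1:3, ]  # one age band
  b <- benchmark_set(2015, tibble::tibble(age_group = "45-49",
                                          sex = "male", target = 600))
  res <- gregwt_calibrate(recs, b)
  expect_true(res$converged)
  expect_equal(res$iterations, 1L)
  expect_equal(res$weights, recs$weight * 600 / 300, tolerance = 1e-12)
})

test_that("calibration reproduces the closed-form linear solution", {
  recs <- cal_fixture()[1:3, ]
  # two overlapping margins: the 45-49 male population (all three) and
  # its full-time count (record 1)
  b <- dplyr::bind_rows(
    tibble::tibble(variable = "population", age_group = "45-49",
                   sex = "male", target = 330),
    tibble::tibble(variable = "employed_ft", age_group = "45-49",
                   sex = "male", target = 90))
  res <- gregwt_calibrate(recs, b)
  expect_true(res$converged)

  # hand solution of the chi-square calibration: w = d (1 + X lambda),
  # lambda from (X' D X) lambda = T - X' d, solved as an explicit 2x2
  # system
  d <- recs$weight
  X <- cbind(rep(1, 3), c(1, 0, 0))
  A <- t(X) %*% (d * X)
  rhs <- c(330, 90) - as.vector(t(X) %*% d)
  det_a <- A[1, 1] * A[2, 2] - A[1, 2] * A[2, 1]
  lambda <- c(A[2, 2] * rhs[1] - A[1, 2] * rhs[2],
              -A[2, 1] * rhs[1] + A[1, 1] * rhs[2]) / det_a
  w_hand <- d * (1 + as.vector(X %*% lambda))
  expect_equal(res$weights, w_hand, tolerance = 1e-8)
  # and the hand solution itself hits the margins
  expect_equal(sum(w_hand), 330, tolerance = 1e-9)
  expect_equal(w_hand[1], 90, tolerance = 1e-9)
})

test_that("infeasible and non-convergent calibrations are reported", {
  recs <- cal_fixture()
  b_empty <- benchmark_set(2015, tibble::tibble(
    age_group = "60-64", sex = "female", target = 100))
  expect_error(gregwt_calibrate(recs, b_empty),
               "population\\[60-64,female\\]")

  b_far <- benchmark_set(2015, tibble::tibble(
    age_group = c("45-49", "50-54"), sex = "male",
    target = c(30000, 15000)))
  res <- gregwt_calibrate(recs, b_far, bounds = c(0.5, 2))
  expect_false(res$converged)
  expect_gt(res$max_rel_error, 1e-6)
  expect_equal(res$bound_hits, 4)
  expect_true(all(res$weights <= 2 * recs$weight + 1e-9))
})

test_that("disease trends rescale prevalence and conserve strata", {
  cfg <- population_config(n_records = 3000)
  base <- generate_base_population(cfg, 61)
  base$weekly_income <- 100; base$weekly_welfare <- 0
  base$weekly_tax <- 0

  unit <- dplyr::mutate(default_disease_trends(),
                        annual_multiplier = 1)
  same <- apply_disease_trend(base, unit, target_year = 2020)
  expect_equal(same$weight, base$weight)

  tr <- dplyr::mutate(default_disease_trends(),
                      annual_multiplier = ifelse(disease == "ihd",
                                                 0.99, 1))
  out <- apply_disease_trend(base, tr, base_year = 2009,
                             target_year = 2015)
  # brute-force weighted-prevalence oracle per stratum
  ihd <- is_ihd(base$main_condition)
  for (s in c("male", "female")) {
    for (a in unique(base$age_group)) {
      sel <- base$sex == s & base$age_group == a
      if (!any(sel & ihd)) next
      prev0 <- sum(base$weight[sel & ihd]) / sum(base$weight[sel])
      prev1 <- sum(out$weight[sel & ihd]) / sum(out$weight[sel])
      expect_equal(prev1 / prev0, 0.99^6, tolerance = 1e-9)
      # stratum totals conserved
      expect_equal(sum(out$weight[sel]), sum(base$weight[sel]),
                   tolerance = 1e-9)
    }
  }

  # prevalence stabilises after the trend window closes
  t2023 <- apply_disease_trend(base, tr, target_year = 2023)
  t2030 <- apply_disease_trend(base, tr, target_year = 2030)
  expect_equal(t2030$weight, t2023$weight)

  # a trend implying prevalence above one is an error
  all_diab <- dplyr::mutate(base,
                            main_condition = "type2_diabetes")
  explode <- dplyr::mutate(default_disease_trends(),
                           annual_multiplier = 1.5)
  expect_error(apply_disease_trend(all_diab, explode,
                                   target_year = 2015), "> 1")
})

test_that("uprating applies the component growth rules exactly", {
  rec <- person_row()
  rec$weekly_income <- 100
  rec$weekly_welfare <- 321.87
  rec$weekly_tax <- 50
  up <- uprate_economics(rec, 2015)
  expect_equal(up$weekly_income, 102.01)
  expect_equal(up$weekly_tax, 50 * 1.01^2)
  expect_equal(up$weekly_welfare, 321.87)  # zero real growth
  expect_equal(uprate_economics(rec, 2013), rec)  # base-year identity
  bad_rules <- tibble::tibble(component = "wealth",
                              annual_real_growth = 0.01,
                              base_year = 2013)
  expect_error(uprate_economics(rec, 2015, bad_rules), "unknown")
  expect_error(uprate_economics(rec, 2012), "precedes")
})

test_that("uprating and calibration commute", {
  cfg <- population_config(n_records = 1000)
  base <- generate_base_population(cfg, 71)
  donors <- generate_donor_pool(cfg, 72, n = 2000)
  imp <- match_economic_data(base, donors, 73)
  b <- default_benchmarks(2020)
  a <- uprate_economics(imp, 2020)
  a$weight <- gregwt_calibrate(a, b)$weights
  z <- imp
  z$weight <- gregwt_calibrate(z, b)$weights
  z <- uprate_economics(z, 2020)
  expect_equal(a, z, tolerance = 1e-12)
})

test_that("projection composes to identity under neutral inputs", {
  cfg <- population_config(n_records = 500)
  base <- generate_base_population(cfg, 81)
  donors <- generate_donor_pool(cfg, 82, n = 1000)
  imp <- match_economic_data(base, donors, 83)
  # benchmarks equal to the achieved base margins
  tot <- imp |>
    dplyr::group_by(age_group, sex) |>
    dplyr::summarise(target = sum(weight), .groups = "drop")
  b <- benchmark_set(2013, tot)
  unit <- dplyr::mutate(default_disease_trends(),
                        annual_multiplier = 1)
  out <- project_to_year(imp, 2013, benchmarks = b, trends = unit)
  expect_equal(out$weight, imp$weight, tolerance = 1e-9)
  expect_equal(out$weekly_income, imp$weekly_income)
  expect_equal(attr(out, "year"), 2013)
})

test_that("default projection hits the year's population benchmark", {
  cfg <- population_config(n_records = 2000)
  base <- generate_base_population(cfg, 91)
  donors <- generate_donor_pool(cfg, 92, n = 4000)
  imp <- match_economic_data(base, donors, 93)
  out <- project_to_year(imp, 2030)
  cal <- attr(out, "calibration")
  expect_true(cal$converged)
  expect_lt(cal$max_rel_error, 1e-6)
  # uprating applies after calibration, so weights alone carry the total
  expect_equal(sum(out$weight), 7130200, tolerance = 1e-6)
  # determinism of the full stage
  out2 <- project_to_year(imp, 2030)
  expect_identical(out$weight, out2$weight)
  expect_identical(out$weekly_income, out2$weekly_income)
})
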