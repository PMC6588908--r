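cf_case <- function(id = "C1", sex = "male", age_group = "45-49",
                    education = "degree", weight = 100, income = 400,
                    welfare = 300, tax = 0) {
  tibble::tibble(person_id = id, sex = sex, age_group = age_group,
                 education = education, weight = weight,
                 weekly_income = income, weekly_welfare = welfare,
                 weekly_tax = tax)
}

cf_donor <- function(id = "D1", sex = "male", age_group = "45-49",
                     education = "degree", weight = 100, income = 1350,
                     welfare = 0, tax = 250) {
  tibble::tibble(person_id = id, sex = sex, age_group = age_group,
                 education = education, weight = weight,
                 weekly_income = income, weekly_welfare = welfare,
                 weekly_tax = tax)
}

test_that("spec validation enforces its preconditions", {
  expect_error(counterfactual_spec(n_sims = 0), "n_sims")
  expect_error(counterfactual_spec(ci_level = 1), "ci_level")
  expect_error(counterfactual_spec(match_vars = c("education", "sex")))
  s <- counterfactual_spec("ft_no_ihd", n_sims = 10)
  expect_s3_class(s, "counterfactual_spec")
})

test_that("a single-donor cell is always assigned that donor", {
  cases <- cf_case()
  donors <- dplyr::bind_rows(
    cf_donor("D1"),
    cf_donor("D2", sex = "female", income = 99))
  for (s in 1:25) {
    a <- draw_counterfactual_set(cases, donors, seed = s)
    expect_equal(a$donor_row, 1L)
    expect_equal(a$fallback_depth, 0L)
  }
})

test_that("weight-proportional sampling follows a 3:1 cell", {
  cases <- cf_case()
  donors <- dplyr::bind_rows(cf_donor("D1", weight = 300, income = 1000),
                             cf_donor("D2", weight = 100, income = 2000))
  spec <- counterfactual_spec("ft_no_ihd", n_sims = 10000,
                              master_seed = 7)
  draws <- run_simulations(spec, cases, donors)
  # the replicate difference identifies the donor: -600 vs -1600
  p1 <- mean(draws$income == 400 - 1000)
  se <- sqrt(0.75 * 0.25 / 10000)
  expect_lt(abs(p1 - 0.75), 3 * se)

  unif <- counterfactual_spec("ft_no_ihd", n_sims = 10000,
                              master_seed = 7,
                              weight_proportional = FALSE)
  p_unif <- mean(run_simulations(unif, cases, donors)$income == -600)
  expect_lt(abs(p_unif - 0.5), 3 * sqrt(0.25 / 10000))
})

test_that("assignments never cross matched cells", {
  grid <- tidyr::expand_grid(sex = c("male", "female"),
                             age_group = c("45-49", "50-54", "55-59"))
  cases <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    cf_case(paste0("C", i), sex = grid$sex[i],
            age_group = grid$age_group[i], income = i)
  }))
  donors <- dplyr::bind_rows(lapply(seq_len(nrow(grid)), function(i) {
    cf_donor(paste0("D", i), sex = grid$sex[i],
             age_group = grid$age_group[i], income = 100 * i)
  }))
  for (s in 1:50) {
    a <- draw_counterfactual_set(cases, donors, seed = s)
    expect_equal(donors$sex[a$donor_row], cases$sex)
    expect_equal(donors$age_group[a$donor_row], cases$age_group)
  }
  # an empty (sex, age_group) cell is an error that names the cell
  expect_error(
    draw_counterfactual_set(cf_case(age_group = "60-64"), donors),
    "60-64")
})

test_that("replicate differences are the weighted mean of case gaps", {
  cases <- cf_case(weight = 2, income = 400)
  donors <- cf_donor(income = 1350)
  a <- draw_counterfactual_set(cases, donors, seed = 1)
  expect_equal(replicate_difference(a, cases, donors, "income"), -950)

  cases3 <- dplyr::bind_rows(
    cf_case("C1", weight = 1, income = 300, welfare = 310, tax = 0),
    cf_case("C2", weight = 2, income = 500, welfare = 250, tax = 5),
    cf_case("C3", weight = 3, income = 400, welfare = 330, tax = 0))
  donors3 <- dplyr::bind_rows(
    cf_donor("D1", education = "year12", income = 1000, welfare = 10,
             tax = 200))
  cases3$education <- "year12"
  a3 <- draw_counterfactual_set(cases3, donors3, seed = 2)
  # hand-computed: sum(w * (x_case - x_donor)) / sum(w)
  expect_equal(replicate_difference(a3, cases3, donors3, "income"),
               (1 * (300 - 1000) + 2 * (500 - 1000) +
                  3 * (400 - 1000)) / 6)
  expect_equal(replicate_difference(a3, cases3, donors3, "welfare"),
               (1 * 300 + 2 * 240 + 3 * 320) / 6)
  # identical outcomes give a null difference
  same <- dplyr::mutate(donors3, weekly_income = 400)
  cases_same <- dplyr::mutate(cases3, weekly_income = 400)
  a0 <- draw_counterfactual_set(cases_same, same, seed = 3)
  expect_equal(replicate_difference(a0, cases_same, same, "income"), 0)
})

test_that("simulations are deterministic and degenerate pools collapse", {
  cases <- dplyr::bind_rows(cf_case("C1"),
                            cf_case("C2", sex = "female", income = 350))
  donors <- dplyr::bind_rows(
    cf_donor("D1", income = 1300),
    cf_donor("D2", sex = "female", income = 1100))
  spec <- counterfactual_spec("ft_no_ihd", n_sims = 40, master_seed = 3)
  d1 <- run_simulations(spec, cases, donors)
  d2 <- run_simulations(spec, cases, donors)
  expect_identical(d1, d2)
  # one donor per cell: zero Monte-Carlo variance
  expect_equal(length(unique(d1$income)), 1)
  one <- counterfactual_spec("ft_no_ihd", n_sims = 1, master_seed = 3)
  expect_equal(nrow(run_simulations(one, cases, donors)), 1)
})

test_that("percentile intervals follow the nearest-rank rule", {
  expect_equal(percentile_ci(as.numeric(1:1000), 0.95),
               c(lower = 25, upper = 975))
  expect_equal(percentile_ci(rep(3.5, 10), 0.95),
               c(lower = 3.5, upper = 3.5))
  expect_error(percentile_ci(1:10, 1.0), "between 0 and 1")
  expect_error(percentile_ci(1:10, 0), "between 0 and 1")
  expect_error(percentile_ci(5, 0.95), "at least 2")
  # order statistics are invariant to draw order
  shuffled <- withr::with_seed(1, sample(as.numeric(1:1000)))
  expect_equal(percentile_ci(shuffled, 0.95),
               c(lower = 25, upper = 975))
})

test_that("wider donor dispersion never shrinks the interval", {
  des <- design_recovery()
  widths <- vapply(c(0.05, des$ft_sdlog, 0.6), function(sdl) {
    p <- make_cf_population(77, n_cases = 150, n_donors = 2000,
                            des = within_list(des, ft_sdlog = sdl))
    spec <- counterfactual_spec("ft_no_ihd", n_sims = 400,
                                master_seed = 9)
    dr <- run_simulations(spec, p$cases, p$donors)
    ci <- percentile_ci(dr$income, 0.95)
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
})

test_that("the projected-population wrapper compares the right groups", {
  cfg <- population_config(n_records = 3000)
  base <- generate_base_population(cfg, 121)
  donors <- generate_donor_pool(cfg, 122, n = 5000)
  imp <- match_economic_data(base, donors, 123)
  spec <- counterfactual_spec("labour_force_no_ihd", n_sims = 50,
                              master_seed = 5)
  est <- run_counterfactual(imp, spec)
  expect_equal(est$outcome, c("income", "welfare", "tax"))
  expect_true(all(est$lower <= est$estimate & est$estimate <= est$upper))
  # lost-PLY cases earn less and receive more welfare than the pool
  expect_lt(est$estimate[est$outcome == "income"], 0)
  expect_gt(est$estimate[est$outcome == "welfare"], 0)
})
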