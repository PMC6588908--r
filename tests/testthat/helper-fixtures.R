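# Shared fixture builders.  Everything is generated in code at test time;
# nothing is read from disk.

person_row <- function(person_id = "P1", age = 47L, sex = "male",
                       income_unit_type = "couple_no_children",
                       education = "degree",
                       labour_force_status = "employed_ft",
                       nilf_reason = "not_applicable",
                       main_condition = "none", hours_per_week = 40,
                       home_owner = TRUE, receives_age_pension = FALSE,
                       receives_dsp = FALSE, income_quintile = 4L,
                       weight = 100) {
  tibble::tibble(
    person_id = person_id, age = age,
    age_group = c("45-49", "50-54", "55-59",
                  "60-64")[findInterval(age, c(45, 50, 55, 60))],
    sex = sex, income_unit_type = income_unit_type,
    education = education, labour_force_status = labour_force_status,
    nilf_reason = nilf_reason, main_condition = main_condition,
    hours_per_week = hours_per_week, home_owner = home_owner,
    receives_age_pension = receives_age_pension,
    receives_dsp = receives_dsp, income_quintile = income_quintile,
    weight = weight)
}

donor_row <- function(donor_id = "D1", sex = "male",
                      age_group = "45-49",
                      income_unit_type = "couple_no_children",
                      income_quintile = 4L,
                      receives_age_pension = FALSE,
                      receives_dsp = FALSE,
                      labour_force_status = "employed_ft",
                      hours_band = "35+", education = "degree",
                      home_owner = TRUE, weekly_income = 1000,
                      weekly_welfare = 0, weekly_tax = 200) {
  tibble::tibble(
    donor_id = donor_id, sex = sex, age_group = age_group,
    income_unit_type = income_unit_type,
    income_quintile = income_quintile,
    receives_age_pension = receives_age_pension,
    receives_dsp = receives_dsp,
    labour_force_status = labour_force_status,
    hours_band = hours_band, education = education,
    home_owner = home_owner, weekly_income = weekly_income,
    weekly_welfare = weekly_welfare, weekly_tax = weekly_tax)
}

# Donor matching a person on all ten variables.
matching_donor <- function(person, donor_id = "D1", weekly_income = 1000,
                           weekly_welfare = 0, weekly_tax = 200) {
  donor_row(donor_id = donor_id, sex = person$sex,
            age_group = person$age_group,
            income_unit_type = person$income_unit_type,
            income_quintile = person$income_quintile,
            receives_age_pension = person$receives_age_pension,
            receives_dsp = person$receives_dsp,
            labour_force_status = person$labour_force_status,
            hours_band = hours_band(person$hours_per_week),
            education = person$education,
            home_owner = person$home_owner,
            weekly_income = weekly_income,
            weekly_welfare = weekly_welfare, weekly_tax = weekly_tax)
}

# Brute-force fallback trace: for one base record, the minimal depth at
# which any donor matches and the admissible donor ids at that depth.
# Reimplements the drop-from-the-end rule independently of the package.
brute_force_admissible <- function(person, donors) {
  vars_full <- c("sex", "age_group", "labour_force_status",
                 "receives_dsp", "receives_age_pension", "education",
                 "income_quintile", "hours_band", "income_unit_type",
                 "home_owner")
  p <- person
  p$hours_band <- hours_band(p$hours_per_week)
  for (depth in 0:8) {
    vars <- vars_full[seq_len(10 - depth)]
    ok <- rep(TRUE, nrow(donors))
    for (v in vars) ok <- ok & (donors[[v]] == p[[v]][1])
    if (any(ok)) {
      return(list(depth = depth, donor_ids = donors$donor_id[ok]))
    }
  }
  list(depth = NA_integer_, donor_ids = character())
}

# Weighted-median oracle: enumerate candidate values, pick the smallest
# whose cumulative weight reaches half the total.
weighted_median_oracle <- function(x, w) {
  tot <- sum(w)
  for (v in sort(unique(x))) {
    if (sum(w[x <= v]) >= tot / 2) return(v)
  }
  stop("unreachable")
}

# Replace named elements of a list (used to vary one design knob).
within_list <- function(x, ...) {
  mods <- list(...)
  x[names(mods)] <- mods
  x
}

# Log-normal design for the counterfactual parameter-recovery harness:
# cases at the lost-PLY median with sdlog 0.5; the full-time law is
# placed so the mean gap is exactly `gap` AU$/week with equal absolute
# income SDs on both sides (so replicate spread matches synthesis
# noise).
design_recovery <- function(case_median = 415.83, case_sdlog = 0.5,
                            gap = 950) {
  case_mean <- case_median * exp(case_sdlog^2 / 2)
  ft_mean <- case_mean + gap
  case_sd <- case_mean * sqrt(exp(case_sdlog^2) - 1)
  ft_sdlog <- sqrt(log(1 + (case_sd / ft_mean)^2))
  list(case_median = case_median, case_sdlog = case_sdlog,
       ft_median = ft_mean / exp(ft_sdlog^2 / 2), ft_sdlog = ft_sdlog,
       gap = gap)
}

# Direct case/donor synthesis for the coverage study: categorical match
# variables uniform over their domains, survey-like weights, incomes
# from the designed laws.
make_cf_population <- function(seed, n_cases = 500, n_donors = 9000,
                               des = design_recovery()) {
  withr::with_seed(seed, {
    mk <- function(n, median, sdlog, prefix) {
      tibble::tibble(
        person_id = paste0(prefix, seq_len(n)),
        sex = sample(c("male", "female"), n, TRUE),
        age_group = sample(c("45-49", "50-54", "55-59", "60-64"), n,
                           TRUE),
        education = sample(c("below_year12", "year12", "diploma",
                             "degree"), n, TRUE),
        weight = runif(n, 50, 150),
        weekly_income = rlnorm(n, log(median), sdlog),
        weekly_welfare = 0, weekly_tax = 0)
    }
    list(cases = mk(n_cases, des$case_median, des$case_sdlog, "C"),
         donors = mk(n_donors, des$ft_median, des$ft_sdlog, "D"))
  })
}

# Generator configuration for the full-chain parameter recovery run:
# only lost-PLY cases and full-time-without-IHD records, with the
# designed income laws.
recovery_config <- function(n_records, des = design_recovery()) {
  population_config(
    n_records = n_records,
    group_shares = c(ft_no_ihd = 0.91, ft_ihd = 0, pt_no_ihd = 0.04,
                     pt_ihd = 0, nilf_ihd = 0.05, other = 0),
    income_median = c(ft_no_ihd = des$ft_median, ft_ihd = 1186.08,
                      pt_no_ihd = 600.78, pt_ihd = 567.83,
                      nilf_ihd = des$case_median, other = 430),
    income_sdlog = c(ft_no_ihd = des$ft_sdlog, ft_ihd = 0.68,
                     pt_no_ihd = 0.569, pt_ihd = 0.35,
                     nilf_ihd = des$case_sdlog, other = 0.45))
}
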