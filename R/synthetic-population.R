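#' Configuration for the synthetic population and donor pool
#'
#' Builds the parameter set from which both the survey-like base
#' population and the economic donor pool are generated.  Defaults encode
#' the study conditions of the base year: the six analysis-group shares
#' and the group medians of weekly income, welfare and tax (2013 dollars).
#' Incomes are log-normal per group, parameterised so the group median
#' equals its target (right skew is typical of income microdata, and the
#' median is the anchoring statistic reported for every group).  Welfare
#' for people out of the labour force due to IHD is a Disability Support
#' Pension-like base: a fixed fraction (default 77.4%) of the person's
#' income with multiplicative noise.  Tax is a piecewise-linear function
#' of income, `rate * max(0, income - threshold)`, with the per-group
#' threshold placed so the group's median tax hits its target.
#'
#' @param n_records Number of person records to generate.
#' @param target_population Weighted population the base file
#'   represents; survey weights are drawn uniformly on
#'   (0.5, 1.5) x `target_population / n_records`, a moderate-variance
#'   positive law whose total approximates the base-year population.
#' @param group_shares Named numeric vector of shares over
#'   `ft_no_ihd, ft_ihd, pt_no_ihd, pt_ihd, nilf_ihd, other`; must sum
#'   to 1 (within 1e-9).
#' @param income_median,income_sdlog Named per-group location (median,
#'   AU$/week) and log-scale of the income law.
#' @param welfare_prob,welfare_median Probability of receiving any
#'   welfare and the median amount when received, per group (ignored for
#'   `nilf_ihd`, which uses the DSP-like rule).
#' @param dsp_welfare_frac,dsp_welfare_sdlog DSP-like rule for the
#'   `nilf_ihd` group: welfare = `dsp_welfare_frac` x income with
#'   log-normal noise of scale `dsp_welfare_sdlog`, capped at income.
#' @param tax_rate,tax_threshold Named per-group marginal rate and
#'   weekly tax-free threshold.
#' @return A list of class `ply_config`.
#' @export
#' @examples
#' cfg <- population_config(n_records = 1000)
#' sum(cfg$group_shares)
population_config <- function(
    n_records = 20000,
    target_population = 5945000,
    group_shares = c(ft_no_ihd = 0.5308, ft_ihd = 0.0106,
                     pt_no_ihd = 0.2009, pt_ihd = 0.0040,
                     nilf_ihd = 0.0011, other = 0.2526),
    income_median = c(ft_no_ihd = 1305.46, ft_ihd = 1186.08,
                      pt_no_ihd = 600.78, pt_ihd = 567.83,
                      nilf_ihd = 415.83, other = 430),
    income_sdlog = c(ft_no_ihd = 0.615, ft_ihd = 0.68,
                     pt_no_ihd = 0.569, pt_ihd = 0.35,
                     nilf_ihd = 0.20, other = 0.45),
    welfare_prob = c(ft_no_ihd = 0.10, ft_ihd = 0.08,
                     pt_no_ihd = 0.35, pt_ihd = 0.50,
                     nilf_ihd = 1.00, other = 0.70),
    welfare_median = c(ft_no_ihd = 120, ft_ihd = 100,
                       pt_no_ihd = 180, pt_ihd = 200,
                       nilf_ihd = 321.87, other = 320),
    dsp_welfare_frac = 0.774,
    dsp_welfare_sdlog = 0.05,
    tax_rate = c(ft_no_ihd = 0.25, ft_ihd = 0.25,
                 pt_no_ihd = 0.15, pt_ihd = 0.15,
                 nilf_ihd = 0.19, other = 0.19),
    tax_threshold = c(ft_no_ihd = 358.66, ft_ihd = 387.48,
                      pt_no_ihd = 500.78, pt_ihd = 567.83,
                      nilf_ihd = 1000, other = 450)) {
  cfg <- list(
    n_records = as.integer(n_records),
    target_population = target_population,
    group_shares = group_shares[ply_groups],
    income_median = income_median[ply_groups],
    income_sdlog = income_sdlog[ply_groups],
    welfare_prob = welfare_prob[ply_groups],
    welfare_median = welfare_median[ply_groups],
    dsp_welfare_frac = dsp_welfare_frac,
    dsp_welfare_sdlog = dsp_welfare_sdlog,
    tax_rate = tax_rate[ply_groups],
    tax_threshold = tax_threshold[ply_groups]
  )
  class(cfg) <- "ply_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "ply_config"))
  if (cfg$n_records < 0) stop("n_records must be >= 0", call. = FALSE)
  if (cfg$target_population <= 0) {
    stop("target_population must be positive", call. = FALSE)
  }
  for (fld in c("group_shares", "income_median", "income_sdlog",
                "welfare_prob", "welfare_median", "tax_rate",
                "tax_threshold")) {
    v <- cfg[[fld]]
    if (length(v) != length(ply_groups) || anyNA(v)) {
      stop("configuration field '", fld,
           "' must supply one finite value per analysis group",
           call. = FALSE)
    }
  }
  if (abs(sum(cfg$group_shares) - 1) > 1e-9) {
    stop("group_shares must sum to 1 (got ",
         format(sum(cfg$group_shares), digits = 15), ")", call. = FALSE)
  }
  if (any(cfg$group_shares < 0)) {
    stop("group_shares must be non-negative", call. = FALSE)
  }
  if (any(cfg$income_median <= 0) || any(cfg$income_sdlog <= 0)) {
    stop("income scale/location parameters must be positive",
         call. = FALSE)
  }
  if (cfg$dsp_welfare_frac <= 0 || cfg$dsp_welfare_frac >= 1) {
    stop("dsp_welfare_frac must lie in (0, 1)", call. = FALSE)
  }
  invisible(cfg)
}

## Shared categorical machinery: draws analysis group and all demographic
## and matching attributes for n people.  Both the base population and the
## donor pool are drawn from this joint law, which guarantees that donor
## cells cover base cells with probability approaching one as the pool
## grows.
generate_people <- function(cfg, n) {
  group <- sample(ply_groups, n, replace = TRUE, prob = cfg$group_shares)
  age <- sample(45:64, n, replace = TRUE)
  sex <- sample(sexes, n, replace = TRUE, prob = c(0.494, 0.506))

  ## Residual-group composition: unemployed, NILF for other reasons, and
  ## NILF due to ill-health with a non-IHD main condition (the three
  ## residual situations, in realistic relative sizes).
  sub <- rep(NA_character_, n)
  oth <- group == "other"
  sub[oth] <- sample(c("unemp_ft", "unemp_pt", "nilf_other", "nilf_ill"),
                     sum(oth), replace = TRUE,
                     prob = c(0.10, 0.05, 0.6587, 0.1913))

  lfs <- rep(NA_character_, n)
  lfs[group %in% c("ft_no_ihd", "ft_ihd")] <- "employed_ft"
  lfs[group %in% c("pt_no_ihd", "pt_ihd")] <- "employed_pt"
  lfs[group == "nilf_ihd"] <- "nilf"
  lfs[oth] <- c(unemp_ft = "unemployed_seeking_ft",
                unemp_pt = "unemployed_seeking_pt",
                nilf_other = "nilf", nilf_ill = "nilf")[sub[oth]]

  nilf_reason <- rep("not_applicable", n)
  nilf_reason[group == "nilf_ihd"] <- "own_ill_health"
  nilf_reason[oth & sub == "nilf_ill"] <- "own_ill_health"
  nilf_reason[oth & sub == "nilf_other"] <- "other"

  cond <- rep(NA_character_, n)
  ihd <- group %in% c("ft_ihd", "pt_ihd", "nilf_ihd")
  cond[ihd] <- sample(ihd_codes, sum(ihd), replace = TRUE,
                      prob = c(0.5, 0.3, 0.2))
  ill_oth <- oth & sub == "nilf_ill"
  cond[ill_oth] <- sample(c("stroke", "cancer", "type2_diabetes",
                            "copd", "other"),
                          sum(ill_oth), replace = TRUE,
                          prob = c(0.15, 0.20, 0.25, 0.15, 0.25))
  rest <- is.na(cond)
  cond[rest] <- sample(c("none", "other", "stroke", "cancer",
                         "type2_diabetes", "copd"),
                       sum(rest), replace = TRUE,
                       prob = c(0.55, 0.20, 0.02, 0.06, 0.12, 0.05))

  hours <- numeric(n)
  ft <- lfs == "employed_ft"
  pt <- lfs == "employed_pt"
  hours[ft] <- sample(35:50, sum(ft), replace = TRUE)
  hours[pt] <- sample(4:34, sum(pt), replace = TRUE)

  edu_prob <- list(default = c(0.35, 0.25, 0.22, 0.18),
                   low = c(0.55, 0.25, 0.13, 0.07))
  education <- rep(NA_character_, n)
  low_edu <- group == "nilf_ihd" | ill_oth
  education[low_edu] <- sample(education_levels, sum(low_edu),
                               replace = TRUE, prob = edu_prob$low)
  education[!low_edu] <- sample(education_levels, sum(!low_edu),
                                replace = TRUE, prob = edu_prob$default)

  income_unit_type <- sample(income_unit_types, n, replace = TRUE,
                             prob = c(0.45, 0.25, 0.22, 0.08))

  quintile_prob <- list(
    ft_no_ihd = c(0.05, 0.10, 0.20, 0.30, 0.35),
    ft_ihd = c(0.05, 0.10, 0.20, 0.30, 0.35),
    pt_no_ihd = c(0.15, 0.25, 0.25, 0.20, 0.15),
    pt_ihd = c(0.15, 0.25, 0.25, 0.20, 0.15),
    nilf_ihd = c(0.50, 0.30, 0.10, 0.07, 0.03),
    other = c(0.35, 0.30, 0.15, 0.12, 0.08))
  income_quintile <- integer(n)
  for (g in ply_groups) {
    sel <- group == g
    if (any(sel)) {
      income_quintile[sel] <- sample(1:5, sum(sel), replace = TRUE,
                                     prob = quintile_prob[[g]])
    }
  }

  ho_prob <- c(ft_no_ihd = 0.78, ft_ihd = 0.76, pt_no_ihd = 0.72,
               pt_ihd = 0.70, nilf_ihd = 0.55, other = 0.60)
  home_owner <- unname(runif(n) < ho_prob[group])

  dsp_prob <- rep(0.02, n)
  dsp_prob[group == "nilf_ihd"] <- 0.85
  dsp_prob[ill_oth] <- 0.80
  dsp_prob[oth & sub == "nilf_other"] <- 0.10
  receives_dsp <- runif(n) < dsp_prob

  receives_age_pension <- runif(n) < ifelse(age >= 60, 0.08, 0.005)

  wbar <- cfg$target_population / n
  weight <- round(runif(n, 0.5 * wbar, 1.5 * wbar), 4)

  tibble::tibble(
    group = group, age = age,
    age_group = age_to_group(age), sex = sex,
    income_unit_type = income_unit_type, education = education,
    labour_force_status = lfs, nilf_reason = nilf_reason,
    main_condition = cond, hours_per_week = hours,
    home_owner = home_owner,
    receives_age_pension = receives_age_pension,
    receives_dsp = receives_dsp,
    income_quintile = income_quintile, weight = weight)
}

## Weekly income, welfare and tax for n people of a given analysis group,
## under the per-group rules of the configuration.  Amounts in 2013
## dollars, rounded to cents.
draw_economics <- function(cfg, group) {
  n <- length(group)
  income <- rlnorm(n, meanlog = log(cfg$income_median[group]),
                   sdlog = cfg$income_sdlog[group])
  welfare <- numeric(n)
  dsp <- group == "nilf_ihd"
  if (any(dsp)) {
    welfare[dsp] <- pmin(
      income[dsp],
      income[dsp] * cfg$dsp_welfare_frac *
        exp(rnorm(sum(dsp), 0, cfg$dsp_welfare_sdlog)))
  }
  if (any(!dsp)) {
    gets <- !dsp & runif(n) < cfg$welfare_prob[group]
    welfare[gets] <- pmin(
      income[gets],
      rlnorm(sum(gets), log(cfg$welfare_median[group[gets]]), 0.4))
  }
  tax <- unname(cfg$tax_rate[group] *
                  pmax(0, income - cfg$tax_threshold[group]))
  tibble::tibble(weekly_income = round(income, 2),
                 weekly_welfare = round(welfare, 2),
                 weekly_tax = round(tax, 2))
}

#' Generate the synthetic survey base population
#'
#' Draws `config$n_records` person records emulating the pooled
#' disability-survey base file: demographics, labour-force state, reason
#' for being out of the labour force, main chronic condition, and a
#' positive survey weight.  Deterministic given `seed`.
#'
#' @param config A [population_config()].
#' @param seed Integer seed controlling all randomness.
#' @return A tibble of person records (one row per person).
#' @export
#' @examples
#' pop <- generate_base_population(population_config(n_records = 500), 1)
#' table(pop$labour_force_status)
generate_base_population <- function(config, seed) {
  validate_config(config)
  if (config$n_records == 0) return(empty_population())
  withr::with_seed(seed, {
    ppl <- generate_people(config, config$n_records)
  })
  out <- dplyr::mutate(
    dplyr::select(ppl, -"group"),
    person_id = sprintf("P%06d", dplyr::row_number()),
    .before = 1)
  validate_person_records(out)
  out
}

empty_population <- function() {
  tibble::tibble(person_id = character(), age = integer(),
                 age_group = character(), sex = character(),
                 income_unit_type = character(), education = character(),
                 labour_force_status = character(),
                 nilf_reason = character(), main_condition = character(),
                 hours_per_week = numeric(), home_owner = logical(),
                 receives_age_pension = logical(),
                 receives_dsp = logical(), income_quintile = integer(),
                 weight = numeric())
}

#' Generate the synthetic economic donor pool
#'
#' Draws donor records emulating the income/tax-transfer microsimulation
#' source: the ten matching variables plus weekly income, welfare and tax
#' in 2013 dollars.  Donors are drawn from the same joint categorical law
#' as the base population, so every matching cell occupied by base
#' records is covered by donors with probability approaching one as the
#' pool grows.
#'
#' @param config A [population_config()].
#' @param seed Integer seed.
#' @param n Pool size (defaults to `config$n_records`).
#' @return A tibble of donor records.
#' @export
generate_donor_pool <- function(config, seed, n = config$n_records) {
  validate_config(config)
  if (n == 0) {
    return(tibble::tibble(donor_id = character(), sex = character(),
                          age_group = character(),
                          income_unit_type = character(),
                          income_quintile = integer(),
                          receives_age_pension = logical(),
                          receives_dsp = logical(),
                          labour_force_status = character(),
                          hours_band = character(),
                          education = character(), home_owner = logical(),
                          weekly_income = numeric(),
                          weekly_welfare = numeric(),
                          weekly_tax = numeric()))
  }
  withr::with_seed(seed, {
    ppl <- generate_people(config, n)
    eco <- draw_economics(config, ppl$group)
  })
  out <- tibble::tibble(
    donor_id = sprintf("D%06d", seq_len(n)),
    sex = ppl$sex, age_group = ppl$age_group,
    income_unit_type = ppl$income_unit_type,
    income_quintile = ppl$income_quintile,
    receives_age_pension = ppl$receives_age_pension,
    receives_dsp = ppl$receives_dsp,
    labour_force_status = ppl$labour_force_status,
    hours_band = hours_band(ppl$hours_per_week),
    education = ppl$education, home_owner = ppl$home_owner,
    weekly_income = eco$weekly_income,
    weekly_welfare = eco$weekly_welfare,
    weekly_tax = eco$weekly_tax)
  validate_donor_records(out)
  out
}

#' Validate person records against the schema invariants
#'
#' Checks ages against bands, the NILF-reason consistency rule, zero
#' hours outside employment, positive weights, and categorical domains.
#' Errors on the first violated invariant.
#'
#' @param df A person-record data frame.
#' @return The input, invisibly.
#' @export
validate_person_records <- function(df) {
  need <- c("person_id", "age", "age_group", "sex", "income_unit_type",
            "education", "labour_force_status", "nilf_reason",
            "main_condition", "hours_per_week", "home_owner",
            "receives_age_pension", "receives_dsp", "income_quintile",
            "weight")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$age < 45 | df$age > 64)) stop("age outside [45, 64]",
                                           call. = FALSE)
  if (!all(df$age_group == age_to_group(df$age))) {
    stop("age_group inconsistent with age", call. = FALSE)
  }
  if (!all(df$sex %in% sexes)) stop("invalid sex code", call. = FALSE)
  if (!all(df$labour_force_status %in% lfs_levels)) {
    stop("invalid labour_force_status", call. = FALSE)
  }
  if (!all(df$main_condition %in% condition_codes)) {
    stop("invalid main_condition code", call. = FALSE)
  }
  nilf <- df$labour_force_status == "nilf"
  if (any(xor(nilf, df$nilf_reason != "not_applicable"))) {
    stop("nilf_reason must be set iff labour_force_status is nilf",
         call. = FALSE)
  }
  if (any(df$hours_per_week[!df$labour_force_status %in% employed_lfs]
          != 0)) {
    stop("hours_per_week must be 0 unless employed", call. = FALSE)
  }
  if (any(df$hours_per_week < 0)) stop("negative hours", call. = FALSE)
  if (any(df$weight <= 0)) stop("weights must be positive", call. = FALSE)
  if (any(!df$income_quintile %in% 1:5)) {
    stop("income_quintile outside 1..5", call. = FALSE)
  }
  invisible(df)
}

#' Validate donor records against the schema invariants
#'
#' @param df A donor-record data frame.
#' @return The input, invisibly.
#' @export
validate_donor_records <- function(df) {
  need <- c("donor_id", "sex", "age_group", "income_unit_type",
            "income_quintile", "receives_age_pension", "receives_dsp",
            "labour_force_status", "hours_band", "education",
            "home_owner", "weekly_income", "weekly_welfare", "weekly_tax")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (nrow(df) == 0) return(invisible(df))
  if (any(df$weekly_income < 0) || any(df$weekly_welfare < 0) ||
      any(df$weekly_tax < 0)) {
    stop("economic amounts must be non-negative", call. = FALSE)
  }
  if (any(df$weekly_welfare > df$weekly_income + 1e-9)) {
    stop("weekly_welfare exceeds weekly_income", call. = FALSE)
  }
  if (!all(df$hours_band %in% hours_bands)) {
    stop("invalid hours_band", call. = FALSE)
  }
  invisible(df)
}

#' Write / read population and donor files
#'
#' Plain UTF-8 CSV with a header row, one record per row, column names
#' exactly the schema field names.  Writing then reading a file returns
#' the original records (amounts are stored to the cent, weights to four
#' decimals, so the round trip is exact).
#'
#' @param df Records to write.
#' @param path File path.
#' @return `write_records_csv()` returns `path` invisibly;
#'   `read_person_csv()` / `read_donor_csv()` return validated tibbles.
#' @export
write_records_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE, quote = FALSE,
            fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_records_csv
#' @export
read_person_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
  df$age <- as.integer(df$age)
  df$income_quintile <- as.integer(df$income_quintile)
  validate_person_records(df)
  df
}

#' @rdname write_records_csv
#' @export
read_donor_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE,
                                   fileEncoding = "UTF-8"))
  df$income_quintile <- as.integer(df$income_quintile)
  validate_donor_records(df)
  df
}
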