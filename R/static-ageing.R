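#' Benchmark cells for a projection year
#'
#' A benchmark set is a tibble with one row per calibration cell:
#' `variable` (`"population"`, `"employed_ft"` or `"employed_pt"`),
#' `age_group`, `sex`, and the `target` weighted count.  Population rows
#' are person totals by age band and sex; employment rows are full-time /
#' part-time counts within the same cells (rate x population).
#'
#' @param year Projection year.
#' @param pop_totals Tibble `age_group, sex, target` of population
#'   totals.
#' @param ft_rates,pt_rates Optional tibbles `age_group, sex, rate` of
#'   employment rates; omitted margins are simply not calibrated to.
#' @return A benchmark tibble with attribute `year`.
#' @export
benchmark_set <- function(year, pop_totals, ft_rates = NULL,
                          pt_rates = NULL) {
  stopifnot(all(c("age_group", "sex", "target") %in% names(pop_totals)))
  if (any(pop_totals$target <= 0)) {
    stop("population totals must be positive", call. = FALSE)
  }
  rows <- dplyr::mutate(pop_totals, variable = "population")
  add_rate <- function(rates, variable) {
    if (is.null(rates)) return(NULL)
    stopifnot(all(c("age_group", "sex", "rate") %in% names(rates)))
    if (any(rates$rate < 0 | rates$rate > 1)) {
      stop("employment rates must lie in [0, 1]", call. = FALSE)
    }
    dplyr::inner_join(pop_totals, rates, by = c("age_group", "sex")) |>
      dplyr::transmute(.data$age_group, .data$sex,
                       target = .data$target * .data$rate,
                       variable = variable)
  }
  rows <- dplyr::bind_rows(rows,
                           add_rate(ft_rates, "employed_ft"),
                           add_rate(pt_rates, "employed_pt"))
  ft <- rows$target[rows$variable == "employed_ft"]
  pt <- rows$target[rows$variable == "employed_pt"]
  if (length(ft) && length(pt)) {
    pop <- rows[rows$variable == "population", ]
    emp <- dplyr::bind_rows(
      rows[rows$variable != "population", ]) |>
      dplyr::group_by(.data$age_group, .data$sex) |>
      dplyr::summarise(emp = sum(.data$target), .groups = "drop") |>
      dplyr::inner_join(pop, by = c("age_group", "sex"))
    if (any(emp$emp > emp$target + 1e-9)) {
      stop("full-time + part-time targets exceed the population total ",
           "in at least one cell", call. = FALSE)
    }
  }
  out <- dplyr::select(rows, "variable", "age_group", "sex", "target")
  attr(out, "year") <- year
  out
}

#' Default projection benchmarks
#'
#' Population totals for 45-64-year-olds by projection year, distributed
#' over age band x sex with a mild ageing gradient, plus full-time and
#' part-time employment rates by age band and sex.  The age/sex rate
#' profiles are fixed and rescaled per year so the population-weighted
#' overall full-time and part-time shares follow the projected upward
#' drift in mature-age employment.
#'
#' @param year One of 2015, 2020, 2025, 2030.
#' @return A benchmark tibble (see [benchmark_set()]).
#' @export
default_benchmarks <- function(year) {
  totals <- c(`2015` = 5945000, `2020` = 6374100, `2025` = 6677300,
              `2030` = 7130200)
  ft_overall <- c(`2015` = 0.5414, `2020` = 0.5504, `2025` = 0.5533,
                  `2030` = 0.5581)
  pt_overall <- c(`2015` = 0.2049, `2020` = 0.2138, `2025` = 0.2182,
                  `2030` = 0.2210)
  y <- as.character(year)
  if (!y %in% names(totals)) {
    stop("no default benchmarks for year ", year, call. = FALSE)
  }
  age_share <- c(`45-49` = 0.27, `50-54` = 0.26, `55-59` = 0.24,
                 `60-64` = 0.23)
  sex_share <- c(male = 0.494, female = 0.506)
  grid <- tidyr::expand_grid(age_group = age_groups, sex = sexes)
  grid$target <- totals[y] * age_share[grid$age_group] *
    sex_share[grid$sex]

  ft_profile <- c(male_1 = 0.72, male_2 = 0.70, male_3 = 0.64,
                  male_4 = 0.50, female_1 = 0.42, female_2 = 0.43,
                  female_3 = 0.38, female_4 = 0.25)
  pt_profile <- c(male_1 = 0.10, male_2 = 0.10, male_3 = 0.12,
                  male_4 = 0.14, female_1 = 0.30, female_2 = 0.30,
                  female_3 = 0.29, female_4 = 0.24)
  key <- paste(grid$sex, match(grid$age_group, age_groups), sep = "_")
  w <- grid$target / sum(grid$target)
  scale_to <- function(profile, overall) {
    profile[key] * overall / sum(profile[key] * w)
  }
  ft <- dplyr::mutate(grid[c("age_group", "sex")],
                      rate = scale_to(ft_profile, ft_overall[y]))
  pt <- dplyr::mutate(grid[c("age_group", "sex")],
                      rate = scale_to(pt_profile, pt_overall[y]))
  benchmark_set(year, grid, ft, pt)
}

benchmark_design <- function(records, benchmarks) {
  n <- nrow(records)
  X <- matrix(0, n, nrow(benchmarks))
  for (j in seq_len(nrow(benchmarks))) {
    cell <- records$age_group == benchmarks$age_group[j] &
      records$sex == benchmarks$sex[j]
    ind <- switch(
      benchmarks$variable[j],
      population = cell,
      employed_ft = cell & records$labour_force_status == "employed_ft",
      employed_pt = cell & records$labour_force_status == "employed_pt",
      stop("unknown benchmark variable: ", benchmarks$variable[j],
           call. = FALSE))
    X[ind, j] <- 1
  }
  X
}

cell_label <- function(benchmarks) {
  paste0(benchmarks$variable, "[", benchmarks$age_group, ",",
         benchmarks$sex, "]")
}

#' GREGWT-style calibration of survey weights to benchmarks
#'
#' Adjusts person weights so weighted totals hit every benchmark cell,
#' minimising the chi-square (generalized-regression) distance
#' \eqn{\sum_i (w_i - d_i)^2 / d_i} from the input weights.  The linear
#' solution \eqn{w_i = d_i (1 + x_i^\top \lambda)} is truncated to the
#' multiplier bounds and re-solved over the unrestricted units until all
#' cell totals are within `tolerance` (iterative restricted calibration,
#' the documented behaviour of GREGWT-family algorithms).
#'
#' @param records Records carrying `age_group`, `sex`,
#'   `labour_force_status` and `weight`.
#' @param benchmarks A benchmark tibble (see [benchmark_set()]).
#' @param tolerance Maximum relative benchmark error accepted as
#'   converged.
#' @param max_iter Iteration cap.
#' @param bounds Length-2 multiplier bounds `(lo, hi)` with
#'   `lo < 1 < hi`.
#' @return A list of class `gregwt_result`: `weights`, `iterations`,
#'   `max_rel_error`, `converged`, `bound_hits`, and a per-cell `cells`
#'   tibble of achieved totals.
#' @export
gregwt_calibrate <- function(records, benchmarks, tolerance = 1e-6,
                             max_iter = 50, bounds = c(0.1, 10)) {
  stopifnot(bounds[1] < 1, bounds[2] > 1, nrow(records) > 0)
  d <- records$weight
  X <- benchmark_design(records, benchmarks)
  target <- benchmarks$target

  empty <- colSums(X) == 0 & target > 0
  if (any(empty)) {
    stop("infeasible benchmark cell(s) with positive target but no ",
         "contributing records: ",
         paste(cell_label(benchmarks)[empty], collapse = ", "),
         call. = FALSE)
  }

  rel_err <- function(g) {
    max(abs(crossprod(X, d * g) - target) / pmax(abs(target), 1))
  }

  n <- length(d)
  g <- rep(1, n)
  free <- rep(TRUE, n)
  err <- rel_err(g)
  iter <- 0L
  while (err > tolerance && iter < max_iter && any(free)) {
    iter <- iter + 1L
    dfree <- d * free
    A <- crossprod(X, dfree * X)
    resid <- target - as.vector(crossprod(X, d * g))
    lambda <- tryCatch(solve(A, resid),
                       error = function(e) MASS::ginv(A) %*% resid)
    g_new <- g + as.vector(X %*% lambda) * free
    out_of_bounds <- g_new < bounds[1] | g_new > bounds[2]
    g <- pmin(pmax(g_new, bounds[1]), bounds[2])
    free <- free & !out_of_bounds
    err <- rel_err(g)
  }

  achieved <- as.vector(crossprod(X, d * g))
  res <- list(
    weights = d * g,
    iterations = iter,
    max_rel_error = err,
    converged = err <= tolerance,
    bound_hits = sum(!free),
    cells = dplyr::mutate(
      benchmarks, achieved = achieved,
      rel_error = abs(achieved - target) / pmax(abs(target), 1)))
  class(res) <- "gregwt_result"
  res
}

#' @export
print.gregwt_result <- function(x, ...) {
  cat("GREGWT-style calibration:",
      if (x$converged) "converged" else "NOT converged",
      "in", x$iterations, "iteration(s)\n")
  cat("  max relative benchmark error:",
      format(x$max_rel_error, digits = 4), "\n")
  cat("  weights truncated at bounds:", x$bound_hits, "\n")
  invisible(x)
}

#' Default chronic-disease prevalence trends
#'
#' Annual proportional prevalence multipliers per trended disease and
#' sex, constant across age bands, following the direction of the
#' national burden-of-disease trends: ischemic heart disease and stroke
#' decreasing in both sexes, cancer roughly stable, type 2 diabetes
#' increasing, chronic obstructive pulmonary disease stable in men and
#' increasing in women.  Trends apply from the trend window start until
#' 2023, after which prevalence stabilises.
#'
#' @return Tibble `disease, sex, age_group, annual_multiplier`.
#' @export
default_disease_trends <- function() {
  per_sex <- tibble::tribble(
    ~disease, ~sex, ~annual_multiplier,
    "ihd", "male", 0.990,
    "ihd", "female", 0.990,
    "stroke", "male", 0.995,
    "stroke", "female", 0.995,
    "cancer", "male", 1.000,
    "cancer", "female", 1.000,
    "type2_diabetes", "male", 1.015,
    "type2_diabetes", "female", 1.015,
    "copd", "male", 1.000,
    "copd", "female", 1.010)
  tidyr::expand_grid(per_sex, age_group = age_groups)
}

## Main-condition code -> trended disease grouping (NA = untrended).
condition_trend_group <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code %in% ihd_codes] <- "ihd"
  out[code %in% c("stroke", "cancer", "type2_diabetes", "copd")] <-
    code[code %in% c("stroke", "cancer", "type2_diabetes", "copd")]
  out
}

#' Adjust weights for chronic-disease prevalence trends
#'
#' Within each sex x age-band stratum, the weighted prevalence of each
#' trended disease is moved to `base prevalence x
#' multiplier^(min(target_year, 2023) - base_year)` by scaling the
#' weights of records with that main condition; untrended records are
#' rescaled so the stratum total weight is conserved.  Prevalence rates
#' stabilise after 2023.
#'
#' @param records Weighted records with `sex`, `age_group`,
#'   `main_condition`, `weight`.
#' @param trends Trend tibble (see [default_disease_trends()]).
#' @param base_year Year the input prevalences refer to.
#' @param target_year Projection year (`>= base_year`).
#' @param trend_end Year after which prevalence is held constant.
#' @return The records with adjusted weights.
#' @export
apply_disease_trend <- function(records, trends = default_disease_trends(),
                                base_year = 2009, target_year,
                                trend_end = 2023) {
  stopifnot(target_year >= base_year)
  if (any(trends$annual_multiplier <= 0)) {
    stop("trend multipliers must be positive", call. = FALSE)
  }
  years <- min(target_year, trend_end) - base_year

  r <- records
  r$..row <- seq_len(nrow(r))
  r$..dis <- condition_trend_group(r$main_condition)
  r <- dplyr::left_join(
    r, dplyr::rename(trends, ..dis = "disease"),
    by = c("..dis", "sex", "age_group"))
  r$..factor <- ifelse(is.na(r$annual_multiplier), NA_real_,
                       r$annual_multiplier^years)

  adj <- r |>
    dplyr::group_by(.data$sex, .data$age_group) |>
    dplyr::mutate(
      ..tot = sum(.data$weight),
      ..base_prev = sum(.data$weight * !is.na(.data$..factor)) /
        .data$..tot,
      ..new_prev = sum(.data$weight * dplyr::coalesce(.data$..factor, 0)) /
        .data$..tot) |>
    dplyr::ungroup()

  if (any(adj$..new_prev > 1 + 1e-12)) {
    stop("trend multipliers imply total trended prevalence > 1 in at ",
         "least one stratum", call. = FALSE)
  }
  bad <- adj$..base_prev >= 1 - 1e-12 &
    abs(adj$..new_prev - adj$..base_prev) > 1e-12
  if (any(bad)) {
    stop("stratum with no untrended records cannot conserve total ",
         "weight under a non-unit trend", call. = FALSE)
  }

  scale_rest <- (1 - adj$..new_prev) / (1 - adj$..base_prev)
  new_w <- ifelse(is.na(adj$..factor),
                  adj$weight * scale_rest,
                  adj$weight * adj$..factor)
  out <- records
  out$weight[adj$..row] <- new_w
  out
}

#' Default real-growth uprating rules
#'
#' Weekly income and tax grow at 1% per annum in real terms from the
#' 2013 base year; welfare payments are indexed to CPI only (zero real
#' growth).
#'
#' @return Tibble `component, annual_real_growth, base_year`.
#' @export
default_uprating_rules <- function() {
  tibble::tibble(component = c("income", "tax", "welfare"),
                 annual_real_growth = c(0.01, 0.01, 0),
                 base_year = 2013)
}

#' Uprate economic amounts to a projection year
#'
#' Multiplies each weekly amount by `(1 + rate)^(target_year -
#' base_year)` per component rule.
#'
#' @param records Imputed records with `weekly_income`, `weekly_welfare`,
#'   `weekly_tax`.
#' @param target_year Projection year (`>=` each rule's base year).
#' @param rules Uprating rules (see [default_uprating_rules()]).
#' @return The records with uprated amounts.
#' @export
uprate_economics <- function(records, target_year,
                             rules = default_uprating_rules()) {
  cols <- c(income = "weekly_income", welfare = "weekly_welfare",
            tax = "weekly_tax")
  unknown <- setdiff(rules$component, names(cols))
  if (length(unknown)) {
    stop("unknown uprating component(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(target_year < rules$base_year)) {
    stop("target_year precedes the uprating base year", call. = FALSE)
  }
  out <- records
  for (i in seq_len(nrow(rules))) {
    col <- cols[[rules$component[i]]]
    fac <- (1 + rules$annual_real_growth[i])^(target_year -
                                                rules$base_year[i])
    out[[col]] <- out[[col]] * fac
  }
  out
}

#' Statically age the imputed base file to a projection year
#'
#' Composition of the three ageing stages, in order: disease-trend
#' adjustment of weights, GREGWT-style calibration to the year's
#' population and employment benchmarks, and real-terms uprating of
#' economic amounts.
#'
#' @param records Imputed person records.
#' @param year Projection year.
#' @param benchmarks Benchmark tibble (defaults to
#'   [default_benchmarks()] for `year`).
#' @param trends,rules Trend and uprating inputs.
#' @param tolerance,max_iter,bounds Calibration controls.
#' @param trend_base_year Year the base-file prevalences refer to.
#' @return Projected records with attributes `year` and `calibration`.
#' @export
project_to_year <- function(records, year,
                            benchmarks = default_benchmarks(year),
                            trends = default_disease_trends(),
                            rules = default_uprating_rules(),
                            tolerance = 1e-6, max_iter = 50,
                            bounds = c(0.1, 10),
                            trend_base_year = 2009) {
  r <- apply_disease_trend(records, trends, trend_base_year, year)
  cal <- gregwt_calibrate(r, benchmarks, tolerance, max_iter, bounds)
  if (!cal$converged) {
    warning("calibration for ", year, " did not converge (max relative ",
            "error ", format(cal$max_rel_error, digits = 4), ")")
  }
  r$weight <- cal$weights
  r <- uprate_economics(r, year, rules)
  attr(r, "year") <- year
  attr(r, "calibration") <- cal
  r
}
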