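#' Run the full projection pipeline
#'
#' End-to-end run on synthetic data: generate the base population and
#' donor pool, impute weekly income/welfare/tax by synthetic matching,
#' then for each projection year statically age the file (disease
#' trends, GREGWT-style calibration, uprating), classify the analysis
#' groups, summarise them, run the counterfactual Monte Carlo against
#' the full-time, part-time and labour-force-wide pools, and aggregate
#' national costs and lost GDP.
#'
#' All randomness is driven by `seed`; a fixed `(config, seed)` pair
#' reproduces every output byte-for-byte.
#'
#' @param config A [population_config()].
#' @param years Projection years (subset of 2015/2020/2025/2030 when
#'   using the default benchmarks).
#' @param seed Master integer seed.
#' @param n_sims Monte-Carlo replicates per comparison.
#' @param donor_n Donor pool size (defaults to `config$n_records`).
#' @param benchmarks Function `year -> benchmark tibble`.
#' @param trends,rules,gdp_inputs Static-ageing and GDP inputs.
#' @param weeks_per_year Annualisation factor.
#' @param out_dir Optional directory; when given, writes `table1.csv`
#'   (group summaries), `table2.csv` (counterfactual estimates),
#'   `national_costs.csv`, `gdp.csv` and `run.log`.
#' @return A list `table1, table2, national_costs, gdp, diagnostics`.
#' @export
run_pipeline <- function(config = population_config(),
                         years = c(2015, 2020, 2025, 2030),
                         seed = 1L, n_sims = 1000,
                         donor_n = config$n_records,
                         benchmarks = default_benchmarks,
                         trends = default_disease_trends(),
                         rules = default_uprating_rules(),
                         gdp_inputs = default_gdp_inputs(),
                         weeks_per_year = 52,
                         out_dir = NULL) {
  base <- generate_base_population(config, sub_seed(seed, 1))
  donors <- generate_donor_pool(config, sub_seed(seed, 2), n = donor_n)
  imputed <- match_economic_data(base, donors, sub_seed(seed, 3))

  table1 <- list(); table2 <- list(); costs <- list(); gdp <- list()
  calib <- list()
  for (i in seq_along(years)) {
    year <- years[i]
    proj <- project_to_year(imputed, year, benchmarks(year), trends,
                            rules)
    calib[[as.character(year)]] <- attr(proj, "calibration")
    table1[[i]] <- dplyr::mutate(group_summaries(proj), year = year,
                                 .before = 1)
    ests <- lapply(c("ft_no_ihd", "pt_no_ihd", "labour_force_no_ihd"),
                   function(pool) {
                     spec <- counterfactual_spec(
                       donor_pool = pool, n_sims = n_sims,
                       master_seed = sub_seed(seed, 100 + 10 * i +
                                                match(pool, c(
                                                  "ft_no_ihd",
                                                  "pt_no_ihd",
                                                  "labour_force_no_ihd"))))
                     run_counterfactual(proj, spec)
                   })
    ests <- dplyr::bind_rows(ests)
    table2[[i]] <- dplyr::mutate(ests, year = year, .before = 1)

    n_ply <- sum(proj$weight[classify_group(proj) == "nilf_ihd"])
    lf_est <- ests[ests$donor_pool == "labour_force_no_ihd", ,
                   drop = FALSE]
    costs[[i]] <- national_cost_summary(year, lf_est, n_ply, gdp_inputs,
                                        weeks_per_year)
    gi <- gdp_inputs[gdp_inputs$year == year, , drop = FALSE]
    gdp[[i]] <- tibble::tibble(
      year = year, gdp_millions = gi$gdp_millions,
      lost_gdp = costs[[i]]$lost_gdp,
      potential_gdp_gain_pct = costs[[i]]$potential_gdp_gain_pct)
  }

  res <- list(table1 = dplyr::bind_rows(table1),
              table2 = dplyr::bind_rows(table2),
              national_costs = dplyr::bind_rows(costs),
              gdp = dplyr::bind_rows(gdp),
              diagnostics = list(
                imputation = imputation_diagnostics(imputed),
                calibration = lapply(calib, function(cal) {
                  list(converged = cal$converged,
                       iterations = cal$iterations,
                       max_rel_error = cal$max_rel_error)
                })))

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(res$table1, file.path(out_dir, "table1.csv"),
              row.names = FALSE)
    write.csv(res$table2, file.path(out_dir, "table2.csv"),
              row.names = FALSE)
    write.csv(res$national_costs,
              file.path(out_dir, "national_costs.csv"),
              row.names = FALSE)
    write.csv(res$gdp, file.path(out_dir, "gdp.csv"), row.names = FALSE)
    log_lines <- c(
      "plymod pipeline run",
      paste0("seed: ", seed),
      paste0("years: ", paste(years, collapse = ", ")),
      paste0("n_records: ", config$n_records,
             "; donor_n: ", donor_n, "; n_sims: ", n_sims),
      paste0("config_hash: ", rlang::hash(config)),
      paste0("imputation match_rate: ",
             format(res$diagnostics$imputation$match_rate, digits = 6)),
      vapply(names(res$diagnostics$calibration), function(y) {
        d <- res$diagnostics$calibration[[y]]
        paste0("calibration ", y, ": converged=", d$converged,
               " iterations=", d$iterations, " max_rel_error=",
               format(d$max_rel_error, digits = 4))
      }, character(1)))
    writeLines(log_lines, file.path(out_dir, "run.log"))
  }
  res
}

#' Read a scenario configuration file
#'
#' Accepts YAML (needs the `yaml` package) or JSON.  Recognised top-level
#' keys override [population_config()] arguments; unknown keys are an
#' error so typos fail loudly.
#'
#' @param path Config file path.
#' @return A `ply_config`.
#' @export
read_scenario_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML scenario files requires the 'yaml' package",
           call. = FALSE)
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  allowed <- names(formals(population_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown)) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  raw <- lapply(raw, function(x) if (is.list(x)) unlist(x) else x)
  do.call(population_config, raw)
}
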