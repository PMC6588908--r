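#' Published national-level statistics and their printed inputs
#'
#' Read-only fixture of the published headline numbers this package can
#' recompute from other printed numbers: every entry carries the
#' operation (`percent_change`, `share_pct` or `gdp_gain`), its two
#' printed inputs, the published derived value (as formatted, two
#' decimals), a source string, and a role.  Role `"reproduced"` entries
#' must match recomputation after two-decimal display rounding; role
#' `"display_only"` entries are published figures whose printed inputs do
#' not reproduce them at two decimals (small inconsistencies in the
#' source report, retained for completeness but never asserted).
#'
#' @return A tibble
#'   `id, op, input1, input2, published, role, source`.
#' @export
published_values <- function() {
  tibble::tribble(
    ~id, ~op, ~input1, ~input2, ~published, ~role, ~source,
    "ply_count_growth_pct", "percent_change", 6700, 8100, 20.90,
    "reproduced", "lost-PLY headcount 2015 -> 2030",
    "ft_no_ihd_growth_pct", "percent_change", 3155900, 3917800, 24.14,
    "reproduced", "employed full-time without IHD, 2015 -> 2030",
    "pt_no_ihd_growth_pct", "percent_change", 1194100, 1551100, 29.90,
    "reproduced", "employed part-time without IHD, 2015 -> 2030",
    "ft_ihd_change_pct", "percent_change", 62800, 61200, -2.55,
    "reproduced", "employed full-time with IHD, 2015 -> 2030",
    "pt_ihd_growth_pct", "percent_change", 23900, 24900, 4.18,
    "reproduced", "employed part-time with IHD, 2015 -> 2030",
    "ply_income_growth_pct", "percent_change", 415.83, 423.38, 1.82,
    "reproduced", "median weekly income of the lost-PLY group",
    "welfare_share_income_2015_pct", "share_pct", 321.87, 415.83, 77.40,
    "reproduced", "median welfare as share of median income, 2015",
    "welfare_share_income_2030_pct", "share_pct", 365.52, 423.38, 86.33,
    "reproduced", "median welfare as share of median income, 2030",
    "ihd_workers_ft_share_pct", "share_pct", 62800, 86700, 72.43,
    "reproduced", "full-time share of employed persons with IHD, 2015",
    "ihd_workers_pt_share_pct", "share_pct", 23900, 86700, 27.57,
    "reproduced", "part-time share of employed persons with IHD, 2015",
    "ply_population_share_2015_pct", "share_pct", 6700, 5945000, 0.11,
    "reproduced", "lost-PLY share of the 45-64 population, 2015",
    "lost_income_growth_pct", "percent_change", 273, 443, 62.27,
    "reproduced", "national lost income (AU$m) 2015 -> 2030",
    "extra_welfare_growth_pct", "percent_change", 106, 143, 34.91,
    "reproduced", "national extra welfare (AU$m) 2015 -> 2030",
    "lost_tax_diff_growth_pct", "percent_change", 256.10, 335.73, 31.09,
    "reproduced", "weekly tax difference vs full-time, 2015 -> 2030",
    "lost_gdp_growth_pct", "percent_change", 785, 1125, 43.31,
    "reproduced", "lost GDP (AU$m) 2015 -> 2030",
    "gdp_gain_2015_pct", "gdp_gain", 785, 1483861, 0.05,
    "reproduced", "potential GDP gain, 2015",
    "gdp_gain_2030_pct", "gdp_gain", 1125, 2149073, 0.05,
    "reproduced", "potential GDP gain, 2030",
    "population_growth_pct", "percent_change", 5945000, 7130200, 19.95,
    "display_only",
    "45-64 population 2015 -> 2030 (printed inputs give 19.94)",
    "lost_tax_growth_pct", "percent_change", 74, 117, 58.12,
    "display_only",
    "national lost tax (AU$m) 2015 -> 2030 (printed inputs give 58.11)",
    "welfare_growth_alt_pct", "percent_change", 106, 143, 43.91,
    "display_only",
    "welfare growth as restated in discussion (inputs give 34.91)",
    "income_diff_growth_pct", "percent_change", 950.30, 1269.82, 63.94,
    "display_only",
    "relative income-difference growth (inputs give 33.62)")
}

#' Recompute the published derived statistics
#'
#' Recomputes every fixture entry from its printed inputs through the
#' cost-aggregation operations and flags whether the two-decimal rounded
#' result equals the published figure.  Entries with `published = NA`
#' (injected sentinels) are flagged `"unpublished"` rather than matched.
#'
#' @param fixture Fixture tibble (defaults to [published_values()]).
#' @param ids Optional subset of entry ids; an unknown id is an error
#'   naming it.
#' @return The fixture with columns `recomputed` (unrounded),
#'   `recomputed_2dp`, and `match` (`TRUE`/`FALSE`/`NA` for
#'   unpublished).
#' @export
reproduce_derived_statistics <- function(fixture = published_values(),
                                         ids = NULL) {
  if (!is.null(ids)) {
    missing <- setdiff(ids, fixture$id)
    if (length(missing)) {
      stop("fixture key(s) not found: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    fixture <- fixture[match(ids, fixture$id), , drop = FALSE]
  }
  rec <- mapply(function(op, a, b) {
    switch(op,
           percent_change = percent_change(a, b),
           share_pct = share_pct(a, b),
           gdp_gain = potential_gdp_gain_pct(a, b),
           stop("unknown operation: ", op, call. = FALSE))
  }, fixture$op, fixture$input1, fixture$input2)
  out <- dplyr::mutate(
    fixture,
    recomputed = unname(rec),
    recomputed_2dp = round_half_up(.data$recomputed, 2),
    match = dplyr::if_else(is.na(.data$published), NA,
                           .data$recomputed_2dp == .data$published))
  out
}

#' Render national-cost series figures
#'
#' One figure per cost component (lost income, extra welfare payments,
#' lost tax revenue) against projection year, with the percentile CI as
#' a band.  The plotted values are exactly the rows of the national-cost
#' summary; when `out_dir` is given the underlying long table is also
#' written as `national_costs_long.csv` alongside one PNG per component.
#'
#' @param summaries National cost summaries (rows from
#'   [national_cost_summary()]).
#' @param out_dir Optional output directory.
#' @return Invisibly, a list with `data` (long tibble
#'   `year, component, cost, lower, upper`) and `plots` (named list of
#'   ggplot objects).
#' @export
render_cost_series <- function(summaries, out_dir = NULL) {
  stopifnot(nrow(summaries) >= 1)
  long <- dplyr::bind_rows(
    dplyr::transmute(summaries, year = .data$year,
                     component = "lost_income", cost = .data$lost_income,
                     lower = .data$lost_income_lower,
                     upper = .data$lost_income_upper),
    dplyr::transmute(summaries, year = .data$year,
                     component = "extra_welfare",
                     cost = .data$extra_welfare,
                     lower = .data$extra_welfare_lower,
                     upper = .data$extra_welfare_upper),
    dplyr::transmute(summaries, year = .data$year,
                     component = "lost_tax", cost = .data$lost_tax,
                     lower = .data$lost_tax_lower,
                     upper = .data$lost_tax_upper)) |>
    dplyr::arrange(.data$component, .data$year)
  titles <- c(lost_income = "Lost income through lost PLYs due to IHD",
              extra_welfare = "Extra welfare payments through lost PLYs",
              lost_tax = "Lost tax revenue through lost PLYs")
  plots <- lapply(unique(long$component), function(comp) {
    d <- long[long$component == comp, ]
    ggplot2::ggplot(d, ggplot2::aes(x = .data$year, y = .data$cost)) +
      ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
        fill = "grey80") +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::labs(title = titles[[comp]], x = "Projection year",
                    y = "AU$ millions (2013 dollars)") +
      ggplot2::theme_minimal()
  })
  names(plots) <- unique(long$component)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write.csv(long, file.path(out_dir, "national_costs_long.csv"),
              row.names = FALSE)
    for (comp in names(plots)) {
      ggplot2::ggsave(file.path(out_dir, paste0(comp, ".png")),
                      plots[[comp]], width = 6, height = 4, dpi = 150)
    }
  }
  invisible(list(data = long, plots = plots))
}
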