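#' Annual national cost from a weekly counterfactual difference
#'
#' Scales the labour-force-wide weekly difference up to an annual
#' national amount: `|weekly difference| x weighted lost-PLY persons x
#' weeks per year / 1e6`, in AU$ millions per year.  CI endpoints are
#' passed through the same monotone map and re-ordered.
#'
#' @param estimate Either a single weekly difference (numeric) or a
#'   one-row estimate tibble from [run_counterfactual()]; in the latter
#'   case the donor pool must be `labour_force_no_ihd` (national costs
#'   compare against the whole labour force without IHD).
#' @param n_lost_ply Weighted number of persons with lost PLYs.
#' @param weeks_per_year Annualisation factor (default 52).
#' @return For numeric input, the cost in AU$ millions; for a tibble
#'   row, a tibble `outcome, cost, lower, upper`.
#' @export
#' @examples
#' national_cost(-783, 6700)  # ~ 272.8 AU$ millions
national_cost <- function(estimate, n_lost_ply, weeks_per_year = 52) {
  stopifnot(n_lost_ply >= 0)
  to_millions <- function(x) abs(x) * n_lost_ply * weeks_per_year / 1e6
  if (is.numeric(estimate)) {
    return(to_millions(estimate))
  }
  stopifnot(is.data.frame(estimate), nrow(estimate) == 1)
  if (!identical(estimate$donor_pool, "labour_force_no_ihd")) {
    stop("national costs require the labour_force_no_ihd donor pool ",
         "(got ", estimate$donor_pool, ")", call. = FALSE)
  }
  ci <- sort(to_millions(c(estimate$lower, estimate$upper)))
  tibble::tibble(outcome = estimate$outcome,
                 cost = to_millions(estimate$estimate),
                 lower = ci[1], upper = ci[2])
}

#' GDP inputs per projection year
#'
#' Reads the packaged fixture of projected GDP (AU$ millions, 2013
#' dollars) and the reference workforce (employed persons) per projection
#' year.  The GDP column carries the published Treasury projections; the
#' workforce column is a synthetic stand-in back-derived from the
#' published GDP, lost-GDP and lost-PLY headcount rows (Treasury's own
#' workforce projections are not public), shipped as
#' `extdata/gdp_inputs_synthetic.csv`.
#'
#' @param path Optional alternative CSV with columns
#'   `year, gdp_millions, workforce`.
#' @return A tibble `year, gdp_millions, workforce`.
#' @export
default_gdp_inputs <- function(path = system.file(
  "extdata", "gdp_inputs_synthetic.csv", package = "plymod")) {
  df <- tibble::as_tibble(read.csv(path))
  stopifnot(all(c("year", "gdp_millions", "workforce") %in% names(df)),
            all(df$gdp_millions > 0), all(df$workforce > 0))
  df
}

#' Lost GDP from lost labour-force participation
#'
#' Proportional-labour decomposition of output: `lost GDP = GDP x lost
#' workers / reference workforce` (AU$ millions).  Linear in the lost
#' headcount.
#'
#' @param n_lost_ply Weighted persons out of the labour force due to
#'   IHD.
#' @param gdp_inputs One-row tibble `year, gdp_millions, workforce`
#'   (a row of [default_gdp_inputs()]).
#' @return Lost GDP in AU$ millions.
#' @export
lost_gdp <- function(n_lost_ply, gdp_inputs) {
  stopifnot(n_lost_ply >= 0, nrow(gdp_inputs) == 1,
            gdp_inputs$gdp_millions > 0, gdp_inputs$workforce > 0)
  gdp_inputs$gdp_millions * n_lost_ply / gdp_inputs$workforce
}

#' Potential percentage gain in GDP
#'
#' `100 x lost_gdp / gdp`: the share of GDP that would be recovered if
#' those with lost PLYs could remain in the labour force.
#'
#' @param lost_gdp,gdp AU$ millions (same units); `gdp > 0`.
#' @return Percent.
#' @export
potential_gdp_gain_pct <- function(lost_gdp, gdp) {
  if (gdp <= 0) stop("gdp must be positive", call. = FALSE)
  100 * lost_gdp / gdp
}

#' Percent change between two values
#'
#' `100 x (later - earlier) / earlier`.  Display rounding to two
#' decimals is applied at report time, never inside computation.
#'
#' @param earlier,later Numeric scalars; `earlier` must be non-zero.
#' @return Percent.
#' @export
#' @examples
#' percent_change(6700, 8100)  # 20.895... -> prints as 20.90
percent_change <- function(earlier, later) {
  if (any(earlier == 0)) stop("earlier value must be non-zero",
                              call. = FALSE)
  100 * (later - earlier) / earlier
}

#' Percentage share of a whole
#'
#' `100 x part / whole` with `whole > 0`.
#'
#' @param part,whole Numeric scalars.
#' @return Percent.
#' @export
share_pct <- function(part, whole) {
  if (any(whole <= 0)) stop("whole must be positive", call. = FALSE)
  100 * part / whole
}

#' National cost summary for one projection year
#'
#' Converts the labour-force-wide counterfactual estimates into annual
#' national amounts and attaches the lost-GDP valuation: lost personal
#' income, extra welfare payments and lost tax revenue (AU$ millions per
#' year, with percentile CIs), lost GDP, and the potential percentage
#' gain in GDP.
#'
#' @param year Projection year.
#' @param estimates Estimate tibble from [run_counterfactual()] with the
#'   `labour_force_no_ihd` pool (rows for income, welfare, tax).
#' @param n_lost_ply Weighted lost-PLY persons for the year.
#' @param gdp_inputs Tibble of GDP inputs (see [default_gdp_inputs()]).
#' @param weeks_per_year Annualisation factor.
#' @return A one-row tibble (class `ply_cost_summary` rowwise):
#'   `year, n_lost_ply, lost_income, lost_income_lower, ...,
#'   lost_gdp, potential_gdp_gain_pct`.
#' @export
national_cost_summary <- function(year, estimates, n_lost_ply,
                                  gdp_inputs = default_gdp_inputs(),
                                  weeks_per_year = 52) {
  stopifnot(all(c("income", "welfare", "tax") %in% estimates$outcome))
  one <- function(oc) {
    national_cost(estimates[estimates$outcome == oc, , drop = FALSE],
                  n_lost_ply, weeks_per_year)
  }
  inc <- one("income"); wel <- one("welfare"); tax <- one("tax")
  gi <- gdp_inputs[gdp_inputs$year == year, , drop = FALSE]
  if (nrow(gi) != 1) stop("no GDP inputs for year ", year, call. = FALSE)
  lg <- lost_gdp(n_lost_ply, gi)
  tibble::tibble(
    year = year, n_lost_ply = n_lost_ply,
    lost_income = inc$cost, lost_income_lower = inc$lower,
    lost_income_upper = inc$upper,
    extra_welfare = wel$cost, extra_welfare_lower = wel$lower,
    extra_welfare_upper = wel$upper,
    lost_tax = tax$cost, lost_tax_lower = tax$lower,
    lost_tax_upper = tax$upper,
    lost_gdp = lg,
    potential_gdp_gain_pct = potential_gdp_gain_pct(
      lg, gi$gdp_millions))
}
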