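#' Specification of a counterfactual comparison
#'
#' Cases are always the lost-PLY group (out of the labour force due to
#' IHD).  The donor pool is one of: full-time employed without IHD,
#' part-time employed without IHD, or the whole labour force without IHD
#' (full-time, part-time or unemployed — the pool used for national
#' costs).  Matching is on sex, age band and highest educational
#' attainment; donors are sampled with replacement, by default with
#' probability proportional to their survey weight so the counterfactual
#' respects the population the pool represents (a uniform switch is
#' provided since the sampling law within a cell is a modelling choice).
#'
#' @param donor_pool One of `"ft_no_ihd"`, `"pt_no_ihd"`,
#'   `"labour_force_no_ihd"`.
#' @param n_sims Number of Monte-Carlo replicates.
#' @param ci_level Confidence level for the percentile interval.
#' @param match_vars Matching variables, most important first; fallback
#'   drops from the end, never below `(sex, age_group)`.
#' @param weight_proportional Sample donors proportional to weight
#'   (`TRUE`, default) or uniformly.
#' @param master_seed Integer master seed; replicate `k` uses a
#'   deterministic sub-seed derived from `(master_seed, k)`.
#' @return A list of class `counterfactual_spec`.
#' @export
counterfactual_spec <- function(donor_pool = c("labour_force_no_ihd",
                                               "ft_no_ihd", "pt_no_ihd"),
                                n_sims = 1000, ci_level = 0.95,
                                match_vars = c("sex", "age_group",
                                               "education"),
                                weight_proportional = TRUE,
                                master_seed = 1L) {
  donor_pool <- match.arg(donor_pool)
  stopifnot(n_sims >= 1, ci_level > 0, ci_level < 1,
            length(match_vars) >= 2,
            identical(match_vars[1:2], c("sex", "age_group")))
  structure(list(case_group = "nilf_ihd", donor_pool = donor_pool,
                 n_sims = as.integer(n_sims), ci_level = ci_level,
                 match_vars = match_vars,
                 weight_proportional = weight_proportional,
                 master_seed = as.integer(master_seed)),
            class = "counterfactual_spec")
}

## Subset of projected records forming a donor pool.
select_donor_pool <- function(records, donor_pool) {
  ihd <- is_ihd(records$main_condition)
  lfs <- records$labour_force_status
  keep <- switch(donor_pool,
                 ft_no_ihd = lfs == "employed_ft" & !ihd,
                 pt_no_ihd = lfs == "employed_pt" & !ihd,
                 labour_force_no_ihd = lfs %in% in_labour_force_lfs & !ihd,
                 stop("unknown donor pool: ", donor_pool, call. = FALSE))
  records[keep, , drop = FALSE]
}

## Precompute the sampling structure.  For every fallback depth d the
## donors are ordered by the depth-d key with a cumulative-weight vector;
## each case stores the depth at which its cell is first non-empty
## (variables dropped from the end of match_vars, never below
## (sex, age_group)) together with the (offset, mass) of that cell.  A
## weighted draw for case i is then: t = offset_i + u * mass_i; donor =
## ord[findInterval(t, cumw) + 1] in the depth-d structure.
prepare_counterfactual <- function(cases, donors, match_vars,
                                   weight_proportional = TRUE) {
  stopifnot(nrow(cases) > 0)
  if (nrow(donors) == 0) stop("empty donor pool", call. = FALSE)
  dw <- if (weight_proportional) donors$weight else rep(1, nrow(donors))

  n_cases <- nrow(cases)
  case_depth <- rep(NA_integer_, n_cases)
  case_base <- rep(NA_real_, n_cases)
  case_mass <- rep(NA_real_, n_cases)
  depth_struct <- list()

  max_depth <- length(match_vars) - 2
  assigned <- rep(FALSE, n_cases)
  for (depth in 0:max_depth) {
    vars <- match_vars[seq_len(length(match_vars) - depth)]
    dkey <- match_key(donors, vars)
    ord <- order(dkey)
    cumw <- cumsum(dw[ord])
    key_sorted <- dkey[ord]
    ends <- cumsum(rle(key_sorted)$lengths)
    starts <- c(1, utils::head(ends, -1) + 1)
    cell_keys <- key_sorted[starts]
    cell_base <- c(0, cumw[utils::head(ends, -1)])
    cell_mass <- cumw[ends] - cell_base
    depth_struct[[depth + 1]] <- list(ord = ord, cumw = cumw)

    open <- which(!assigned)
    if (!length(open)) break
    ckey <- match_key(cases[open, , drop = FALSE], vars)
    hit <- match(ckey, cell_keys)
    ok <- !is.na(hit)
    rows <- open[ok]
    case_depth[rows] <- depth
    case_base[rows] <- cell_base[hit[ok]]
    case_mass[rows] <- cell_mass[hit[ok]]
    assigned[rows] <- TRUE
  }

  if (!all(assigned)) {
    missing_keys <- unique(match_key(cases[!assigned, , drop = FALSE],
                                     match_vars[1:2]))
    stop("no donors available even at the (sex, age_group) key for ",
         "cell(s): ",
         paste(gsub("\r", "/", missing_keys), collapse = "; "),
         call. = FALSE)
  }

  list(depth_struct = depth_struct, case_depth = case_depth,
       case_base = case_base, case_mass = case_mass,
       n_donors = nrow(donors))
}

## One assignment: u is a vector of uniforms, one per case; returns donor
## row indices.
draw_assignment <- function(prep, u) {
  idx <- integer(length(u))
  for (d in unique(prep$case_depth)) {
    s <- prep$depth_struct[[d + 1]]
    sel <- prep$case_depth == d
    t <- prep$case_base[sel] + u[sel] * prep$case_mass[sel]
    j <- findInterval(t, s$cumw) + 1
    idx[sel] <- s$ord[pmin(j, prep$n_donors)]
  }
  idx
}

#' Draw one counterfactual assignment
#'
#' Assigns every case exactly one donor, sampled with replacement within
#' its matched cell (see [counterfactual_spec()] for the matching and
#' sampling rules).  Deterministic given `seed`.
#'
#' @param cases Case records (must carry the match variables, `weight`,
#'   and a `person_id`).
#' @param donors Donor records from the comparison pool.
#' @param match_vars Matching variables, most important first.
#' @param seed Integer seed.
#' @param weight_proportional Sample donors proportional to weight.
#' @return A tibble `case_id, donor_row, fallback_depth`.
#' @export
draw_counterfactual_set <- function(cases, donors,
                                    match_vars = c("sex", "age_group",
                                                   "education"),
                                    seed = 1L,
                                    weight_proportional = TRUE) {
  prep <- prepare_counterfactual(cases, donors, match_vars,
                                 weight_proportional)
  u <- withr::with_seed(seed, runif(nrow(cases)))
  idx <- draw_assignment(prep, u)
  tibble::tibble(case_id = cases$person_id,
                 donor_row = idx,
                 fallback_depth = prep$case_depth)
}

#' Weighted mean case-minus-counterfactual difference for one replicate
#'
#' \eqn{\sum_i w_i (x_i^{case} - x_i^{donor}) / \sum_i w_i} over cases
#' `i`, using the case survey weights.  Negative values mean cases
#' receive less than their counterfactuals.
#'
#' @param assignment Result of [draw_counterfactual_set()].
#' @param cases,donors The records the assignment refers to.
#' @param outcome One of `"income"`, `"welfare"`, `"tax"`.
#' @return A single number (AU$/week).
#' @export
replicate_difference <- function(assignment, cases, donors,
                                 outcome = c("income", "welfare",
                                             "tax")) {
  outcome <- match.arg(outcome)
  col <- paste0("weekly_", outcome)
  stopifnot(nrow(assignment) == nrow(cases))
  pos <- match(assignment$case_id, cases$person_id)
  w <- cases$weight[pos]
  sum(w * (cases[[col]][pos] - donors[[col]][assignment$donor_row])) /
    sum(w)
}

#' Run the counterfactual Monte-Carlo simulations
#'
#' Draws `spec$n_sims` independent counterfactual assignments (replicate
#' `k` seeded deterministically from `(master_seed, k)`) and records, for
#' each replicate, the weighted mean case-minus-counterfactual
#' difference for each of the three outcomes.
#'
#' @param spec A [counterfactual_spec()].
#' @param cases,donors Case and donor-pool records.
#' @return A tibble of draws `replicate, income, welfare, tax` with
#'   attribute `spec`.
#' @export
run_simulations <- function(spec, cases, donors) {
  stopifnot(inherits(spec, "counterfactual_spec"))
  prep <- prepare_counterfactual(cases, donors, spec$match_vars,
                                 spec$weight_proportional)
  w <- cases$weight
  sw <- sum(w)
  case_part <- c(income = sum(w * cases$weekly_income),
                 welfare = sum(w * cases$weekly_welfare),
                 tax = sum(w * cases$weekly_tax))
  dmat <- cbind(income = donors$weekly_income,
                welfare = donors$weekly_welfare,
                tax = donors$weekly_tax)
  draws <- matrix(NA_real_, spec$n_sims, 3,
                  dimnames = list(NULL, colnames(dmat)))
  for (k in seq_len(spec$n_sims)) {
    u <- withr::with_seed(sub_seed(spec$master_seed, k),
                          runif(nrow(cases)))
    idx <- draw_assignment(prep, u)
    draws[k, ] <- (case_part - colSums(w * dmat[idx, , drop = FALSE])) /
      sw
  }
  out <- tibble::as_tibble(draws)
  out <- dplyr::mutate(out, replicate = dplyr::row_number(),
                       .before = 1)
  attr(out, "spec") <- spec
  out
}

#' Percentile confidence interval from Monte-Carlo draws
#'
#' Nearest-rank empirical quantiles at `(1 - level)/2` and
#' `1 - (1 - level)/2`: with 1000 draws at level 0.95, the 25th and
#' 975th order statistics.
#'
#' @param draws Numeric vector of replicate values (length >= 2).
#' @param level Confidence level in (0, 1).
#' @return Named numeric vector `c(lower, upper)`.
#' @export
percentile_ci <- function(draws, level = 0.95) {
  if (length(draws) < 2) {
    stop("at least 2 draws are required for a percentile interval",
         call. = FALSE)
  }
  if (level <= 0 || level >= 1) {
    stop("ci level must lie strictly between 0 and 1", call. = FALSE)
  }
  n <- length(draws)
  a <- (1 - level) / 2
  lo <- max(1L, floor(n * a))
  hi <- min(n, ceiling(n * (1 - a)))
  s <- sort(draws)
  c(lower = s[lo], upper = s[hi])
}

#' Summarise draws into counterfactual estimates
#'
#' Point estimate is the mean of the replicate differences; the interval
#' is the percentile CI.
#'
#' @param draws Result of [run_simulations()].
#' @param level Confidence level (defaults to the spec's).
#' @return A tibble `outcome, donor_pool, estimate, lower, upper,
#'   n_sims`.
#' @export
summarise_draws <- function(draws, level = NULL) {
  spec <- attr(draws, "spec")
  level <- level %||% spec$ci_level
  rows <- lapply(c("income", "welfare", "tax"), function(oc) {
    ci <- percentile_ci(draws[[oc]], level)
    tibble::tibble(outcome = oc,
                   donor_pool = spec$donor_pool %||% NA_character_,
                   estimate = mean(draws[[oc]]),
                   lower = ci[["lower"]], upper = ci[["upper"]],
                   n_sims = nrow(draws))
  })
  dplyr::bind_rows(rows)
}

#' Counterfactual comparison on a projected population
#'
#' Convenience wrapper: splits a projected, imputed population into the
#' lost-PLY cases and the requested donor pool, runs the simulations and
#' summarises them.
#'
#' @param records Projected imputed records.
#' @param spec A [counterfactual_spec()].
#' @return A tibble of estimates (see [summarise_draws()]).
#' @export
run_counterfactual <- function(records, spec) {
  grp <- classify_group(records)
  cases <- records[grp == "nilf_ihd", , drop = FALSE]
  if (nrow(cases) == 0) {
    stop("no lost-PLY cases in the projected population", call. = FALSE)
  }
  donors <- select_donor_pool(records, spec$donor_pool)
  summarise_draws(run_simulations(spec, cases, donors))
}
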