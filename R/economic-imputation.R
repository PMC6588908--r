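#' Build an exact-key match index over a donor pool
#'
#' Keys donors by the ten matching variables in their fixed priority
#' order (`sex, age_group, labour_force_status, receives_dsp,
#' receives_age_pension, education, income_quintile, hours_band,
#' income_unit_type, home_owner`).  Every donor is reachable under its
#' exact key; lookup is exact-key only.
#'
#' @param donors Donor records (see [generate_donor_pool()]).
#' @param depth Number of variables dropped from the end of the priority
#'   order (0 = full ten-variable key).
#' @return A named list mapping key strings to integer vectors of donor
#'   row indices.
#' @export
build_match_index <- function(donors, depth = 0) {
  if (nrow(donors) == 0) stop("donor pool is empty", call. = FALSE)
  stopifnot(depth >= 0, depth <= length(match_vars_priority) - 2)
  vars <- match_vars_priority[seq_len(length(match_vars_priority) - depth)]
  split(seq_len(nrow(donors)), match_key(donors, vars))
}

match_key <- function(df, vars) {
  do.call(paste, c(lapply(df[vars], as.character), sep = "\r"))
}

#' Impute weekly income, welfare and tax by synthetic matching
#'
#' Hot-deck imputation: each base record receives the economic fields of
#' one donor sharing its most specific non-empty matching key.  Variables
#' are dropped from the end of the priority order (home ownership first)
#' until at least one donor exists; within the cell the donor is chosen
#' uniformly at random, with replacement across base records.  Records
#' with no donor even at the `{sex, age_group}` key are excluded and
#' counted.  Deterministic given `seed`.
#'
#' @param base Person records.
#' @param donors Donor records.
#' @param seed Integer seed.
#' @return A tibble of imputed persons: the base columns plus
#'   `weekly_income`, `weekly_welfare`, `weekly_tax`, `donor_id` and
#'   `fallback_depth`, with attribute `n_unmatched`.
#' @export
match_economic_data <- function(base, donors, seed) {
  if (nrow(base) == 0) stop("base population is empty", call. = FALSE)
  if (nrow(donors) == 0) stop("donor pool is empty", call. = FALSE)
  b <- base
  b$hours_band <- hours_band(b$hours_per_week)

  n <- nrow(b)
  chosen <- integer(n)
  depth_used <- integer(n)
  matched <- logical(n)
  max_depth <- length(match_vars_priority) - 2

  withr::with_seed(seed, {
    remaining <- seq_len(n)
    for (depth in 0:max_depth) {
      vars <- match_vars_priority[
        seq_len(length(match_vars_priority) - depth)]
      idx <- split(seq_len(nrow(donors)), match_key(donors, vars))
      bkey <- match_key(b[remaining, , drop = FALSE], vars)
      hit <- bkey %in% names(idx)
      if (any(hit)) {
        rows <- remaining[hit]
        cells <- idx[bkey[hit]]
        len <- lengths(cells)
        pick <- pmin(len, floor(runif(length(cells)) * len) + 1)
        chosen[rows] <- mapply(function(v, p) v[[p]], cells, pick)
        depth_used[rows] <- depth
        matched[rows] <- TRUE
        remaining <- remaining[!hit]
      }
      if (!length(remaining)) break
    }
  })

  n_unmatched <- sum(!matched)
  if (n_unmatched > 0) {
    message(n_unmatched,
            " base record(s) had no donor at any fallback depth and were",
            " excluded")
  }
  keep <- which(matched)
  out <- base[keep, , drop = FALSE]
  out$weekly_income <- donors$weekly_income[chosen[keep]]
  out$weekly_welfare <- donors$weekly_welfare[chosen[keep]]
  out$weekly_tax <- donors$weekly_tax[chosen[keep]]
  out$donor_id <- donors$donor_id[chosen[keep]]
  out$fallback_depth <- depth_used[keep]
  attr(out, "n_unmatched") <- n_unmatched
  out
}

#' Diagnostics for a synthetic-matching run
#'
#' @param imputed Result of [match_economic_data()].
#' @return A list: `n_matched`, `n_unmatched`, `match_rate`,
#'   `mean_fallback_depth`, `depth_table`, and `income_by_group` (weighted
#'   median weekly income per analysis group).
#' @export
imputation_diagnostics <- function(imputed) {
  n_un <- attr(imputed, "n_unmatched") %||% 0L
  n_m <- nrow(imputed)
  grp <- classify_group(imputed)
  by_grp <- tibble::tibble(group = grp,
                           weekly_income = imputed$weekly_income,
                           weight = imputed$weight) |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      n = dplyr::n(),
      median_weekly_income = weighted_median(.data$weekly_income,
                                             .data$weight),
      .groups = "drop")
  list(
    n_matched = n_m,
    n_unmatched = n_un,
    match_rate = n_m / (n_m + n_un),
    mean_fallback_depth = mean(imputed$fallback_depth),
    depth_table = as.list(table(imputed$fallback_depth)),
    income_by_group = by_grp)
}

#' Write imputation diagnostics as JSON
#'
#' @param diag Result of [imputation_diagnostics()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_diagnostics_json <- function(diag, path) {
  jsonlite::write_json(diag, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
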