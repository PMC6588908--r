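#' Is a main-condition code in the ischemic heart disease group?
#'
#' The IHD grouping pools the heart disease, angina and myocardial
#' infarction survey responses.
#'
#' @param main_condition Character vector of codes from the model
#'   codelist.
#' @return Logical vector.
#' @export
#' @examples
#' is_ihd(c("angina", "type2_diabetes", "none"))
is_ihd <- function(main_condition) {
  unknown <- setdiff(unique(main_condition), condition_codes)
  if (length(unknown)) {
    stop("unknown main_condition code(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  main_condition %in% ihd_codes
}

#' Identify a lost productive life year due to IHD
#'
#' A person contributes a lost PLY in a given year when they are not in
#' the labour force, their main reason is their own ill-health or
#' disability, and their main chronic condition is in the IHD group.
#'
#' @param records Person records (data frame) or vectors via the
#'   individual arguments.
#' @return Logical vector.
#' @export
identify_lost_ply <- function(records) {
  records$labour_force_status == "nilf" &
    records$nilf_reason == "own_ill_health" &
    is_ihd(records$main_condition)
}

#' Classify records into the five analysis groups plus the residual
#'
#' Full-time and part-time employment split by IHD status; out of the
#' labour force due to IHD per [identify_lost_ply()]; everything else
#' (the unemployed, those out of the labour force for other reasons, and
#' those out of the labour force due to ill-health with a non-IHD main
#' condition) falls into `other`.
#'
#' @param records Person records.
#' @return Character vector with values in
#'   `ft_no_ihd, ft_ihd, pt_no_ihd, pt_ihd, nilf_ihd, other`.
#' @export
classify_group <- function(records) {
  ihd <- is_ihd(records$main_condition)
  lfs <- records$labour_force_status
  out <- rep("other", nrow(records))
  out[lfs == "employed_ft" & !ihd] <- "ft_no_ihd"
  out[lfs == "employed_ft" & ihd] <- "ft_ihd"
  out[lfs == "employed_pt" & !ihd] <- "pt_no_ihd"
  out[lfs == "employed_pt" & ihd] <- "pt_ihd"
  out[identify_lost_ply(records)] <- "nilf_ihd"
  out
}

#' Weighted mean, standard deviation and median
#'
#' Survey-weighted statistics: mean \eqn{\sum w_i x_i / \sum w_i}, SD the
#' square root of the weighted mean squared deviation (same weights), and
#' median under the lower-median convention — the smallest observed value
#' whose cumulative weight reaches half the total (deterministic and
#' independent of record order).
#'
#' @param x Numeric values.
#' @param w Positive weights.
#' @return A single number.
#' @export
weighted_mean <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  sum(w * x) / sum(w)
}

#' @rdname weighted_mean
#' @export
weighted_sd <- function(x, w) {
  m <- weighted_mean(x, w)
  sqrt(sum(w * (x - m)^2) / sum(w))
}

#' @rdname weighted_mean
#' @export
weighted_median <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= sum(w) / 2)[1]]
}

#' Weighted summary of the analysis groups
#'
#' One row per analysis group and economic outcome: weighted population
#' count, share of the total population, and the weighted mean, SD and
#' median of the weekly amount.  Shares over all groups sum to one.
#' Empty groups are reported with a zero count and `NA` moments.
#'
#' @param records Imputed person records (weights plus `weekly_income`,
#'   `weekly_welfare`, `weekly_tax`).
#' @return A tibble `group, weighted_n, share, outcome, mean, sd,
#'   median`.
#' @export
group_summaries <- function(records) {
  stopifnot(all(records$weight > 0))
  grp <- factor(classify_group(records), levels = ply_groups)
  total_w <- sum(records$weight)
  long <- tibble::tibble(
    group = rep(grp, 3),
    weight = rep(records$weight, 3),
    outcome = rep(c("income", "welfare", "tax"), each = nrow(records)),
    value = c(records$weekly_income, records$weekly_welfare,
              records$weekly_tax))
  filled <- tidyr::expand_grid(group = factor(ply_groups, ply_groups),
                               outcome = c("income", "welfare", "tax"))
  long |>
    dplyr::group_by(.data$group, .data$outcome) |>
    dplyr::summarise(
      weighted_n = sum(.data$weight),
      mean = weighted_mean(.data$value, .data$weight),
      sd = weighted_sd(.data$value, .data$weight),
      median = weighted_median(.data$value, .data$weight),
      .groups = "drop") |>
    dplyr::right_join(filled, by = c("group", "outcome")) |>
    dplyr::mutate(
      weighted_n = dplyr::coalesce(.data$weighted_n, 0),
      share = .data$weighted_n / total_w,
      group = as.character(.data$group)) |>
    dplyr::select("group", "weighted_n", "share", "outcome", "mean",
                  "sd", "median") |>
    dplyr::arrange(match(.data$group, ply_groups), .data$outcome)
}
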