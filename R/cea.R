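#' Cost-effectiveness ratio
#'
#' The core cost-effectiveness statistic: societal cost divided by the
#' number of households achieving the outcome (stopping open defecation or
#' gaining ownership of a usable latrine), interpreted as the societal cost
#' to convert one household. The counterfactual is no change absent the
#' intervention.
#'
#' When the outcome count is zero or negative (the outcome worsened), the
#' ratio would be meaningless or misleadingly negative; such results are
#' returned as undefined (`NA` ratio, `defined = FALSE`) with an explanatory
#' note rather than an error, mirroring the convention of suppressing
#' negative ratios in reporting.
#'
#' @param total_cost Societal cost in currency units (non-negative;
#'   vectorized).
#' @param outcome_count Signed count of achieving households (vectorized).
#' @param outcome_measure Label: `"stopped_od"` or `"gained_ownership"`.
#' @param n_people,n_households Optional population sizes used to add a
#'   per-person ratio (cost per person in achieving households' population,
#'   i.e. per-household ratio divided by mean household size).
#' @param arm,country,region Labels carried into the result.
#' @return Tibble of class `clts_ce` with columns `total_cost`,
#'   `outcome_count`, `ce_per_household`, `ce_per_person`, `defined`,
#'   `note`.
#' @export
#' @examples
#' cost_effectiveness(576061, 1605, "stopped_od")
cost_effectiveness <- function(total_cost, outcome_count,
                               outcome_measure = "stopped_od",
                               n_people = NA_real_, n_households = NA_real_,
                               arm = NA_character_, country = NA_character_,
                               region = NA_character_) {
  check_nonneg(total_cost, "total_cost")
  outcome_measure <- match.arg(outcome_measure, OUTCOME_MEASURES,
                               several.ok = TRUE)
  defined <- outcome_count > 0
  ce_hh <- ifelse(defined, total_cost / outcome_count, NA_real_)
  note <- dplyr::case_when(
    outcome_count > 0 ~ "",
    outcome_count == 0 ~ "no households achieved the outcome",
    TRUE ~ "outcome worsened; negative ratio suppressed"
  )
  out <- tibble::tibble(
    arm = arm, country = country, region = region,
    outcome_measure = outcome_measure,
    total_cost = total_cost, outcome_count = outcome_count,
    n_households = n_households, n_people = n_people,
    ce_per_household = ce_hh,
    ce_per_person = per_person(ce_hh, n_people, n_households),
    defined = defined, note = note
  )
  class(out) <- c("clts_ce", class(out))
  out
}

#' Convert a per-household ratio to a per-person ratio
#'
#' Divides the per-household cost-effectiveness ratio by the mean household
#' size (`n_people / n_households`). Undefined ratios propagate as `NA`.
#'
#' @param ce Per-household ratio(s): a numeric vector or a `clts_ce` tibble
#'   (whose `ce_per_household` column is used).
#' @param n_people,n_households Population totals defining mean household
#'   size; must be positive.
#' @return Numeric vector of per-person ratios.
#' @export
#' @examples
#' per_person(358.92, 58248, 12217)
per_person <- function(ce, n_people, n_households) {
  if (inherits(ce, "clts_ce")) ce <- ce$ce_per_household
  ifelse(!is.na(ce) & !is.na(n_people) & !is.na(n_households) &
           n_people > 0 & n_households > 0,
         ce / (n_people / n_households), NA_real_)
}

#' Incremental cost-effectiveness ratio
#'
#' The extra cost per extra unit of outcome of a comparator intervention
#' over a reference: `(cost_c - cost_r) / (outcome_c - outcome_r)`. The
#' result is labeled by its quadrant on the cost-effectiveness plane:
#' a comparator that is both cheaper and more effective is `"dominant"`, one
#' that is costlier and less effective is `"dominated"`, otherwise the ICER
#' quantifies a genuine trade-off. Equal outcomes give an undefined ICER.
#'
#' @param reference,comparator Numeric vectors or lists with elements
#'   `cost` and `outcome` (achieving-household counts on the same outcome
#'   measure and population).
#' @return One-row tibble with `delta_cost`, `delta_outcome`, `icer`,
#'   `defined`, `quadrant`, `note`.
#' @export
#' @examples
#' icer(c(cost = 36739, outcome = 168), c(cost = 63348, outcome = 421))
icer <- function(reference, comparator) {
  ref <- as.list(reference)
  cmp <- as.list(comparator)
  d_cost <- cmp$cost - ref$cost
  d_out <- cmp$outcome - ref$outcome
  if (d_out == 0) {
    return(tibble::tibble(
      delta_cost = d_cost, delta_outcome = 0, icer = NA_real_,
      defined = FALSE, quadrant = "indeterminate",
      note = "no incremental effect"
    ))
  }
  quadrant <- if (d_out > 0 && d_cost <= 0) {
    "dominant"
  } else if (d_out < 0 && d_cost >= 0) {
    "dominated"
  } else if (d_out > 0) {
    "trade-off: more effective, more costly"
  } else {
    "trade-off: less effective, cheaper"
  }
  tibble::tibble(
    delta_cost = d_cost, delta_outcome = d_out, icer = d_cost / d_out,
    defined = TRUE, quadrant = quadrant, note = ""
  )
}
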