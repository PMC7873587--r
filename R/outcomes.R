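#' Classify usable-latrine ownership from observation
#'
#' A household counts as owning a usable latrine only if a latrine was
#' actually observed on the day of surveying, had stable flooring, and was
#' not full. Latrines that were full, unstable, or could not be observed do
#' not count, and any missing observation field defaults to not-usable.
#' This observation-validated rule guards against the known optimism of
#' self-reported latrine ownership.
#'
#' @param records A household-record tibble (see [generate_households()] for
#'   the schema); the relevant columns are `latrine_observed`,
#'   `latrine_floor_stable` and `latrine_full`.
#' @return Logical vector, one element per record.
#' @export
classify_usable_latrine <- function(records) {
  observed <- records$latrine_observed %in% TRUE
  stable <- records$latrine_floor_stable %in% TRUE
  full <- records$latrine_full %in% TRUE
  observed & stable & !full
}

#' Classify household defecation practice
#'
#' Collapses reported practice into the binary outcome used for
#' cost-effectiveness: `latrine_use` covers private, shared and communal
#' latrine use; everything else is `open_defecation`. Self-reported private
#' latrine use is validated against observation: households reporting a
#' private latrine that is full, unstable or unobservable are reclassified
#' as open defecation. Shared and communal use cannot be validated at the
#' household's own latrine and is taken as reported.
#'
#' @inheritParams classify_usable_latrine
#' @return Character vector of `"open_defecation"` / `"latrine_use"`.
#' @export
classify_defecation <- function(records) {
  practice <- records$reported_practice
  bad <- setdiff(unique(practice), REPORTED_PRACTICES)
  if (length(bad) > 0L) {
    stop("unknown reported_practice value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  usable <- classify_usable_latrine(records)
  use <- practice %in% c("shared_latrine", "communal_latrine") |
    (practice == "private_latrine" & usable)
  ifelse(use, "latrine_use", "open_defecation")
}

#' Estimate baseline ownership from latrine-age recall
#'
#' Where no baseline survey exists, baseline coverage can be estimated from
#' the follow-up survey by asking how old each latrine is: a usable latrine
#' older than the elapsed intervention window must predate the intervention.
#'
#' @param records Follow-up wave household records with `latrine_age_months`
#'   populated for latrine-owning households.
#' @param window_months Months elapsed between intervention start and the
#'   follow-up survey.
#' @return Fraction of households whose usable latrine predates the
#'   intervention.
#' @export
recall_baseline_ownership <- function(records, window_months) {
  check_nonneg(window_months, "window_months")
  usable <- classify_usable_latrine(records)
  ages <- records$latrine_age_months
  if (any(usable) && all(is.na(ages[usable]))) {
    stop("latrine_age_months is missing for every latrine-owning household; ",
         "recall-based baseline estimation needs latrine ages", call. = FALSE)
  }
  mean(usable & !is.na(ages) & ages > window_months)
}

#' Conservative baseline open defecation
#'
#' Without a baseline survey, a conservative assumption is that every
#' decrease in open defecation came from an increase in latrine ownership,
#' so baseline OD = follow-up OD + change in ownership. The result is an
#' assumption-derived estimate, clamped to [0, 1] with a warning when the
#' arithmetic exceeds the unit interval.
#'
#' @param followup_od Follow-up open-defecation fraction.
#' @param delta_ownership Signed change in usable-latrine ownership
#'   (follow-up minus baseline).
#' @return Baseline OD fraction, with attribute `assumed = TRUE`.
#' @export
#' @examples
#' conservative_baseline_od(0.40, 0.09) # 0.49, so delta OD = -0.09
conservative_baseline_od <- function(followup_od, delta_ownership) {
  check_fraction(followup_od, "followup_od")
  check_fraction(delta_ownership, "delta_ownership", lo = -1, hi = 1)
  est <- followup_od + delta_ownership
  if (est < 0 || est > 1) {
    warning(sprintf(
      "conservative baseline OD %.3f outside [0, 1]; clamped", est),
      call. = FALSE)
    est <- min(max(est, 0), 1)
  }
  structure(est, assumed = TRUE)
}

#' Outcome change from known fractions
#'
#' Low-level constructor for an outcome-change row. Changes are follow-up
#' minus baseline fractions; achieving-household counts are derived from the
#' unrounded fractions and then rounded half-away-from-zero, with the sign
#' convention that a decrease in open defecation yields a positive count of
#' households stopping OD. Worsened outcomes give negative counts, which are
#' retained (not clipped) and flagged downstream.
#'
#' @param baseline_od,followup_od Open-defecation fractions per wave.
#' @param baseline_ownership,followup_ownership Usable-latrine ownership
#'   fractions per wave.
#' @param n_households,n_people Denominators for the population covered.
#' @param arm,country,region Labels carried into the result.
#' @return One-row tibble of class `clts_outcome` with columns `delta_od`,
#'   `delta_ownership`, `households_stopping_od`,
#'   `households_gaining_ownership` and the labels/denominators.
#' @export
outcome_change <- function(baseline_od, followup_od, baseline_ownership,
                           followup_ownership, n_households, n_people,
                           arm = NA_character_, country = NA_character_,
                           region = NA_character_) {
  check_fraction(baseline_od, "baseline_od")
  check_fraction(followup_od, "followup_od")
  check_fraction(baseline_ownership, "baseline_ownership")
  check_fraction(followup_ownership, "followup_ownership")
  if (n_households <= 0) stop("n_households must be positive", call. = FALSE)
  delta_od <- followup_od - baseline_od
  delta_own <- followup_ownership - baseline_ownership
  out <- tibble::tibble(
    arm = arm, country = country, region = region,
    n_households = n_households, n_people = n_people,
    delta_od = delta_od, delta_ownership = delta_own,
    households_stopping_od = round_half_away(-delta_od * n_households),
    households_gaining_ownership = round_half_away(delta_own * n_households)
  )
  class(out) <- c("clts_outcome", class(out))
  out
}

#' Compute outcome change from a two-wave household panel
#'
#' Classifies each wave with [classify_defecation()] and
#' [classify_usable_latrine()] and summarizes the change between waves.
#' Denominators (`n_households`, `n_people`) are taken from the follow-up
#' wave. Both waves must cover the same arm and region.
#'
#' @param records Household records containing both survey waves
#'   (`survey_wave` of `"baseline"` and `"followup"`), or the follow-up wave
#'   only if `baseline` is supplied.
#' @param baseline Optional: either a baseline-wave record tibble, or a
#'   named list/vector with elements `od` and `ownership` giving estimated
#'   baseline fractions (e.g. from [recall_baseline_ownership()] and
#'   [conservative_baseline_od()]).
#' @return One-row `clts_outcome` tibble (see [outcome_change()]).
#' @export
compute_outcome_change <- function(records, baseline = NULL) {
  records <- tibble::as_tibble(records)
  if (is.null(baseline)) {
    base <- records[records$survey_wave == "baseline", ]
    follow <- records[records$survey_wave == "followup", ]
  } else if (is.data.frame(baseline)) {
    base <- tibble::as_tibble(baseline)
    follow <- records
  } else {
    base <- NULL
    follow <- records
  }
  if (nrow(follow) == 0L) stop("no follow-up records", call. = FALSE)
  lab <- function(x) if (length(u <- unique(x[!is.na(x)])) == 1L) u else "All"
  arm <- lab(follow$arm)
  region <- lab(follow$region)
  country <- if ("country" %in% names(follow)) lab(follow$country) else NA_character_
  wave_fractions <- function(w) {
    c(od = mean(classify_defecation(w) == "open_defecation"),
      ownership = mean(classify_usable_latrine(w)))
  }
  f <- wave_fractions(follow)
  if (is.null(base)) {
    b <- c(od = unname(baseline[["od"]]), ownership = unname(baseline[["ownership"]]))
  } else {
    if (nrow(base) == 0L) stop("no baseline records", call. = FALSE)
    if (!setequal(unique(base$arm), unique(follow$arm)) ||
        !setequal(unique(base$region), unique(follow$region))) {
      stop("baseline and follow-up waves cover different arm/region",
           call. = FALSE)
    }
    b <- wave_fractions(base)
  }
  outcome_change(
    baseline_od = b[["od"]], followup_od = f[["od"]],
    baseline_ownership = b[["ownership"]], followup_ownership = f[["ownership"]],
    n_households = nrow(follow), n_people = sum(follow$n_members),
    arm = arm, country = country, region = region
  )
}

#' Aggregate outcome changes across regions
#'
#' Pools regional outcome rows by summing denominators and achieving-household
#' counts; pooled deltas are recomputed as household-weighted means, so the
#' pooled row is internally consistent (count = -delta * n up to rounding).
#'
#' @param outcomes A `clts_outcome` tibble with one row per member.
#' @inheritParams aggregate_ledgers
#' @return One-row `clts_outcome` tibble.
#' @export
aggregate_outcomes <- function(outcomes, arm = NULL, country = NULL,
                               region = NULL, scope = "aggregate") {
  outcomes <- tibble::as_tibble(outcomes)
  if (nrow(outcomes) == 0L) stop("no outcome rows to aggregate", call. = FALSE)
  union_label <- function(x, given) {
    if (!is.null(given)) return(given)
    u <- unique(x[!is.na(x)])
    if (length(u) == 1L) u else "All"
  }
  n_hh <- sum(outcomes$n_households)
  out <- tibble::tibble(
    arm = union_label(outcomes$arm, arm),
    country = union_label(outcomes$country, country),
    region = union_label(outcomes$region, region),
    n_households = n_hh,
    n_people = sum(outcomes$n_people),
    delta_od = -sum(outcomes$households_stopping_od) / n_hh,
    delta_ownership = sum(outcomes$households_gaining_ownership) / n_hh,
    households_stopping_od = sum(outcomes$households_stopping_od),
    households_gaining_ownership = sum(outcomes$households_gaining_ownership)
  )
  if ("scope" %in% names(outcomes)) out$scope <- scope
  class(out) <- c("clts_outcome", class(out))
  out
}
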