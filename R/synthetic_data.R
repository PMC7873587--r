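#' Define a regional survey profile
#'
#' A profile captures the statistical structure of one study region:
#' household demographics, baseline sanitation levels, intervention effect
#' sizes, and spending behavior. Profiles drive [generate_households()],
#' which simulates a two-wave household panel with these margins.
#'
#' The generator draws usable-latrine ownership and latrine use
#' independently at baseline (ownership and use need not coincide: many
#' owners do not use their latrine, and many users share a neighbor's), so
#' the fraction of latrine users who own their own latrine equals
#' `baseline_ownership`. `shared_use_fraction` splits the remaining
#' (non-owner) users between "shared" and "communal" reporting labels.
#'
#' @param region_name,country Labels.
#' @param mean_village_size Mean households per village.
#' @param household_size_mean,household_size_sd Household size is drawn from
#'   a rounded normal truncated at 1 person (realized means therefore sit
#'   slightly above nominal for small means).
#' @param baseline_ownership Baseline fraction of households owning a usable
#'   latrine (observed, stable floor, not full).
#' @param baseline_od Baseline fraction of households practicing open
#'   defecation; latrine use is its complement.
#' @param delta_od,delta_ownership Signed changes (follow-up minus baseline)
#'   in the OD and usable-ownership fractions. Transitions are simulated at
#'   the household level (e.g. each baseline-OD household stops OD with
#'   probability `-delta_od / baseline_od`), preserving panel structure.
#' @param shared_use_fraction Fraction of non-owner latrine users reporting
#'   a shared (vs communal) facility.
#' @param unusable_fraction Fraction of non-owner households with an
#'   unusable latrine (full, unstable flooring, or unobservable) on survey
#'   day.
#' @param hardware_spend_mean,hired_labor_spend_mean Mean USD spent on
#'   latrine hardware / hired construction labor by households that gain a
#'   latrine (right-skewed lognormal with many zeros elsewhere).
#' @param community_hours_mean Mean unpaid sanitation labor hours for
#'   latrine-gaining households.
#' @param survey_window_months Months between intervention start and the
#'   follow-up survey (drives latrine-age recall).
#' @return A list of class `clts_profile`.
#' @export
region_profile <- function(region_name, country,
                           mean_village_size,
                           household_size_mean, household_size_sd = 2,
                           baseline_ownership, baseline_od,
                           delta_od = 0, delta_ownership = 0,
                           shared_use_fraction = 0.5,
                           unusable_fraction = 0.2,
                           hardware_spend_mean = 5,
                           hired_labor_spend_mean = 0,
                           community_hours_mean = 5,
                           survey_window_months = 24) {
  check_fraction(baseline_ownership, "baseline_ownership")
  check_fraction(baseline_od, "baseline_od")
  check_fraction(delta_od, "delta_od", lo = -1, hi = 1)
  check_fraction(delta_ownership, "delta_ownership", lo = -1, hi = 1)
  check_fraction(shared_use_fraction, "shared_use_fraction")
  check_fraction(unusable_fraction, "unusable_fraction")
  check_nonneg(mean_village_size, "mean_village_size")
  check_nonneg(household_size_sd, "household_size_sd")
  check_nonneg(hardware_spend_mean, "hardware_spend_mean")
  check_nonneg(hired_labor_spend_mean, "hired_labor_spend_mean")
  check_nonneg(community_hours_mean, "community_hours_mean")
  check_nonneg(survey_window_months, "survey_window_months")
  if (household_size_mean <= 0) {
    stop("`household_size_mean` must be positive", call. = FALSE)
  }
  followup_od <- baseline_od + delta_od
  followup_own <- baseline_ownership + delta_ownership
  check_fraction(followup_od, "baseline_od + delta_od")
  check_fraction(followup_own, "baseline_ownership + delta_ownership")
  structure(
    list(region_name = region_name, country = country,
         mean_village_size = mean_village_size,
         household_size_mean = household_size_mean,
         household_size_sd = household_size_sd,
         baseline_ownership = baseline_ownership, baseline_od = baseline_od,
         delta_od = delta_od, delta_ownership = delta_ownership,
         shared_use_fraction = shared_use_fraction,
         unusable_fraction = unusable_fraction,
         hardware_spend_mean = hardware_spend_mean,
         hired_labor_spend_mean = hired_labor_spend_mean,
         community_hours_mean = community_hours_mean,
         survey_window_months = survey_window_months),
    class = "clts_profile")
}

#' Built-in study region profiles
#'
#' Profiles for the five study regions, calibrated to the published regional
#' survey characteristics (baseline latrine ownership 10%-98%, baseline OD
#' 27%-96%, household sizes 3.3-6.4, village sizes 29-123 households) with
#' effect sizes taken from the conventional-CLTS arm in each region. The
#' Ethiopian interventions ran 12 months with a follow-up survey 2 years
#' after baseline; the Ghanaian ones were surveyed 2.5 years after start.
#'
#' @return Named list of `clts_profile` objects
#'   (`Oromia`, `SNNP`, `Central`, `Upper West`, `Volta`).
#' @export
study_region_profiles <- function() {
  list(
    "Oromia" = region_profile(
      "Oromia", "Ethiopia", mean_village_size = 29,
      household_size_mean = 6.1, household_size_sd = 2.2,
      baseline_ownership = 0.51, baseline_od = 0.70,
      delta_od = -0.48, delta_ownership = 0.43,
      shared_use_fraction = 0.2, unusable_fraction = 0.25,
      hardware_spend_mean = 3, hired_labor_spend_mean = 0,
      community_hours_mean = 6, survey_window_months = 24),
    "SNNP" = region_profile(
      "SNNP", "Ethiopia", mean_village_size = 38,
      household_size_mean = 5.6, household_size_sd = 2.2,
      baseline_ownership = 0.98, baseline_od = 0.27,
      delta_od = 0.15, delta_ownership = -0.22,
      shared_use_fraction = 0.2, unusable_fraction = 0.4,
      hardware_spend_mean = 2, hired_labor_spend_mean = 0,
      community_hours_mean = 5, survey_window_months = 24),
    "Central" = region_profile(
      "Central", "Ghana", mean_village_size = 64,
      household_size_mean = 3.3, household_size_sd = 1.8,
      baseline_ownership = 0.24, baseline_od = 0.34,
      delta_od = -0.06, delta_ownership = 0.07,
      shared_use_fraction = 0.7, unusable_fraction = 0.2,
      hardware_spend_mean = 10, hired_labor_spend_mean = 4,
      community_hours_mean = 4, survey_window_months = 30),
    "Upper West" = region_profile(
      "Upper West", "Ghana", mean_village_size = 68,
      household_size_mean = 6.4, household_size_sd = 2.4,
      baseline_ownership = 0.10, baseline_od = 0.96,
      delta_od = -0.13, delta_ownership = 0.08,
      shared_use_fraction = 0.7, unusable_fraction = 0.2,
      hardware_spend_mean = 8, hired_labor_spend_mean = 3,
      community_hours_mean = 4, survey_window_months = 30),
    "Volta" = region_profile(
      "Volta", "Ghana", mean_village_size = 123,
      household_size_mean = 3.6, household_size_sd = 1.8,
      baseline_ownership = 0.25, baseline_od = 0.36,
      delta_od = -0.09, delta_ownership = 0.12,
      shared_use_fraction = 0.7, unusable_fraction = 0.2,
      hardware_spend_mean = 12, hired_labor_spend_mean = 5,
      community_hours_mean = 4, survey_window_months = 30)
  )
}

#' Generate a synthetic two-wave household survey panel
#'
#' Simulates `n` households through baseline and follow-up surveys with the
#' margins of a regional profile. Baseline usable-latrine ownership and
#' latrine use are drawn independently per household; between waves each
#' household transitions at the individual level (OD households stop OD with
#' probability `-delta_od / baseline_od` when OD falls; non-owners gain a
#' usable latrine with probability `delta_ownership / (1 - ownership)` when
#' ownership rises; worsening directions are symmetric). Reported practice
#' follows from the wave's states: users owning a usable latrine report
#' private use, other users report shared/communal facilities, non-users
#' report open defecation. Running [compute_outcome_change()] on the result
#' therefore recovers the profile's fractions and deltas up to binomial
#' noise.
#'
#' @param profile A `clts_profile` (see [region_profile()]).
#' @param n Number of households (>= 0).
#' @param seed Integer seed; the (profile, n, seed) triple fully determines
#'   the output.
#' @param arm Intervention arm label stamped on the records.
#' @return Tibble of `2 * n` household records (one row per household per
#'   wave) with columns `household_id`, `village_id`, `arm`, `country`,
#'   `region`, `n_members`, `survey_wave`, `reported_practice`,
#'   `latrine_observed`, `latrine_full`, `latrine_floor_stable`,
#'   `latrine_age_months`, `hardware_spend`, `hired_labor_spend`,
#'   `sanitation_hours`.
#' @export
generate_households <- function(profile, n, seed, arm = "CLTS") {
  stopifnot(inherits(profile, "clts_profile"))
  if (n < 0) stop("`n` must be >= 0", call. = FALSE)
  cols <- function(k) tibble::tibble(
    household_id = character(k), village_id = character(k),
    arm = character(k), country = character(k), region = character(k),
    n_members = integer(k), survey_wave = character(k),
    reported_practice = character(k), latrine_observed = logical(k),
    latrine_full = logical(k), latrine_floor_stable = logical(k),
    latrine_age_months = numeric(k), hardware_spend = numeric(k),
    hired_labor_spend = numeric(k), sanitation_hours = numeric(k))
  if (n == 0L) return(cols(0L))

  p <- profile
  with_seed_if(seed, {
    n_villages <- max(1L, as.integer(round(n / p$mean_village_size)))
    village <- sample.int(n_villages, n, replace = TRUE)
    size <- pmax(1L, as.integer(round(rnorm(n, p$household_size_mean,
                                            p$household_size_sd))))
    own0 <- runif(n) < p$baseline_ownership
    use0 <- runif(n) >= p$baseline_od

    # household-level transitions between waves
    own1 <- own0
    if (p$delta_ownership > 0) {
      gain_p <- p$delta_ownership / (1 - p$baseline_ownership)
      own1[!own0] <- runif(sum(!own0)) < gain_p
    } else if (p$delta_ownership < 0) {
      lose_p <- -p$delta_ownership / p$baseline_ownership
      own1[own0] <- runif(sum(own0)) >= lose_p
    }
    use1 <- use0
    if (p$delta_od < 0) {
      stop_p <- -p$delta_od / p$baseline_od
      use1[!use0] <- runif(sum(!use0)) < stop_p
    } else if (p$delta_od > 0) {
      relapse_p <- p$delta_od / (1 - p$baseline_od)
      use1[use0] <- runif(sum(use0)) >= relapse_p
    }
    gained <- own1 & !own0

    wave <- function(own, use, which_wave) {
      k <- n
      practice <- ifelse(!use, "open_defecation",
                         ifelse(own, "private_latrine",
                                ifelse(runif(k) < p$shared_use_fraction,
                                       "shared_latrine", "communal_latrine")))
      # non-owners may still have an unusable latrine standing
      has_unusable <- !own & (runif(k) < p$unusable_fraction)
      fail_mode <- sample(c("full", "unstable", "unobserved"), k,
                          replace = TRUE)
      observed <- own | (has_unusable & fail_mode != "unobserved")
      full <- ifelse(own, FALSE,
                     ifelse(has_unusable & fail_mode == "full", TRUE,
                            ifelse(observed, FALSE, NA)))
      stable <- ifelse(own, TRUE,
                       ifelse(has_unusable & fail_mode == "unstable", FALSE,
                              ifelse(observed, TRUE, NA)))
      age <- rep(NA_real_, k)
      has_latrine <- own | has_unusable
      if (which_wave == "baseline") {
        age[has_latrine] <- runif(sum(has_latrine), 0, 120)
        hardware <- hired <- hours <- numeric(k)
      } else {
        new <- gained
        old <- has_latrine & !new
        age[new] <- runif(sum(new), 0, p$survey_window_months)
        age[old] <- p$survey_window_months + runif(sum(old), 0, 60)
        # right-skewed spending with many zeros: only latrine-gaining
        # households spend during the study window
        lspend <- function(m) if (m > 0)
          rlnorm(k, meanlog = log(m) - 0.5, sdlog = 1) else numeric(k)
        hardware <- ifelse(new, lspend(p$hardware_spend_mean), 0)
        hired <- ifelse(new & runif(k) < 0.5,
                        lspend(2 * p$hired_labor_spend_mean), 0)
        hours <- ifelse(new, lspend(p$community_hours_mean), 0)
      }
      tibble::tibble(
        household_id = sprintf("%s-H%05d", p$region_name, seq_len(k)),
        village_id = sprintf("%s-V%03d", p$region_name, village),
        arm = arm, country = p$country, region = p$region_name,
        n_members = size, survey_wave = which_wave,
        reported_practice = practice, latrine_observed = observed,
        latrine_full = full, latrine_floor_stable = stable,
        latrine_age_months = age, hardware_spend = hardware,
        hired_labor_spend = hired, sanitation_hours = hours)
    }
    dplyr::bind_rows(wave(own0, use0, "baseline"), wave(own1, use1, "followup"))
  })
}

#' Generate a synthetic cost ledger
#'
#' Builds a single-row cost ledger from supplied per-category totals,
#' optionally perturbed multiplicatively by a uniform relative jitter
#' (useful for stress-testing downstream stages with cost variation).
#'
#' @param arm,region,country Labels.
#' @param totals Named numeric vector of non-negative category amounts; the
#'   names must be cost categories (`management`, `training`,
#'   `facilitation`, `local_actor_time`, `community_time`, `hired_labor`,
#'   `hardware`); omitted categories are 0.
#' @param jitter Relative half-width in `[0, 1)`; with `jitter = 0` the
#'   ledger equals the supplied totals, otherwise each category is scaled by
#'   an independent uniform factor in `[1 - jitter, 1 + jitter]`.
#' @param seed Integer seed for the jitter draws.
#' @return Single-row `clts_ledger`.
#' @export
#' @examples
#' generate_cost_ledger("HEW CLTS", "Oromia",
#'                      c(management = 4345, training = 9979))
generate_cost_ledger <- function(arm, region, totals, jitter = 0,
                                 seed = NULL, country = NA_character_) {
  bad <- setdiff(names(totals), COST_CATEGORIES)
  if (length(bad) > 0L) {
    stop("unknown cost categories: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  check_nonneg(totals, "totals")
  check_fraction(jitter, "jitter", lo = 0, hi = 1 - 1e-12)
  amounts <- stats::setNames(rep(0, length(COST_CATEGORIES)), COST_CATEGORIES)
  amounts[names(totals)] <- totals
  if (jitter > 0) {
    amounts <- with_seed_if(seed,
      amounts * (1 + runif(length(amounts), -jitter, jitter)))
  }
  as_cost_ledger(tibble::as_tibble(c(
    list(arm = arm, country = country, region = region, scope = "region"),
    as.list(amounts))))
}
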