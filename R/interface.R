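SURVEY_COLUMNS <- c(
  "household_id", "village_id", "arm", "country", "region", "n_members",
  "survey_wave", "reported_practice", "latrine_observed", "latrine_full",
  "latrine_floor_stable", "latrine_age_months", "hardware_spend",
  "hired_labor_spend", "sanitation_hours"
)

LEDGER_CSV_COLUMNS <- c("arm", "country", "region", "scope", "category",
                        "amount_usd")

check_columns <- function(df, mandatory, what, path) {
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("%s %s is missing mandatory column(s): %s",
                 what, path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(names(df), mandatory)
  if (length(extra) > 0L) {
    warning(sprintf("%s %s has unknown column(s), ignored: %s",
                    what, path, paste(extra, collapse = ", ")),
            call. = FALSE)
  }
  df[, mandatory]
}

#' Read and write household survey records
#'
#' One row per household per survey wave, in the schema produced by
#' [generate_households()]. Round-trips are lossless.
#'
#' @param path CSV file path.
#' @param records Household record tibble.
#' @return `read_survey_csv()` returns the record tibble;
#'   `write_survey_csv()` returns `path` invisibly.
#' @export
read_survey_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(
                          latrine_observed = readr::col_logical(),
                          latrine_full = readr::col_logical(),
                          latrine_floor_stable = readr::col_logical(),
                          .default = readr::col_guess()))
  if (nrow(df) == 0L) {
    warning("empty survey file: ", path, call. = FALSE)
    return(generate_households(study_region_profiles()[[1]], 0L, seed = 1L))
  }
  check_columns(df, SURVEY_COLUMNS, "survey CSV", path)
}

#' @rdname read_survey_csv
#' @export
write_survey_csv <- function(records, path) {
  readr::write_csv(records[, SURVEY_COLUMNS], path)
  invisible(path)
}

#' Read and write cost ledgers
#'
#' The on-disk form is long: one row per (arm, country, region, scope,
#' category) with an `amount_usd` column; optional `hours` and
#' `rate_usd_per_hour` columns monetize time categories when `amount_usd`
#' is missing. In memory a ledger is wide (see [as_cost_ledger()]).
#'
#' @param path CSV file path.
#' @param ledgers A `clts_ledger` tibble.
#' @return `read_ledger_csv()` returns a `clts_ledger`;
#'   `write_ledger_csv()` returns `path` invisibly.
#' @export
read_ledger_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (nrow(df) == 0L) {
    warning("empty ledger file: ", path, call. = FALSE)
    return(as_cost_ledger(tibble::tibble(arm = character(),
                                         region = character())))
  }
  has_time <- all(c("hours", "rate_usd_per_hour") %in% names(df))
  if (has_time) {
    df$amount_usd <- ifelse(
      is.na(df$amount_usd),
      monetize_time(ifelse(is.na(df$hours), 0, df$hours),
                    ifelse(is.na(df$rate_usd_per_hour), 0,
                           df$rate_usd_per_hour)),
      df$amount_usd)
    df <- df[, setdiff(names(df), c("hours", "rate_usd_per_hour"))]
  }
  df <- check_columns(df, LEDGER_CSV_COLUMNS, "ledger CSV", path)
  bad <- setdiff(unique(df$category), COST_CATEGORIES)
  if (length(bad) > 0L) {
    stop("ledger CSV ", path, " has unknown categories: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  wide <- tidyr::pivot_wider(df, names_from = "category",
                             values_from = "amount_usd", values_fill = 0)
  as_cost_ledger(wide)
}

#' @rdname read_ledger_csv
#' @export
write_ledger_csv <- function(ledgers, path) {
  ledgers <- as_cost_ledger(ledgers)
  long <- tidyr::pivot_longer(ledgers, dplyr::all_of(COST_CATEGORIES),
                              names_to = "category",
                              values_to = "amount_usd")
  readr::write_csv(long, path)
  invisible(path)
}

#' Read and write outcome-change tables
#'
#' One row per (arm, country, region) with population denominators, signed
#' deltas and achieving-household counts, as produced by
#' [compute_outcome_change()] / [aggregate_outcomes()].
#'
#' @param path CSV file path.
#' @param outcomes A `clts_outcome` tibble.
#' @return `read_outcomes_csv()` returns a `clts_outcome` tibble;
#'   `write_outcomes_csv()` returns `path` invisibly.
#' @export
read_outcomes_csv <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  mandatory <- c("arm", "country", "region", "n_households", "n_people",
                 "households_stopping_od", "households_gaining_ownership")
  missing <- setdiff(mandatory, names(df))
  if (length(missing) > 0L) {
    stop("outcomes CSV ", path, " is missing mandatory column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  out <- tibble::as_tibble(df)
  class(out) <- c("clts_outcome", class(out))
  out
}

#' @rdname read_outcomes_csv
#' @export
write_outcomes_csv <- function(outcomes, path) {
  readr::write_csv(outcomes, path)
  invisible(path)
}

#' Bundled study fixture: published cost categories and outcome counts
#'
#' The package ships the printed per-column cost-category amounts and
#' outcome counts of the four-intervention CLTS evaluation (10 regional
#' columns, 4 per-arm country roll-ups, 1 pooled column). The regional rows
#' (`scope == "region"`) are the computational inputs; the printed roll-ups
#' serve as a regression surface for the pipeline's own aggregation.
#'
#' @param scope `"region"` (default) for the computational input rows,
#'   `"all"` for every printed column including roll-ups.
#' @return `clts_study_costs()`: a `clts_ledger`; `clts_study_outcomes()`:
#'   a `clts_outcome` tibble.
#' @export
clts_study_costs <- function(scope = c("region", "all")) {
  scope <- match.arg(scope)
  led <- read_ledger_csv(system.file("extdata", "study_costs.csv",
                                     package = "cltsce", mustWork = TRUE))
  if (scope == "region") led[led$scope == "region", ] else led
}

#' @rdname clts_study_costs
#' @export
clts_study_outcomes <- function(scope = c("region", "all")) {
  scope <- match.arg(scope)
  out <- read_outcomes_csv(system.file("extdata", "study_outcomes.csv",
                                       package = "cltsce", mustWork = TRUE))
  if (scope == "region") out[out$scope == "region", ] else out
}

#' Read an analysis configuration
#'
#' Configurations are YAML (or JSON, a YAML subset) with optional keys
#' `ledgers` and `outcomes` (CSV paths; default: the bundled study fixture),
#' `outcome_measures` (subset of `stopped_od`, `gained_ownership`),
#' `psa` (`n_draws`, `seed`, `cost_half_width`, `sd_fallback_fraction`, or
#' `FALSE`/`no` to skip), and `output_dir`.
#'
#' @param path Path to a YAML/JSON config file.
#' @return A named list suitable for [run_pipeline()].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  yaml::read_yaml(path)
}

#' Run the full cost-effectiveness pipeline
#'
#' Orchestrates the analysis end to end: read regional cost ledgers and
#' outcome changes, roll them up per arm within each country and across the
#' whole study, compute societal cost breakdowns, cost-effectiveness ratios
#' per household and per person for each outcome measure, and (optionally) a
#' Monte Carlo sensitivity interval for every defined ratio. Cells whose
#' outcome worsened are carried as flagged-undefined rather than dropped,
#' and each suppressed cell is logged.
#'
#' @param config A config list (see [read_config()]) or a path to a config
#'   file. With no arguments the bundled study fixture is analyzed.
#' @param quiet Suppress progress/log messages.
#' @return A list of class `clts_report`: `outcomes`, `costs`, `cea`, and
#'   `psa` tibbles (the latter `NULL` when PSA is disabled). If
#'   `config$output_dir` is set, each table is also written there as CSV.
#' @export
#' @examples
#' rep <- run_pipeline(list(psa = FALSE), quiet = TRUE)
#' subset(rep$cea, scope == "pooled", c(outcome_measure, ce_per_household))
run_pipeline <- function(config = list(), quiet = FALSE) {
  if (is.character(config)) config <- read_config(config)
  say <- function(...) if (!quiet) message(...)

  ledgers <- config$ledgers %||% clts_study_costs()
  if (is.character(ledgers)) ledgers <- read_ledger_csv(ledgers)
  ledgers <- as_cost_ledger(ledgers)
  outcomes <- config$outcomes %||% clts_study_outcomes()
  if (is.character(outcomes)) outcomes <- read_outcomes_csv(outcomes)
  measures <- config$outcome_measures %||% OUTCOME_MEASURES
  measures <- match.arg(measures, OUTCOME_MEASURES, several.ok = TRUE)
  say(sprintf("inputs: %d regional ledgers, %d outcome rows",
              nrow(ledgers), nrow(outcomes)))

  key <- function(df) paste(df$arm, df$country, df$region)
  if (!setequal(key(ledgers), key(outcomes))) {
    stop("ledger and outcome tables cover different (arm, country, region) ",
         "cells", call. = FALSE)
  }

  # roll-ups: per-arm country aggregates, then one pooled column
  roll_led <- list(ledgers)
  roll_out <- list(tibble::as_tibble(outcomes)[, c(
    "arm", "country", "region", "n_households", "n_people",
    "delta_od", "delta_ownership",
    "households_stopping_od", "households_gaining_ownership")])
  roll_out[[1]]$scope <- "region"
  for (grp in split(seq_len(nrow(ledgers)),
                    paste(ledgers$arm, ledgers$country))) {
    roll_led <- c(roll_led, list(
      aggregate_ledgers(ledgers[grp, ], region = "All", scope = "country")))
  }
  for (grp in split(seq_len(nrow(outcomes)),
                    paste(outcomes$arm, outcomes$country))) {
    roll_out <- c(roll_out, list(
      aggregate_outcomes(outcomes[grp, ], region = "All", scope = "country")))
  }
  roll_led <- c(roll_led, list(aggregate_ledgers(
    ledgers, arm = "All CLTS", country = "All", region = "All",
    scope = "pooled")))
  roll_out <- c(roll_out, list(aggregate_outcomes(
    outcomes, arm = "All CLTS", country = "All", region = "All",
    scope = "pooled")))
  all_led <- as_cost_ledger(dplyr::bind_rows(roll_led))
  all_out <- dplyr::bind_rows(roll_out)

  costs <- total_cost(all_led)
  joined <- dplyr::inner_join(
    costs, all_out,
    by = c("arm", "country", "region"), suffix = c("", ".out"))

  ce_rows <- lapply(measures, function(m) {
    count <- switch(m, stopped_od = joined$households_stopping_od,
                    gained_ownership = joined$households_gaining_ownership)
    ce <- cost_effectiveness(
      joined$total_cost, count, m,
      n_people = joined$n_people, n_households = joined$n_households,
      arm = joined$arm, country = joined$country, region = joined$region)
    ce$scope <- joined$scope
    ce
  })
  cea_table <- dplyr::bind_rows(ce_rows)
  for (i in which(!cea_table$defined)) {
    say(sprintf("suppressed CE cell: %s / %s / %s [%s] -- %s",
                cea_table$arm[i], cea_table$country[i], cea_table$region[i],
                cea_table$outcome_measure[i], cea_table$note[i]))
  }

  psa_cfg <- config$psa %||% list()
  psa_table <- NULL
  if (!isFALSE(psa_cfg)) {
    n_draws <- psa_cfg$n_draws %||% 1000
    seed <- psa_cfg$seed %||% 1L
    hw <- psa_cfg$cost_half_width %||% 0.3
    sdf <- psa_cfg$sd_fallback_fraction %||% 0.5
    say(sprintf("PSA: %d draws per defined cell (seed %d)", n_draws,
                as.integer(seed)))
    runs <- list()
    out_key <- paste(all_out$arm, all_out$country, all_out$region)
    for (i in seq_len(nrow(all_led))) {
      oi <- all_out[match(paste(all_led$arm[i], all_led$country[i],
                                all_led$region[i]), out_key), ]
      for (m in measures) {
        count <- switch(m, stopped_od = oi$households_stopping_od,
                        gained_ownership = oi$households_gaining_ownership)
        if (count <= 0) next
        runs <- c(runs, list(run_psa(
          all_led[i, ], oi, measure = m, n_draws = n_draws,
          seed = seed + length(runs), cost_half_width = hw,
          sd_fallback_fraction = sdf)))
      }
    }
    psa_table <- dplyr::bind_rows(runs)
  }

  report <- structure(
    list(outcomes = all_out, costs = costs, cea = cea_table,
         psa = psa_table),
    class = "clts_report")
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(report)) {
      if (!is.null(report[[nm]])) {
        readr::write_csv(report[[nm]],
                         file.path(config$output_dir, paste0(nm, ".csv")))
      }
    }
    say("report written to ", config$output_dir)
  }
  report
}

#' @export
print.clts_report <- function(x, ...) {
  cat("<clts_report>\n")
  for (nm in names(x)) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  $%s: %d rows\n", nm, nrow(x[[nm]])))
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
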