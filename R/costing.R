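#' Monetize unpaid time
#'
#' Converts unpaid local-actor or community time into a currency amount using
#' a value-of-time rate, the standard step in societal-perspective costing
#' where volunteer and government time carries an economic cost even though
#' no money changes hands. Rates are typically derived from local wage data.
#'
#' @param hours Hours of time (non-negative, vectorized).
#' @param rate Value-of-time rate in currency per hour (non-negative).
#' @return `hours * rate`, in currency units.
#' @export
#' @examples
#' monetize_time(10, 0.5)
monetize_time <- function(hours, rate) {
  check_nonneg(hours, "hours")
  check_nonneg(rate, "rate")
  hours * rate
}

#' Construct or normalize a cost ledger
#'
#' A cost ledger is a tibble with one row per (arm, region) and one column
#' per societal cost category: `management`, `training`, `facilitation`
#' (program costs, borne by the implementer) and `local_actor_time`,
#' `community_time`, `hired_labor`, `hardware` (local costs, borne by local
#' actors and households). All amounts are nominal USD of the study period;
#' no discounting is applied.
#'
#' Time categories may be supplied either directly in monetized form or as
#' `*_hours` and `*_rate` column pairs, which are multiplied out via
#' [monetize_time()]. If both a monetized amount and an (hours, rate) pair
#' are present and disagree, the monetized amount wins and a warning is
#' issued.
#'
#' @param x A data frame with columns `arm`, `region` and the cost
#'   categories above (missing categories are filled with 0); optionally
#'   `country` and `scope`, and optionally `local_actor_hours`,
#'   `local_actor_rate`, `community_hours`, `community_rate`.
#' @return A tibble of class `clts_ledger`.
#' @export
as_cost_ledger <- function(x) {
  x <- tibble::as_tibble(x)
  if (!all(c("arm", "region") %in% names(x))) {
    stop("a cost ledger needs `arm` and `region` columns", call. = FALSE)
  }
  for (tc in c("local_actor", "community")) {
    hcol <- paste0(tc, "_hours")
    rcol <- paste0(tc, "_rate")
    mcol <- paste0(tc, "_time")
    if (all(c(hcol, rcol) %in% names(x))) {
      monetized <- monetize_time(x[[hcol]], x[[rcol]])
      if (mcol %in% names(x)) {
        mismatch <- !is.na(x[[mcol]]) & abs(x[[mcol]] - monetized) > 0.005
        if (any(mismatch)) {
          warning(sprintf(
            "%s: monetized amounts differ from hours x rate in %d row(s); keeping monetized amounts",
            mcol, sum(mismatch)), call. = FALSE)
        }
        x[[mcol]] <- ifelse(is.na(x[[mcol]]), monetized, x[[mcol]])
      } else {
        x[[mcol]] <- monetized
      }
    }
  }
  for (cat in COST_CATEGORIES) {
    if (!cat %in% names(x)) x[[cat]] <- 0
    check_nonneg(x[[cat]], cat)
  }
  if (!"country" %in% names(x)) x$country <- NA_character_
  if (!"scope" %in% names(x)) x$scope <- "region"
  out <- x[, c("arm", "country", "region", "scope", COST_CATEGORIES)]
  class(out) <- c("clts_ledger", class(out))
  out
}

#' Total societal cost of a ledger
#'
#' Sums the seven cost categories into a program subtotal (management +
#' training + facilitation), a local subtotal (local actor time + community
#' time + hired labor + hardware), and a societal total. No discount rate is
#' applied: costs are treated as nominal USD over the short study period.
#'
#' @param ledger A `clts_ledger` (or coercible data frame); may have many
#'   rows.
#' @return The ledger with `program_cost`, `local_cost` and `total_cost`
#'   columns appended.
#' @export
#' @examples
#' led <- as_cost_ledger(data.frame(
#'   arm = "CLTS", region = "demo", management = 100, training = 50,
#'   facilitation = 25, hardware = 10
#' ))
#' total_cost(led)$total_cost
total_cost <- function(ledger) {
  ledger <- as_cost_ledger(ledger)
  dplyr::mutate(
    ledger,
    program_cost = rowSums(dplyr::pick(dplyr::all_of(PROGRAM_CATEGORIES))),
    local_cost = rowSums(dplyr::pick(dplyr::all_of(LOCAL_CATEGORIES))),
    total_cost = .data$program_cost + .data$local_cost
  )
}

#' Aggregate cost ledgers category-wise
#'
#' Rolls regional ledgers up to country or study level by summing each cost
#' category. Aggregation is exact (no re-rounding), so the total cost of the
#' aggregate equals the sum of the member totals.
#'
#' @param ledgers A `clts_ledger` with one row per member, or a list of
#'   single-row ledgers.
#' @param arm,country,region Labels for the aggregate row; default to the
#'   unique member value, or `"All"` where members differ.
#' @param scope Scope label for the aggregate row (default `"aggregate"`).
#' @return A single-row `clts_ledger`.
#' @export
aggregate_ledgers <- function(ledgers, arm = NULL, country = NULL,
                              region = NULL, scope = "aggregate") {
  if (is.list(ledgers) && !is.data.frame(ledgers)) {
    ledgers <- dplyr::bind_rows(ledgers)
  }
  ledgers <- as_cost_ledger(ledgers)
  if (nrow(ledgers) == 0L) {
    stop("cannot aggregate an empty collection of ledgers", call. = FALSE)
  }
  union_label <- function(x, given) {
    if (!is.null(given)) return(given)
    u <- unique(x[!is.na(x)])
    if (length(u) == 1L) u else "All"
  }
  out <- tibble::tibble(
    arm = union_label(ledgers$arm, arm),
    country = union_label(ledgers$country, country),
    region = union_label(ledgers$region, region),
    scope = scope
  )
  for (cat in COST_CATEGORIES) out[[cat]] <- sum(ledgers[[cat]])
  class(out) <- c("clts_ledger", class(out))
  out
}
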