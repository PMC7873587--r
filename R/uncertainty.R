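#' Distribution specifications for sensitivity analysis
#'
#' Two parameter-uncertainty families are used in the probabilistic
#' sensitivity analysis: measured costs get a relative uniform band around
#' the base value (a conservative choice for quantities that were measured,
#' not estimated), and outcome counts get a normal distribution whose
#' standard deviation comes from impact-evaluation data when available, and
#' otherwise falls back to a stated fraction of the point estimate.
#'
#' @param center Point estimate the distribution is centered on.
#' @param half_width Relative half-width of the uniform band (default 0.30,
#'   i.e. +/-30%); must lie in (0, 1).
#' @param sd Standard deviation of the normal; `NULL` invokes the fallback.
#' @param sd_fallback_fraction Fallback: `sd = fraction * |center|`
#'   (default 0.5, i.e. 50% of the point estimate).
#' @return A list of class `clts_dist` with elements `kind`, `center` and
#'   the dispersion parameter.
#' @export
#' @examples
#' dist_uniform_relative(100)           # uniform on [70, 130]
#' dist_normal(0.10)                    # sd falls back to 0.05
dist_uniform_relative <- function(center, half_width = 0.3) {
  check_fraction(half_width, "half_width", lo = 1e-12, hi = 1 - 1e-12)
  structure(list(kind = "uniform_relative", center = center,
                 half_width = half_width), class = "clts_dist")
}

#' @rdname dist_uniform_relative
#' @export
dist_normal <- function(center, sd = NULL, sd_fallback_fraction = 0.5) {
  if (is.null(sd)) sd <- sd_fallback_fraction * abs(center)
  check_nonneg(sd, "sd")
  structure(list(kind = "normal", center = center, sd = sd),
            class = "clts_dist")
}

#' Draw parameter values from a distribution specification
#'
#' @param spec A `clts_dist` from [dist_uniform_relative()] or
#'   [dist_normal()].
#' @param n Number of draws.
#' @return Numeric vector of length `n`. Uniform draws lie in
#'   `center * (1 - w)` to `center * (1 + w)`; a zero-sd normal (or a
#'   zero-centered uniform) collapses to the center.
#' @export
sample_draws <- function(spec, n) {
  stopifnot(inherits(spec, "clts_dist"))
  switch(spec$kind,
    uniform_relative = spec$center *
      (1 + runif(n, -spec$half_width, spec$half_width)),
    normal = if (spec$sd == 0) rep(spec$center, n) else
      rnorm(n, spec$center, spec$sd),
    stop("unknown distribution kind: ", spec$kind, call. = FALSE)
  )
}

#' Monte Carlo probabilistic sensitivity analysis of a CE ratio
#'
#' Propagates cost and outcome uncertainty into the cost-effectiveness
#' ratio. Per draw, each of the seven cost categories is perturbed
#' independently by its uniform band, the outcome count is drawn from its
#' normal, and the ratio is recomputed. The 95% interval is the empirical
#' 2.5th/97.5th percentile (linear interpolation) of the defined draws,
#' with the lower bound truncated at zero. Draws whose outcome is zero or
#' negative would give a meaningless ratio; they are excluded from the
#' percentiles and reported as `fraction_undefined`.
#'
#' @param ledger Single-row cost ledger (see [as_cost_ledger()]).
#' @param outcome Single-row outcome-change tibble (see [outcome_change()]).
#' @param measure `"stopped_od"` or `"gained_ownership"`.
#' @param n_draws Number of Monte Carlo draws (default 1000).
#' @param seed Integer seed; identical inputs and seed reproduce the result
#'   exactly.
#' @param cost_half_width Relative half-width of every cost category's
#'   uniform band (default 0.30); 0 switches cost uncertainty off.
#' @param outcome_sd Standard deviation of the outcome count; `NULL` falls
#'   back to `sd_fallback_fraction` of the point estimate.
#' @param sd_fallback_fraction See [dist_normal()]; default 0.5.
#' @return One-row tibble of class `clts_psa`: `point_estimate`, `ci_low`,
#'   `ci_high` (per household), `fraction_undefined`, `n_draws`, `seed`.
#' @export
run_psa <- function(ledger, outcome, measure = "stopped_od",
                    n_draws = 1000, seed = NULL, cost_half_width = 0.3,
                    outcome_sd = NULL, sd_fallback_fraction = 0.5) {
  stopifnot(n_draws >= 1)
  ledger <- as_cost_ledger(ledger)
  if (nrow(ledger) != 1L || nrow(outcome) != 1L) {
    stop("run_psa expects a single-row ledger and a single-row outcome; ",
         "aggregate first", call. = FALSE)
  }
  measure <- match.arg(measure, OUTCOME_MEASURES)
  count_col <- switch(measure, stopped_od = "households_stopping_od",
                      gained_ownership = "households_gaining_ownership")
  base_count <- outcome[[count_col]]
  base_cost <- total_cost(ledger)$total_cost

  draws <- with_seed_if(seed, {
    cost_draws <- rep(0, n_draws)
    for (cat in COST_CATEGORIES) {
      center <- ledger[[cat]]
      cost_draws <- cost_draws + if (center == 0 || cost_half_width == 0)
        center else
        sample_draws(dist_uniform_relative(center, cost_half_width), n_draws)
    }
    count_spec <- dist_normal(base_count, sd = outcome_sd,
                              sd_fallback_fraction = sd_fallback_fraction)
    list(cost = cost_draws, count = sample_draws(count_spec, n_draws))
  })

  defined <- draws$count > 0
  frac_undef <- mean(!defined)
  if (!any(defined)) {
    stop(sprintf(
      "all %d draws gave a non-positive outcome (fraction_undefined = 1); ",
      n_draws), "no CE interval can be formed", call. = FALSE)
  }
  ce_draws <- draws$cost[defined] / draws$count[defined]
  ci <- quantile(ce_draws, c(0.025, 0.975), names = FALSE, type = 7)
  out <- tibble::tibble(
    arm = ledger$arm, country = ledger$country, region = ledger$region,
    outcome_measure = measure,
    point_estimate = if (base_count > 0) base_cost / base_count else NA_real_,
    ci_low = max(0, ci[1]), ci_high = ci[2],
    fraction_undefined = frac_undef,
    n_draws = n_draws,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
  class(out) <- c("clts_psa", class(out))
  out
}

#' Do two PSA confidence intervals overlap?
#'
#' Two interventions whose 95% intervals intersect cannot be declared
#' different in cost-effectiveness at that confidence level. Both results
#' must be on the same outcome measure.
#'
#' @param a,b Single-row `clts_psa` results (see [run_psa()]).
#' @return One-row tibble with both intervals, the `overlap` flag and a
#'   readable `summary` string.
#' @export
overlap_report <- function(a, b) {
  if (!identical(a$outcome_measure, b$outcome_measure)) {
    stop("cannot compare intervals on different outcome measures",
         call. = FALSE)
  }
  overlap <- a$ci_low <= b$ci_high && b$ci_low <= a$ci_high
  tibble::tibble(
    outcome_measure = a$outcome_measure,
    arm_a = a$arm, ci_low_a = a$ci_low, ci_high_a = a$ci_high,
    arm_b = b$arm, ci_low_b = b$ci_low, ci_high_b = b$ci_high,
    overlap = overlap,
    summary = sprintf(
      "[%.2f, %.2f] vs [%.2f, %.2f]: intervals %s",
      a$ci_low, a$ci_high, b$ci_low, b$ci_high,
      if (overlap) "overlap" else "do not overlap")
  )
}
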