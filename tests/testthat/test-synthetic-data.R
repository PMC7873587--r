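test_that("household generation is deterministic and honors the empty case", {
  prof <- study_region_profiles()[["Oromia"]]
  a <- generate_households(prof, 150, seed = 12, arm = "HEW CLTS")
  b <- generate_households(prof, 150, seed = 12, arm = "HEW CLTS")
  expect_identical(a, b)
  c <- generate_households(prof, 150, seed = 13, arm = "HEW CLTS")
  expect_false(identical(a, c))
  expect_equal(nrow(a), 300)  # one row per household per wave
  expect_setequal(unique(a$survey_wave), c("baseline", "followup"))

  empty <- generate_households(prof, 0, seed = 1)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("household_id", "reported_practice", "latrine_full")
                  %in% names(empty)))
})

test_that("generated records satisfy their structural invariants", {
  prof <- study_region_profiles()[["Upper West"]]
  recs <- generate_households(prof, 800, seed = 4)
  expect_true(all(recs$n_members >= 1))
  expect_true(all(recs$hardware_spend >= 0))
  expect_true(all(recs$hired_labor_spend >= 0))
  expect_true(all(recs$sanitation_hours >= 0))
  expect_true(all(recs$reported_practice %in%
                    c("open_defecation", "private_latrine",
                      "shared_latrine", "communal_latrine")))
  # private reporters always have an observable latrine record
  priv <- recs[recs$reported_practice == "private_latrine", ]
  expect_true(all(priv$latrine_observed))
  # spending is concentrated in latrine-gaining follow-up households
  expect_true(all(recs$hardware_spend[recs$survey_wave == "baseline"] == 0))
})

test_that("empirical baseline fractions converge to the profile", {
  prof <- study_region_profiles()[["Oromia"]]  # ownership 0.51, OD 0.70
  recs <- generate_households(prof, 5000, seed = 2024)
  base <- recs[recs$survey_wave == "baseline", ]
  own_hat <- mean(classify_usable_latrine(base))
  od_hat <- mean(classify_defecation(base) == "open_defecation")
  se <- function(p) sqrt(p * (1 - p) / 5000)
  expect_lt(abs(own_hat - 0.51), 3 * se(0.51))
  expect_lt(abs(od_hat - 0.70), 3 * se(0.70))
})

test_that("follow-up recall of latrine age recovers baseline ownership", {
  prof <- study_region_profiles()[["Volta"]]
  recs <- generate_households(prof, 4000, seed = 8)
  follow <- recs[recs$survey_wave == "followup", ]
  est <- recall_baseline_ownership(follow, prof$survey_window_months)
  expect_lt(abs(est - prof$baseline_ownership),
            3 * sqrt(0.25 / 4000) + 0.01)
})

test_that("cost ledger generation respects totals, jitter bounds and errors", {
  totals <- c(management = 8690, training = 17617, facilitation = 4891)
  exact <- generate_cost_ledger("HEW CLTS", "All", totals, jitter = 0)
  expect_equal(exact$management, 8690)
  expect_equal(exact$training, 17617)
  expect_equal(exact$facilitation, 4891)
  expect_equal(exact$hardware, 0)

  zero <- generate_cost_ledger("x", "y", c(management = 0, hardware = 0))
  expect_equal(total_cost(zero)$total_cost, 0)

  # bound check across 1000 seeds: every jittered category in [0.7, 1.3]x
  ok <- vapply(1:1000, function(s) {
    led <- generate_cost_ledger("a", "r", totals, jitter = 0.3, seed = s)
    all(led$management >= 0.7 * 8690, led$management <= 1.3 * 8690,
        led$training >= 0.7 * 17617, led$training <= 1.3 * 17617,
        led$facilitation >= 0.7 * 4891, led$facilitation <= 1.3 * 4891)
  }, logical(1))
  expect_true(all(ok))

  expect_error(generate_cost_ledger("a", "r", c(management = -5)), "totals")
  expect_error(generate_cost_ledger("a", "r", c(bananas = 5)), "bananas")
  expect_error(region_profile("X", "Y", 30, 5, 2, baseline_ownership = 1.2,
                              baseline_od = 0.5), "baseline_ownership")
})

test_that("pooling generated regions equals the household-weighted mean", {
  profs <- study_region_profiles()[c("Central", "Volta")]
  ns <- c(600, 900)
  ocs <- dplyr::bind_rows(purrr::map2(profs, ns, function(p, n) {
    compute_outcome_change(generate_households(p, n, seed = 77))
  }))
  pooled <- aggregate_outcomes(ocs)
  w <- ocs$n_households / sum(ocs$n_households)
  expect_equal(pooled$n_households, sum(ns))
  expect_equal(pooled$households_stopping_od,
               sum(ocs$households_stopping_od))
  expect_lt(abs(pooled$delta_ownership - sum(w * ocs$delta_ownership)),
            2 * 0.5 / sum(ns))
})
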