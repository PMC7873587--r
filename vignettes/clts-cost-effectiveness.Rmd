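---
title: "Methods: societal cost-effectiveness of CLTS interventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: societal cost-effectiveness of CLTS interventions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cltsce)
```

## The analytical model

`cltsce` computes retrospective (ex-post) cost-effectiveness of sanitation
behavior-change interventions from a societal perspective. The estimand for
each intervention arm and geography is

$$\mathrm{CE}_i = \frac{\text{Cost}}{\text{Outcome}_i},$$

the societal cost per household achieving outcome $i$, where the two
outcomes are stopping open defecation (OD) and gaining ownership of a
usable private latrine. Three modeling commitments define the method:

1. **Bottom-up, activity-based costing.** Costs enter as seven measured
   category amounts rather than allocated budgets: management, training and
   facilitation (program costs, borne by the implementer) and local-actor
   time, community time, hired labor and hardware (local costs, borne by
   local actors and households). Unpaid time is monetized at a
   value-of-time rate derived from local wages (`monetize_time()`). Costs
   are nominal USD over a short (roughly two-year, 2012–2014) window, so no
   discount rate or inflation adjustment is applied.
2. **Observation-validated outcomes.** Self-reported private latrine use is
   trusted only when the latrine was observed with stable flooring and not
   full on survey day; otherwise the household is classified as OD.
   Shared and communal latrine use counts as latrine use but not as
   ownership. This asymmetric validation (use can be demoted, never
   promoted) may overestimate OD but protects against the well-documented
   optimism of self-report.
3. **A zero-change counterfactual.** Outcome counts assume OD and ownership
   would have been static absent the intervention; no secular-trend
   adjustment is made. Counts are derived from *unrounded* survey
   fractions, then rounded half-away-from-zero — reconstructing published
   tables from printed (rounded) percentages typically leaves sub-1%
   residuals in the ratios, which is the tolerance used throughout the
   regression tests.

Worsened outcomes produce negative counts. Dividing positive costs by
negative counts yields misleading ratios, so such cells are flagged
undefined (`defined = FALSE`, with a reason) and carried through reporting
as suppressed rather than dropped or clipped; the SNNP region in the
bundled fixture exercises this path.

Incremental cost-effectiveness (`icer()`) is the standard
$\Delta\text{cost}/\Delta\text{effect}$ with quadrant labels on the
cost-effectiveness plane (dominant / dominated / trade-off). It is reported
alongside, not instead of, the per-arm ratios.

## Uncertainty model

`run_psa()` propagates parameter uncertainty by Monte Carlo (default 1000
draws, explicit seed):

- **Costs** were measured rather than estimated, so each of the seven
  category amounts gets an independent multiplicative uniform band of
  ±30% around its base value — a deliberately conservative band for
  measured quantities. Each category is drawn separately; there is no
  pooled cost shock.
- **Outcomes** get a normal distribution. Where an impact-evaluation
  standard deviation is available it can be supplied (`outcome_sd`);
  otherwise the SD falls back to 50% of the point estimate, again a
  conservative width. Draws are made on the count scale; because the
  normal family is closed under scaling, this is numerically identical to
  drawing the delta fraction and multiplying by the household count, and
  draws are deliberately not re-rounded to integers to avoid discreteness
  artifacts in the percentiles.
- Parameters are drawn independently: nothing is stated about cost–outcome
  correlation and none is imposed.
- The 95% interval is the empirical 2.5th/97.5th percentile of the defined
  draws, using `stats::quantile()` type 7 (linear interpolation), with the
  lower bound truncated at zero. Draws whose outcome count is ≤ 0 cannot
  yield a meaningful ratio; they are excluded from the percentiles and
  reported separately as `fraction_undefined`, mirroring the suppression
  rule for point estimates. With outcome SD at 50% of a positive mean, this
  fraction converges to the normal tail mass $\Phi(-2) \approx 0.0228$,
  which the test suite checks against the closed-form value.

Two degenerate behaviors anchor the implementation: with all uncertainty
switched off the interval collapses exactly onto the deterministic point
estimate, and with cost-only uncertainty the interval endpoints converge to
$(0.715, 1.285)\times$ the point estimate (the analytic 2.5%/97.5%
quantiles of a ±30% uniform).

## The synthetic-data generator

No household-level survey data were deposited for the study the package is
calibrated to, so `generate_households()` simulates two-wave panels whose
margins match the published regional profiles (`study_region_profiles()`):
baseline usable-latrine ownership from 10% (Upper West) to 98% (SNNP),
baseline OD from 27% to 96%, mean household sizes 3.3–6.4 and village sizes
29–123 households, with effect sizes from the conventional-CLTS arm of each
region. Design choices, in the order they matter:

- **Panel transitions, not resampled cross-sections.** Each baseline-OD
  household stops OD with probability $-\delta_{OD}/p_{OD}$ (and
  symmetrically for worsening directions and for ownership), preserving
  the longitudinal structure a panel survey implies and making
  "households that flipped" a well-defined quantity the outcomes stage can
  count exactly.
- **Ownership and use are drawn independently at baseline.** The study
  regions show ownership both far above use (SNNP: 98% own, 73% use) and
  far below it (Upper West: 10% own, 4% use... of which most share), so
  neither implies the other. Reported practice then follows from the
  states: users owning a usable latrine report private use, other users
  report shared/communal facilities, non-users report OD. A consequence is
  that classification recovers both margins by construction, up to
  binomial noise — the parameter-recovery test generates 5,000 households
  per region and requires agreement within 3 binomial standard errors.
- **Household size** is a rounded normal truncated at 1 person (the study
  reports only regional means; the SD defaults of ~2 persons are typical
  of rural household surveys). Truncation biases small means slightly
  upward, which is acceptable because no acceptance quantity depends on
  household size beyond per-person scaling of synthetic runs.
- **Latrine age** for recall-based baseline estimation: latrines gained
  during the study window get an age uniform on (0, window); pre-existing
  ones get window + uniform(0, 60) months. The window is 24 months for the
  Ethiopian regions and 30 for the Ghanaian ones, matching the elapsed
  time between intervention start and follow-up survey.
- **Spending** is right-skewed (lognormal, sdlog = 1) and concentrated in
  latrine-gaining households, all others recording zero — matching the
  many-zeros structure of household sanitation-spending data. Only
  aggregate spending was published, so the per-region means are rough
  calibrations and carry no acceptance weight.

What the generator does **not** emulate: within-village outcome
correlation (village labels exist but carry no random effect — the study
reports none), survey nonresponse, measurement error in latrine
observation, and intra-household variation (outcomes are household-level
throughout). Passing parameter-recovery tests therefore shows the
classification and aggregation chain is internally consistent, not that it
is robust to clustered or messy field data.

Oromia's teacher-arm printed effect (+53 points of ownership on a 51%
regional baseline) cannot be represented as a coherent region-wide profile
(it would exceed 100%); the published per-arm baselines evidently differ
from the region-wide table. The built-in profiles therefore use the
conventional arm's effects, all of which are feasible.

## The bundled fixture and roll-up arithmetic

`clts_study_costs()` / `clts_study_outcomes()` ship the published
per-column category amounts and outcome counts — 10 regional columns, 4
per-arm country columns, 1 pooled column. The pipeline *computes* from the
regional rows and aggregates upward; the printed roll-ups are kept purely
as a regression surface. Two systematic residuals are expected and tested
for rather than hidden:

- printed category amounts are rounded to whole dollars, so recomputed
  column totals sit within ±$2 of printed totals;
- the published country-level counts were derived from unrounded pooled
  fractions (e.g. a printed count of 168 against regional counts summing
  to 169), so aggregated counts can differ by 1, moving ratios by well
  under 1%.

Internally costs are kept at cent precision and only rounded for display.
CE values are compared with relative tolerances, never string equality.

## Problem sizes and determinism

Every stochastic function takes an explicit integer seed and is exactly
reproducible under it (`withr::with_seed`, leaving the caller's RNG state
untouched). The test suite uses 5,000 households per region for parameter
recovery, 1,000 seeds for jitter-bound checks, and up to 100,000 Monte
Carlo draws for the distributional-convergence checks; the full suite runs
in well under a minute.

## Known limitations

- The analysis inherits the study's design limits: recall-based baselines
  in Ghana, household-level outcomes, value-of-time assumptions, and a
  zero-change counterfactual.
- The uncertainty model covers parameter uncertainty only — no sampling
  variability of the survey itself, no variance-based global sensitivity
  indices.
- Benefit-cost ratios, DALYs and health-impact extrapolation are out of
  scope; the package stops at cost per household (or person) changing
  sanitation status.
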