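# cltsce

Societal cost-effectiveness analysis of community-led total sanitation
(CLTS) interventions.

CLTS is a no-subsidy, demand-generation approach to rural sanitation:
facilitators "trigger" communities to abandon open defecation (OD) and
build their own latrines. Program evaluators and health economists who need
to know what a CLTS campaign costs *per household changing behavior* face
three recurring tasks: assembling societal costs bottom-up from program and
local components, classifying household survey responses into defensible
outcome states, and propagating cost and outcome uncertainty into the final
ratios. `cltsce` implements that pipeline end to end, calibrated to a
four-intervention CLTS evaluation in Ethiopia (HEW-facilitated and
teacher-facilitated CLTS, Oromia and SNNP regions) and Ghana (NGO CLTS with
and without natural-leader training, Central, Upper West and Volta
regions).

## The statistic

For each intervention arm and region, the cost-effectiveness ratio is

```
CE_i = Cost / Outcome_i ,   i ∈ {stopping OD, gaining usable-latrine ownership}
```

where `Cost` is the societal total — program costs (management, training,
facilitation) plus local costs (monetized local-actor and community time,
hired labor, latrine hardware) — and `Outcome_i` is the count of households
achieving outcome *i*, derived from survey fractions. Ownership counts only
latrines that were *observed, had stable flooring, and were not full* on
survey day; reported private-latrine use failing that check is reclassified
as OD. Worsened outcomes (negative counts) make the ratio misleading and
are carried as flagged-undefined cells rather than reported. Incremental
comparisons use the standard ICER `Δcost / Δeffect` with
cost-effectiveness-plane dominance labels, and uncertainty is assessed by
Monte Carlo: each cost category drawn from a ±30% uniform band, outcome
counts from a normal whose SD defaults to 50% of the point estimate, with
percentile 95% intervals truncated at zero.

## Worked example

The bundled fixture carries the published per-region cost-category amounts
and outcome counts. The pipeline rolls them up, computes every ratio, and
flags suppressed cells:

```r
library(cltsce)
report <- run_pipeline(list(psa = FALSE), quiet = TRUE)
subset(report$cea, scope == "pooled",
       c(outcome_measure, total_cost, outcome_count,
         ce_per_household, ce_per_person))
#>   outcome_measure total_cost outcome_count ce_per_household ce_per_person
#>        stopped_od     576062          1606          358.694       75.2328
#>  gained_ownership     576062          1085          530.933      111.3584
```

Across both countries, converting one household away from open defecation
cost about $359 ($75 per person); one household gaining a usable private
latrine cost about $531 ($111 per person). The teacher-facilitated pilot in
Ethiopia bought additional OD reductions at ~$106 per extra household over
conventional HEW-facilitated CLTS:

```r
eth <- subset(report$cea, country == "Ethiopia" & region == "All" &
                outcome_measure == "stopped_od")
icer(c(cost = eth$total_cost[1], outcome = eth$outcome_count[1]),
     c(cost = eth$total_cost[2], outcome = eth$outcome_count[2]))
#>   delta_cost delta_outcome  icer defined quadrant
#> 1      26611           252  106. TRUE    trade-off: more effective, more costly
```

A Monte Carlo sensitivity run shows how wide the plausible range is even
for a well-measured arm:

```r
led <- aggregate_ledgers(subset(clts_study_costs(), arm == "HEW CLTS"), region = "All")
oc  <- aggregate_outcomes(subset(clts_study_outcomes(), arm == "HEW CLTS"), region = "All")
run_psa(led, oc, "stopped_od", n_draws = 1000, seed = 1)
#>  outcome_measure point_estimate   ci_low  ci_high fraction_undefined
#>       stopped_od       217.3905 105.0458 1156.174              0.029
```

Synthetic two-wave household panels with the study's regional margins are
available for testing any stage without survey data:

```r
recs <- generate_households(study_region_profiles()[["Oromia"]], 1000, seed = 1)
compute_outcome_change(recs)
```

## Package layout

- `R/synthetic_data.R` — regional profiles, household-panel and cost-ledger
  generators
- `R/outcomes.R` — observation-validated outcome classification and change
  computation
- `R/costing.R` — bottom-up societal costing, time monetization,
  aggregation
- `R/cea.R` — CE ratios, per-person conversion, ICER
- `R/uncertainty.R` — Monte Carlo probabilistic sensitivity analysis
- `R/interface.R` — CSV schemas, config, and the `run_pipeline()`
  orchestrator
- `vignettes/clts-cost-effectiveness.Rmd` — methods and modeling choices
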