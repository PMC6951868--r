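# sepscreen

Rule-based severe-sepsis surveillance screening over longitudinal clinical
event streams, with a synthetic-EHR cohort generator and an evaluation layer
for the alert-reliability / condition-sensitivity trade-off.

## The problem

Hospital sepsis surveillance systems continuously screen a patient's
physiological data and notify a provider when a severe-sepsis pattern
appears. Their usefulness hinges on a tension: parameters and thresholds
tuned for reliability (few false alerts, low commission error) sacrifice
sensitivity (missed detections, omission error), and a single hyperactive
parameter can wreck provider trust in the whole system. `sepscreen` is for
informaticians and biostatisticians who want to study that trade-off in a
controlled setting: it implements the screen as a deterministic temporal
rules engine, ships three progressively constrained scenario presets, and
evaluates them on cohorts — real tables or synthetic ones with known ground
truth.

## The model

An encounter is flagged at the first observation instant *t* at which

* ≥ 2 **SIRS criteria** hold — temperature > 38.3 °C or < 36.0 °C, heart
  rate > 90 /min, respiratory rate > 20 /min, WBC > 12 000 or < 4 000 /mm³
  or band forms > 10 % — and
* ≥ 1 **organ-dysfunction parameter** holds — SBP < 90 or MAP < 65 mmHg,
  SBP decrease > 40 mmHg from the baseline (first in-window) reading,
  lactate > 2.0 mmol/L, bilirubin ≥ 2.0 mg/dL, creatinine ≥ 2.0 mg/dL,
  platelets < 100 000 /µL, INR > 1.5,

each criterion judged over its own trailing half-open lookback window
(12 h lactate, 72 h creatinine, 30 h otherwise). Corrected lab re-results
are collapsed by an update counter before screening. Flagged encounters are
attributed to exactly one parameter class (`mods` when ≥ 2 organ systems
are involved at alert time). Presets: `sep2_based` (the full screen, in the
style of the CMS severe-sepsis definition), `near_sep2` (drops the SBP-drop
parameter), `conservative` (additionally requires a creatinine rise ≥ 0.5
mg/dL, caps bilirubin at 10 mg/dL, and eliminates platelets/INR).

Downstream: suspected infection = qualifying culture drawn + qualifying IV
anti-infective given; NEWS acuity (six-component) and apparent strong ion
difference at admission; PPV / sensitivity per scenario; cross-scenario
substitution analysis with Woolf crude odds ratios; and per-parameter
logistic mortality models (covariates age, sex, NEWS category).

## Worked example

```r
library(sepscreen)

we  <- worked_example_cohort()          # 12 hand-authored encounters
ref  <- screen_cohort(we$cohort, scenario_preset("sep2_based"))
near <- screen_cohort(we$cohort, scenario_preset("near_sep2"))
inf  <- label_infection(we$cohort, quiet = TRUE)

ref[flagged == TRUE, .(encounter_id, first_alert_time, attributed_class)]
#>    encounter_id    first_alert_time attributed_class
#> 1:          W01 2016-04-02 01:00:00          lactate
#> 2:          W02 2016-04-02 01:00:00         sbp_drop
#> 3:          W03 2016-04-02 01:00:00       sbp_or_map
#> 4:          W04 2016-04-02 01:00:00        bilirubin
#> 5:          W05 2016-04-02 01:00:00        bilirubin
#> 6:          W06 2016-04-02 01:00:00       creatinine
#> 7:          W07 2016-04-02 01:00:00        platelets
#> 8:          W08 2016-04-02 01:00:00              inr
#> 9:          W09 2016-04-02 01:00:00             mods

evaluate_scenario(near, inf, ref)
#> <scenario_evaluation> near_sep2
#>   flagged: 8, with suspected infection: 2 (PPV 25%)
#>   sensitivity vs reference: 100%, flagged-count change: -11%
```

Nine of the twelve encounters alert under the full screen, each attributed
to its planted parameter class; the three controls (normal, SIRS-alone,
organ-alone) never alert. Removing the SBP-drop parameter loses exactly the
SBP-drop-only encounter `W02` — an 11 % drop in flagged count — while both
suspected-infection alerts are retained (sensitivity 100 % here, because
`W02` was not an infection case). On large synthetic cohorts the same
machinery produces the familiar pattern: reliability (PPV) climbs and
sensitivity falls as the presets tighten.

At scale:

```r
g      <- generate_cohort(cohort_spec(n_encounters = 5000, seed = 1))
alerts <- screen_cohort(g$cohort, scenario_preset("sep2_based"))
merge(alerts, g$ground_truth, by = "encounter_id")[
  , mean(flagged == septic_profile)]
#> [1] 1
```

The generator's planted septic profiles are recovered exactly (sensitivity
= specificity = 1) — its built-in acceptance oracle.

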