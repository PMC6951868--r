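---
title: "Methods: rule-based sepsis surveillance screening and its evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rule-based sepsis surveillance screening and its evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepscreen)
library(data.table)
```

## The screening model

Hospital sepsis surveillance systems continuously evaluate a patient's
physiological data stream and notify a provider when a severe-sepsis pattern
appears. `sepscreen` implements such a system as a deterministic temporal
rules engine over per-encounter event streams, together with everything
needed to study its behaviour: a synthetic cohort generator with ground
truth, scenario presets that progressively constrain the rule set, and an
evaluation layer for the reliability/sensitivity trade-off this class of
system lives on.

An encounter is **flagged** at the first instant `t` at which both hold:

* at least two **SIRS criteria** are met: temperature > 38.3 °C or < 36.0 °C;
  heart rate > 90 /min; respiratory rate > 20 /min; WBC > 12 000 /mm³,
  < 4 000 /mm³, or band forms > 10 %;
* at least one **organ-dysfunction parameter** is met: SBP < 90 mmHg or
  MAP < 65 mmHg; SBP decrease > 40 mmHg from baseline; lactate > 2.0 mmol/L;
  bilirubin ≥ 2.0 mg/dL; creatinine ≥ 2.0 mg/dL; platelets < 100 000 /µL;
  INR > 1.5.

Each criterion is judged over its own trailing **lookback window**: 12 h for
lactate, 72 h for creatinine, 30 h for everything else. Windows are
half-open, `(t − lookback, t]`: the reading arriving at the evaluation
instant counts; a reading exactly `lookback` hours old does not. This
convention is unambiguous at the boundary and matches the intuitive reading
of "within the lookback period". The **baseline SBP** for the drop parameter
is the *first* SBP reading inside the 30-h window; the parameter fires when
baseline minus the window minimum strictly exceeds 40 mmHg. Defining
hypotension-from-baseline is genuinely ambiguous (many pairs of readings
could be compared); this reading maximizes detections, which is exactly the
hyperactivity the scenario comparison is designed to expose.

Evaluation runs at every observation event time between admission and
discharge, not on a fixed clock grid: alert state can only change when data
arrive. Inequalities are applied exactly as written above — strict for the
SIRS thresholds, lactate, platelets, INR and the SBP drop; inclusive (≥)
for bilirubin and creatinine. Values exactly at a strict threshold never
trigger; values exactly at an inclusive threshold always do, and the tests
pin both directions.

### Update resolution

Real EHR extracts contain multiple instances of the same clinical event —
a lab result re-verified or corrected after first posting. Every observation
therefore carries an `update_seq` counter; a clinical event is identified by
(encounter, concept, event time) and only its highest-counter instance
survives `resolve_timeline()`. Two instances of one event with *equal*
counters are rejected at ingest as a data error rather than broken
arbitrarily — the counter exists precisely to disambiguate. Resolution is
idempotent and invariant to input order, and the whole pipeline is invariant
to planted update noise once resolved (both are property-tested). Event
identity keyed by (concept, event time) rather than an order identifier is a
design decision; order identifiers are not part of the input schema.
Timestamps are timezone-naive at minute resolution.

## Scenario presets

Three immutable presets ship as YAML under `inst/scenarios/`:

| preset | change relative to the full screen |
|---|---|
| `sep2_based` | none — the full parameter set above |
| `near_sep2` | removes the SBP-decrease-from-baseline parameter |
| `conservative` | additionally requires a creatinine *rise* ≥ 0.5 mg/dL within 72 h on top of the ≥ 2.0 mg/dL threshold; excludes bilirubin > 10 mg/dL; eliminates platelets and INR |

Each successive preset only restricts criteria, so flagged sets nest:
`conservative ⊆ near_sep2 ⊆ sep2_based` on every cohort — a structural
invariant the tests verify on twenty seeded cohorts. The conservative
creatinine rule is interpreted *conjunctively* (threshold **and** rise):
the conservative scenario is a constrained variant, and a disjunctive
reading would enlarge rather than shrink its flagged set. The rise must end
at the qualifying high value (a fall from 2.8 to 1.1 does not qualify),
implemented as `value − running-window-minimum ≥ 0.5` at the qualifying
observation.

### Attribution

For per-parameter reporting each flagged encounter is attributed to exactly
one class, judged at the first activation instant only (the alert is a
point-in-time notification, so later deterioration does not rewrite it).
Parameters from two or more organ systems — cardiovascular = {SBP drop,
SBP/MAP, lactate}, hepatic = {bilirubin}, renal = {creatinine},
hematologic = {platelets, INR} — give `mods`. Within one system the class is
resolved by precedence in the order the criteria are defined (SBP drop >
SBP/MAP > lactate; platelets > INR). No published convention for the
within-system split exists; the choice affects how single-system counts
divide between sibling rows, never the totals, and the partition property
(class counts sum exactly to the flagged count) holds regardless.

## Acuity and outcome labels

**NEWS** is computed in its six-component form — respiratory rate, SpO₂,
temperature, SBP, heart rate, level of consciousness (AVPU) — using the
first documented post-admission value of each component independently.
The supplemental-oxygen item of the standard scale is not among these six
inputs, so the maximum is 18 points; the reporting bands (0–4, 5–6, 7–8,
9–25) are unaffected. Missing components score 0 with a warning rather than
excluding the encounter, since an admission score is wanted for every
characterized patient. **SIDa**, the apparent strong ion difference, is
`(Na + K + 1.85) − Cl` from the first chemistry results, flagged outside
[34, 48] mmol/L with both boundaries inclusive; the correction constant
1.85 is applied as given in the source scale without further derivation.

**Suspected infection** is the conjunction of a qualifying microbiology
culture drawn and a qualifying anti-infective administered intravenously at
any point in the encounter — no temporal coupling between the two is
imposed, because none is part of the definition. The drug list is kept
exactly as defined, including fluticasone-salmeterol (an inhaled
respiratory agent; fidelity over plausibility). **Mortality** is in-hospital
death or referral to hospice at discharge.

## Evaluation layer

*Alert reliability* is PPV on suspected infection: the share of flagged
encounters with the infection label. *Condition sensitivity* needs a
denominator, and no gold-standard sepsis adjudication exists in this data
model; the denominator is therefore the suspected-infection patients flagged
by the reference (`sep2_based`) scenario, which consequently scores 100 % by
construction, and stricter presets can only fall from there.

The *substitution analysis* restricts to suspected-infection patients
flagged by both scenarios of a pair, counts those whose attributed class
changed, and contrasts mortality between the reclassified and same-class
subgroups as a crude odds ratio. Confidence intervals use the Woolf (log-OR
Wald) method, SE = √(1/a + 1/b + 1/c + 1/d); a zero cell triggers a 0.5
continuity correction on all cells with a warning, never silently.

*Mortality models* are binary logistic regressions fit by IRLS
(`stats::glm`, convergence tolerance 1e-8) among suspected-infection
patients flagged by one scenario, one parameter class per model with the
absence of that class as reference — the one-parameter-per-model structure
follows how per-parameter risk is conventionally reported, keeping each
estimate interpretable against its own complement. Covariates: age in years
(continuous, untransformed), sex, and NEWS category as a factor with the
lowest band as reference. Non-convergence and (quasi-)separation
(|coefficient| > 15 or SE > 50) are surfaced as failed fits with a
diagnostic. With no covariates the fit reduces to the closed-form crude OR,
which the tests verify to 1e-6 — an identity that also serves as the
independent oracle for the model code.

## The synthetic generator

`generate_cohort()` emulates the four input tables — encounters,
observations, cultures, medication administrations — with enough structure
to exercise every rule, and no more:

* **Vitals** are baseline noise within normal bands plus a transient
  deterioration episode, not a physiologic model: the screen only reacts to
  threshold crossings within windows, so threshold-relevant structure is the
  only structure that matters for correctness.
* **Septic profiles** (default 26 % of encounters, echoing the flagged
  share of a large hospital cohort) get two SIRS-satisfying vitals at the
  episode time and the planted organ value(s) one hour later, guaranteeing
  activation; the planted class follows configurable weights defaulting to
  the observed mix in severe-sepsis surveillance, with the SBP-drop class
  most frequent.
* **Controls** are deliberate near-misses: SIRS alone, or one organ
  criterion alone, never both in temporal conjunction — and every in-stay
  SBP series spans less than 40 mmHg so the drop parameter cannot fire
  where it was not planted. This makes the SEP-2-based screen recover the
  planted labels with sensitivity and specificity exactly 1, which is the
  generator's acceptance oracle rather than a claim about real data.
* **Substitution structure**: a primary class invisible to a stricter
  preset (SBP drop, platelets, INR, bilirubin above the cap) may, with
  probability `frac_secondary_param` (default 0.35), receive a second
  planted parameter six hours later. Under the stricter preset the alert
  then fires on the secondary parameter — the synthetic analogue of
  patients resurfacing under a different classification.
* **Infection**: per-class infection probabilities follow the relative
  reliability pattern of the parameter classes (SBP drop least reliable,
  lactate most), rescaled so the class-weighted mean equals
  `frac_infected_given_flagged` (default 0.64). This is what makes PPV rise
  as presets drop the unreliable classes. Controls are infected at a
  background rate, and non-qualifying noise (oral antibiotics, unlisted IV
  drugs, culture-only encounters) exercises the labeling filters.
* **Mortality** is logistic: base odds (default rate 0.12) multiplied by
  a per-class odds ratio for each planted parameter. Age, sex and NEWS are
  drawn independently of death, so crude and adjusted estimates coincide in
  expectation and a planted odds ratio is recoverable by either route.
* **Update noise** rewrites a fraction of lab events to a perturbed stale
  value with the truth appended as a correction, so resolution is exercised
  end-to-end.

One RNG stream seeded once drives everything; the same spec and seed give
byte-identical tables. Ages are drawn from a truncated normal (mean 65,
SD 17, clamped to 18–100), approximating a median of 66 with quartiles near
52–76; length of stay is log-normal around a 4-day median, truncated to
0.5–30 days.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: autocorrelated or trending vitals, circadian and
measurement-frequency structure ("informed presence": sicker patients are
measured more often), missing-not-at-random documentation, real hypotension
dynamics (the planted SBP drop is a single clean excursion), culture
positivity, antibiotic timing relative to suspicion, and hospital-level
heterogeneity. Synthetic PPVs and sensitivities are structural consequences
of the planted design, not estimates of any real cohort's values; study-scale
figures from a real deployment can only be reproduced from that deployment's
data.

## Numerical choices and degenerate inputs

* Ingest rejects (never clamps) implausible values, unparseable timestamps,
  under-18 encounters, non-positive stays, orphan events and tied update
  counters, counting each rejection by reason.
* Empty event streams are valid: no data means no criteria met and no flag.
* A cohort with nothing flagged yields an `NA` PPV with a warning (not 0),
  and the report carries an explicit no-alerts marker.
* Woolf intervals use the 0.5 continuity correction only when a cell is
  zero, always with a warning.
* Logistic fits use `epsilon = 1e-8`, `maxit = 100`; separation is detected
  rather than reported as a confident estimate.

## Problem sizes used in the checks

The package's own acceptance checks run on cohorts of 5 000 encounters for
the scale properties (label recovery, attribution partition, PPV
convergence, planted-OR recovery), twenty 150-encounter seeds for the
nesting property, ten 100-encounter seeds for update-noise equivalence, and
one hundred 400-patient replicates for interval coverage of a null odds
ratio — sizes chosen so every stochastic check has comfortable statistical
room while the whole suite stays quick to run. `scripts/acceptance.R`
regenerates a 5 000-encounter cohort from a command-line seed and recomputes
the headline quantities from scratch.

## A worked example

```{r worked}
we <- worked_example_cohort()
alerts <- lapply(
  c(sep2_based = "sep2_based", near_sep2 = "near_sep2",
    conservative = "conservative"),
  function(s) screen_cohort(we$cohort, scenario_preset(s)))
alerts$sep2_based[, .(encounter_id, flagged, attributed_class)]

inf <- label_infection(we$cohort, quiet = TRUE)
evaluate_scenario(alerts$near_sep2, inf, alerts$sep2_based)
```

The SBP-drop-only encounter (`W02`) is flagged by `sep2_based` alone; the
high-bilirubin encounter (`W05`) and the hematologic encounters (`W07`,
`W08`) drop out under `conservative`; the multiple-organ case (`W09`) is
attributed `mods` everywhere; the three controls are never flagged.

## Known limitations

The engine scores the screen itself, not treatment-bundle timing, qSOFA or
ICD-based ascertainment. Unit conversion is out of scope: concepts carry
fixed units and out-of-range values are rejected rather than reinterpreted.
The within-system attribution precedence and the conjunctive conservative
creatinine rule are documented interpretations of ambiguous prose; both are
isolated behind `attribute_class()` and the scenario configuration, so a
different reading is a one-line change. Mortality model estimates on
synthetic cohorts reflect the generator's planted structure only.
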