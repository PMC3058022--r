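---
title: "Benchmarking daily ICU severity scores for cardiac surgery cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking daily ICU severity scores for cardiac surgery cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icubench)
```

## The validation problem

A severity score is clinically useful as a daily mortality predictor only
if it is both *calibrated* (predicted and observed death rates agree
across risk strata) and *discriminating* (non-survivors score higher than
survivors). `icubench` implements this validation for four scores used in
postoperative cardiac-surgery ICUs — CASUS, SOFA, APACHE II and SAPS II —
computed fresh on every ICU day from the day's most abnormal
observations, plus their stay-level Mean- and Max-derivatives.

This vignette records the modelling choices, the parameters that matter,
and what the shipped synthetic cohort generator does and does not
emulate.

## From raw observations to daily scores

**Worst-value panels.** Raw observations arrive in long format
(`stay_id`, `day`, `variable`, `value`, `unit`), possibly several
readings per variable per day. `reduceDailyWorst()` collapses each
stay-day to a panel holding, per continuous variable, *both* the daily
minimum and maximum. This is deliberate: "most abnormal" is not a
property of a variable but of a score. A sodium of 128 mmol/L and one of
152 mmol/L on the same day are both abnormal; APACHE II penalizes the low
value more (2 vs 1 points), SAPS II the high one (1 vs 0). Each engine
therefore scores both extremes of a bidirectional item and keeps the
larger point value, which is provably equivalent to scoring every raw
reading of the day and keeping the worst (the point bands are monotone on
each side of the normal range). Urine output is summed over the day, the
Glasgow Coma Scale takes the daily minimum, ordinal states the daily
maximum, and device/support flags are OR-ed.

**Day boundary.** A "day" is a calendar day aligned to ICU admission;
day 1 is the operative/admission day regardless of admission hour, and a
partial first day is scored as-is. Sub-daily windows are out of scope.

**Units.** Canonical units are conventional clinical units (creatinine
and bilirubin in mg/dL, lactate in mmol/L, PaO2 in mmHg, FiO2 as a
fraction, urine output in mL/day) because the published point tables are
expressed in them; `inst/extdata/units.yaml` declares the accepted SI
alternatives with linear conversions.

**Missing data.** The default mode imputes the normal (zero-point) value
for a variable never observed on a stay-day and logs every imputation in
an attribute; `impute = "strict"` raises an error instead. Assuming
normal for unmeasured variables is the convention of the original scoring
systems; the log keeps the choice auditable.

**Point tables as data.** Each engine reads its band table from a YAML
file under `inst/extdata/score_tables/`, with half-open bands (lower
bound inclusive). Keeping the tables as reviewable data rather than code
lets a reviewer diff them against the source publications. The CASUS
table is a documented reconstruction: its ten-descriptor structure
(pressure-adjusted heart rate = HR x CVP / MAP folding three
cardiovascular inputs into one descriptor, plus oxygenation, lactate,
bilirubin, creatinine, platelets, neurologic state, renal replacement,
IABP and VAD) follows the published descriptions, but the band boundaries
and device weights are this package's reconstruction in the published
0-4-per-descriptor style — the YAML header says so, and the file should
be checked against the original before any clinical use.

Two engine-specific conventions deserve a note:

* **APACHE II oxygenation** switches subscale at FiO2 0.5 (PaO2 below,
  alveolar-arterial gradient above, with AaDO2 = FiO2·713 − PaCO2/0.8 −
  PaO2 at sea level). The published rule is not monotone across that
  boundary — raising FiO2 from 0.4 to 0.6 can lower the item's points —
  so the monotonicity property tests skip exactly that branch flip.
  Creatinine points double under acute renal failure, proxied here by the
  daily renal-replacement flag. The acid-base item uses arterial pH when
  available and the serum-bicarbonate bands only as a fallback.
* **GCS under sedation.** Postoperative sedation depresses the recorded
  GCS. By default the recorded value is scored; `gcsPolicy = "assume15"`
  substitutes an assumed pre-sedation 15, removing the CNS contribution.
  CASUS's neurologic state is a separate ordinal clinical assessment and
  is never derived from GCS.

APACHE II was defined on the worst values of the first 24 h; here it is
applied serially on every ICU day, holding the age, admission-type and
chronic-health contributions constant across days. SAPS II's published
probability transform is implemented (`saps2Probability()`) but excluded
from the benchmark, which recalibrates all four systems uniformly —
SOFA and CASUS have no native probability, so recalibration is the only
footing on which the four are comparable.

## The statistical battery

For day *d*, the at-risk set is every stay with ICULOS ≥ *d* — exits are
deaths or live discharges, never censoring — and:

* `fitScoreLogistic()` fits `P(death) = logit⁻¹(α + β·score)` by maximum
  likelihood; OR = exp(β) with Wald 95% CI exp(β ± 1.96·SE). Complete
  separation is detected and raised as an error rather than returned as a
  silently enormous OR; days where that happens are reported as
  unevaluable rows.
* `hosmerLemeshow()` groups subjects into deciles of recalibrated risk
  (default sample quantiles; ties share a group, so heavy ties can reduce
  the group count) and refers
  Σ (O−E)²/(E(1−E/n)) to χ² with (groups − 2) df. Groups whose expected
  count vanishes are merged into a neighbour with a warning. The
  decile-of-risk, g−2 convention is the canonical one for validation
  samples; `g` is configurable.
* `rocAuc()` computes the AUC from mid-ranks (the Mann-Whitney
  probability with ties at one half). An anti-discriminating score yields
  AUC < 0.5 and is reported as-is, never folded. The 95% CI is DeLong by
  default (via pROC, with the direction pinned so no folding can occur)
  or Hanley-McNeil on request.
* `occ()` is the percentage of subjects whose predicted class at the
  probability cutoff (default 0.5 — the standard "correct classification"
  convention, exposed as a parameter) matches the outcome.

Days with fewer at-risk stays than `min_n` (default 100) are flagged
unevaluable instead of computed: the day horizon (default 6) and the
floor generalize the practice of stopping the per-day analysis before
small-sample statistics become unstable. Significance for the
miscalibration flag is fixed at p < 0.05. No multiple-testing correction
is applied, and no score-vs-score AUC difference test is run — both are
outside the benchmark's scope.

## The synthetic cohort generator

No patient-level cohort of this kind is publicly available, so the
package generates one. Each stay draws:

1. demographics — age from a normal (mean 67.65, sd 11.4 years) truncated
   to [19, 89] and rounded, which yields a realized mean near 66.9 and sd
   near 10.6; sex female with probability 0.296; a surgery type from the
   published eight-category mix; admission category (85% scheduled
   surgical); rare chronic-health flags;
2. a latent baseline severity `s0 ~ Gamma(shape 2, scale 1.1)` and a
   latent course: deteriorating with probability
   `plogis(-5.25 + 0.8·s0)`, recovering otherwise. Tying deterioration to
   admission severity is what gives day-1 scores genuine prognostic
   signal; with a severity-independent mixture the operative-day AUC
   would be 0.5 by construction;
3. a daily trajectory `s_d = drift + 0.9·s_(d-1) + N(0, 0.35)`, floored
   at 0, with drift −0.35 (recovering) or +1.3 (deteriorating);
4. per-day competing exits: death with probability
   `plogis(-10.1 + 0.55·s_d)`, else live discharge with probability
   `plogis(2.0 − 1.5·s_d)`, else the stay continues (administrative cap
   200 days). The steep discharge slope shuts discharge off for
   deteriorating stays, which is what produces the long right tail of
   length of stay (median 2, mean ≈ 4.3, occasional stays beyond 100
   days) from a purely hazard-based, day-indexed process;
5. emissions: each of 20 continuous variables is a monotone linear link
   of `s_d` with Gaussian noise, clamped to physiologic bounds, read
   `readings_per_day = 3` times daily (so the worst-value reduction is
   exercised non-trivially); urine output is emitted as three portions
   summing to a severity-dependent daily total; GCS declines with
   severity; neurologic state, catecholamine dose class and the
   ventilation/IABP/VAD/dialysis flags switch at severity thresholds
   (day 1 is always ventilated, as after cardiac surgery). Preoperative
   EuroSCORE fields are emitted as noisy monotone functions of `s0` and
   are toy values — no joint distribution with outcome is claimed.

The hazard and trajectory defaults were tuned once against the printed
cohort margins (ICU mortality 5.2%, ICULOS mean 4.3/median 2.0/75th
percentile 4.0 days, age 66.9 years, 29.6% female) and frozen in
`inst/extdata/generator_default.yaml`; the `targets` block in that file
records what the configuration is calibrated to, and
`calibrationReport()` prints the realized margins of any cohort for
side-by-side comparison.

Everything is driven by one seed: the same configuration and seed
reproduce every emitted byte, and `runBenchmark()` writes a manifest
(seed, configuration digest, package version) sufficient to reproduce a
report exactly.

A hidden truth table (per-day latent severities, course labels, true
hazard parameters) travels as an attribute, accessible only through
`cohortTruth()` and never written into the public CSV files; recovery
tests read it through that separate path. Pooled stay-days are exact
Bernoulli draws of the death hazard, so logistic regression of
death-on-day on latent severity recovers the planted slope — the
package's parameter-recovery property.

**The null configuration.** Setting the death slope to 0 removes the
severity-outcome link only if the discharge slope is also 0: with
severity-dependent discharge, sicker stays linger longer, accumulate more
per-day death risk, and outcome correlates with severity through exposure
time alone. The "no discrimination" reference configuration therefore
zeroes both slopes, and under it every system's AUC sits at 0.5 up to
Monte-Carlo error.

**What the generator does not emulate.** A single scalar severity drives
all organs, so the correlation structure across organ systems is far
simpler than reality; there is no bypass-time physiology, no readmission
process, no seasonal or center effects, and no missing data. Passing
tests on these cohorts therefore demonstrates that the pipeline computes
its statistics correctly under a controllable data-generating process —
not that any score is clinically superior on real patients, and not that
the real cohort's published statistics are reproduced (they are
properties of an unavailable dataset and are deliberately not targets).

## Numerical choices and degenerate inputs

* Band lookup is half-open (`lo ≤ x < hi`) everywhere; the tables
  partition the real line, so every finite value scores.
* Logistic fits reject designs with fewer than two subjects per outcome
  class, all-identical scores, or complete separation (classed errors).
* Hosmer-Lemeshow requires n ≥ g and probabilities strictly inside
  (0, 1); tie-collapsed or merged groups reduce the degrees of freedom
  accordingly, and fewer than three distinct quantile breaks is an error.
* AUC confidence bounds come from DeLong (deterministic, the default) —
  for a degenerate AUC of 1 the interval has zero width — or
  Hanley-McNeil.
* Evaluation rows never silently substitute: anything that cannot be
  computed (too few at-risk stays, degenerate fit) is an unevaluable row
  with the reason in `note`, rendered as blanks.

## Problem sizes used by the test suite

The suite validates the statistics at the scales its claims are stated
for: AUC against exhaustive pair enumeration on 100 random datasets of up
to 200 subjects; Hosmer-Lemeshow type-I error on 1000 correctly-specified
cohorts of n = 1000 (rejection rate at α = 0.05 within [0.03, 0.07]);
Wald-interval coverage of a planted logistic slope on 500 cohorts of
n = 500; null-configuration discrimination on 50 generated cohorts of
n = 1000; and generator calibration on 20 default cohorts of n = 2801.
Day-limited experiments use the generator's emission horizon
(`emit_days`) to skip emitting observations that the experiment never
scores; the trajectory and outcomes are unaffected.

## Known limitations

* The CASUS band boundaries are a reconstruction (above); oracle tests
  pin the engine to the shipped table, not to the original publication.
* APACHE II chronic-health weighting on readmission days, and the exact
  windowing of intraoperative values into day 1, are undocumented in the
  validation literature this package follows; the choices here (constant
  chronic component, calendar-day windows) are design decisions.
* The Hosmer-Lemeshow test's behaviour under heavy ties depends on the
  grouping convention; deciles of risk with ties kept together is the
  default, and fixed probability bands are intentionally not offered
  beyond configuring `g`.
* Odds ratios are per score point and therefore not comparable across
  systems with different point ranges; the benchmark reports them per
  system without cross-score comparison.
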