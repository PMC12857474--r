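---
title: "Predicting long-term institutionalization: models, design choices, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting long-term institutionalization: models, design choices, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`pliRisk` implements a population-screening pipeline for two-year risk of
long-term institutionalization (LTI) in nursing homes, built for
administrative claims data. This vignette is the package's account of the
science: the outcome definition, the model and its assumptions, the
parameters that matter, the synthetic-data generator, and the numerical
choices made where the design was genuinely open.

## The outcome: LTI spells on a residential history

Claims arrive as overlapping stay intervals from multiple payers. We
first resolve them to a *residential history*: exactly one setting per
calendar day. When stays overlap, acute care wins — the priority is
hospital > ED > NH > hospice > community — because a nursing-home resident
transferred to hospital is, for outcome purposes, in hospital that day,
and this preserves the meaning of "spell interrupted by acute care".

An **LTI spell** starts on a nursing-home day and accumulates NH days. It
survives runs of *interrupting* settings (hospital, ED — any length) and
community runs of at most `max_community_gap` days (default 7); a longer
community run ends the spell at its last NH day. The spell *qualifies*
when cumulative NH days exceed `day_threshold` (default 90, i.e., "more
than 90"; exactly 90 does not qualify). Both knobs live in
`spell_rule()`.

Three boundary decisions were open and are resolved as follows:

* **Hospice days** are treated like acute interruptions: they never break
  a spell but contribute no NH days. The alternative (hospice as
  community) is one `spell_rule(interrupting_settings =)` call away.
* **The day threshold** is 90 by default; 100 — a variant that appears in
  some published tabulations — is available through the same rule object.
* **Windowing**: a person is LTI-positive when a qualifying spell *starts*
  within the two-year outcome window; NH-day accumulation may continue
  past the window end up to a configurable data horizon (default 910
  days), since a spell that begins in month 23 should not be censored
  into a false negative. Death ends the timeline on the death date; a
  spell already past the threshold remains qualifying.

Stay intervals are inclusive of both endpoints and handled internally as
day sets. The detector is certified against an independent brute-force
day-by-day scanner on 1,000+ randomized timelines in the test suite, and
is monotone in both rule parameters.

Cohort eligibility exclusions run in a fixed order — (a) qualifying
baseline-year spell or any hospice stay, (b) no face-to-face encounter,
(c) baseline-year death, (d) hospital/NH setting on the last baseline
day — with each person tallied once, at the first rule that removes them.

## Covariates

**Frailty (JFI proxy).** The published frailty index is a proprietary
calibration, so the package uses a transparent proxy: the number of
disjoint condition groups (default 13: dementia, stroke, neurodegenerative
disease, malnutrition, pressure ulcer, musculoskeletal injury, heart
failure, seizure, schizophrenia, and four functional domains — mobility
impairment, ADL dependence, sensory impairment, incontinence) with at
least one qualifying diagnosis in the look-back. Each group adds at most
1; the map is fully configurable (`frailty_map()`). Thresholds keep their
published roles: a score of 6+ stands in for the 2+-ADL criterion, 5+
(on VA-source data only) enters the High-Need/High-Risk rule.

**Auxiliary risk score (CAN proxy).** The real system consumes an
externally produced one-year death-or-hospitalization probability. The
package fits a small logistic model of that outcome (age, frailty, prior
hospitalization) on a seeded 20% slice of the cohort and scores everyone.
This is approximately, not strictly, out-of-sample for the 20% slice — a
deliberate simplification, acceptable because the score is one covariate
among many, not the object of inference. A configurable fraction
(default 4.5%) is flagged missing and imputed at the cohort median with
the missingness indicator retained; the median avoids giving imputed
persons leverage in either tail.

**Strata.** Monthly flags over the 12 baseline months: IAH-Q
(hospitalization AND post-acute SNF stay AND ≥2 chronic conditions AND
JFI ≥ 6, all within that month's 12-month look-back) and HNHR
(hospitalization AND VA-data JFI ≥ 5, excluding hospice/palliative,
HBPC/CLC, and ESRD). Any qualifying month in either indicator assigns
elevated risk (ER); otherwise common risk (CR). "Post-acute care" is read
as SNF-type nursing-home stays (home-health episodes are not modelled);
"chronic conditions" are counted over the 18 model conditions minus the
two acute events (sepsis, fracture), since no canonical list is published.

**Race-centered age** is `age − mean(age | race group)`, with means
computed over the analysis cohort. Its purpose is bias mitigation: when
LTI occurs at systematically younger ages in one group, a pooled raw-age
coefficient under-scores that group's cases and inflates their
false-negative rate; centering absorbs the group-level age offset without
introducing race itself as a predictor.

**Production mode** emulates claims lag: non-VA records from the most
recent `lag_months` (default 9) are suppressed; the look-back extends to
24 months; the frailty index becomes the maximum of the 12 monthly
scores; and prior LTI is ascertained only in months 13–24 (the recent
year being unreliable without complete claims). The prior-SNF covariate
uses months 13–24 in both modes, matching its published definition. With
no lag and no records before month 13, production and complete modes
coincide exactly — a property the tests pin down.

## Stratified models

Each stratum gets its own maximum-likelihood binary regression
(`stats::glm`, logit default, probit alternative; IRLS tolerance 1e-8,
max 100 iterations). Facility fixed effects are reference-coded with the
largest facility as reference; facilities unseen at prediction time get
effect 0. Rows are sorted by person id before fitting so results are
bit-stable under input reordering. Constant columns are dropped with a
warning; a covariate whose ranges under the two outcomes do not overlap
raises a perfect-separation error naming it.

The staged fit mirrors operational practice: a first stage with raw age
and the full covariate set; covariates with Wald p < 0.05 in *either*
stratum are retained; the final models refit with race-centered age on
the retained set. Facility effects are kept in the final stage (the
alternative is one argument away). McFadden's pseudo-R²
(`1 − ℓ/ℓ₀`) is reported per stratum — the flavor is a package choice and
its values are not comparable to statistics computed on real data.
Average marginal effects use counterfactual differences for binary
covariates and mean derivatives for continuous ones, with delta-method
(default) or bootstrap intervals.

## Threshold optimization and tiers

High-risk thresholds (τ_ER, τ_CR) maximize captured LTI events subject to
a pooled number-needed-to-screen budget `NNS = flagged/TP ≤ nns_max`
(default 8). Flagging is inclusive (`score ≥ τ`), so observed score
values serve as the candidate grid. The optimizer reduces each stratum to
one candidate per achievable true-positive count — the minimal-flagged
prefix — which is lossless: for any fixed TP split, extra flagged persons
only hurt the budget and every tie-break. Ties resolve by lower pooled
NNS, fewer flagged, then higher τ_ER. The reduction is certified against
full exhaustive enumeration in the tests; an optional percentile grid
handles very large cohorts, with the oracle comparison run on the same
grid. Infeasible budgets raise an error reporting the best achievable
NNS.

Moderate-tier thresholds are *not* part of the published operating point;
the package derives them by re-running the optimizer at a wider budget
(default NNS ≤ 25) and clamping at the high thresholds so tiers nest.
This is an extrapolation, clearly labelled and configurable.

## Evaluation

Standard definitions: sensitivity TP/P, specificity TN/N, PPV TP/flagged,
NNS flagged/TP (= 1/PPV). Decile calibration sorts by score with a stable
tie-break on person id and cuts ten equal-count bins; with heavy ties the
stable sort keeps tied persons adjacent (bins may split a tie run — the
paper-style plot is unaffected). The c-statistic uses the rank-sum
identity with ties counted half. The fairness audit reports the
false-negative rate (cases not flagged high / cases) per race group
within stratum and the between-group gap. k-fold cross-validation
stratifies fold assignment by outcome within stratum and re-tunes
thresholds inside each training set, so no leakage flows from test folds
into threshold choice. Undefined quantities (no positives, no flagged
true positives in a facility) are explicit `NA`s with messages, never
silent drops.

## The synthetic cohort

The generator's defaults are the study conditions, chosen once:

* overall two-year LTI ≈ 1.1%, via class-specific latent logistic models
  whose intercepts are calibrated by root-finding so realized rates hit
  the targets (5% in the latent elevated-need class, 0.47% otherwise);
* non-LTI deaths ≈ 5 per LTI event, calibrated the same way, with 30%
  mortality among LTI entrants;
* a latent elevated-need class (14% of persons) with condition-prevalence
  contrasts patterned on published stratum profiles and a frailty-count
  distribution
  (mean 7.8 vs 2.9) such that the *derived* ER stratum — computed by the
  actual IAH-Q/HNHR rules, not copied from the latent class — lands near
  9.3% of the eligible cohort;
* exclusion-pattern rates (hospice 0.8%, no face-to-face 3.5%, baseline
  death 2.4%, inpatient on the last day 2%) patterned on the published
  attrition;
* two race groups (80/20) with age means 62/56 (SD 16/14), and an
  age-at-LTI differential: the comparison group's true risk uses an
  effective age 6 years older.

LTI-positive persons receive outcome-period NH sequences that satisfy the
spell rule with randomized interruption patterns (single runs, hospital
interludes, ≤7-day community gaps) exercising the detector's edge cases;
non-LTI persons receive at most short post-acute stays (≤45 days). The
stored truth indicator is therefore *identical* to what the detector
recovers — an invariant the tests assert exactly. Diagnoses are emitted
as person-month records (onset uniform over 24 months, re-coded
quarterly, per-record VA/Medicare source), which is what makes the
production-mode lag meaningful.

Two design notes deserve emphasis:

* **Death is a two-step draw, not competing risks.** LTI is drawn first
  from the latent model, then death; death censors nothing except by
  truncating timelines. This matches the margins the design targets but
  understates death-LTI dependence; treat mortality-adjacent conclusions
  accordingly.
* **The age-shift parameter moves rates, not case ages.** An additive
  shift in the risk model's age term is an exponential tilt, so it raises
  the comparison group's LTI *rate* (that is what creates the
  false-negative-rate gap a raw-age model exhibits, and what
  race-centered age repairs — the package's paired simulation shows the
  CR-stratum gap shrinking from ≈0.13 to ≈0.04 on average). The *age at
  entry* differential instead follows a closed form under normal ages:
  case-age gap ≈ (μ_W − μ_B) + β_age(σ²_W − σ²_B) ≈ 9.6 years younger
  entry in the comparison group under the defaults. The tests assert the
  realized gap against that derived expression, not against the raw
  shift value.

What the generator does **not** emulate: realistic claim formats, cost
microsimulation, Medicare Advantage/Medicaid encounter structure, and —
beyond the elevated-need contrast — the joint correlation structure of
covariates, which no published margin constrains. Passing tests therefore
certify the *machinery* (detection, feature construction, fitting,
optimization, evaluation arithmetic) and the *direction* of design
effects (stratification, centering), not real-data performance levels;
headline real-data metrics are unreachable without the restricted source
data.

## Problem sizes and tolerances

The test suite runs the detector oracle on 1,000 random timelines,
exhaustive threshold enumeration up to 10,000 persons, logistic parameter
recovery over 200 replicates at n = 50,000 (pooled 95% CI coverage
asserted within [0.925, 0.975]), decile calibration at n = 50,000 within
4-SD binomial bands, the fairness comparison as a paired simulation over
three seeds at n = 50,000, and full-pipeline runs at 8,000–20,000
persons; the acceptance script uses n = 60,000. Monte-Carlo bands
(LTI rate 0.9–1.3%, death ratio 4.2–5.8, ER share ±2 points) were fixed
alongside the generator defaults. At these sizes the end-to-end pipeline
completes in about a minute on one core; all randomness flows from
explicit seeds and runs are bit-reproducible.

## Known limitations

Beyond the generator simplifications above: the CAN proxy is fit
in-cohort rather than supplied externally; facility effects are plain
fixed effects (no shrinkage), which overfits facilities with few events
at small n; the moderate tier is an extrapolated operating point; and the
exclusion order, while fixed and tested, changes individual tally counts
(not the eligible set) if permuted.
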