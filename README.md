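# pliRisk

Predicting two-year risk of long-term institutionalization (LTI) from
claims-style administrative records.

Health systems that pay for long-term care want to find the small fraction
of community-dwelling patients — here, veterans — who will enter a nursing
home for the long term within the next two years, early enough that
home- and community-based services can still delay or avoid that entry.
The outcome is rare (about 1.1% over two years), roughly five people die
without LTI for every one who experiences it, and the strongest drivers
(function, family support) are absent from claims. `pliRisk` implements
the full screening pipeline that works within those constraints, plus a
synthetic claims generator with known ground truth so every stage is
testable without restricted data.

## The method

1. **Residential history.** Overlapping stay records (nursing home,
   hospital, ED, hospice, any payer) are resolved into one setting per
   calendar day. An **LTI spell** accumulates nursing-home days, survives
   acute-care interruptions of any length and community gaps of at most 7
   consecutive days, and qualifies when cumulative NH days exceed 90.
   Cohort exclusions (baseline LTI or hospice, no face-to-face care,
   baseline death, hospitalized/institutionalized on the index eve) are
   applied in a fixed order.
2. **Covariates.** A transparent diagnosis-group frailty count (JFI
   proxy), an auxiliary one-year death-or-hospitalization probability (CAN
   proxy, with explicit missingness), prior utilization and cost, 18
   condition flags, and **race-centered age**: `age − mean(age | race
   group)`, which removes the bias left by differential age at LTI entry
   across racial groups.
3. **Stratification.** Monthly Independence-at-Home qualification
   (hospitalization + post-acute SNF + ≥2 chronic conditions + JFI ≥ 6)
   and High-Need/High-Risk (hospitalization + VA-data JFI ≥ 5, minus
   hospice/palliative, HBPC/CLC, and ESRD) flags split the cohort into
   elevated-risk (ER, ≈9%) and common-risk (CR) strata, each with its own
   logistic (or probit) model with facility fixed effects, covariates
   retained at Wald p < 0.05.
4. **Thresholds and tiers.** Stratum-specific high-risk thresholds
   (τ_ER, τ_CR) maximize captured LTI events subject to a pooled
   number-needed-to-screen budget, NNS = flagged/TP ≤ 8; a wider budget
   (NNS ≤ 25) defines the moderate tier. The optimizer reduces each
   stratum to its minimal-flagged prefix per true-positive count, which is
   provably lossless, and matches exhaustive enumeration exactly.
5. **Evaluation.** Sensitivity/specificity/PPV/NNS, per-stratum
   c-statistics and McFadden pseudo-R², decile calibration, per-facility
   NNS, stratified k-fold cross-validation, and a false-negative-rate
   equity audit by race group within stratum.

A production variant handles claims lag: non-VA records from the most
recent `lag_months` are suppressed, look-back extends to 24 months, the
frailty index becomes the maximum of monthly scores, and prior LTI is
ascertained in months 13–24 only.

## Worked example

```r
library(pliRisk)

cohort <- simulate_cohort(sim_config(n_persons = 20000, seed = 42))
cohort
#> <pli_cohort> 20000 persons, index 2017-10-01 | LTI 1.16%, deaths 8.60%

result <- pli_pipeline(cohort, seed = 1)
result
#> <pli_result> mode=complete link=logit  n=18251 eligible
#>   ER share 9.7% | high tier 974 (NNS 7.73, sens 56.5%, spec 95.3%)
#>   c-statistic: CR 0.882, ER 0.764

result$thresholds$high
#> <threshold_pair> tau_ER=0.0597 tau_CR=0.0479  NNS=7.73 sens=0.565 flagged=974 TP=126

result$report$tier_table[, c("tier", "n", "lti", "lti_pct")]
#>       tier     n lti    lti_pct
#> 1     high   974 126 12.9363450
#> 2 moderate  3939  72  1.8278751
#> 3      low 13338  25  0.1874344
```

Reading: of 20,000 simulated veterans, 18,251 survive the eligibility
exclusions; 9.7% land in the elevated-risk stratum. The tuned thresholds
(≈6.0% risk in ER, ≈4.8% in CR) flag 974 people — screening 7.7 of them
finds one future LTI entrant — and that high tier holds a 12.9% two-year
LTI rate versus 0.19% in the low tier. `plot_calibration(result)` and
`plot_facility_nns(result)` draw the calibration and facility-NNS
figures; `kfold_cv()` cross-validates the whole fit-tune-evaluate loop.

A thin command-line wrapper covers the same steps
(`Rscript inst/cli/pli.R simulate|build-rhf|features|pipeline --help`-style
flags are documented in the script header).

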