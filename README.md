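# ercpredict

Validation toolkit for a vein-level risk score that predicts **early
reconnection / dormant conduction (ERC)** after cryoballoon pulmonary vein
isolation (PVI).

## The problem

After cryoballoon PVI for atrial fibrillation, a vein that looks isolated can
reconnect within 30 minutes, spontaneously or when unmasked by adenosine.
Finding ERC matters — treating it with additional applications improves
rhythm outcome — but the standard 30-minute wait plus adenosine challenge
adds time and patient discomfort to every procedure. A simple score computed
from parameters already on the console at the end of the freeze can predict
the *absence* of ERC and let selected patients skip the wait:

```
score = 0.02 · TTI + 0.5 · n_unsuccessful + 0.2 · nadir
```

where `TTI` is the time to isolation (s), `n_unsuccessful` the number of
unsuccessful cryo-applications, and `nadir` the nadir balloon temperature
(°C). A vein with `score ≥ cutoff` should be tested for ERC; ties count as
positive. Two cutoffs are supported: the originally derived −6.7 and the
common cutoff −7.2 chosen to perform well in derivation and validation
cohorts alike.

`ercpredict` is for anyone validating such a score on their own cohort: it
covers freeze-trace feature extraction (freeze AUC, freeze magnitude,
warming times), the score and its bedside decision table, the full
diagnostic-accuracy suite (sensitivity/specificity, likelihood ratios,
prevalence-adjusted predictive values via Bayes, ROC with DeLong confidence
intervals, expected whole-vein counts, cross-cohort cutoff comparison), and
one-year AF-free survival under blanking-period and antiarrhythmic-drug
(AAD) censoring rules. A synthetic cohort generator with the matching
covariate structure makes every stage testable without patient data.

## Worked example

Diagnostic metrics from confusion counts at the common cutoff −7.2
(27/10/131/482 true-positive/false-negative/false-positive/true-negative
veins), with predictive values at a cohort prevalence of 41/774:

```r
library(ercpredict)
m <- metrics_from_confusion(list(tp = 27, fn = 10, fp = 131, tn = 482),
                            prevalence = 41 / 774)
round(m[, c("sensitivity", "specificity", "lr_pos", "lr_neg", "ppv", "npv")], 4)
#>   sensitivity specificity lr_pos lr_neg    ppv    npv
#> 1      0.7297      0.7863 3.4147 0.3437 0.1604 0.9811
```

The sensitivity 72.97% and specificity 78.63% come straight from the counts;
the positive likelihood ratio 3.415 says a positive score is ~3.4× more
likely in an ERC vein; the NPV 98.11% — driven by the low 5.3% prevalence —
is what justifies skipping the adenosine test after a negative score.

A full validation run on a synthetic cohort (200 patients, four veins each):

```r
veins <- generate_cohort(cohort_config(seed = 2024))
run_validation_report(veins)
#> ERC validation report
#>   689 of 800 veins with complete model data; prevalence used 0.0563
#>   AUC 0.801 (95% CI [0.746, 0.856])
#>   cutoff -6.7: sens 42.11%, spec 87.25%, LR+ 3.302, LR- 0.664, PPV 16.45%, NPV 96.20%
#>   cutoff -7.2: sens 55.26%, spec 78.65%, LR+ 2.588, LR- 0.569, PPV 13.36%, NPV 96.72%
#>   cutoff -6.7: 64/110 patients with all data would skip testing (12 ERC patient(s) missed)
#>   cutoff -7.2: 46/110 patients with all data would skip testing (9 ERC patient(s) missed)
```

The bedside decision table inverts the score at the cutoff: for each nadir
temperature and unsuccessful-application count it gives the minimal TTI that
makes testing necessary (`decision_table()`, `decision_table_wide()`,
`autoplot()`). For example a vein with nadir −39 °C and no unsuccessful
applications needs testing from TTI ≥ 30 s; with nadir −44 °C and three
unsuccessful applications, from TTI ≥ 5 s; a vein at −46 °C with no
unsuccessful applications never reaches the cutoff within the 95 s display
cap.

Survival analysis with the study's censoring rules:

```r
fu <- generate_followup(followup_config(seed = 1))
entries <- build_survival_entries(fu$followup, fu$aad_intervals)
km_estimate(entries)   # per-group product-limit curves; autoplot() to draw
log_rank(entries)      # two-group log-rank chi-square and p-value
```

Patients enter the curve after a 90-day blanking period; only AAD-free days
accrue survival time; a recurrence on an AAD censors at the last AAD-free
follow-up date, and patients with no AAD-free follow-up are excluded (see
`survival_exclusions()`).

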