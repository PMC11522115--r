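---
title: "Validating an ERC prediction score for cryoballoon PVI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating an ERC prediction score for cryoballoon PVI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ercpredict)
```

## The clinical question

Cryoballoon pulmonary vein isolation (PVI) is a standard single-shot
ablation for atrial fibrillation. A vein that is electrically isolated at
the end of the freeze can nevertheless reconnect early: either spontaneous
reconnection during a 30-minute waiting period or dormant conduction
unmasked by intravenous adenosine — collectively *ERC*. ERC is worth
finding (re-ablating it improves outcome), but the waiting period and the
adenosine challenge cost roughly half an hour per procedure and cause
transient chest discomfort, dyspnea and flushing.

The score validated here predicts ERC at the vein level from three
quantities available on the console the moment isolation is achieved:

$$\mathrm{score} = 0.02\,\mathrm{TTI} + 0.5\,n_\mathrm{unsucc} +
  0.2\,T_\mathrm{nadir}$$

with TTI the time to isolation in seconds, $n_\mathrm{unsucc}$ the number
of unsuccessful cryo-applications on that vein, and $T_\mathrm{nadir}$ the
nadir balloon temperature in °C. All three reflect occlusion quality: a
poorly occluded vein isolates late, needs repositioning, and never gets as
cold because leaking blood warms the balloon. The coefficients are taken as
given — deriving them (by logistic regression on a derivation cohort) is
outside this package's scope.

A vein with score at or above the cutoff should be tested for ERC; the tie
counts as positive by the score's published definition. The package
supports the originally derived cutoff −6.7 and the common cutoff −7.2.

## Freeze-trace features

`extract_features()` treats a trace as piecewise linear between samples.

* **Freeze AUC** (°C·s): area between the curve and the 0 °C axis, counted
  only where the temperature is below zero, by trapezoidal integration with
  linear interpolation of the zero crossings. This is exact for polyline
  traces and invariant under grid refinement, and assumes no model for the
  curve.
* **Freeze magnitude** (°C): freeze AUC divided by the time below 0 °C — a
  time-normalised freeze intensity that always lies in $[0, |nadir|]$.
* **Spot temperatures** at 30 s, 60 s and at the TTI, by linear
  interpolation, never extrapolated. The TTI is an electrogram annotation
  and is always supplied, never derived from temperature.
* **Warming times** to 0, 15 and 20 °C. The reference point for "warming
  time" is not standardised by console exports; the package defaults to the
  time of the global temperature nadir (earliest sample in case of ties,
  for determinism) and accepts an explicit thaw-start marker via
  `warming_ref = "marker"`. Consoles frequently stop recording at automatic
  balloon deflation before 20 °C is reached; for traces flagged
  `deflation_truncated` the elapsed time to the final sample is returned
  with a `truncated` flag rather than `NA`, matching how truncated warming
  times are collected in practice.

## Diagnostic-accuracy suite

Throughout the package a prediction is positive iff score ≥ cutoff — the
ROC sweep, the confusion counts and the classifier all share this
convention, so operating points on the curve are exactly reproducible with
`confusion_at_cutoff()`.

Sensitivity and specificity come from the confusion counts. Predictive
values are computed by Bayes' theorem at a caller-supplied prevalence,
deliberately decoupled from the complete-case sample's class balance: the
natural choice is the cohort-level vein prevalence (all veins, before
complete-case filtering), because that is the prevalence a lab actually
faces. `expected_counts()` converts rates back to whole veins
(`sensitivity × n_ERC`, `(1−specificity) × n_nonERC`,
`(1−sensitivity) × n_ERC`), rounding half away from zero since base R's
banker's rounding would split printed counts.

The empirical AUC equals the Mann–Whitney pair statistic; its confidence
interval uses the DeLong placement variance (the standard for empirical
ROC curves), with Hanley–McNeil available by flag. Both are implemented
in-package so the threshold convention stays consistent; the test suite
cross-checks them against brute-force pair enumeration and against pROC.

`compare_cutoffs()` evaluates candidate cutoffs in two cohorts at once and
selects the cutoff maximising the *minimum* Youden index across the two.
Choosing a common cutoff for derivation and validation data is often done
by visual inspection of overlaid ROC curves; the max–min-Youden rule is an
explicit, reproducible surrogate for that practice, not a claim about how
any particular study chose its value.

### The bedside decision table

`decision_table()` inverts the score at the cutoff:
$\mathrm{TTI}^\* = (\mathrm{cutoff} - 0.5\,n - 0.2\,T)/0.02$, the minimal
TTI making a vein test-positive. Cells with $\mathrm{TTI}^\* \le 0$ are
*always test*; cells beyond the display cap are *never test*. The cap
defaults to 95 s — the largest threshold the published grid displays; 90 s
is also the repositioning limit during ablation, so the cap is exposed as
an argument rather than hard-coded. Because the decimal coefficients are
not binary-exact, the inversion snaps its result to $10^{-7}$; without
this, thresholds that are exactly 95 land an epsilon above the cap and flip
to *never test*.

## Survival under blanking and AAD rules

One-year AF-free survival is compared between ERC and non-ERC patients with
specific accounting rules, all implemented in
`build_survival_entries()`:

* a 90-day blanking period — recurrences inside it are ignored and
  patients enter the curve at its end;
* the survival clock counts **only AAD-free days** after blanking. Days on
  an antiarrhythmic drug pause the clock (this differs from calendar time
  and is the package's most consequential rule); a `reset` mode that
  restarts the clock after each AAD spell is available by flag, since the
  pause-versus-reset choice is genuinely underdetermined;
* a recurrence while on an AAD cannot count as an AAD-free event: the
  patient is censored at the last AAD-free follow-up date. If no AAD-free
  follow-up after blanking exists, the patient is excluded — this single
  rule reproduces the accounting in which patients recurring on a drug they
  never stopped do not enter the curve at all;
* patients whose entire post-blanking follow-up was on an AAD, or with
  missing/inconsistent dates, are excluded with a logged reason; entry
  count plus exclusion count always equals the input patient count;
* administrative censoring at 365 days on the survival clock.

"Last follow-up date without AAD" is taken from the
`last_aad_free_day` column when supplied (a visit date), and otherwise
derived as the latest time before the recurrence not covered by any AAD
interval. Kaplan–Meier estimation and the log-rank test are delegated to
the survival package (`survfit`/`survdiff`); the p-value uses the
chi-square distribution with $k-1$ degrees of freedom and no continuity
correction. Tests verify both against hand product-limit and
observed-minus-expected computations.

## What the synthetic generator emulates

`generate_cohort()` draws, per vein, a latent ERC group and then
group-conditional covariates:

* **TTI**: log-normal — right-skewed and positive, matching the
  median-below-mean pattern of procedural times — calibrated so the median
  and IQR hit 40 (27–60) s in non-ERC veins and 50 (38–75) s in ERC veins.
  Calibration solves `meanlog = log(median)`,
  `sdlog = log(q75/q25) / (2 Φ⁻¹(0.75))`.
* **Nadir temperature**: normal, median −47 (IQR −51…−43) °C versus −41
  (−45…−38) °C; `sd = IQR / (2 Φ⁻¹(0.75))`.
* **Unsuccessful applications**: zero-inflated geometric with 21.2% versus
  36.6% of veins having at least one, and geometric tails beyond the first
  (success probability 0.6, giving mostly counts of 1–2).
* **Prevalence**: vein-level ERC probability 5.3%; with a patient-level
  random effect (logit scale, default sd 0) the intercept is recalibrated
  by quadrature so the marginal prevalence is preserved. The default of 0
  mirrors the fact that the score itself was built ignoring within-patient
  clustering; a positive sd is available to study that limitation.
* About 12% of veins are marked `untested` (drawn among non-ERC veins, so
  the observed prevalence equals the target) and each predictor is missing
  in 5.6% of veins — chosen so that roughly 84% of veins are complete
  cases, the completeness structure a validation analysis has to cope
  with.

An optional `outcome_model` (logistic in the true score) replaces the
group-conditional labels; it exists for property tests — slope 0 must
destroy discrimination (AUC ≈ 0.5) and AUC must increase strictly with the
slope. Under the default group-conditional laws the score's AUC on
generated data is ≈ 0.8, in the range reported for this kind of score.

What the generator does **not** emulate: console noise artifacts,
esophageal temperature, accessory or common-ostium veins, informative
missingness (fields are missing completely at random), and any correlation
between covariates beyond what the shared ERC label induces. Passing tests
on synthetic data therefore demonstrate correctness of the pipeline's
arithmetic and rules, not clinical transportability.

`generate_trace()` builds temperature curves as exponential-approach
cooling toward the requested nadir, then a linear rewarm to 0 °C followed
by an exponential approach to body temperature, sampled at 1 Hz (cooling
time constant 20 s, rewarm rate 7 °C/s, rewarm time constant 40 s — chosen
to land the spot temperatures at 30/60 s, the freeze magnitude near 38–41
°C and the warming times near their observed medians). The generating
curve's exact feature values are attached as a `truth` attribute, giving
closed-form oracles for the extractor. `generate_followup()` emits
patients in each exclusion/censoring category with exact configured
counts (defaults mirror the 201-patient accounting: 13 missing follow-up,
7 AAD-only, 23 recurrences on a never-stopped AAD), an exponential event
time among entrants (rate 0.28/year) and a group hazard ratio for
simulation studies.

## Numerical and design choices

* Ties at the score cutoff are positive ("equal to or above").
* Nadir with tied minima: earliest time, for determinism.
* Missing table cells are empty strings on disk, never sentinel numerics —
  a −999 in a temperature column is a corrupted covariate, not a missing
  one.
* Vein labels are fixed to the four standard pulmonary veins
  (LSPV/LIPV/RIPV/RSPV); rows with other labels are rejected with a
  diagnostic rather than guessed at. Structurally invalid rows (unparsable
  numerics, unknown statuses) are likewise rejected per row; clinical
  plausibility checks are left to the caller.
* When a vein has several applications, the predictors should come from
  the application achieving isolation (that is what the TTI definition
  refers to); `extract_features_from_manifest()` returns one row per
  application so either that or a coldest-application rule can be applied
  upstream.
* Problem sizes in the test suite: property checks run on cohorts of
  150–6000 patients, ROC oracles on up to 10³ veins, and the log-rank
  type-I simulation on 400 replicates of 60-patient two-group cohorts
  (rejection rate checked against the nominal 5% and p-value uniformity by
  Kolmogorov–Smirnov).

## Limitations

The validation metrics assume vein-level independence, which is known to be
imperfect (a patient's veins share anatomy and operator); the random-effect
option in the generator exists precisely to probe how clustering moves the
metrics. Predictive values are only as good as the supplied prevalence.
The decision table inherits the score's calibration — it is a display of
the score at one cutoff, not a new model. And nothing here adjudicates
recurrences from raw rhythm recordings; follow-up events are inputs.
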