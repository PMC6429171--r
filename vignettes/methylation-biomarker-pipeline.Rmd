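---
title: "Discovering and evaluating tissue-specific DNA methylation biomarkers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering and evaluating tissue-specific DNA methylation biomarkers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methmark)
```

## The problem

A DNA methylation marker intended for detecting prostate cancer — ideally
one day from a blood draw — has to satisfy more than "methylated in tumor,
unmethylated in normal prostate". Most cell-free DNA in plasma comes from
blood leukocytes, so any CpG with even low-level methylation in blood cells
will produce false positive signal; and a marker methylated in colorectal or
lung tumors cannot distinguish prostate cancer from other malignancies.
methmark implements a discovery-and-evaluation pipeline built around exactly
these constraints: a genome-wide selection cascade over grouped Illumina
450K β-value matrices, reduction of quantitative methylation-specific PCR
(qMSP) validation plates to normalized methylation levels, and diagnostic
(ROC) plus prognostic (biochemical-recurrence survival) evaluation of the
resulting markers.

Every stage is exercised on synthetic data with planted ground truth, so
the pipeline's behaviour is checkable end to end: the generators know which
CpGs should survive the cascade, what every plate well's true template
quantity is, and which hazard coefficients generated a cohort.

## The discovery cascade

The substrate is a β-value matrix (CpG × sample, β ∈ [0, 1], the methylated
fraction of a locus) with each sample assigned to one of five groups:
peripheral blood, normal prostate, prostate cancer, other normal tissue,
other cancer tissue. For a vector of group values and a cutoff *c*,
the primitive statistic is the fraction of non-missing values strictly
greater than *c* (`fraction_above()`); missing β values leave both
numerator and denominator (per-CpG complete case — no imputation).

The cascade has three rules, all thresholds strict:

1. **Blood pre-filter** — discard any CpG with detectable methylation
   (β > 0.2) in more than 1% of peripheral-blood samples.
2. **Search string 1, "pan-cancer" candidates** — among survivors, select
   CpGs hypermethylated (β > 0.5) in more than 80% of prostate-cancer
   samples, excluding CpGs with β > 0.2 in more than 19% of normal
   prostate samples.
3. **Search string 2, "PCa-specific" candidates** — select CpGs with
   β > 0.5 in more than 60% of prostate-cancer samples, excluding CpGs
   with β > 0.2 in more than 8% of other-cancer samples or in more than
   30% of normal prostate samples.

Because every "more than *x*%" is read strictly, a CpG sitting exactly at
an exclusion bound is retained; the boundary behaviour is unit-tested, so
changing this reading is a one-constant edit in `filter_thresholds()`.
Candidates are then summarized per CpG: group medians, the median
difference (prostate-cancer median minus the maximum of the other four
group medians), and a two-sided Mann–Whitney test of prostate cancer
versus normal prostate, with an effect criterion of median difference
> 0.30 and p < 0.001.

```{r discovery}
sim <- generate_beta_matrix(simulation_config(seed = 7))
report <- run_discovery(sim$beta, sim$annotation)
report
```

## What the β-value generator emulates — and what it does not

`generate_beta_matrix()` draws each CpG's per-group values from Beta
distributions attached to a *marker archetype* (`default_archetypes()`),
chosen because β is bounded in [0, 1] and array β-values are classically
bimodal. Six archetypes span the outcomes the cascade separates:
PCa-specific markers, pan-cancer markers, blood-methylated CpGs,
globally (un)methylated CpGs, and a near-miss class that fails exactly the
normal-prostate exclusion. Shape parameters are calibration choices, not
estimates from any dataset: "unmethylated" groups use Beta(1, 20), blood
background Beta(1, 50) (P(β > 0.2) ≈ 1.4·10⁻⁵), hypermethylated groups
Beta(8, 2) (P(β > 0.5) ≈ 0.98), and the near-miss normal prostate
Beta(3, 3). These are deliberately decisive — at the default group sizes
each archetype's cascade verdict matches its declared intent with per-CpG
probability well above 0.99 — so planted-truth tests measure the cascade,
not the generator's noise.

The default group sizes (219 blood / 20 normal prostate / 47 prostate
cancer / 158 other normal / 573 other cancer) mirror the composition of a
large 450K compendium discovery set scaled down four-fold; at 200 CpGs per
archetype a full discovery run takes a few seconds. Missing values are
inserted completely at random (default 1%) — enough to exercise
denominator handling, not a model of array QC failure. The generator does
**not** emulate Infinium probe chemistry, batch or normalization effects,
probe cross-reactivity, or correlated methylation along the genome; a
passing planted-truth test therefore says the selection logic is correct,
not that real discovery data would be as cleanly separable.

## qMSP quantification and quality control

qMSP amplifies only bisulfite-converted methylated template; the readout
per well is a quantification cycle Ct, with "undetermined" meaning the
signal never crossed threshold. Quantity follows the standard log-linear
model Ct = intercept + slope·log₁₀(quantity); the generator's default
slope of −1/log₁₀(2) ≈ −3.32 cycles per decade corresponds to 100%
amplification efficiency, and `fit_standard_curve()` recovers slope,
intercept, R² and efficiency from the plate's serial-dilution standards.

Reduction follows a fixed order of operations per sample-target
triplicate:

1. **Outlier removal** — a replicate deviating by more than 2 cycles from
   the median of its siblings is dropped; at most one per triplicate. The
   median-of-others comparison was chosen over pairwise comparison because
   it is symmetric and naturally removes at most one well; a disagreeing
   pair of replicates is never adjudicated.
2. **Zero rules per replicate** — a replicate is zeroed when its Ct is
   undetermined, above the cycle cap (40 in large-scale mode, 37 in
   small-scale validation mode), or above the minimum Ct observed in the
   run's negative controls (whole-genome-amplified DNA and water), read
   conservatively as the earliest-amplifying control. Zero rules are
   applied per replicate, before averaging; idempotent, so a replicate
   zeroed by one rule stays zero under the others.
3. **Averaging on the linear scale** — quantities (not Ct values) are
   averaged, so zeroed replicates dilute the estimate as they should.
4. **Sample QC** — a sample fails when its mean ALUC4 Ct exceeds 24
   (insufficient DNA input), when MYOD1 never amplifies (failed bisulfite
   conversion), or when a reference assay has fewer than two amplified
   replicates. Per marker target, exactly one amplified replicate fails
   that sample-target (a single surviving reaction is unconfirmable),
   while zero amplified replicates is a *valid quantity-0 result* — this
   distinction is what lets a blood panel report a 0% false positive rate
   instead of failing QC wholesale.
5. **Normalization** — marker quantities are divided by the sample's
   ALUC4 quantity, making levels invariant to global DNA input.

Every removal, zeroing and failure is recorded in a ledger, so each well
is accounted for as used, removed, zeroed (with the rule named), or part
of a failed sample.

## Diagnostic evaluation

Orientation is fixed: higher methylation means malignant. `mann_whitney()`
counts pairs with ties at ½ and uses exact enumeration when the combined
sample size is ≤ 12 (feasible and exact under ties; 924 arrangements at
6 + 6) and the tie-corrected normal approximation without continuity
correction otherwise. `roc()` places candidate thresholds at midpoints
between consecutive distinct levels plus ∓∞ sentinels, classifies strictly
above threshold, and computes AUC by trapezoid — identical to U/(n₁n₂) to
1e−9, which the tests assert on a thousand random instances.
`sensitivity_at_specificity()` treats the specificity bound as a floor
(the conservative reading of "fixing specificity at 95%"), and
`detection_performance()` calls a sample positive iff its normalized level
is strictly above zero.

## Prognostic evaluation

The endpoint is biochemical recurrence (BCR) after radical prostatectomy,
in months. Patients are dichotomized into high/low methylation by
`derive_cutoff()`: BCR status at a 36-month horizon (recurred by then /
recurrence-free at least that long / censored earlier, hence excluded from
cutoff derivation *only*), then the ROC threshold maximizing Youden's J,
ties broken toward higher specificity. Kaplan–Meier curves, medians
(smallest time with S(t) ≤ 0.5, else "not reached") and two-sided log-rank
tests compare the groups; Cox proportional-hazards models (Efron tie
handling — month-resolution times tie often — with Breslow behind a flag)
report hazard ratios with 95% Wald intervals (normal quantile 1.959964).
Harrell's C is computed from the linear predictor with the classical pair
convention: a pair is comparable iff the strictly smaller time carries an
event, score ties count ½. `backward_select()` removes the worst covariate
with Wald p > 0.05 until none remains, and reports the final model's
concordance with and without the marker covariates. Multiplicity is
adjusted by Benjamini–Hochberg by default with Hochberg selectable, since
both conventions are current in this literature. Kaplan–Meier, log-rank
and the Cox fitter itself are delegated to the survival package; the
package's own tests check them against brute-force risk-set products,
O(n²) pair enumeration and the Cox score test.

The cohort generator draws exponential event times under a
proportional-hazards model with covariates centered at their expectations,
so the configured baseline hazard (default 0.008 events/month) is the
hazard of an average patient whatever the coefficients. Default covariates
mirror routine clinicopathological variables (positive surgical margin
30.5%, PSA ≥ 10 ng/mL 60%, Gleason 8–10 18.3%, pT ≥ pT2c 78.7%, D'Amico
groups 12/41/47%), and the censoring target (46% total) is met by topping
up administrative censoring at the 219-month horizon with uniform
censoring before the event, self-calibrated against the drawn times.
Exponential times suffice here because Cox estimation is agnostic to the
baseline hazard shape.

## A calibration caveat the tests make explicit

Deriving a marker's cutoff from the same cohort in which the resulting
groups are then compared is not a calibrated test. With a marker
*independent* of outcome, the package's own null experiment (500
replicates, n = 150) shows the dichotomize-then-log-rank p-values are
stochastically smaller than uniform — roughly 16% fall below 0.05 — purely
from cutoff-selection optimism, a well-known property of maximally
selected statistics. The companion experiment with a pre-specified median
split, no selection, is exactly uniform (5.0% below 0.05), which localizes
the inflation to the selection step, not the survival machinery. Log-rank
p-values quoted after ROC-derived dichotomization should therefore be
read as descriptive; honest inference needs an independent cohort or a
selection-aware correction.

## Numerical choices and degenerate inputs

* All randomness flows from single integer seeds through named substreams,
  so adding one generator call never shifts another generator's stream and
  every run is bit-reproducible.
* Missing β and undetermined Ct are empty fields on disk, `NA` in memory;
  readers reject out-of-range values naming the offending CpG/sample or
  well.
* `fraction_above()` errors on an all-missing denominator rather than
  returning NaN; summaries flag (not drop) CpGs with an empty group.
* Cox fits reject non-convergence and diverging coefficients (complete
  separation) instead of returning unusable estimates; survival fits
  reject non-positive times, which is how a degenerate zero-horizon
  cohort surfaces.
* `derive_cutoff()` refuses constant marker levels (no informative
  threshold) and one-class horizon statuses.
* Strata with a single dichotomy class or no events are reported
  untestable rather than failing a subgroup analysis.

## Problem sizes

Defaults were chosen so a full synthetic pipeline run (`run_pipeline()`)
completes in seconds: a 1200 × 1017 discovery matrix, a 124-sample
two-marker plate with four-point standard curves in triplicate, and a
197-patient cohort. The test suite's property checks use matrices up to a
few hundred CpGs, concordance oracles up to n = 200, and coefficient
recovery at n = 2000 over 100 replicates.

## Known limitations

Beyond the generator simplifications above: the pipeline evaluates one
marker at a time (no multi-marker panels or penalized models); confidence
intervals for AUC are not computed; competing risks and time-dependent
covariates are out of scope; and the D'Amico/CAPRA-S risk scores are
consumed as precomputed ordinal inputs, never derived from their
components.
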