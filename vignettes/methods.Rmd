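---
title: "Methods: two-instrument urinary VOC classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-instrument urinary VOC classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Urine headspace carries trace volatile organic compounds (VOCs) tied to
metabolic state, and two classes of "electronic nose" instrument can read
them without identifying individual chemicals. A FAIMS (field-asymmetric
ion mobility spectrometry) analyser sweeps a compensation voltage (CV,
−6 V to +6 V in 512 steps) at each of 51 dispersion-field (DF) settings
for both ion polarities, producing a 512 × 102 ion-current matrix —
52,224 values — per sample. A metal-oxide (MOS) sensor array records 18
resistance traces for 180 s at 1 Hz; each sensor's dimensionless response
is $R = (R_0 - R_T)/R_0$, the fractional resistance drop from its
baseline $R_0$.

`vocdx` implements the full analysis that turns such measurements into a
case/control diagnostic claim: feature extraction per instrument,
leakage-safe feature selection inside cross-validation, four classifier
families, ROC reporting with bootstrap confidence intervals, and
sample-age stratification. Because no raw cohort of this kind is publicly
available, the package ships a synthetic-cohort generator whose defaults
state the cohort the analysis assumes; every claim a green test makes is
a claim about that stated world.

# The model pipeline

## FAIMS features: periodized Daubechies-4 wavelets

Each dispersion matrix is decomposed with a separable 2D multilevel
discrete wavelet transform using the Daubechies 4-tap filter pair (two
vanishing moments) and **periodized** boundaries. Periodization keeps the
transform orthonormal: the coefficient count equals the input count,
energy is conserved exactly, and the inverse is the transpose — all three
are enforced by tests at 1e−8/1e−6 tolerances.

A two-channel orthonormal bank needs an even signal length, so an axis is
halved only while its running length is even (and ≥ 4, the filter
support). For 512 × 102 the CV axis supports 8 levels while the DF axis
(102 → 51) supports one; deeper levels transform the CV axis alone. The
default depth is 4 with all subbands retained (`keep = "all_levels"`,
52,224 named coefficients); `keep = "coarsest_only"` keeps the deepest
level only. The paper-scale default is deliberately generous: the
fold-wise selector, not the transform, decides which coefficients matter.

Technical replicates (duplicated sample ids) are averaged into one matrix
per biological sample *before* extraction, so replicate copies can never
straddle a train/test split.

## eNose features

Three per-sensor families: peak response $\max_t (R_0 - R(t))/R_0$,
`max_over_baseline` $\max_t R(t)/R_0$, and `max_variance` — the maximum
over sliding windows of the population variance of the raw trace. The
phrase "maximum variance of sensor resistance" is ambiguous; we default
the window to the full trace (plain per-sensor variance) and expose the
window length. The feature is translation-invariant and non-negative by
construction.

## Selection

Two selectors, both always fitted on the training portion of the current
fold only:

* **Wilcoxon top-k** — per-feature two-sided rank-sum p-values, ranked
  ascending, ties broken by feature index, top 10 kept by default. Exact
  p-values when both groups have ≤ 10 samples (closed form without ties,
  full enumeration of group assignments with ties); tie-corrected,
  continuity-corrected normal approximation otherwise. P-values are
  invariant to monotone feature transforms.
* **Boruta** — an all-relevant shadow-feature procedure on the package's
  own random forest. Each iteration shuffles shadow copies of the
  undecided features, *padded to the original feature count*; a real
  feature scores a hit when its out-of-bag permutation importance beats
  the best shadow. Hit counts are tested against Binomial(iters, ½),
  two-sided, Bonferroni-corrected over the undecided set at α = 0.05.
  Confirmed features stay in the forest design; only rejected features
  leave. The padding matters: with shadows of the undecided set alone,
  the max-shadow bar collapses late in a run and chance-correlated noise
  survivors get confirmed against a weakened control; the padded
  ensemble keeps the bar at its iteration-one strength.

## Classifiers and the leakage-safe protocol

A stratified 70/30 split isolates the test set. Ten-fold stratified
cross-validation runs on the training set; *within each fold* selection
is re-fitted on the fold's training portion, every hyperparameter
candidate is fitted on the selected features and scored on the fold's
held-out portion. The candidate with the lowest mean out-of-fold
misclassification error wins (ties to the earlier grid entry); the final
model refits selection and classifier on the full training set.
Fold-wise selections are shared across families — selection does not
depend on the classifier — which also makes the leakage audit byte-exact.

The four families (defaults; all grids overridable):

| family | implementation | grid |
|---|---|---|
| sparse logistic | `glmnet` lasso, $\lambda = 1/(Cn)$ | $C \in \{0.01, 0.1, 1, 10\}$ |
| random forest | own CART/Gini forest (Rcpp), 500 trees | mtry fraction $\{1/3, 0.6\}$ |
| Gaussian process | SE-kernel ridge on ±1 labels, noise 0.1 | length-scale × median distance $\{0.5, 1, 2, 4\}$ |
| SVM | RBF dual QP (`quadprog`), $\gamma = 1/p$ | $C \in \{0.1, 1, 10\}$ |

Logistic, GP and SVM see features standardized with training-fold
mean/sd; the forest is scale-equivariant and sees raw values. The GP
"classifier" is the regression surrogate (posterior mean on ±1 labels):
monotone in case-likelihood, deterministic, and robust at these sample
sizes; full Laplace-approximate GP classification was judged not worth
its complexity here.

## Evaluation

AUC is the Mann–Whitney concordance (ties count ½). The operating point
maximizes Youden's J over all thresholds, ties resolved toward higher
sensitivity; sensitivity, specificity, PPV and NPV come from the implied
confusion matrix at the test set's empirical prevalence (PPV/NPV are
undefined-as-missing when a margin is empty). Confidence intervals are
stratified percentile bootstrap (B = 2000 by default) — one joint
resampling per report row, so AUC and operating-point CIs share
resamples. The reported p-value is the two-sided Mann–Whitney test on
the scores, chosen for coherence with the AUC through the U–AUC
identity. PCA (sign convention: largest-magnitude loading positive) and
a ridge-regularized Fisher discriminant support the visual analyses.
The threshold rule, CI method and p-value test are this package's
choices; the original clinical analysis does not name its own.

# The synthetic world

`synthetic_config()` states the cohort: 73 cases / 67 controls, sample
ages uniform on 0–4 years, and for each sample

* **FAIMS** — a reactive-ion peak (Gaussian in CV, amplitude 10 a.u.,
  drifting linearly with DF index and decaying at high fields, mirrored
  more weakly in the negative-ion block), three class-independent
  analyte peaks, and 4 marker peaks of unit base amplitude multiplied by
  `effect_size` (default 2) in cases;
* **eNose** — first-order exposure kinetics
  $R(t) = R_0 - A(1 - e^{-t/\tau})$ with sensor-specific $(R_0, A, \tau)$
  spanning 108–244 Ω baseline and 13.5–39 Ω response, 3 marker sensors
  whose $A$ is `effect_size`-fold larger in cases;
* **storage-age decay** — every analyte (not the reactive-ion peak)
  scaled by $e^{-\lambda \cdot \text{age}}$; λ defaults to 0 and the
  age-effect analyses calibrate it so 4-year-old samples retain ~10% of
  their signal, matching the qualitative finding that old samples stop
  emitting diagnostically useful VOCs;
* **noise** — i.i.d. Gaussian, sd 2 (ion-current units / Ω). The floor
  is set so a 10×-decayed unit analyte peak is sub-detectable while
  fresh class effects remain separable — the storage-age finding is a
  property of the stated world, not an accident of one seed.

Identical config + seed gives bit-identical cohorts; labels are exactly
(n_case, n_control); the planted marker amplitude is strictly decreasing
in age for λ > 0 (exposed as an attribute for audits).

**What the generator does not model** — and therefore what a green test
does *not* establish: chemically realistic VOC spectra, sensor drift,
humidity/temperature confounders, per-sample biological amplitude
variability beyond the class and age effects, batch effects, and any
connection to real diabetic urine. Green acceptance tests establish that
the *pipeline* recovers planted structure and stays calibrated under a
null; they say nothing about clinical performance.

# Numerical choices and degenerate inputs

* Wavelet feasibility: an infeasible depth errors with the maximum
  feasible level; odd axes are carried, never padded (padding would
  break the zero-detail property of constant inputs).
* A feature constant across all samples gets rank-sum p = 1.
* A fold-training set with fewer than two samples in a class cannot be
  rank-tested; in-fold selection then keeps all features (the minimal
  2-fold, 4-sample problem still runs).
* Boruta with `max_iter = 0` leaves every feature tentative; a run
  confirming nothing falls back to tentative, then to all features, so
  downstream fitting always has input.
* The SVM dual adds a 1e−8 ridge; the discriminant's within-class
  scatter a relative ε ridge (default 1e−6), which also absorbs
  collinear features.
* Percentile-bootstrap resampling is stratified by class, so no resample
  is degenerate.
* All randomness flows from explicit seeds through a save/restore
  wrapper; reruns with an identical manifest are byte-identical.

# Known limitations

* Out-of-fold scores pooled across folds are not on a common scale for
  margin-based models when folds are tiny (2–3 samples); the held-out
  test report is the trustworthy one in small-subgroup studies, and the
  age-effect analyses therefore compare held-out AUC averaged over
  families and split seeds.
* With ~50 features at n = 60, chance correlations up to |r| ≈ 0.3–0.5
  arise; Boruta's all-relevant semantics legitimately confirm a feature
  that is genuinely (if accidentally) associated in the observed sample,
  which is why its null control is asserted as a rate over seeded runs,
  not per run. Two design choices tighten that control well beyond a
  literal shadow-of-the-undecided implementation: the shadow ensemble is
  padded to the original feature count so the max-shadow bar does not
  collapse late in a run, and the Bonferroni correction uses the full
  feature count throughout, making α a per-run family-wise error rate.
  Even so, a dataset containing a family-wise significant chance
  association is confirmed by construction; the null-control acceptance
  tally measures 18/20 clean runs against its asserted 19/20 and is left
  red with this explanation rather than widened.
* The Gaussian-process scores are uncalibrated regression outputs;
  thresholding them at 0 is a convention, not a probability statement.
* Null-calibration bands on AUC apply to means over seeds: a single
  24-sample test set has an AUC standard deviation of ~0.12 under the
  null.
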