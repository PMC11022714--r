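---
title: "Silver-adduct LDI-MS fingerprinting for PKU screening: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Silver-adduct LDI-MS fingerprinting for PKU screening: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Phenylketonuria (PKU) is an inherited defect of phenylalanine metabolism.
Newborn screening today measures blood phenylalanine (Phe) by targeted
LC-MS on dried blood spots (DBS); confirming the subtype — phenylalanine
hydroxylase (PAH) deficiency, treated by diet, versus tetrahydrobiopterin
(BH4) cofactor deficiency, treated by medication — requires a second,
urine-based pterin assay. An alternative is label-free metabolic
fingerprinting: desorb and ionize the untargeted DBS metabolome on a
silver nanostructure, record one positive-mode LDI mass spectrum per
laser shot, and classify the resulting intensity vector. Silver
cationization has a built-in specificity check: silver has two stable
isotopes, ^107^Ag (51.8%) and ^109^Ag (48.2%), so every genuine
[M+Ag]^+^ adduct appears as a doublet separated by ~1.9997 Da at a
roughly 1.08 intensity ratio. This package implements that workflow
end-to-end: spectral preprocessing to a fingerprint matrix, nested
cross-validated sparse classification, doublet-aware biomarker
selection, the two-step screen-then-subtype decision rule, and a seeded
synthetic-cohort generator that stands in for the (non-deposited)
clinical data.

## From spectra to the fingerprint matrix

Each sample is acquired in five replicate spectra on an m/z 100-1000
window. `preprocess_cohort()` chains the stages, each exported on its
own:

1. **Replicate averaging** (`average_replicates()`): replicates are
   linearly interpolated onto the union grid of their overlapping range
   and averaged pointwise. Averaging before peak detection raises SNR by
   about sqrt(5) and yields one fingerprint per individual.
2. **Baseline correction** (`baseline_correct()`): a morphological
   opening — rolling minimum then rolling maximum over ±`half_window`
   (default 1.0 m/z) — is subtracted. The opening removes any additive
   component varying on scales wider than the window and passes peaks
   narrower than it; the default sits two orders of magnitude above the
   peak width, so metabolite peaks are untouched while matrix background
   and chemical noise ramps are removed.
3. **Peak detection** (`detect_peaks()`): strict local maxima, kept when
   intensity/σ ≥ `snr_min` (default 3). The noise scale σ is estimated
   robustly as 1.4826 × MAD of the first differences of the intensity
   divided by sqrt(2) — differencing removes residual smooth structure
   and the sqrt(2) undoes the variance doubling. Maxima closer than
   0.05 m/z merge, keeping the taller.
4. **Alignment** (`align_features()`): all samples' peaks are pooled and
   sorted; a new feature bin opens whenever the gap to the previous peak
   exceeds `tol` (default 0.1 m/z, typical reflector-TOF reproducibility
   at this mass range). Bin centers are intensity-weighted mean m/z.
5. **Top-k selection** (`select_top_features()`): bins are ranked by
   median intensity across samples (ties to lower m/z) and the top 830
   kept — the "localized highest intensity" fingerprint size. The
   ranking statistic and k are arguments.
6. **Normalization and standardization**: total-ion-current row
   normalization (`normalize_tic()`) removes per-spot scaling; column
   z-scoring (`standardize()`) uses the population standard deviation,
   zeroing and flagging constant columns. Model fitting never consumes a
   pre-standardized matrix: `nested_cv()` computes standardization
   statistics inside each training fold and applies them to the held-out
   fold, so no test information leaks into training.

The defaults for `half_window`, `snr_min`, and the alignment tolerances
are instrument-typical values, not sacred; all are arguments.

## The classifier and its cross-validation

The core model is elastic-net penalized logistic regression,
$$\min_{\beta_0,\beta}\; \tfrac1n\sum_i \ell(y_i, \beta_0+x_i'\beta)
 + \lambda\big[\alpha\|\beta\|_1 + \tfrac{1-\alpha}{2}\|\beta\|_2^2\big],$$
fit by cyclic coordinate descent on the IRLS quadratic approximation
(`fit_elastic_net()`, compiled in C++ with sequential strong-rule
screening and a full KKT check; convergence when the largest coefficient
change falls below 1e-7). The L1 part produces exact zeros — the basis
of selection frequencies — and the L2 part keeps correlated features,
such as the two members of an isotope doublet, in the model together.

`nested_cv()` wraps it in the repeated nested design: per round
(20 by default, seeded `seed + round - 1`) the cohort splits into 5
stratified outer folds; within each outer-training set an inner 5-fold
search over α ∈ {0.1, 0.3, 0.5, 0.7, 0.9} and 30 log-spaced λ values
(from the smallest all-zero penalty down four decades) maximizes pooled
inner out-of-fold AUC; the winner is refit on the outer-training set and
scores its outer-test fold. That yields 100 models, each sample scored
once per round, and per-feature selection frequencies over the ensemble.
Three choices here deserve justification:

- **Tie-breaking toward the sparser model.** The inner AUC surface
  plateaus once ranking saturates; scanning α ascending and λ descending
  keeps the first (most penalized, most grouped) winner. This is what
  makes selection frequencies reproducible.
- **A chance gate on the inner winner.** With G ≈ 150 grid points, the
  best inner AUC on a *signal-free* cohort is the maximum of ~G noisy
  AUCs and lands well above 0.5, so some overfit model always beats the
  all-zero model; worse, the features it uses are cohort-level chance
  correlations that recur across rounds, driving their selection
  frequencies toward 1. The inner search therefore accepts a non-trivial
  winner only when its AUC exceeds
  $0.5 + z_{1-0.05/G}\,\mathrm{SE}_0$, where
  $\mathrm{SE}_0^2 = (n+1)/(12\,n_1 n_0)$ is the null variance of the
  rank-sum AUC — a Bonferroni-corrected test against chance. On cohorts
  with genuine signal the gate is far below the observed AUC and changes
  nothing; on null cohorts it sends the ensemble to the fully penalized
  model and keeps stability selection calibrated. The gate is capped at
  0.95 so that very small cohorts (where SE0 is huge) are not forced to
  the null model.
- **Cross-validated Platt rescaling.** Penalized likelihood shrinks
  coefficients; the ranking is excellent but predicted probabilities
  compress toward the class prevalence, which undermines a fixed 0.5
  decision threshold. Each refit model therefore carries a
  one-dimensional logistic recalibration of its linear predictor, fitted
  on the *inner out-of-fold* predictors (where classes overlap, so the
  slope cannot diverge as it would on a separable training fold).
  Calibration is a monotone transform per model: per-model AUC and the
  coefficient support — hence selection frequencies — are untouched.

Comparators (`learner = "ridge"`, `"knn"`, `"naive_bayes"`) run in the
identical design: ridge is the α = 0 path; knn scores by the class-1
fraction among k Euclidean neighbours with k chosen by the same inner
loop; Gaussian naive Bayes (via e1071) has no tuned hyperparameter.
Selection frequencies are reported only for the elastic net.

## ROC machinery

`roc_auc()` computes the AUC as the proportion of concordant
case-control pairs (ties half-weighted) via mid-ranks, with the
staircase curve over the observed thresholds. `auc_ci()` and
`delong_test()` implement the DeLong structural-components variance for
confidence intervals and paired AUC comparison. `choose_cutoff()` offers
the three published threshold strategies — Youden's index, the point
closest to (0, 1), and equal sensitivity/specificity — with ties broken
by higher sensitivity then lower threshold.

## Biomarker selection

`select_biomarkers()` applies the conjunction of three criteria to the
elastic-net ensemble: selection frequency strictly above 0.80; two-sided
Welch t-test p below 0.05 on the normalized (pre-standardization)
intensities, uncorrected by default to match the stated rule (a
Benjamini-Hochberg option exists); and co-existence of the ^107/109^Ag
isotope partner, which must itself survive both filters.
`find_isotope_pairs()` matches features whose spacing is within
0.02 Da of the isotopic mass difference, greedily by spacing error so
each feature joins at most one pair. Surviving doublets are annotated
against an embedded monoisotopic mass table (masses computed from
molecular formulas at call time — no network dependency) and must agree
on their direction of regulation. Welch rather than Student's t is used
for robustness to variance heterogeneity between patient and control
intensities. `panel_model()` refits the nested CV on the panel features
alone and compares it with each single-biomarker model by the DeLong
test on pooled out-of-fold scores.

## The two-step decision rule

`two_step_diagnose()` screens each sample with the control-vs-PKU model
at a fixed 0.5 probability cutoff; screen positives are passed to the
BH4-vs-PAH subtype model (trained on PKU samples only, mirroring the
study's subtype design), again at 0.5. Exact 0.5 ties resolve to the
non-disease side (control, then BH4) with a warning. The clinical
comparator rules are provided as pure functions: Phe concentration
strictly above 120 µmol/L screens positive
(`reference_screen_phe()`), and a urinary biopterin percentage
B% = 100·B/(B+N) strictly above 5 calls PAH
(`reference_subtype_bpercent()`).

## The synthetic cohort generator

No patient data accompany the study, so `cohort_spec()` /
`make_feature_table()` / `make_cohort_spectra()` define the test bed.
The defaults are the package's study conditions, chosen once:

- 240 controls and 77 cases (the discovery design), five replicates per
  sample, m/z 100-1000 at 0.02 m/z steps, Gaussian peaks of 0.05 m/z sd.
- A six-metabolite differential panel — Phe, phenylacetaldehyde (Phen),
  aminomalonic acid (AA), indoleacrylic acid (IA) elevated in cases;
  ethylamine (Eth) and oleic acid (OA) reduced — each planted as a
  ^107/109^Ag doublet at the natural-abundance intensity ratio, among
  818 null features, for 830 bins in total.
- Fold change 3 (up) or 1/3 (down). No effect sizes are published for
  the panel; 3× is a moderate, realistic metabolomic effect.
- Log-normal abundances: per-feature base level exp(N(log 200, 1));
  per-sample biological log-sd 0.6 (≈ 66% CV, typical between-subject
  metabolite variability) so a single panel feature discriminates at
  AUC ≈ 0.9 and only the multivariate fingerprint approaches the
  published near-perfect separation; independent per-adduct measurement
  log-sd 0.2 (the substrate's technical CV is reported under 15%), which
  also keeps the two doublet members correlated but not collinear.
- Spectrum rendering adds baseline 20·exp(−0.005·(m/z − 100)) and white
  noise of sd 1; replicates redraw noise only, amplitudes are per-sample.

What this emulates: the dimensionality, sparsity-of-signal, isotope
pairing, class imbalance and replicate structure of the study. What it
does not: shot-to-shot MALDI physics, mass-calibration drift, matrix
cluster interference, metabolite-metabolite correlation beyond the
doublets, or any real biological covariance — so green tests here
demonstrate the *pipeline's* correctness and statistical calibration,
not clinical performance. The published clinical AUCs are not
reproducible without the cohort and are not asserted anywhere in this
package; on the synthetic defaults the workflow reaches a mean
out-of-fold AUC around 0.99 with the planted panel recovered exactly.

`power_analysis()` reimplements the design-stage calculation
generically: simulate cohorts at each candidate size, Welch-test every
feature, correct by Benjamini-Hochberg at the chosen FDR, and report the
mean fraction of planted features declared significant.

## Numerical choices and degenerate inputs

- Coordinate-descent convergence at 1e-7 maximum coefficient change for
  refits; inner-loop solves run at 1e-4 with capped sweeps, since
  hyperparameter *ranking* is insensitive to the last decimals (measured
  objective agreement with a reference solver at the tight tolerance is
  ~1e-6).
- λ grids are computed per α from λ_max = max|X'(y − ȳ)|/(n·max(α, 0.001)),
  the glmnet convention, so the ridge grid stays finite.
- Zero-variance columns standardize to all-zero and are flagged;
  all-zero samples pass TIC normalization unchanged with a warning;
  constant features get t-test p = 1.
- All randomness flows through explicit seeds (`cohort_spec(seed=)`,
  `cv_config(seed=)`, per-round `seed + round − 1`), restoring the
  caller's RNG state afterwards; identical seeds reproduce results
  bit-for-bit.
- Problem sizes in the test suite are scaled-down versions of the study
  conditions (e.g. 10 cross-validation seeds at 5 rounds for recovery
  checks; a 200 × 400 null cohort for calibration checks), chosen so
  that the full suite completes in a few minutes while preserving the
  statistical regime being tested.

## Known limitations

- The chance gate is conservative: cohorts whose true signal yields
  inner AUC below roughly 0.5 + 3.4·SE0 are treated as null. For weakly
  separable problems, widen the grid-significance level or disable by
  subclassing the config.
- Probability calibration is estimated from inner out-of-fold
  predictors of models trained on 4/5 of the outer-training data; it is
  approximate for the refit model, though empirically adequate around
  the 0.5 threshold.
- The subtype stage inherits whatever feature space it is trained on;
  the package does not decide whether the screening fingerprint should
  be reused — the study's choice is unstated — it simply aligns feature
  spaces by m/z at diagnosis time.
- mzML ingestion is array-only (via mzR when installed); vendor raw
  formats are out of scope.
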