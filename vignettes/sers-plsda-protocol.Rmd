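---
title: "Methods: PLS-DA classification of serum SERS spectra"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PLS-DA classification of serum SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sersclass)
```

This vignette is the package's own account of the methods it
implements: the statistical model, the preprocessing chain, the
resampling design, the synthetic-data model that stands in for clinical
cohorts, and the numerical and design choices made where more than one
reasonable option existed.

## The classification problem

A SERS serum spectrum is a vector of ~2000 intensities on a shared
Raman-shift grid (here 1950 points, 517–1913 cm⁻¹). Serum composition
does not change wholesale between diseases; what changes are the
relative contributions of metabolites and macromolecules, visible as
modest intensity shifts at specific bands (uric acid near 638 cm⁻¹,
glycogen/carbohydrates near 1051 cm⁻¹, protein and lipid modes
elsewhere). Two features of such data drive the whole design:

1. **p ≫ n with strong collinearity.** Thousands of correlated
   predictors, at most a few hundred spectra. PLS-DA handles this by
   projecting onto a handful of covariance-maximising latent variables.
2. **Replicate structure.** Each patient contributes 3–4 replicate
   spectra that share acquisition conditions and biology. Any
   validation that lets replicates of one patient straddle the
   train/test boundary leaks patient identity and overstates accuracy.
   Every split in this package — the outer 80/20 split and the inner CV
   folds — therefore operates on whole patients.

## PLS-DA

The response is coded 0/1 (the positive class is the clinical case
group; by default the class with fewer patients, and the choice is
recorded in every protocol result). With the response univariate, the
NIPALS weight vector per component is closed-form, `w_a ∝ X_aᵀ y_a`, so
no inner iteration is needed; components are extracted by deflating
both `X` and `y`. Predictors are mean-centred on the training set only.
No column autoscaling is applied: spectra are already SNV-normalised
row-wise, and per-column scaling would inflate noise channels in the
quiet spectral regions.

At full rank the PLS coefficient vector coincides with the
least-squares solution — the test suite asserts this against a QR
oracle — and the score-basis identity `b = W (PᵀW)⁻¹ q` is checked
against sequential reconstruction at `1e-8`.

Classification thresholds the continuous score at 0.5, ties to the
positive class. The threshold is exposed (`protocol_config(threshold =)`)
but 0.5 on a 0/1-coded balanced response is the natural default, and
ROC/AUC — computed on the continuous scores, never on hard labels —
summarises performance across all thresholds anyway.

**LV selection.** The number of latent variables is chosen as the first
local minimum of the cross-validated RMSE curve: the smallest count
whose RMSE drops below its predecessor and does not exceed its
successor; a curve that only decreases yields its last (global-minimum)
index. Cross-validated rather than calibration RMSE is used because the
selection must protect against overfitting, which calibration error
cannot see. Folds are patient-grouped; `K = 10` by default (any
standard choice works — the curve's first minimum, not its absolute
level, is what matters), capped at the patient count. The search range
`max_lv = 15` comfortably contains the 5–7 LVs typically selected on
cohorts of this size.

**VIP.** `VIP_j = sqrt(p · Σ_a SSY_a (w_ja/‖w_a‖)² / Σ_a SSY_a)` with
`SSY_a = q_a² t_aᵀt_a`. The mean of squared VIPs is identically 1; the
suite asserts this for every fitted model, so the "VIP > 1 means
above-average contribution" reading stays valid.

## Preprocessing

Order is fixed: crop → Savitzky–Golay smoothing → polynomial background
removal → SNV. Smoothing before baseline estimation keeps noise spikes
from pulling the iterative fit; SNV last guarantees every spectrum
enters the model at mean 0, sample SD 1 (asserted to `1e-10`).

* **Savitzky–Golay** (window 15 grid points, polynomial order 1,
  derivative order 0) is delegated to `signal::sgolayfilt`, whose
  boundary rows evaluate the boundary-window polynomial rather than
  truncating. The window is parameterised in grid points, the standard
  filter convention. Interior values are the tested contract, checked
  against a brute-force windowed least-squares oracle.
* **Background removal** uses the modified-polynomial iteration: fit a
  degree-15 polynomial, clip the working spectrum to the pointwise
  minimum of spectrum and fit, refit, repeat until the fit changes by
  less than `1e-6` relative RMS or 100 iterations. A single
  least-squares fit of that degree would ride up the peaks; clipping
  lets the polynomial settle beneath them onto the fluorescence
  continuum. Degree 15 on raw wavenumbers is numerically hopeless, so
  the fit uses a Chebyshev basis on the axis rescaled to [−1, 1], with
  one QR factorisation reused across iterations. Stopping is governed
  by `baseline_tol` relative to the input range; two inputs differing
  by a low-degree polynomial may stop one clipping iteration apart, so
  shift-invariance holds to the iteration tolerance, not exactly.
* **SNV** uses the sample (n−1) standard deviation and refuses
  zero-variance input outright rather than returning NaNs.
* **Crop** is the closed interval [517, 1913]; the default grid is
  generated endpoints-inclusive, so default preprocessing preserves all
  1950 points.

## The resampling protocol

Cohorts are imbalanced (e.g. 41 vs 103 patients), and PLS-DA trained on
imbalanced classes biases the score toward the majority. The protocol
therefore re-balances before every fit:

1. **Balance**: patients of the larger class are randomly subsampled
   (without replacement by default — "bootstrap" here means random
   subset selection; a with-replacement mode exists behind
   `balance_patient_sampling = "with"` for sensitivity analysis) down
   to the smaller class's patient count. Within every retained patient,
   `spectra_per_patient_draw = 3` spectra are drawn — without
   replacement when available, with replacement otherwise — so both
   classes contribute equal patients *and* equal spectra.
2. **Split**: whole patients are assigned to the training side until
   its spectra count is the feasible count nearest
   `train_fraction × total` (default 0.8). Ties between counts go to
   the larger training set; among allocations achieving the same count,
   the one closest to class-proportional is taken. The last rule
   matters: with equal replicate counts many patient allocations give
   identical spectra counts, and an arbitrary choice there can
   systematically unbalance the training class mix, which biases the
   score threshold and drives *below*-chance test accuracy on null
   data. Both classes are guaranteed on both sides.
3. **Fit and score**: LV selection by patient-grouped CV on the
   training part only, then one PLS-DA fit, then sensitivity,
   specificity, accuracy and ROC/AUC on both sides, plus the fold's
   VIP vector.

Steps 1–3 run afresh at each of the `P × T` folds — each balanced draw
is treated as a new observation of the design — giving `P·T` fold
results aggregated as unweighted mean, min and max per metric, and an
element-wise mean VIP profile. `P = T = 5` (25 folds) matches the
larger study design, `P = T = 3` (9 folds) the smaller. Every fold's
seed derives deterministically from the protocol seed and the fold
index, so runs are reproducible and folds are independent of loop
order.

`vip_band_report()` condenses the mean VIP profile to the peak library:
the maximum within ±10 cm⁻¹ of each band centre (roughly one linewidth;
window configurable, 0 = exact grid lookup) and its rank among bands.

## The synthetic cohort model

No public spectra accompany the clinical designs this package targets,
so the generator is a first-class, tested module, not a fixture. A
spectrum is

    gain × patient_effect × Σ_bands A_b · f_b(class) · L(ν; ν_b, w_b)
      + baseline(ν) + ε(ν)

* **Line shape**: Lorentzian — the Raman convention — with HWHM 8 cm⁻¹,
  a typical solution-phase linewidth on this grid.
* **Peak library**: the 15 prominent serum bands (587–1657 cm⁻¹) with
  their usual assignments. Default class effects encode the reported
  respiratory-vs-referent directions: 20% shifts at the two headline
  bands (638 cm⁻¹ down, 1051 cm⁻¹ up in the respiratory class), 10% at
  the secondary bands (724, 947, 1390 up; 1657 down), all others
  neutral. The 20/10% split makes the headline bands dominant but not
  solitary — a realistic difficulty level at which the pipeline must
  still rank 638 and 1051 first.
* **Patient effect**: one multiplicative log-normal amplitude factor
  per patient (σ_log = 0.15), the simplest structure that induces
  within-patient correlation — precisely what patient-wise splitting
  must respect. It scales all bands jointly, as overall SERS
  enhancement variation does.
* **Baseline**: a 5th-order polynomial in scaled wavenumber with a
  positive ambient term, mimicking a smooth fluorescence continuum
  decaying toward higher shifts; amplitude comparable to the strongest
  bands, as in raw serum SERS before background correction.
* **Noise and gain**: additive Gaussian detector noise (σ = 0.02 of the
  unit peak scale, a mid-range SNR for averaged accumulations) and a
  per-spectrum log-normal gain (σ_log = 0.10) for acquisition-to-
  acquisition intensity drift.
* **Replicates**: 3 per patient by default (the smaller study design's
  33 spectra from 11 patients implies exactly 3); `spectra_jitter`
  optionally varies counts per patient to emulate uneven totals, at the
  cost of exact count conservation.
* **Determinism**: every patient's random stream derives from a hash of
  the master seed and the patient id, so cohorts are bit-reproducible
  and stable under class reordering.

`null_cohort()` forces all class factors to 1: both classes are drawn
from the identical distribution, making labels pure noise. The suite
uses it to verify the protocol's calibration — mean test accuracy and
AUC near 0.5 — which is exactly the check that caught the split-tie
bias described above.

**What the generator does not emulate** — and hence what passing tests
do and do not show: no band-position jitter or instrument wavenumber
miscalibration, no band-shape variation or overlapping-band congestion
beyond the 15-band library, no heteroscedastic or correlated noise, no
cosmic-ray artefacts, no within-patient biological drift between
replicates, and class differences confined to band amplitudes. Perfect
separation on default synthetic cohorts therefore demonstrates that the
pipeline recovers planted structure without patient leakage — not that
comparable accuracy is attainable on clinical spectra, where overlap
between groups is far larger.

## Numerical choices and degenerate inputs

* NIPALS stops with an error if no residual covariance remains
  (`‖Xᵀy‖ < 1e-12`) when a fixed LV count demands more components;
  inside cross-validation the coefficient path is instead frozen at the
  last extractable component, so every candidate LV count stays defined
  when a training fold is perfectly fitted early.
* ROC operating points are computed at every distinct score (call
  positive iff score ≥ threshold) with ∞ sentinels; trapezoidal AUC
  then equals Mann–Whitney concordance with ties counted ½, a
  property asserted to `1e-12` against an O(n²) oracle and against an
  established independent implementation.
* `confusion()` refuses inputs where a requested rate is undefined (no
  positive, or no negative, truths) instead of returning NaN.
* Readers reject non-monotone wavenumber axes, unmatched or duplicate
  spectrum ids, and non-finite intensities; nothing is silently
  imputed.

## Problem sizes used by the tests and the acceptance script

Most unit tests run on short 200–300-point axes with 4–18 patients —
the statistical structure, not the grid resolution, is what those tests
exercise. The calibration and recovery checks use full-resolution
cohorts sized to the two study designs: 41 + 103 patients (432 spectra)
for signal recovery over 25 folds, 15 + 20 patients for the null
calibration, 11 + 20 for the smaller design's 9-fold run. These sizes
are the package's reference conditions; larger cohorts only tighten
the same checks.

## Known limitations

* PLS1 binary classification only: no multiclass PLS2, no posterior-
  probability decision rules, no sparse or orthogonal PLS variants.
* The first-local-minimum rule is deliberately simple; no one-standard-
  error rule or permutation-based significance of the selected model.
* Balancing with replacement can place copies of one patient's spectra
  in the balanced set; the patient-wise split then treats the patient
  atomically, so there is still no train/test leakage, but effective
  test sizes shrink.
* No instrument-transfer facilities (wavenumber alignment,
  interpolation between grids) and no vendor formats (SPC/JCAMP); the
  documented wide-CSV dialect is the interchange contract.
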