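---
title: "Classifying dementia state from tear-fluid SERS spectra: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying dementia state from tear-fluid SERS spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tearspec)
```

## The problem

Surface-enhanced Raman spectroscopy (SERS) of human tears offers a
non-invasive window on the biochemical changes that accompany
neurodegeneration. A microliter tear drop on a gold-nanoparticle substrate
yields a vibrational spectrum dominated by the major tear proteins
(lysozyme, lactoferrin, lipocalin, IgA): phenylalanine, tyrosine and
tryptophan ring modes, and the amide I/II/III backbone bands whose
positions track protein secondary structure. Subjects fall into three
classes — healthy controls (Ctr), mild cognitive impairment (MCI) and
Alzheimer's disease (AD) — and the analytical task is to decide, from a
subject's average spectrum, which class they belong to.

`tearspec` implements the full chemometric chain for this task:

1. **Pretreatment** — multilevel bior6.8 wavelet decomposition to remove
   the slowly varying fluorescence background and the finest-scale noise,
   followed by standard-normal-variate (SNV) scaling of each spectrum.
2. **Band deconvolution** — Levenberg–Marquardt least-squares fits of
   spectral regions as sums of Lorentzian bands, from which band centers
   and the marker ratio $I_{1342}/I_{1243}$ (tryptophan C–H deformation
   over amide III $\beta$-sheet, fitted peak heights) are extracted.
3. **Class comparison** — class-average spectra, difference spectra
   against the control class with a $\pm 0.68\,\mathrm{SD}$ dispersion
   band, and a per-wavenumber one-way ANOVA significance map.
4. **i-PCA classification** — covariance-matrix PCA run separately on 22
   fixed wavenumber intervals; the pooled interval scores feed a Gaussian
   naive-Bayes classifier. The shipped final model uses the PC3–PC6 scores
   of seven intervals (456–553, 707–755, 1202–1307, 1308–1353, 1354–1383,
   1552–1582, 1583–1639 cm⁻¹) and is evaluated by training-set recall
   (overall accuracy and misclassification rate).

No public tear-SERS data set exists, so the package also ships a
synthetic-data generator (`default_profiles()`, `simulate_tears()`) that
emulates the statistical structure of such a study and serves as the
test bed for every stage.

## The spectrum container

All stages consume and produce a `sers_spectra`: a long tibble with one
row per (spectrum, wavenumber) pair, a shared strictly-increasing uniform
grid, per-spectrum `subject_id` / `replicate_id` / `class_label`, and an
append-only `provenance` attribute. The canonical grid is 400–1900 cm⁻¹
at 2 cm⁻¹ spacing (751 points), the instrument resolution the package
models. Plain-text I/O (`read_spectra()`, `write_spectra()`) supports a
commented two-column dialect and a matrix dialect with
`subject/replicate/class` column headers; both round-trip bit-identically
at 17 significant digits.

## Wavelet background and noise removal

`wavelet_correct()` decomposes each spectrum with the bior6.8
biorthogonal filter bank (implemented in the package: Mallat pyramid,
symmetric half-sample extension, perfect-reconstruction cropping; with
nothing removed the transform is the identity to ~1e-12). Background is
the coarsest approximation; noise is the finest detail level. Defaults:

* `n_levels = 8`. The minimal depth at which one approximation
  coefficient spans ≥ 200 cm⁻¹ is 7; the default goes one dyadic step
  deeper because at depth 7 a measurable part of the Lorentzian band
  tails leaks into the discarded approximation and biases fitted peak
  heights (the recovered $I_{1342}/I_{1243}$ shifts by ≈ +7%), while at
  depth 8 the bias is ≈ 2%. The price is a slightly larger smooth
  background residual, which the deconvolution's local baseline absorbs
  (below).
* `background_levels = 8` (the final approximation), `noise_levels = 1`.
* Symmetric extension: it minimises edge ringing on smooth baselines.

SNV scaling `(I - mean(I)) / sd(I)` uses the population-variance
convention (divide by $n$); it is idempotent and invariant under affine
intensity transforms. The order is wavelet first, then SNV.

A consequence of removing *only* the coarsest approximation is that
background structure at intermediate scales (≈ 100–500 cm⁻¹) survives
pretreatment. With the shipped several-fold fluorescence background the
post-correction residual can reach ~20% of the strongest band in places.
This is deliberate: removing the intermediate detail levels as well would
also delete genuine broad spectral structure, and the downstream fits
carry a local baseline precisely to absorb what the global correction
leaves behind. The 3%-level fidelity of the correction operator itself is
verified in the tests at depth 7 with a background comparable to the
strongest band.

## Lorentzian deconvolution

Both the generator and the fitter use the Lorentzian
$L(\nu) = A\,\gamma^2 / ((\nu - c)^2 + \gamma^2)$ with
$\gamma = \mathrm{fwhm}/2$. `fit_lorentzians()` minimises the residual
sum of squares over all centers, widths and heights simultaneously
(minpack.lm's Levenberg–Marquardt), with bounds: heights ≥ 0, widths in
[4, 120] cm⁻¹, centers inside the region. A local polynomial baseline
(default quadratic) is fitted along with the bands: under the shipped
background it reduces the systematic error of recovered height ratios
from ≈ −5% (linear) to ≈ −2%.

Seeding is deterministic: prominence-filtered local maxima of a 5-point
smoothed copy (`seed_peaks()`), optionally augmented or replaced by the
control band table (`template_seeds()`). For crowded regions the optional
`center_bound` / `fwhm_bound` arguments keep each fitted band near its
template seed (template-guided deconvolution); the package's own
recovery analyses use `center_bound = 18` cm⁻¹ and `fwhm_bound = 2`,
without which occasional fits swap the identities of the overlapping
1591 / 1612 / amide I components.

"Intensity" in $I_{1342}/I_{1243}$ means the fitted Lorentzian peak
height — not raw counts at that wavenumber and not band area. Band areas
would give different values. `band_ratio()` matches fitted bands to the
1342 and 1243 cm⁻¹ targets within 15 cm⁻¹ (ties toward the lower center)
and offers a residual-bootstrap uncertainty.

## Class difference maps

`difference_map()` works on one spectrum per subject (average replicates
first). At every wavenumber it reports the difference of class means, the
reference class's $\pm 0.68\,\mathrm{SD}$ dispersion band, and a
classical one-way ANOVA F test between the two groups. A point is flagged
significant only when both $p < \alpha$ (default 0.05) *and* the
difference falls outside the dispersion band — the joint criterion is
what the original analysis displays, and it is conservative. No
multiple-testing correction is applied by default (the original analysis
applies none); Benjamini–Hochberg is available behind `p_adjust = "BH"`.
Contiguous significant runs are summarised as signed regions.

## i-PCA and naive Bayes

`default_intervals()` returns the 22 fixed closed intervals partitioning
400–1900 cm⁻¹; a grid point $\nu$ belongs to $[lo, hi]$ iff
$lo \le \nu < hi + 1$, which on the canonical grid assigns every point to
exactly one interval. `spectra_pca()` eigendecomposes the covariance
matrix of mean-centered intensities (deterministic sign convention: each
loading's largest-magnitude element is positive);
`build_score_table()` pools the first 7 score columns of each interval
into a 154-column feature table keyed `"lo-hi.PCk"`.

`train_nb()` fits a Gaussian naive-Bayes model: per class and feature a
mean and a population variance (floored at $10^{-9}$ times the mean
feature variance), plus class priors (empirical frequencies by default;
uniform available because the design is unbalanced at 6/7/18).
`classify_nb()` works in the log domain and breaks exact posterior ties
by the fixed class order Ctr < MCI < AD. `evaluate_recall()` reports the
overall accuracy, the misclassification rate and the confusion matrix.
`search_feature_subsets()` mechanises the model-selection step that was
done by inspection in the original analysis: exhaustive over candidate PC
sets crossed with greedy forward selection over intervals, within an
evaluation budget, with a full audit log.

The subject-level unit everywhere is one averaged spectrum per subject;
PC indexing is 1-based; no external validation is claimed — training-set
recall is exactly what the original small, unbalanced study could report,
and a leave-one-out helper would be an extension beyond it.

## The synthetic generator: what it emulates

`default_profiles()` encodes the study conditions: 6 Ctr, 7 MCI and 18 AD
subjects, 3 replicate spectra each, on the canonical grid.

**Band tables.** The control table holds the assigned tear-SERS modes
(Phe 998, Tyr 1173, amide III 1248/1291, Trp 1346, amide II 1525, amide I
1639, ... ) plus minor unassigned modes that fill the remaining windows
as a real tear spectrum does. Disease classes depart from the control
table following the reported intensity directions and band shifts: the
amide I center moves to 1625 (MCI) and 1628 (AD); Tyr moves to ≈ 1165 in
both disease classes; AD modes broaden. Three printed quantities pin the
calibration exactly:

* class-mean fitted $I_{1342}/I_{1243}$ of 1.1 (Ctr), 1.8 (MCI),
  1.5 (AD). With independent mean-one log-normal band scatter of log-sd
  $\sigma_c$, the expected fitted ratio is the profile ratio times
  $e^{\sigma_c^2}$; and the deconvolution under default conditions
  recovers the ratio a measured 4.4% low (band overlap plus broad
  background structure). The Trp heights divide out both factors, so the
  expected *measured* subject-mean ratio equals the printed value.
* the AD-minus-Ctr difference peaks at 1007 (positive), 1591 (positive)
  and 1459 (negative): the AD profile raises Phe (shifted up to 1006, so
  the difference peaks at the printed 1007), raises 1591, and depresses
  1459. Effect magnitudes were set by a design-time power analysis so the
  printed deviations are recoverable by the joint ANOVA + dispersion-band
  criterion at the shipped variability level.

**Per-subject variability** has several components, drawn once per
subject: a global enhancement gain (log-normal, `gain_sd = 0.3`;
substrate-to-substrate SERS variability — removed by SNV), a smooth
quadratic spectral tilt on band heights (`tilt_sd = 0.10`), independent
mean-one log-normal band-intensity scatter (`subject_sd`: 0.14 / 0.12 /
0.09 for Ctr / MCI / AD), band-center jitter (0.8 cm⁻¹), band-width
jitter (log-sd 0.07), and — crucially — a broad random background: 32
Gaussian humps of width 55–80 cm⁻¹ (sd) with pointwise sd 0.30 of the
reference amplitude, on top of a cubic fluorescence baseline. Replicates
add independent Gaussian noise (8% of the reference amplitude), matching
the reported per-sample dispersion scale.

The broad humps deserve emphasis. Real spectra vary between subjects in
smooth, spatially correlated ways (unresolved weak bands, residual
fluorescence texture) that survive the wavelet background stage because
they live below its ≈ 500 cm⁻¹ cutoff. Within each narrow i-PCA interval
this structure is large but low-rank (nearly constant-plus-slope), so it
occupies the leading principal components — which is exactly why the
final classification model reads PC3–PC6 rather than PC1–PC2. Without
such structure the class signal sits in the first two components and the
PC3–PC6 model has nothing to work with; a generator lacking it cannot
reproduce the reported classifier design at all.

**Reported dispersions.** The published per-class signal dispersions
(24%, 21%, 37% on average over wavenumbers) are whole-spectrum summaries
dominated by low-signal regions and global amplitude variability. The
generator reproduces dispersion of that order as the *sum* of its
components; the band-level scatter values above are deliberately smaller,
and the AD band-level scatter is the smallest of the three — with AD both
the largest class and the widest, its fitted class density otherwise
absorbs borderline subjects of the other classes and perfect training
recall becomes unattainable.

**The null configuration.** `effect_scale = 0` collapses all class band
tables onto the control table, giving three classes with identical mean
spectra. For type-I-error experiments the tests additionally equalise
`subject_sd` across classes, because the classical (equal-variance) F
test is what the pipeline uses and groups of unequal variance and size
make it anti-conservative; with exchangeable groups the measured joint
flag rate is below the nominal 5%.

**What the generator does not emulate**: cosmic-ray spikes, detector
saturation, wavenumber-calibration drift, replicate-level background
drift, physical plasmonics of the substrate, and any real biochemical
covariance between specific proteins and disease state. Passing tests
demonstrate that the pipeline recovers the structure the generator puts
in — parameter recovery, error control, classifier behaviour — not that
the clinical findings themselves generalise.

## Numerical choices and edge cases

* Wavelet: symmetric extension; depth capped by `floor(log2(n))` with an
  informative error; empty removal sets give the identity.
* SNV: population sd; constant spectra raise a degenerate-input error
  rather than dividing by zero.
* Fits: non-convergence is reported via `converged = FALSE`, never an
  error; standard errors come from the scaled inverse Hessian when it is
  invertible, `NA` otherwise; at least `3 * n_bands + 1` region points
  are required.
* ANOVA: zero within-group variance with equal means gives F = 0, p = 1;
  with unequal means it gives p = 0 with a note.
* PCA: `min(n - 1, p)` components; sign convention as above; two-spectrum
  sets yield a single component with scores $\pm d/2$.
* Naive Bayes: log-domain accumulation; variance floor
  $10^{-9} \times$ mean feature variance; deterministic tie-break.
* Interval membership uses half-open `[lo, hi + 1)` so odd grids still
  partition.

## Problem sizes used by the test-suite

The shipped tests run the full chain on the 6/7/18 cohort for ten seeds,
recover ratios from 50-subject single-class cohorts, recover band centers
from 20-subject cohorts, and control the null difference-map flag rate
over 200 simulated cohorts; the whole suite completes in a few minutes on
one core. These sizes give Monte-Carlo standard errors comfortably inside
the tolerances they are tested against.

## Known limitations

* Training-set recall of the fixed PC3–PC6 model is not a guarantee: on
  roughly one simulated cohort in ten an atypical subject draw produces a
  single misclassification (Gaussian naive Bayes on 31 subjects with
  correlated nuisance violates the independence assumption it relies on).
  The original study, with one data set, could not observe this
  variability; the generator makes it visible.
* The recovered $I_{1342}/I_{1243}$ carries a small residual systematic
  from band overlap that the calibration compensates on average; per-seed
  class means scatter by a few percent around the printed values.
* The 456–553 and 707–755 cm⁻¹ model intervals carry only weak
  class information in the generator (minor disulfide/skeletal modes);
  their PC scores contribute little but are retained because the final
  model's feature set is fixed.
* `wavelet_correct()` removes only the coarsest approximation; strong
  curvature of the real background at 100–500 cm⁻¹ scales passes through
  and must be handled by the fit-level baseline, as described above.
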