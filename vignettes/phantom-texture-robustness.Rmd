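---
title: "Methods: simulating phantom MRI and testing texture-feature robustness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating phantom MRI and testing texture-feature robustness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phantomtex)
```

## What the package models

`phantomtex` asks a narrow, practical question: if the only thing that
changes between two MRI acquisitions is one protocol parameter — magnet
strength, flip angle, number of excitations (NEX), or scanner platform —
which members of a standard 41-feature texture panel change with it?  The
package answers it on simulated images of a nonanatomic calibration phantom,
where the ground truth is fully known, every stage is seeded, and the whole
experiment reruns in seconds.

The processing chain mirrors a typical phantom texture study: contour the
whole phantom, correct the contour for partial-volume artifact with an
iterative optimal threshold, normalize the global grayscale to mean 250 /
SD 30, extract histogram, GLCM, GLRL, gradient and Laws features per slice,
then compare feature distributions across acquisition groups with pooled
t-tests (or one-way ANOVA for the seven flip-angle levels) and
Benjamini–Hochberg Q-values, one 41-test family per contrast.

## The synthetic phantom

The simulated object is a T1-calibration phantom: eighteen 25 mm doped gel
tubes and one 20 mm Gd-DTPA tube (short T1, 300 ms), arranged as two
concentric rings around the Gd tube and embedded in a signal-filled
container gel disc, inside a 240 x 190 mm field of view.  The defaults were
chosen once, on physical grounds, and are not tuned per analysis:

* **T1 ladder 500–1400 ms (log-spaced).**  A monotone T1 spread is what a
  T1-calibration object is built for, and it makes flip-angle changes
  re-rank tube intensities (low flip angles are proton-density weighted,
  high flip angles T1-weighted).  The range is kept moderate so that the
  structural intensity spread inside the contour and the noise level
  contribute on comparable scales — with a very wide ladder the structural
  spread swamps everything and no noise contrast could ever register on the
  histogram SD, which is not the regime the phantom literature reports.
* **The container body** (radius 86 mm, T1 800 ms, proton density 1.4 times
  the tubes') makes the contoured phantom dominate the image statistics.
  Without it the contour covers a fifth of the image, and ROI statistics
  are decoupled from the global normalization targets; published phantom
  tables show ROI means within a few gray levels of the normalization
  target, i.e. the contour-dominated regime.
* **Proton density 20000 (arbitrary units)** simply keeps the 16-bit DICOM
  integer rounding error negligible relative to the noise floor.

## The acquisition and noise model

`spgr_signal()` is the closed-form spoiled-gradient-echo steady state.
Acquisition defaults (TR 4.78 ms, TE 1.12 ms, flip 30 degrees, 5 mm slices,
256 x 192 or 256 x 160 matrices) are the midpoints of the emulated
protocol's printed ranges; per-series values are configurable.

The noise model (`noise_model()`) has five moving parts, each standing in
for one physical mechanism:

* `sigma_base = 100`: complex-channel noise SD per excitation.  Noise is
  added to the real and imaginary channels before the magnitude is taken
  (Rician model), per excitation, and the NEX magnitudes are averaged —
  so the effective noise SD is `sigma_base / sqrt(NEX)` and the background
  has the Rayleigh floor of magnitude images.  The default puts the in-tube
  SNR around 5–10, low enough that noise is a visible part of the within-ROI
  variance, as in fast 3D gradient-echo protocols.
* `noise_corr_fwhm = 2` pixels: the noise field is band-limited (blurred
  white noise rescaled to keep its per-pixel SD).  Reconstruction —
  zero-fill interpolation in particular — leaves MR noise spatially
  correlated: per-pixel variance is preserved but the highest spatial
  frequencies are attenuated.  This is what separates variance-type
  features (which see the full noise power) from second-derivative
  features (which see only its high-frequency tail).
* `field_snr_gain = 2`: 3 T doubles the noiseless signal at fixed noise, a
  first-order field-strength scaling sufficient to exercise the contrast.
* `platform_filter_fwhm = c(A = 0, B = 1.2)` pixels and
  `platform_scale = c(A = 1, B = 1.15)`: vendors differ in reconstruction
  processing; platform B applies a mild Gaussian filter and an intensity
  scale.
* `pd_jitter_cv = 0.06`: each slice draws an independent lognormal
  proton-density factor per tube (and for the body).  Real series have
  slice-to-slice structural variation (slice position, B1, coil profile);
  with bit-identical slice geometry the only within-group variance would be
  noise, every feature difference would be "significant" at any group size,
  and the group-level dispersion published for real phantom series (CVs of
  a few percent) could not be reproduced.  The 6% default matches that
  dispersion scale.

What the generator does **not** emulate: k-space sampling, coil sensitivity,
gradient nonlinearity, B1/B0 inhomogeneity (the emulated protocol applied no
inhomogeneity correction), through-plane structure (slices are independent
realizations of the same 2-D geometry), and any dynamic-contrast kinetics.
Passing tests therefore show that the *pipeline* behaves correctly and that
the *statistical machinery* recovers a known sensitivity structure; they do
not certify feature robustness on any particular scanner.

## Preprocessing: the two corrections

**Partial-volume correction.**  `optimal_threshold()` is the classic
Ridler–Calvard intermeans iteration: start at the midpoint of the range,
replace the threshold by the average of the two class means it induces, stop
when the move is below 0.5 gray level (sub-integer refinement is meaningless
for integer histograms) or after 50 iterations; convergence typically takes
under ten.  `partial_volume_correct()` applies it to the pixels inside the
contour and removes the sub-threshold (background-classified) pixels; the
output mask is always a subset of the input.  Two numerical choices matter:

* The automatic contour (`auto_mask()`) takes the convex hull of the
  largest connected above-threshold component — isolated noise pixels must
  not stretch the contour — and pads it 10% outward.  The pad keeps a thin
  rim of dark background inside the contour, preserving the bimodality the
  intermeans iteration assumes; it emulates the generous uniform contour of
  manual phantom segmentation.
* Inside such a contour the dark class is a small minority, and the
  midpoint-of-range start can fall into the basin of a split *within* the
  bright mode (observed symptom: the corrected mask collapses to a few
  bright pixels).  `partial_volume_correct()` therefore starts the
  iteration at the midpoint of the darkest pixel and the median — a
  dark-anchored start that selects the dark-vs-structure split.
  `optimal_threshold()` itself keeps the classical midpoint default.

**Global normalization.**  `normalize_global()` is the exact affine map to
mean 250 / SD 30, computed over the entire image (not the ROI), applied
before feature extraction, and kept in floating point.  It is idempotent and
invariant to positive affine transforms of its input; a zero-variance image
is an error.

## Feature definitions and numerical choices

* **Quantization.**  `quantize()` bins masked pixels linearly into G = 256
  levels.  Its default range is the masked min–max; the pipeline, however,
  anchors the bins at `target_mean ± 4 target_sd` (130–370 after
  normalization, values outside clipped).  The min–max range of a noisy
  slice is an extreme-value statistic; its slice-to-slice fluctuation
  otherwise leaks a large random scale factor into every level-unit
  feature.  Fixed-bound binning after intensity normalization is the
  standard remedy.
* **GLCM.**  Distance-1 pairs in the four principal directions, both pixels
  inside the mask, symmetric counts, each direction's matrix normalized to
  sum 1 and then averaged.  Entropy is `-sum p ln p` (natural log, with
  0 ln 0 = 0) — reported as a positive quantity.  A constant ROI has a
  one-cell GLCM; its correlation is undefined and returned as `NaN` with a
  warning rather than silently zeroed.
* **GLRL.**  Maximal runs of equal quantized level along the same four
  directions, broken at mask boundaries; the eleven standard
  Galloway/Tang definitions with 1-based gray index (the low-gray-emphasis
  features divide by the squared index, so a 0-based index would be
  singular); features are computed per direction and averaged.
* **GLGM.**  3x3 Sobel gradient magnitude over ROI interior pixels (full
  3x3 neighbourhood inside the mask); mean, population variance, and
  standardized third/fourth moments (kurtosis non-excess: a Gaussian scores
  3).  Zero gradient variance leaves skewness/kurtosis `NaN` with a warning.
* **Laws.**  The nine 3x3 masks from the L3/E3/S3 triple — the kernel family
  is chosen because it yields exactly nine masks — applied after
  subtracting the 3x3 local mean (Laws' illumination correction, with
  border-aware averaging so a flat image scores exactly zero in every
  channel).  The local-mean removal is what puts the L3L3 energy on the
  scale of `256 x (local residual variance)`, the magnitude published
  phantom tables show, rather than the raw `(16 x mean)^2` scale four
  orders larger.
* **Histogram.**  Alongside the global moments, four features are local:
  "range" is the ROI mean of the 3x3 local max–min, and the 2nd/5th/9th
  neighbourhood SDs are the ROI means of the sample SD over a horizontal
  pair, a plus-cross, and the full 3x3 window.  The footnoted
  "k-neighbourhood SD" labels of the published tables fix the neighbourhood
  sizes; the footprint shapes are this package's choice.  Local statistics
  are mask-aware and skip pixels with fewer than two in-mask neighbours.
  Geometric/harmonic means of distributions touching zero are computed on
  values shifted to a minimum of 1.
* **Extras.**  Three additional rows appear in reports but are excluded
  from the 41-feature core and its FDR family: the skewness and kurtosis of
  the ROI intensity distribution, and the total Laws energy (the sum of
  L1–L9).

## Statistics

Two-level contrasts use the pooled-variance Student t (the protocol's
choice), two-tailed, with explicit degenerate handling: zero pooled variance
gives t = 0, p = 1 for equal means and a flagged p = 0 otherwise.  The
seven-level flip-angle contrast needs a single P per feature; a two-sample
test cannot produce one, so the package uses one-way ANOVA, which reduces
exactly to t² for two groups.  The Benjamini–Hochberg step-up is implemented
directly (q of the k-th smallest p is `min over j >= k of m p_(j) / j`,
capped at 1, NA p-values excluded from the family) and is cross-checked
against `stats::p.adjust` in the tests.  The statistical unit is the slice,
as in the emulated tables' group sizes; within-series correlation is
deliberately ignored, exactly as in the protocol being emulated.

## What the sensitivity experiment shows — and what it cannot

The headline simulation compares NEX 1 (36 slices) against NEX 4 (44
slices) — the emulated study's group sizes — with *only* the noise level
differing.  Features that measure fluctuation energy (ROI SD, GLCM contrast
and entropy, run-percentage, the local-neighbourhood SDs) respond strongly;
features pinned by the signal structure's position on the gray scale (the
high-gray-level run emphasis, the intensity fourth moment) do not.  The
test suite requires this separation to reproduce in at least 90% of 50
seeded replicates.

One honest divergence from the real-data tables: in this simulation the
Laws energies are NEX-sensitive, because band-limited noise still carries
real power in the 3x3 texture bands and the slices share their underlying
geometry.  In the real study the Laws features were stable under NEX —
there, slice-to-slice structural heterogeneity (different slice positions
through a physical object) dominates high-frequency energy.  Reproducing
that would require through-plane structure the generator deliberately does
not model; the divergence is a property of the emulation, not of the
pipeline.

## Problem sizes

The test suite simulates at 64 x 64 to 96 x 96 matrices (the phantom
geometry scales with the field of view, so a 64 x 64 slice is simply a
coarser acquisition of the same object), with full-size matrices
(256 x 192 / 256 x 160) exercised in the geometry tests.  Oracle equivalence
uses 100 random ROIs up to 16 x 16 at G = 8 against brute-force
implementations at 1e-10 tolerance; the t-test calibration uses 10^4 null
replicates at n = 40 per group; the NEX experiment uses 50 replicates of the
full 36 + 44 slice design.

## Known limitations

* The simulation is 2-D with independent slices; no through-plane
  structure, no k-space model, no inhomogeneity.
* The intermeans threshold assumes a bimodal ROI; on a contour with no dark
  rim it will split whatever modes exist (documented behaviour of the
  method, handled by the padded contour).
* DICOM support is deliberately minimal: single-frame, uncompressed
  little-endian files with the acquisition tags the pipeline needs;
  multi-frame objects and RT-STRUCT contours are out of scope.
* Feature values depend on the quantization policy (bounds and G); the
  pipeline's anchored bounds are reported in the run log, and comparisons
  across runs are only meaningful at matching settings.
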