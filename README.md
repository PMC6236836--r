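# phantomtex

Radiomic texture features are increasingly used as quantitative imaging
biomarkers, but their values depend not only on the tissue being imaged but
on how the image was acquired.  `phantomtex` quantifies that dependence for
MRI: it simulates spoiled-gradient-echo (SPGR) series of a nonanatomic
multi-tube gel phantom under controlled acquisition parameters, runs the
images through a standardized texture-analysis pipeline, and tests every
feature for sensitivity to **magnet strength** (1.5 T vs 3 T), **flip angle**
(2-30 degrees), **number of excitations** (NEX 1 vs 4), and **scanner
platform** (two vendors with different reconstruction processing).  It is
aimed at medical physicists and radiomics researchers who need to know which
features of their panel survive a protocol change — and at anyone who wants a
fully reproducible, self-contained testbed for texture-analysis code.

## The pipeline

1. **Phantom simulation** (`phantom_config()`, `simulate_series()`).  A
   19-tube phantom (18 gel tubes with a log-spaced T1 ladder plus one
   Gd-DTPA tube, embedded in a container gel) is rasterized onto the
   acquisition matrix and given the closed-form SPGR signal
   `S = PD sin(a) (1 - e^(-TR/T1)) / (1 - cos(a) e^(-TR/T1)) e^(-TE/T2*)`.
   Noise is Rician (magnitude of complex Gaussian noise, added per
   excitation before NEX averaging, so the noise SD scales as 1/sqrt(NEX)),
   spatially band-limited as reconstruction leaves it; platform differences
   are a post-reconstruction Gaussian filter plus an intensity scale.
2. **DICOM I/O** (`write_dicom_series()`, `read_series()`).  Simulated
   series round-trip through standard single-frame DICOM files; real series
   (e.g. a downloaded phantom collection) can be read the same way.
3. **Preprocessing** (`preprocess_slice()`).  A whole-phantom contour
   (automatic convex hull or a PNG/JSON mask), partial-volume artifact
   correction by iterative optimal (Ridler-Calvard) thresholding, then
   global grayscale normalization of the entire image to mean 250 / SD 30.
4. **Feature extraction** (`extract_all()`).  The 41-feature panel:
   12 histogram features, 5 gray-level co-occurrence matrix (GLCM) features
   (entropy, contrast, correlation, energy, homogeneity; four directions
   averaged, distance 1), 11 gray-level run-length (GLRL) features
   (SRE, LRE, GLN, RLN, RP, LGRE, HGRE, SRLGE, SRHGE, LRLGE, LRHGE),
   4 gradient (GLGM) features (Sobel-magnitude mean, variance, skewness,
   kurtosis), and 9 Laws texture energies (3x3 L3/E3/S3 masks), plus three
   report extras.
5. **Sensitivity statistics** (`run_contrast()`).  Per feature: pooled
   two-sample Student t (two-level contrasts) or one-way ANOVA (flip angle),
   with Benjamini-Hochberg Q-values over the 41-feature family of each
   contrast; Q < 0.05 is flagged, mirroring the familiar
   feature x (mean, SD, P, Q) table layout.

## Worked example

```r
library(phantomtex)

cfg <- pipeline_config(n_scale = 0.15,                 # scaled-down study
                       matrix_t1 = c(96, 72), matrix_dce = c(96, 60),
                       output_dir = "demo_run", seed = 2026)
res <- run_pipeline(cfg)
subset(res$results$NEX,
       feature %in% c("hist_mean", "hist_std", "glcm_contrast", "glrl_hgre"))
```

yields (NEX 1 vs 4, the other parameters held fixed):

```
       feature   mean_1   sd_1   mean_4   sd_4  p_value  q_value significant
     hist_mean   281.97   0.38   281.85   1.00 8.06e-01 8.37e-01       FALSE
      hist_std    14.86   1.22    12.14   1.08 2.25e-03 3.30e-03        TRUE
 glcm_contrast   149.85  17.48    75.17   7.47 1.30e-06 3.14e-06        TRUE
     glrl_hgre 26633.01 214.27 26558.23 326.35 6.66e-01 7.18e-01       FALSE
```

Reading the table: quadrupling NEX halves the noise SD, so features that
measure fluctuation energy (the ROI standard deviation drops from 14.9 to
12.1, GLCM contrast from 150 to 75) differ significantly (Q < 0.05, flagged),
while features pinned by the signal structure (the ROI mean under global
normalization, the high-gray-level run emphasis) do not.  In this run 34 of
the 41 features flagged — the blunt message being that most of a texture
panel is *not* robust to an acquisition change.  `run_pipeline()` also writes
`features.csv` (one row per slice), one CSV + Markdown table per contrast,
and a YAML run log with every parameter and seed, so a run is reproducible
from its log.

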