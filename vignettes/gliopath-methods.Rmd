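---
title: "Methods: layered SVM grading of gliomas from pathology patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered SVM grading of gliomas from pathology patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

Gliomas are graded histologically: low-grade tumors (LGG, WHO II–III) show
organized tissue with small, round, sharp-edged nuclei, while high-grade
tumors (HGG, WHO IV / glioblastoma) show nuclear atypia — enlarged,
elongated, irregular nuclei — together with elevated spatial heterogeneity
of the stained tissue and necrotic foci. `gliopath` quantifies these
contrasts from grayscale pathology patches and predicts the binary grade
with layered linear support-vector machines.

The pipeline is:

1. **Patch extraction** — square patches (canonically 1024 × 1024 px, 100
   per slide) are sampled from a slide, kept only if at least 50% of their
   pixels are stained tissue (darker than a near-white glass threshold,
   default 220/255) and if at most 5% of pixels are saturated (0 or 255),
   the latter standing in for a manual artifact screen, which cannot be
   reproduced algorithmically.
2. **Conventional features (26)** — 16 first-order statistics of the whole
   patch (mean, SD, median, skewness, kurtosis, max, min, and the nine
   deciles) plus 10 morphometric descriptors averaged over nuclear
   components: area, perimeter, eccentricity, convex area, Euler number,
   orientation, compactness, major/minor axis lengths and edge sharpness.
   Components come from k-means (k = 2) intensity clustering — the darker
   cluster is the nuclear (hematoxylin) cluster — followed by 8-connected
   labeling; components at or below an area threshold (default 100 px) are
   discarded.
3. **Texture features (18)** — after quantization to 16 gray levels, 8
   gray-level co-occurrence (GLCM) features (contrast, correlation, energy,
   homogeneity, entropy, cluster shade, cluster prominence,
   autocorrelation) and 10 run-length (GLRLM) features (LRE, SRE, RLN, GLN,
   HGLRE, LGLRE, SRHGLE, SRLGLE, LRHGLE, LRLGLE) are computed independently
   in the four main directions (0°, 45°, 90°, 135°) at offset distance 1
   and averaged.
4. **Layered models** — per-patient features (mean over patches, joined
   with age and gender) feed seven linear-SVM models differing in the
   feature layers they see: Ia (conventional), Ib (texture), Ic
   (clinical), IIa/IIb/IIc (pairs), IIIa (all). Each model is evaluated by
   stratified 10-fold cross-validation; within every training fold the
   features are z-scaled, forward feature selection is run under inner
   5-fold CV (except Ic, whose two features need no selection), and the
   SVM cost is tuned on the dyadic grid $C = 2^{\mu}$, $\mu = -5,\dots,5$.
   Pooled test-fold predictions give accuracy/sensitivity/specificity (HGG
   positive) and pooled decision scores give the AUC.
5. **Model comparison** — each model is re-run over permuted dataset
   orderings; paired AUC differences between two models yield a mean
   difference, a 95% percentile interval (2.5th/97.5th percentiles), and an
   empirical one-sided p-value. A difference is called significant when
   the percentile interval excludes zero.

# Conventions and numerical choices

Several steps admit more than one textbook convention; the package fixes
them as follows.

* **Deciles, not ranges.** The "inter-quantile" statistical features are
  the nine decile values (10th–90th percentiles, linear interpolation),
  the information-complete reading that subsumes any derived ranges.
* **Skewness/kurtosis** are the standardized 3rd/4th central moments
  (kurtosis non-excess). On a constant patch both are reported as 0 so
  feature matrices stay finite.
* **Segmentation determinism.** k-means is initialized at the 25th/75th
  intensity percentiles, making the 2-cluster split reproducible without a
  random start. Since the split depends only on intensity order and
  spacing, adding a constant to a patch leaves the segmentation unchanged.
* **Connectivity** is 8-neighbor for foreground components; holes are
  counted in the 4-connected background complement, the topologically dual
  convention, so the Euler number of a solid blob is 1 and of an annulus 0.
* **Perimeter** is the chain length of the traced outer contour. On a
  rasterized disk of radius 50 this yields compactness $4\pi A/P^2 \approx
  0.91$; boundary-pixel counting, the main alternative, is not used because
  it gives impossible compactness values above 1.
* **Axes/eccentricity/orientation** come from second central moments with
  the 1/12 pixel-extent correction (the ellipse-of-equal-moments
  convention); orientation is degrees in (−90°, 90°] from the column axis.
* **Edge sharpness** has no canonical formula; it is defined here as the
  mean Sobel gradient magnitude over component boundary pixels.
* **Quantization** spans each patch's own [min, max] in equal-width bins.
  Per-patch normalization buys robustness to stain-intensity differences at
  a price: features become invariant to affine intensity rescaling, so
  pure-noise amplitude alone is not detectable on an otherwise empty patch.
  On structured tissue the intensity range is anchored by the
  nuclei/stroma contrast and added noise raises GLCM contrast and entropy
  as expected.
* **GLCM** matrices are symmetrized before normalization; entropy is in
  bits with $0\log 0 = 0$; correlation of a zero-variance GLCM is defined
  as 1; level indices in the moment-type features are the 0-based level
  values. The "distance-1, four directions" offsets are exactly the
  neighbors within a pixel's 3 × 3 neighborhood.
* **GLRLM** emphasis formulas index gray levels 1-based so low-gray-level
  emphases are finite at level 0.
* **C grid.** The cost grid is read as the 11 integer exponents −5…5.
  Ties during tuning break toward the smaller cost (larger margin).
* **Forward selection** always keeps its first (best single) feature, then
  stops when the best accuracy improvement is ≤ 0.001 ("steady state") or
  negative ("drop"). Selection uses cost 1; the cost grid is tuned
  afterwards on the selected subset.
* **Metrics are pooled**, not fold-averaged: one confusion matrix and one
  score vector over all outer test folds. Pooling is the stabler choice at
  moderate cohort sizes and is what the reported AUC is computed from.
* **Pairing and p-values.** Permuted-run comparisons pair iterations by
  permutation seed, so the AUC difference isolates the model contrast
  rather than fold noise. "Permutation of the dataset" is implemented as
  row-order reshuffling (which redraws CV fold assignments), not label
  permutation — the comparisons are between real models and need true
  labels. The empirical p uses the add-one correction with ties at half
  weight, $p = (1 + \#\{d<0\} + 0.5\,\#\{d=0\})/(n+1)$, so two identical
  run sets give $p \approx 0.5$ and p is never exactly 0.

# The synthetic cohort generator

Real slide archives are large and access-controlled, so the package ships
a generator that emulates the class contrasts the features are built to
detect. Patches are rendered as darker ellipses ("nuclei") on brighter
stroma; orientation is uniform on [0, π); boundary radii are modulated by
two low-order sinusoids whose amplitude is the `edge_jaggedness`
parameter; additive Gaussian noise models spatial heterogeneity; with some
probability a patch receives one large bright focus imitating necrosis.

The default class profiles realize the qualitative LGG/HGG contrasts:

| parameter | LGG | HGG | rationale |
|---|---|---|---|
| nuclei / 100×100 px | 8 | 13 | higher cellularity in HGG |
| major axis (px) | 11 | 17 | nuclear enlargement |
| axis ratio | 1.3 | 2.1 | loss of circularity |
| nucleus gray | 95 | 80 | hyperchromasia |
| stroma gray | 185 | 175 | denser background |
| noise SD | 6 | 16 | spatial heterogeneity |
| necrosis rate | 0.02 | 0.35 | necrotic foci |
| jaggedness | 0.08 | 0.35 | irregular edges |

Clinical records use class-conditional normal ages — LGG mean 43.19 y (the
patient-weighted mean of the grade II and III cohort means), HGG mean
56.79 y, common SD 12 y (a typical adult-glioma spread; no SD is published
for the cohort the defaults mirror) — and Bernoulli gender at 58.1% male.
By default gender carries no label signal; a configurable log-odds shift
can make it weakly informative.

What the generator does **not** emulate: H&E color (patches are grayscale
by construction), stain variation and color deconvolution, touching/
overlapping nuclei, vascular structures, and the spatial organization of
pseudopalisading necrosis (necrosis is a single bright blob, not a
cell-ringed focus). Passing tests on synthetic cohorts therefore
demonstrate that the pipeline recovers planted class structure of the kind
the features target — not clinical performance on real slides.

# Simulation design of the test and acceptance suites

Problem sizes in the shipped tests are deliberate desk-scale choices:
patches of 64–128 px (the geometry scales down with nucleus sizes),
4–10 patches per patient, cohorts of 20–100 patients, and tens to a few
hundred permutation iterations. The classifier-stack properties
(selection, leakage, synergy, null calibration) are exercised on directly
generated feature tables with planted effect sizes, which isolates the
property under test from the feature extractors; the end-to-end recovery
check runs the full image path on a rendered cohort of 100 patients ×
10 patches. The null calibration of the comparison machinery follows its
natural design — two models with exchangeable (all-noise, equal-size)
feature layers on the same cohort, paired seeds, 200 iterations,
50 replicates. Under this null the one-sided empirical p-value rejects at
close to its nominal rate, which is what the suite asserts. The
percentile-interval rule is more liberal there: the interval describes
iteration-to-iteration spread around the cohort-level chance contrast,
not the sampling error of the mean difference, so on a fixed cohort it
can exclude zero noticeably more often than 5%. Significance calls should
therefore be read together with the p-value, the same caution the
interval/p disagreements in published comparison tables suggest.

# Known limitations

* The tissue filter is a proxy for expert ROI curation; it cannot
  distinguish viable tumor from normal tissue.
* Components are a proxy for nuclei; no instance segmentation or
  overlap resolution is attempted, and morphology is computed on the dark
  k-means cluster only.
* Only linear kernels, no class weighting, no probability calibration.
* No multiple-testing correction across model-pair comparisons.
* Patch-to-patient aggregation is the unweighted mean; alternatives
  (median, quantile pooling) are not explored.
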