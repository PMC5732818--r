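---
title: "CT radiomics for chemoradiotherapy response: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{CT radiomics for chemoradiotherapy response}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific content of `crtradiomics`: the
preprocessing and feature models, the statistical procedures, what the
synthetic cohort generator does and does not emulate, and the design
decisions taken where a published workflow of this kind leaves details
open.

## The problem

Esophageal tumors that respond to chemoradiotherapy tend to differ in
internal phenotype from those that do not: heterogeneity of the blood
supply shows up in contrast-enhanced CT as spatial texture and as asymmetry
of the intensity histogram within the tumor. The pipeline quantifies the
contoured tumor with a fixed inventory of 214 hand-crafted features, filters
them for inter-observer reproducibility, screens them univariately against
RECIST response (CR/PR = responder, SD/PD = nonresponder), and builds small
cross-validated classifiers.

## Preprocessing

**Resampling.** Volumes are resampled to 1×1×1 mm with separable
Catmull–Rom cubic interpolation; masks with nearest-neighbor. The output
grid size per axis is `round(n * spacing / target)`, which preserves the
physical extent to within one voxel. Catmull–Rom weights sum to one, so
constant images are reproduced exactly and a no-op resampling is the
identity — two degenerate cases the tests pin down.

**Quantization.** ROI intensities are mapped to `2^k` discrete levels by
`V(x) = floor(2^k (I − min_Ω I)/(max_Ω I − min_Ω I))`, with the voxel(s) at
the ROI maximum clamped to `2^k − 1` so exactly `2^k` values (0…2^k−1) are
occupied; a literal reading of the floor formula would produce `2^k + 1`
levels, and the clamp reconciles it with the stated level count. Default
k = 4 (16 levels), the setting under which results of this workflow are
conventionally reported. Quantization is invariant to positive affine
rescaling of the input, which is the point: it suppresses
acquisition-dependent intensity ranges.

**Order of operations.** The pipeline resamples first and quantizes second.
Quantized levels are not meaningfully interpolatable (cubic interpolation
between discrete levels produces non-levels), so the reverse order is not
implementable without an extra re-quantization step. This is a documented
choice of this implementation, not a claim about any particular prior
study's internal order.

**2D features** are computed on the axial slice with the largest in-mask
area (ties: lowest index), and the 2D quantization is recomputed over that
section's own pixels, since the gray-level normalization is defined over
"the set of pixels in the contoured ROI" and for a 2D family that ROI is
the section.

## Feature families

The manifest (the single source of truth, `feature_manifest()`) pins
214 features: 60 3D + 154 2D.

* **Shape (3D, 4):** volume (voxel count × voxel volume), size (longest 3D
  diameter, the maximal pairwise distance between in-mask voxel centers),
  solidity (mask volume / convex-hull volume, computed with an in-package
  incremental 3D hull over pooled slice-wise 2D hull vertices — pooling
  slice hulls is exact for the full point cloud), and eccentricity
  `sqrt(1 − λ_min/λ_max)` from the principal-component variances of the
  voxel cloud. Solidity is capped at 1: the hull of voxel *centers* slightly
  underestimates the voxelized volume, and values marginally above 1 are a
  discretization artifact, not signal.
* **Histogram (6 per dimensionality):** mean, variance, skewness (third
  standardized moment), kurtosis (Pearson, *non-excess* — the scale on
  which reported cut-offs near 4 for near-Gaussian data make sense),
  energy and entropy of the `2^k`-bin level histogram.
* **GLCM (19 in 3D, 9 in 2D):** symmetric co-occurrence at distance 1
  accumulated over 13 (3D) / 4 (2D) directions into one matrix — the most
  common convention in the Haralick lineage. Correlation of a constant
  image is defined as 0.
* **GLRLM (13):** run-length features averaged over directions; gray values
  are indexed 1-based inside the emphasis formulas so low-gray-level
  emphases never divide by zero.
* **GLSZM (13):** zones are connected components of equal level with
  8-connectivity (2D) / 26-connectivity (3D); large-zone emphasis is
  `Σ_ij j² P(i,j) / N_z`.
* **NGTDM (5):** Amadasun–King coarseness, contrast, busyness, complexity,
  strength over strict-interior voxels (full 8/26-neighborhood inside the
  ROI). Degenerate denominators yield 0 — including the corner case of a
  perfectly compensated gradient, where the neighborhood mean equals every
  center voxel.
* **GLGCM (2D, 10):** joint histogram of quantized level × Sobel gradient
  magnitude quantized to 16 bins, over the interior of the bounding-box
  crop (background pixels enter at level 0).
* **LoG (2D, 18):** zero-sum Laplacian-of-Gaussian kernels at σ = 1.0
  (fine), 2.0 (medium), 2.5 (coarse texture); six first-order statistics of
  the filtered values inside the mask per σ. Convolution uses replicate
  padding so constants are annihilated exactly up to the border. The
  unnormalized discrete LoG used here carries an intrinsic σ² scaling that
  makes the peak response to a Gaussian blob maximal at the matched filter
  scale — the property the tests verify.
* **Gabor (2D, 80):** 5 scales × 8 orientations (θ = (o−1)π/8). The five
  center frequencies are log-spaced over 0.05–0.4 cycles/pixel (ratio
  2^(3/4); five strictly dyadic scales cannot fit inside that band, so the
  band takes precedence), bandwidth ≈ 1 octave (σ = 0.56/f), aspect ratio
  γ = 0.5, scale 1 = finest. Per filter, MSA is the mean complex-response
  magnitude over in-mask pixels and MSE the Shannon entropy of the 16-bin
  magnitude histogram; `MSA-54` means scale 5, orientation 4.

All degenerate-input conventions (skewness/kurtosis/correlation → 0 at zero
variance; 0·log 0 = 0) are chosen so that every extracted vector is finite.

## Statistics

* **ICC:** two-way, single measure, absolute agreement (ICC(A,1)) from the
  mean-square decomposition — the standard choice for two fixed raters.
  The keep rule is ICC ≥ 0.8 (the threshold itself counts as reproducible).
  Zero-variance tables return 1 with a degeneracy flag.
* **Kruskal–Wallis:** tie-corrected H with a χ² p-value
  (`stats::kruskal.test` behind the module surface); two-group contrasts
  intentionally use the same test rather than substituting a Wilcoxon.
  No multiple-testing correction is applied anywhere; all reports carry raw
  p-values and say so.
* **ROC:** AUC by Mann–Whitney pair counting (ties ½), oriented so
  AUC ≥ 0.5 with the orientation stored as the cut-off side (`>` when high
  values mark the positive class — nonresponders in the screening stage);
  SE by the DeLong placement-value variance; 95% CI = AUC ± 1.96·SE clipped
  to [0,1] (the CI method is a normal approximation, chosen because only an
  SE-style uncertainty is conventionally reported for this quantity);
  cut-offs maximize Youden's J over observed-score midpoints, ties broken
  toward higher sensitivity.
* **DeLong test:** paired comparison with the placement covariance
  structure; rank-equivalent predictors give a zero AUC difference exactly
  and are flagged degenerate with p = 1.
* **McNemar:** exact two-sided binomial on the discordant counts when
  b + c < 25, χ² with continuity correction otherwise, computed on pooled
  10-fold out-of-fold predictions.

## Models

* **SVM:** RBF kernel, C = 1, γ = 1/n_features; **ANN:** one hidden layer
  of ⌈(p+2)/2⌉ logistic units, seeded initialization, iteration cap 200.
  These hyperparameters are fixed in the config and logged; no tuning
  beyond wrapper selection is performed, to avoid introducing a second
  search the workflow does not define.
* **Standardization:** z-scores with training statistics only, reapplied to
  held-out cases.
* **Wrapper selection:** greedy backward elimination from the full input
  set, scored by 10-fold CV accuracy with a fold assignment fixed once per
  search; ties drop the later-manifest feature, and the returned subset is
  the best accuracy seen, preferring smaller subsets on ties. Selection is
  run once per algorithm (subsets may differ). Selection happens *outside*
  the final CV loop — the optimistic bias this introduces is a property of
  the reproduced design and is deliberately not "fixed"; the hold-out split
  is the guard.
* **Pipeline cap:** inside `run_pipeline()` the wrapper input is first
  capped to the top 15 features by training-split Kruskal–Wallis p.
  Backward elimination from ~200 features needs tens of thousands of CV
  evaluations; the cap keeps a full run on a laptop-scale budget while
  leaving `wrapper_select()` itself unrestricted for callers who want the
  full search.
* **Metrics:** weighted TP-rate/FP-rate/precision/F-measure are
  support-weighted per-class averages over pooled out-of-fold predictions
  (note weighted recall algebraically equals accuracy); MCC comes from the
  pooled confusion matrix; AUC from pooled out-of-fold scores.

## The synthetic cohort

The generator emulates the *statistical structure* the analysis needs, not
CT anatomy:

* ellipsoidal tumors (random per-axis anisotropy 0.7–1.3, radius 8–14 mm by
  default) in a 48×48×20 grid of 0.97×0.97×2.5 mm voxels;
* intra-tumor texture = Gaussian random field (white noise smoothed at a
  correlation length, standardized against the in-mask sample) passed
  through a monotone exponential skewing transform, plus independent voxel
  noise; in-mask standardization matters — standardizing globally lets the
  tumor land in a flat region of the skewed field and destroys the intended
  histogram contrast;
* class contrast: responders use skew strength 0 and 4 mm correlation
  length, nonresponders skew 1.2 and 8 mm — higher skewness marking
  nonresponders, the direction clinically reported for this setting;
* inter-patient variability: per-case lognormal multipliers on correlation
  length, heterogeneity and noise (sd 0.3 on the log scale), a ±10 HU mean
  shift, and per-case skew jitter (sd 0.35). Without it, cases are
  near-i.i.d., between-case variance collapses, and ICC filtering is
  meaningless — real cohorts vary far more between patients than between
  two contours of the same patient;
* background: constant soft-tissue-like 45 HU plus noise. An earlier
  zero background created an intensity cliff at the tumor boundary that a
  slightly generous second contour would fall off, biasing every
  quantized feature; peritumoral tissue on real CT is similar in HU to
  tumor, and the generator follows that;
* the second observer: the mask is softened at the perturbation scale
  (default 1 mm), a smooth random field shifts the 0.5 iso-surface locally
  (weighted by `4·soft·(1−soft)` so the far field is untouched), and the
  result is re-thresholded. Magnitude 0 returns the input bit-for-bit;
  expected Dice decreases with magnitude;
* labels: responders alternate CR/PR deterministically (CR first), all
  nonresponders are SD; PD is never generated.

What it does **not** emulate: organ anatomy, contrast kinetics, scanner
artifacts, true inter-observer behavior (perturbation magnitudes are
calibrated only to exercise the ICC filter), and clinically realistic
effect sizes — the default class contrast is deliberately strong, so
synthetic screening finds far more significant features (and higher AUCs)
than a clinical cohort would. Passing tests therefore demonstrate
correctness and calibration of the *machinery*, not clinical performance.

## Numerical and testing choices

Tests pin every matrix builder to an exhaustive brute-force enumeration
(pairs, runs, flood-fill components, neighborhood sums) on random small
arrays, exactly; statistics to closed forms (pair-counted AUC, binomial
McNemar tails, hand rank arithmetic) and to `pROC` as an independent
implementation of the DeLong machinery. Calibration checks use a 49-case
scale: permuted labels give a univariate false-positive rate near 0.05 and
chance-level CV accuracy; a planted 1.5-sd effect on 3 features lets both
classifiers exceed 0.8 CV accuracy on a 37-case training analog. The
end-to-end determinism test reruns the pipeline on a 10-case cohort and
compares output files byte-for-byte; the acceptance script runs the full
49-case default. Problem sizes in the test suite (tumor radii 5–8 mm in
32×32×14 grids) are scaled to keep the whole suite in a few minutes; the
acceptance script uses the full default conditions.

## Known limitations

* Feature definitions follow one internally consistent convention set;
  other radiomics tools differ in binning, aggregation and neighborhood
  conventions, and absolute feature values are not portable across tools.
* The ICC stage assumes exactly two observers.
* Wrapper selection outside the CV loop optimistically biases CV metrics
  (by design, see above).
* The min–max quantization is sensitive to intensity outliers in the ROI;
  with only 16 levels this is mostly benign but it is the main fragility
  of the normalization.
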