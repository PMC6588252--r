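---
title: "Retinal layer texture analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal layer texture analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(octexture)
```

This vignette documents the scientific model behind `octexture`, the
parameters that matter, and the design decisions taken where more than
one reasonable construction existed. It is the package's reference for
*why* things are computed the way they are; the README shows *how* to
run them.

## The pipeline

An OCT macular cube is a 3-D reflectivity volume: a grid of A-scans
(depth profiles) over the en-face plane, with x running temporal→nasal
(for right eyes) and y superior→inferior. Given segmented boundary
surfaces for the retinal layers, each of the six inner layers (RNFL,
GCL, IPL, INL, OPL, ONL) is reduced to a *mean-value fundus* (MVF)
image: the pixel at (x, y) is the arithmetic mean of the A-scan
intensities between the layer's two bounding interfaces. Left eyes are
mirrored about the superior–inferior axis so that the temporal and nasal
sides coincide with right eyes, and all regional labels below assume
this right-eye orientation.

Each MVF image yields 86 texture features:

* **80 local features.** The image is locally-mean downsampled to
  128×128 (giving approximately isotropic ~47 µm sampling for a 6×6 mm
  cube), quantized to 16 grey levels, and divided into a 7×7 block grid.
  Per block, grey-level co-occurrence matrices (GLCMs) are formed at
  unit distance in four directions and 20 metrics are computed, taking
  for each metric the supremum over the four directions. Block values
  are then averaged over the four 3×3 corner neighbourhoods of the grid
  — the superior-temporal, superior-nasal, inferior-temporal and
  inferior-nasal quadrants — excluding the central row and column of
  blocks that contain the fovea.
* **6 global features.** A one-level dual-tree complex wavelet
  transform (DTCWT) decomposes the image into six directionally
  selective complex subbands at ±15°, ±45° and ±75°; the feature is the
  variance of the coefficient magnitudes per subband. These capture
  image-wide oriented contrast that the blockwise GLCM analysis cannot.

Classification is one-vs-one over {HC, AD, PD} with one binary
RBF-kernel SVM per (layer, class pair): 18 models over six layers, or
15 over the default five (the RNFL is excluded by default — its fundus
image is dominated by arcuate fibre bundles, and dropping it follows
the configuration that performs best in this analysis design). Each
model uses exactly six features found by greedy forward selection.
Votes are tallied across layers and pairs; plurality wins, a three-way
tie is `Unknown`, and a two-way tie for the top is resolved by the
pairwise sub-tally between the two tied classes, falling back to
`Unknown` when that sub-tally is itself even. The two-way rule is an
interpretation of "decide by the classification between those two
classes"; it is isolated in `decide_vote()` so it can be revised
independently, and it is tested against an exhaustive enumeration of
tally configurations.

## The synthetic cohort generator

No patient data are distributed, so the generator defines the study
conditions under which the pipeline is exercised.

Each layer's texture is a stationary Gaussian random field: white noise
smoothed with a separable anisotropic Gaussian kernel (correlation
lengths `correlation_length_x/_y`, in pixels), renormalised to unit
marginal variance, scaled by `noise_sd × contrast_gain` and shifted by
`base_intensity`. This is deliberately the simplest stationary textured
field whose parameters are visible to both feature families: anisotropy
moves energy between GLCM directions and between DTCWT subbands, and
contrast gain moves amplitude-sensitive metrics.

The default three-class conditions are: HC isotropic
(correlation lengths 3, 3; gain 1.0), AD horizontally elongated with
raised contrast (6, 2; gain 1.6), PD vertically elongated with reduced
contrast (2, 6; gain 0.7), all at `noise_sd = 12` grey units on a base
near 120. These effect sizes are illustrative knobs — nothing is known
quantitatively about how AD or PD alters layer texture — chosen once so
the three classes are well separated ("strong effect"). The matched
null condition (`null_class_params()`) gives all classes the HC texture
and is used to verify chance-level behaviour.

Geometry: boundary surfaces are parallel smooth sheets with baseline
layer thicknesses (RNFL 30, GCL 35, IPL 32, INL 32, OPL 28, ONL 75 µm,
plus a 50 µm outer band), a radially symmetric Gaussian foveal
depression (default depth 100 µm, width 400 µm) carried mostly by the
inner boundaries so the inner layers thin towards the fovea, and
per-subject log-scale thickness jitter (sd 4%). The per-layer foveal
thinning is capped at 85% of the layer's baseline thickness, so
boundary ordering holds by construction for any pit depth. The default
grid is 512×128×128 voxels at (11.72, 46.88, 3.9) µm, approximating a
6×6 mm macular cube; tests and the acceptance script use a coarser
128×128 en-face grid at 46.88 µm with 64 depth voxels at 8 µm — the
same 6 mm field with fewer samples — as the package's standard
desk-scale problem size.

Both eyes of a subject share a fraction `within_subject_correlation`
(default 0.5) of each layer's field; the left eye is the horizontal
mirror of right-eye orientation. Every random draw comes from a named
sub-stream hashed from (seed, subject, eye, layer), so cohorts are
bit-reproducible and adding subjects never perturbs existing ones.

What the generator does **not** emulate: OCT speckle statistics, vessel
shadows, motion artefacts, segmentation errors, or any axial structure
within a layer (voxels take the layer's en-face field value, so the MVF
equals the field exactly). Passing tests therefore demonstrate the
correctness and calibration of the pipeline, not clinical performance
on real retinas.

## Numerical and statistical choices

* **MVF voxel convention.** The A-scan segment is half-open
  `[upper, lower)` in depth: voxel k (starting at depth (k−1)·dz) is
  included iff its start lies in the interval, with a 10⁻⁹ guard
  against floating-point jitter on exact boundaries. A zero-extent layer
  falls back to the single voxel at the upper boundary. Crossing
  boundaries are a data error naming the offending (x, y).
* **ETDRS radii.** Central disc radius 500 µm (1000 µm diameter), inner
  annulus 500–1500 µm, outer annulus 1500–3000 µm — the standard grid.
  Quadrant boundaries lie on the ±45° diagonals; pixels exactly on a
  diagonal go to the horizontal (temporal/nasal) quadrants. The fovea
  defaults to the grid centre (scans are macula-centred) and can be
  overridden.
* **The 20-metric set.** The extended Haralick list: autocorrelation,
  contrast, correlation, cluster prominence, cluster shade,
  dissimilarity, energy, entropy, homogeneity, maximum probability,
  variance (sum of squares), sum average, sum variance, sum entropy,
  difference variance, difference entropy, IMC1, IMC2, inverse
  difference normalised, inverse difference moment normalised.
  Entropies are reported in bits; IMC1 is base-invariant and IMC2 uses
  its classical natural-log form. Grey-level indices run 1..16.
  `sum_variance` is the variance of the sum distribution about the sum
  average (the modern convention). The set is a function
  (`glcm_metric_names()` + `glcm_metrics()`) and can be swapped.
* **GLCM geometry.** Four directions at unit distance
  (offsets (1,0), (1,1), (0,1), (−1,1) in (x, y)), symmetric counting,
  normalised to sum 1. 128 is not divisible by 7, so the quantized
  image is cropped centrally to 126×126 and analysed in 18×18-pixel
  blocks, preserving the centre alignment of the foveal row/column. The
  direction supremum runs over the four directions at distance 1; a
  scale sweep is left as an extension.
* **Quantization.** Per-image min–max mapping onto 16 equal-width bins
  (constant images map to level 0), removing global brightness
  differences between eyes and devices.
* **DTCWT.** Only level 1 is needed, which a single odd-length
  linear-phase biorthogonal pair realises: the two trees differ by a
  one-sample delay obtained from the polyphase components, combined by
  the quad-to-complex step into six approximately analytic subbands.
  The CDF 9/7 (Antonini) analysis pair is used, with symmetric
  (edge-repeated) extension; subbands are ordered
  (+15°, +45°, +75°, −75°, −45°, −15°), orientations referring to the
  (x, y) axes above. Variances use the population (1/N) normalisation.
  Odd image dimensions are padded by edge replication.
* **Leak-free cross-validation.** Z-scoring, forward selection and SVM
  fitting happen inside each training fold; held-out eyes only ever
  meet frozen transforms. The partition unit is the subject (both eyes
  in the same fold) because eye-level splitting leaks the within-subject
  texture correlation into the test folds; `unit = "eye"` reproduces
  the laxer reading, and `selection = "global"` reproduces
  selection-before-CV. Stratified partitions are redrawn (bounded) until
  every training fold contains all classes.
* **Forward-selection scorer.** Stratified internal cross-validated
  accuracy (k = 5, capped by class size) of the RBF SVM on the training
  fold, with C = 1 and gamma = 1/d for d features — on z-scored
  features this equals the common 1/(d·Var) default. Training-set
  accuracy would overfit the selection. Ties go to the lowest feature
  index, making selection deterministic. The inner scorer is a compact
  C++ SMO solver (the greedy wrapper evaluates ~500 candidate sets per
  model and fold, each needing an internal CV); the final per-model
  SVMs are fitted with e1071, and the two agree on the constructed
  selection tests.
* **Metrics with the `Unknown` column.** An `Unknown` prediction is
  never "predicted c" for any class c: it counts against sensitivity
  and accuracy and in favour of specificity. Empty denominators give
  `NA`, never a silent 0. Two-eye agreement is computed over subjects
  with exactly two classified eyes (single-eye subjects are reported
  separately); a shared `Unknown` counts as agreeing but not correct.
* **Quantiles.** Run distributions use linear interpolation between
  order statistics (R type 7).
* **Feature–thickness correlations.** The thickness paired with a local
  feature is the mean thickness of the feature's layer over the same
  3×3-block quadrant footprint used by the texture aggregation, so
  feature and thickness share spatial support. Pearson r is computed
  within each class group; fewer than 3 pairs gives `NA`.

## Problem sizes used by the tests and acceptance script

The standard strong-effect experiment is 20 subjects per class (120
eyes), five layers, subject-level 10-fold cross-validation repeated 20
times on the 128×128-grid cohort; the null experiment uses the same
cohort size with 2-fold cross-validation repeated 10 times. ANOVA
calibration uses 2000 null replicates of 3×12 eyes; Pearson recovery
uses n = 800 at ρ ∈ {0, 0.7}. These sizes are the package's chosen
desk-scale defaults; all are configurable.

## Known limitations

* The synthetic texture model is stationary and Gaussian; real layer
  texture is neither, and nothing here estimates how large real
  AD/PD texture effects are.
* The 20-metric list and the GLCM distance are one defensible choice
  among several extended-Haralick variants; results depend on the exact
  set, which is why it is pluggable and documented.
* The DTCWT ±45° subbands separate diagonal orientations only
  approximately at level 1; axis-aligned orientations separate cleanly
  (both behaviours are covered by tests).
* Proprietary scanner formats and layer segmentation are out of scope:
  volumes and surfaces enter as plain numeric arrays.
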