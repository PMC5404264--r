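---
title: "Morphometric grading of breast lesions from myoepithelial nuclei: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometric grading of breast lesions from myoepithelial nuclei: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The scientific problem

Breast intraductal proliferative lesions are graded Normal, usual ductal
hyperplasia (UDH), low-grade and high-grade ductal carcinoma in situ
(LG-/HG-DCIS). The myoepithelial cell layer that separates the luminal
epithelium from the basement membrane changes along this progression: its
nuclei become flatter and more spindle-like, and the texture of their
nuclear staining gains contrast. `myomorph` implements a complete pipeline
that grades lesions from these microenvironmental nuclei alone — no tumor
cell is ever measured:

1. nucleus segmentation on paired tiles of p63 immunohistochemistry
   (DAB-brown myoepithelial nuclei with hematoxylin counterstain) and
   routine HE staining;
2. a 32-feature morphometric vector per nucleus;
3. an RBF-kernel SVM classifying each nucleus into the four classes;
4. aggregation of cell predictions to duct and patient level by weighted
   majority, which is where the clinically relevant accuracy emerges.

Because the original slides are not deposited, the package ships a
first-class synthetic cohort generator that reproduces the statistical
structure this analysis relies on, with pixel-level ground truth, so every
stage is testable end to end.

## Stain model

Images are converted to optical density per channel,
$OD = -\log_{10}((I+1)/(I_0+1))$ with background $I_0 = 255$, where stains
mix linearly (Beer–Lambert). Stain vectors are estimated per ROI by a
deterministic plane fit: the two leading singular directions of the
high-OD pixel cloud span the stain plane, and the vectors are read off at
the robust angular extremes (1st/99th percentile) of the cloud within that
plane. The original analysis used a proprietary trained predictor of the
hematoxylin color; the plane fit is the standard published equivalent and,
unlike the original, can be verified against the generator's known vectors
(recovery within 5 degrees is asserted in the tests). The
hematoxylin-like vector is the one with the larger blue OD component; blue
is compared in coarse 0.1 bins with ties broken by the red component, so
estimation noise cannot flip the (very close) blue components of
hematoxylin and eosin. A one-dimensional but chromatic pixel cloud returns
the single supported vector first and flags its complement with zero
confidence; an achromatic cloud has no stain plane and is an error.

## HE segmentation

The hematoxylin projection is scanned by three center detectors —
difference-of-Gaussians at $\sigma$ = 2.5 and 5 px for small and mid-sized
nuclei and a circular Hough transform (radii 8–20 px) of the gradient field
for large ones. Nucleus diameters of roughly 5–15 µm at 0.46 µm/px motivate
these scales; the negative lobes of the band-pass responses are clamped at
zero before each map is rescaled to [0, 1], otherwise flat stroma would
rescale to a spurious plateau. The maps are aggregated by pixelwise
maximum (so a detection at any one scale survives), thresholded at 0.3 and
reduced by greedy non-maxima suppression at 8 px separation.

Each surviving candidate seeds a polar snake. Detector peaks can sit
several pixels off-center on flat nuclei, which a polar parameterization
tolerates badly, so the start point is first pulled to the local
intensity-weighted centroid (a few mean-shift iterations in a 6 px
window). The boundary is then the circular minimum-cost path over 72 rays
and radii up to 30 px: per-ray cost is the *signed* outward radial
derivative of the smoothed profile — the nucleus boundary is a falling
edge going outward, so falling edges attract the path and rising edges
into an adjacent nucleus repel it, which proved decisive for flat DCIS
nuclei squeezed between luminal neighbors (gradient-magnitude cost latched
onto those neighbors). Transitions are limited to |Δr| ≤ 2 px per ray with
penalty λ|Δr| (λ = 0.25 in the OD-gradient units of the projection), and
closure is exact: the dynamic program carries one state per start radius
and the path must return to it. If the traced centroid moves the trace is
restarted there (at most twice). Contours below 25 px area, with mean
interior hematoxylin below 0.3 OD, with centroid in the exclusion mask, or
overlapping an already-accepted contour by more than 30% are dropped; the
last rule removes the duplicate detections that elongated nuclei produce.

## p63 segmentation

Myoepithelial nuclei are DAB-positive, so the p63 path is a pixel
classification problem: a 100-tree random forest on a fixed
interactive-segmentation-style feature stack (per channel: raw value plus
Gaussian-smoothed value, gradient magnitude and Laplacian at scales 1, 2.5
and 5 px — depth 30). Following the original protocol it is trained on a
single annotated HG-DCIS ROI and applied everywhere else. The probability
map is thresholded at 0.5, holes are filled, connected components below
30 px or centered in the exclusion mask are discarded, and component
boundaries become contours. Touching nuclei are deliberately not split:
the downstream size trim absorbs merged blobs.

On real slides myoepithelial nuclei were picked from the HE segmentation
manually by referencing the p63 serial section; in the synthetic pipeline
this manual step is replaced by ground-truth identity (a contour is kept
when its centroid falls in a dilated true myoepithelial mask).

## Morphometry

Each nucleus yields 32 features in a fixed manifest
(`inst/extdata/feature_manifest.json`): 13 shape descriptors (moment-ellipse
axes, min/max Feret calipers on the pixel-center hull, solidity against the
rasterized convex hull, extent, form factor $4\pi A/P^2$ and its
reciprocal compactness, equivalent diameter; perimeter uses
Vossepoel–Smeulders chain-code weights 0.948/1.340), 6 intensity statistics
of the nuclear stain channel (mean, SD, min, max, median, MAD), and the 13
classic Haralick features of a grey-level co-occurrence matrix. The GLCM
uses per-nucleus min–max quantization to 8 levels, accumulates only pixel
pairs that are both inside the mask at distance 1 in the four standard
directions, and is symmetrized and normalized; natural logarithms are used,
and degenerate single-level patches take the defined limits (contrast 0,
homogeneity 1, entropies 0, correlation and the information measures 0), so
every value is finite. Per-nucleus quantization makes the texture features
invariant to affine intensity rescaling by construction. All lengths are
in pixels at 0.46 µm/px — the scale at which a 2174 px tile is 1 mm².

To absorb contour noise (merged touching nuclei, fragments), feature tables
are trimmed per ROI to the central 80% by area: the `floor(0.1 n)` largest
and smallest nuclei are dropped. Ranking is per ROI because the rule
targets ROI-level segmentation noise, and by area because "largest/smallest
nuclei" most naturally means area; both choices are configurable.

## Classification and aggregation

Features are mean-centered and variance-scaled with statistics from the
training rows only; zero-variance features pass through. The multi-class
F-score (between-class scatter over pooled within-class variance) ranks
features; all 32 are used by default, which matched the original finding
that the full set performs best. The SVM uses the RBF kernel with
one-vs-one multi-class voting (the semantics of the LIBSVM family) and the
canonical coarse grid C ∈ 2^{−5..15}, γ ∈ 2^{−15..3} in powers of 4,
selected by stratified 5-fold cross-validated accuracy with ties broken
toward the smaller C then smaller γ. Two split protocols are provided: a
class-stratified 70/30 cell split repeated 5 times, and a leave-one-case-out
21/1 split repeated 10 times with test cases drawn without replacement.
Within `run_pipeline` the grid search runs on the first repetition and the
selected (C, γ) are reused for the remaining refits — the calibration is a
property of the dataset, and this keeps the repeated protocol inexpensive.

Cells are labelled with their ROI's histotype (the deliberately noisy
duct-level labelling of the original protocol, which avoids manual
single-cell annotation), so cell-level accuracy is intentionally modest;
aggregating predicted proportions per duct and per patient and deciding by
weighted majority recovers it. The vote weights are the normalized
reciprocals of the training-set class frequencies by default (the original
describes a "weighted majority" without printing weights; inverse
prevalence is the natural reconstruction for its imbalanced nucleus counts,
and a uniform mode is exposed as the alternative). Ties resolve toward the
more severe class — clinically conservative and deterministic — and
decisions are invariant to rescaling all weights.

## Evaluation

Confusion matrices are accumulated with rows = actual, columns = predicted
in the fixed severity order. Accuracy is 100·trace/total rounded half-up to
one decimal; Cohen's kappa is $(p_o - p_e)/(1 - p_e)$ with $p_e$ from the
marginals, rounded half-up to two decimals — the same rounding as the
published tables, which the package reproduces exactly from its bundled
transcriptions (`reference_tables()`): 12 accuracies and 12 kappas across
cell/duct/patient × p63/HE × four-class/benign-vs-DCIS. Detection
agreement against reference counts is defined as mean per-ROI
`100·(1 − |detected − reference|/reference)` clipped at zero; the original
"segmentation accuracy" formula is unpublished, so this reconstruction is
used only on synthetic ground truth, alongside a mean best-overlap IoU.

## The synthetic cohort

`generate_roi` places non-overlapping circular ducts (radius 13–17% of the
tile) and rings them with elliptical myoepithelial nuclei, major axis
tangential, sizes drawn per class: minor axis mean 14/13/11.5/10 px (SD
1.2), minor/major ratio 0.75/0.70/0.60/0.52 (SD 0.05), texture-contrast
amplitude 0.05/0.08/0.12/0.16 and stain intensity 0.85–1.0 rising from
Normal to HG-DCIS. The direction of every trend follows the observed
biology (flatter, more spindle-like, higher stain contrast with grade); the
magnitudes are package defaults chosen to give realistic overlap between
adjacent classes, since the per-class feature statistics of the original
cohort are not published. Proliferative classes fill duct interiors with
round luminal nuclei; spindle fibroblasts are scattered in the stroma and
flagged in the exclusion mask, mirroring the manual fibroblast/necrosis
masking of the original workflow. Ring slots are sized by each nucleus's
major axis so neighbors do not overlap when the circumference allows it.

One scene is rendered into both stains (emulating serial sections with
exact cross-stain correspondence — real serial sections deform; we do not
model that). Rendering composes concentrations in OD space with the
standard hematoxylin/eosin/DAB absorbance vectors, adds per-pixel
intra-nuclear speckle with the class contrast amplitude, per-nucleus
lognormal staining variability (SD 0.15 on intensity, 0.30 on contrast
amplitude — without nucleus-level variability the intensity features would
be deterministic class labels, which no real stain is), and Gaussian RGB
noise (SD 2 by default). Everything derives from the seed: scenes,
renderings and the whole pipeline are bit-reproducible.

What the generator does *not* emulate: necrosis texture, out-of-focus
blur, scanner color profiles, chromatin substructure, nuclear overlaps in
depth, or ADH (excluded from the original study design). Passing tests on
synthetic cohorts therefore demonstrate the internal correctness and
robustness of the measurement-classification chain, not clinical
performance on real slides; the published real-slide accuracies are
reproduced only at the evaluation layer, from the printed matrices.

## Problem sizes and runtime choices

The package's end-to-end evaluation runs the full 22-case class structure
(7 Normal / 5 UDH / 5 LG / 5 HG) with 2 ROIs per case, 2 ducts per ROI and
10–14 nuclei per duct ring at a tile size of 320 px — about 1000
myoepithelial nuclei. Tile size is reduced from the native 2174 px (nucleus
dimensions are kept at physical scale) so that the two segmentation paths,
the feature extraction and the repeated SVM protocol complete in a few
minutes on one core; the layout, class structure and split protocols are
unchanged. `cohort_spec()` defaults to the native 2174 px tiles for users
who want full-scale material.

## Known limitations

* The polar snake is star-convex: strongly bent or overlapping nuclei are
  traced approximately; merged blobs are handled by the size trim, not by
  splitting.
* The 32-feature manifest is a canonical reconstruction containing every
  feature named in the original results; the exact original list was in
  unpublished supplementary material, so the manifest is a drop-in config.
* Whether the original size trim was per ROI or global, and its exact vote
  weights, are unpublished; both reconstructions are documented above and
  configurable.
* Cell-level accuracies on synthetic cohorts are higher than the published
  real-slide ones (~80% vs ~53%): synthetic labels are clean at ROI level,
  whereas real ducts contain genuinely heterogeneous myoepithelial
  populations. The cell < duct < patient accuracy ordering is preserved.
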