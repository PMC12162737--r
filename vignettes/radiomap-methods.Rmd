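---
title: "Parametric feature maps and field-of-view reproducibility: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parametric feature maps and field-of-view reproducibility: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

radiomap quantifies how strongly radiomic texture features extracted from
short-axis cardiac cine slices depend on the field of view (FOV), and
whether reading the same features from tile-based *parametric feature maps*
removes that dependence. This vignette documents the models, the parameter
choices, and the numerical decisions behind the package; the README shows
the headline workflow.

## Why the field of view matters

Cine cardiac MR is acquired with the FOV adapted to each patient while the
acquisition matrix stays fixed, so the in-plane pixel spacing varies from
examination to examination (here between roughly 1.47 and 1.92 mm/pixel
for FOVs of 256 x 329 to 302 x 390 mm at a 224 x 157 matrix). Texture
features are statistics of the discretized gray-level pattern *in pixel
units*: co-occurrence at a one-pixel offset, runs and zones measured in
pixels, totals proportional to the pixel count of the ROI. Rescaling the
pixel raster therefore changes feature values even when the underlying
tissue is identical. Map-based extraction tiles the image into blocks of
fixed *physical* size (3 x 3 mm in plane, 8 mm through-plane), computes
each feature inside every tile, and reads the ROI value as the mean of the
tile values under the ROI. Because a 3 mm tile is 2 x 2 pixels at every
spacing in the protocol range, the pixel-count and offset structure that
the features see becomes (nearly) FOV-invariant — that is the mechanism
the package measures.

## The synthetic cohort

No imaging data accompany the analysis, so the package generates its own
cohort with the statistical ingredients the pipeline needs, and nothing
more: a resolution-independent scene per subject, rendered at any FOV.

The scene is an annular left-ventricular myocardium (default endocardial
radius 17 mm, epicardial 29 mm) around a bright blood pool, in a dark
background. The myocardium carries a Gaussian random texture field:
white noise smoothed with a Gaussian kernel whose width is the correlation
length (default 3 mm), rescaled to a standard deviation of 15 intensity
units around the myocardial mean. A correlated field is the simplest
texture whose appearance changes with pixel spacing, which is exactly the
resolution sensitivity under study; the correlation length sits between
the finest (1.47 mm) and coarsest (1.92 mm) pixel spacing so that all
renderings sample the field near its characteristic scale.

Rendering convolves the scene with an isotropic Gaussian of sigma equal to
half the pixel spacing per axis (a partial-volume surrogate for
acquisition blur that scales with voxel size; the true MR point-spread
function is out of scope) and samples it at the pixel centers of the
requested FOV/matrix, adding white Gaussian noise (sd 4). Rician noise is
deliberately omitted: at the signal levels used the Gaussian approximation
is accurate. The scene lives on an internal 0.5 mm grid — four times finer
than the finest rendered spacing.

Per-subject variability multiplies the radii by `1 + 0.06 z` and the
tissue intensities by `1 + 0.03 z`, with `z` standard normal truncated at
three standard deviations, plus a small center shift. Each draw is a
deterministic function of `(seed, subject_id)`, so cohorts are bitwise
reproducible and a subject's anatomy is identical across FOVs.

**Intensity design.** Intensities are arbitrary units chosen around the
segmentation window, not scanner units: myocardium 70 +/- 15, blood 320,
background 20. Two constraints fix them. First, the scene must be
threshold-separable: myocardial values stay below 170
(`70 + 3 x 15 = 115`) and blood above it, the premise of the 0--170
threshold segmentation. Second, the blood/myocardium *midpoint* must stay
above 170 for every jittered subject (hence the smaller intensity jitter):
otherwise the 170-isocontour of the partial-volume-blurred image wanders
into the blood pool for bright-myocardium/dark-blood subjects and the
threshold mask erodes asymmetrically across FOVs. With the defaults the
contour hugs the endocardial border from the myocardial side at every FOV,
and the threshold mask recovers the true annulus with a Dice overlap of
about 0.99 (the tests require at least 0.90; partial-volume edge pixels
keep it below 1).

**What the phantom does not emulate:** SSFP physics (banding, flow
enhancement, coil profiles), k-space truncation, cardiac motion and frame
selection, papillary muscles and trabeculation, pathology, and
inter-subject texture *structure* differences (subjects differ in
realization, not in texture model). Passing the directional tests on this
cohort therefore shows that the map mechanism removes resolution
dependence for spatially correlated tissue texture — not that clinical
effect sizes are reproduced.

## Segmentation

The semi-automated clinical workflow (a coarse ROI around the left
ventricle, then an intensity threshold) is reproduced with a circular
region at the subject's true center and epicardial radius, a closed
0--170 window, and a largest-8-connected-component cleanup standing in
for the implicit single region of a manual workflow. Ground-truth-informed
circle placement is acceptable because segmentation reproducibility is not
the study objective; the threshold step is what interacts with the FOV.
Whether 0--170 refers to raw or normalized units in the clinical protocol
is unknowable from the outside; the phantom simply respects the numeric
window.

## The 93-feature catalog

`extract_all()` computes 18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM,
16 GLSZM and 5 NGTDM features per the public reference definitions, on a
single 2D slice. Shape descriptors are excluded by design (the ROI shape
is not altered by the FOV), and no image filters are applied. The exact
extraction settings of the original analysis are not public; the package
fixes the reference implementation's documented defaults and exposes every
one of them in `extraction_settings()`:

* fixed bin width 25, anchored at the masked minimum (so texture features
  are invariant to global intensity shifts);
* co-occurrence distance 1 pixel, four in-plane angles, symmetric
  accumulation; per-angle features averaged over the angles on which they
  are defined (feature-level, not matrix-level, averaging);
* 8-connectivity (Chebyshev distance 1) for dependence, size-zone and
  neighborhood statistics; GLDM dependence tolerance alpha = 0;
* slice thickness enters only the volume-bearing total energy
  (pixel area x 8 mm).

Degenerate inputs carry validity flags instead of silent fills: skewness
and kurtosis of a zero-variance region, GLCM correlation at zero marginal
variance, and all NGTDM features of a single-pixel region are `NA` with
`valid = FALSE`, and are excluded from downstream COVs (with `n_used`
reported). Where the reference definitions give a finite limit the limit
is used instead: NGTDM coarseness is capped at 1e6 when its denominator
vanishes, and the maximal correlation coefficient of a single-level
region is 1. Entropies sum `-p log2 p` over occupied entries only. The
MCC is the square root of the second-largest eigenvalue (real part) of
the row-conditional co-occurrence product matrix restricted to occupied
levels.

The texture engines are implemented natively (C++ matrix assembly, shared
(level, size) feature algebra for run-length/size-zone/dependence
matrices) and are verified in the test suite against exhaustive
brute-force oracles — all-pairs enumeration for GLCM, rle line scans for
GLRLM, BFS flood fill for GLSZM, per-pixel neighbor scans for GLDM/NGTDM —
on 100 seeded random 8 x 8 regions at 1e-8 relative tolerance.

## Parametric maps

`build_tile_grid()` converts the 3 x 3 mm tile to pixels as
`round(tile_mm / spacing_mm)` clamped to at least one pixel — the original
script's rounding behavior is unpublished, so nearest-integer rounding is
declared here. Tiles are anchored at the image origin, trailing partial
tiles are kept and computed as-is, and tiles with fewer than four pixels
yield undefined texture features (first-order statistics survive). Tiles
are computed on *all* of their pixels irrespective of the segmentation
mask, mirroring the workflow of computing maps for the whole image and
copying ROIs onto them afterwards; each tile is discretized independently
against its own minimum, since the map script processes tiles as
independent inputs.

Maps are stored at pixel resolution (each pixel carries its tile's value)
so the original-space ROI transfers without resampling and single-tile
grids reproduce conventional extraction bit-exactly — an identity the
acceptance suite asserts at zero tolerance. The ROI readout is the
unweighted mean over masked pixels on valid tiles (the viewer-style "ADC
map" readout); pixel weighting rather than tile weighting is a declared
choice, with the invalid-pixel fraction reported alongside. The pipeline
computes tile values once per image and averages them with masked-pixel
weights, which is algebraically identical to broadcasting.

## Reproducibility analysis

The COV is the sample standard deviation (n-1 denominator; with only
three FOVs per subject the population formula would understate spread)
divided by the absolute mean, so sign-crossing features such as skewness
remain defined. When the mean is numerically zero
(|mean| < 1e-12 max|x|) the COV is flagged missing rather than reported
as an arbitrarily large number. "Up to 10%" is read inclusively:
stable means COV <= 0.10.

Two designs mirror the two study settings. The *clinical* design computes
one COV per feature across subjects, each subject imaged at one
subject-specific FOV drawn uniformly between the smallest and largest
protocol FOV (FOVs being arbitrary in routine imaging). The
*experimental* design computes one COV per subject and feature across the
three protocol FOVs — 1116 COVs per method for 12 subjects — and a
feature's cohort verdict requires stability for *every* subject (the
stricter of the two readings of "across all FOVs and subjects"; a summary
COV would be more lenient). Method comparison counts stable features per
method, features whose COV decreased under map extraction (for the
experimental design the per-feature COV is summarized as the mean over
subjects' COVs, a declared choice), and features crossing from unstable to
stable; the relative increase in the stable count is reported as a
half-up-rounded percentage, matching how such increases are conventionally
printed (e.g. 29 to 48 is +66%, 24 to 39 is +63%).

## Problem sizes and determinism

The acceptance suite and `scripts/acceptance.R` run the full default
study: 12 subjects x 3 FOVs (36 images, 2 x 1116 COVs) for the
experimental design and 61 subjects for the clinical design, at the full
224 x 157 matrix — a few minutes of compute in total. Unit tests exercise
the same code paths on 48 x 64-pixel renderings and 8 x 8 feature
regions. All randomness (texture fields, jitter, noise, clinical FOV
draws) descends from one integer seed through fixed per-subject,
per-purpose sub-seeds, so every table in a run is bitwise reproducible
and rendering order cannot leak between stages.

## Known limitations

* 2D, single-slice, single-frame only; no 3D extraction or cine dynamics.
* The phantom's texture is stationary and Gaussian; real myocardium is
  neither, and absolute stable-feature counts on synthetic data should not
  be read as clinical estimates — only the comparison between extraction
  strategies under identical conditions is meaningful.
* Inter-rater segmentation variability is out of scope (the segmentation
  is deterministic).
* The reference extraction settings of the original analysis are not
  public; all defaults here are declared, configurable choices.
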