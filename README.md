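# radiomap

Radiomic texture features promise quantitative tissue characterization
from routine cardiac MR, but their values depend on acquisition geometry:
in clinical cine imaging the field of view (FOV) is adapted to each
patient while the acquisition matrix stays fixed, so the pixel spacing —
and with it every pixel-raster statistic — changes from scan to scan.
`radiomap` is an R package for quantifying that dependence and for testing
a remedy: reading features from **parametric feature maps**, in which the
image is tiled into blocks of fixed physical size (3 × 3 mm in plane,
8 mm slice), each of the 93 catalog features is computed per tile, and
the ROI value is recovered as the mean over the map — like reading an ADC
map in a viewer. It is aimed at radiomics methodologists and imaging
scientists who need a reproducible, fully synthetic testbed for
resolution-sensitivity questions.

The package provides, end to end:

* a **synthetic short-axis phantom**: an annular LV myocardium with a
  Gaussian-correlated texture field, bright blood pool and per-subject
  anatomical/intensity jitter, rendered at any FOV with
  spacing = FOV/matrix and partial-volume blur (σ = spacing/2);
* **threshold segmentation** of the myocardium (circular region, closed
  0–170 intensity window, largest 8-connected component);
* a native **93-feature engine** — 18 first-order plus GLCM (24),
  GLDM (14), GLRLM (16), GLSZM (16) and NGTDM (5) per the public
  reference definitions (fixed bin width 25, distance 1, four in-plane
  angles, 8-connectivity), every feature verified against brute-force
  enumeration oracles in the tests;
* the **parametric map engine** (tiling, per-tile extraction, pixel-level
  broadcast, ROI-mean readout) and NRRD I/O;
* **reproducibility reports**: coefficients of variation
  COV = s/|x̄| (sample SD, n−1) with the 10% stability cutoff
  (stable ⇔ COV ≤ 0.10), per-feature across-subject COVs for the
  clinical design and per-subject COVs across FOVs for the experimental
  design, plus conventional-vs-map comparison counts, with
  `tidy()`/`glance()`/`autoplot()` methods throughout.

## Worked example

The default experimental design renders 12 subjects at the three protocol
FOVs (256 × 329, 279 × 359, 302 × 390 mm; 224 × 157 matrix), segments
each slice, extracts all 93 features both conventionally and via
parametric maps, and computes one COV per subject and feature across the
FOVs — 1116 COVs per method:

```r
library(radiomap)
run <- run_experimental(run_config("experimental", seed = 20))
glance(run)
```

```
        design n_subjects n_images n_covs_per_method n_stable_conventional
1 experimental         12       36              1116                    36
  n_stable_map n_improved n_crossed_to_stable relative_increase_pct
1           56         61                  34                    56
  frac_covs_stable_conventional frac_covs_stable_map
1                     0.6344086            0.7732975
```

Read: of 93 features, 36 are stable (COV ≤ 10% for *every* subject) under
conventional ROI extraction, 56 under map-based extraction (+56%); the
overall fraction of per-subject COVs within the cutoff rises from 63% to
77%. Map readout removes the pixel-count and pixel-offset dependence of
the texture statistics, because a 3 mm tile is 2 × 2 pixels at every
spacing in the protocol range. The same pipeline with
`run_clinical(run_config("clinical", seed = 20))` emulates 61 patients
imaged at one subject-specific FOV each and compares across-patient COVs.

Single pieces compose just as well:

```r
spec  <- phantom_spec()
truth <- generate_subject_truth(spec, 1)
img   <- render_fov(truth, default_acquisitions()[[2]])
mask  <- threshold_segment(img, circle_region(img, truth$center_mm,
                                              truth$r_outer_mm))
fv    <- extract_all(img, mask)          # 93 named features
maps  <- compute_all_maps(img, build_tile_grid(img))
map_roi_mean(maps$glcm_Contrast, mask)   # map readout of one feature
autoplot(maps$firstorder_Mean)           # map display
```

See `vignette("radiomap-methods")` for the phantom model, the feature
definitions and settings, and the design decisions (tile rounding, COV
conventions, degenerate-feature handling).

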