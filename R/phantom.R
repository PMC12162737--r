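#' Phantom specification for the synthetic left-ventricle slice
#'
#' Defines the resolution-independent scene the cohort generator renders: an
#' annular myocardium with spatially correlated texture, a bright blood pool
#' inside it and a dark background. Intensity defaults are chosen so that
#' the myocardium stays within the 0--170 segmentation window
#' (`myo_mean_intensity + 3 * myo_texture_sd < 170`) while the blood pool
#' lies above it, mirroring the threshold-based myocardium/blood separation
#' of the imaging workflow.
#'
#' @param center_mm Scene center of the ventricle, mm (before per-subject
#'   jitter).
#' @param r_inner_mm,r_outer_mm Endocardial / epicardial radius in mm
#'   (`0 < r_inner_mm < r_outer_mm`).
#' @param myo_mean_intensity Mean myocardial intensity (arbitrary units).
#' @param myo_texture_sd Standard deviation of the correlated myocardial
#'   texture field.
#' @param texture_corr_length_mm Correlation length of the texture field:
#'   the Gaussian kernel width used to smooth white noise, in mm.
#' @param blood_intensity Blood-pool intensity; must exceed the upper
#'   segmentation threshold.
#' @param background_intensity Background intensity.
#' @param noise_sd Additive Gaussian acquisition noise, per rendered image.
#' @param subject_jitter Fractional coefficients of per-subject variation:
#'   either a single value or `c(radius, intensity)` coefficients for the
#'   radii and the tissue intensities (multiplicative factors
#'   `1 + jitter * z` with `z` standard normal truncated at 3). The radius
#'   coefficient also scales a small per-subject center shift. The
#'   intensity coefficient is kept smaller than the anatomical one so the
#'   blood/myocardium midpoint stays above the segmentation threshold for
#'   every subject.
#' @param seed Integer master seed; every per-subject realization is a
#'   deterministic function of `(seed, subject_id)`.
#' @param extent_mm Physical extent of the internal scene grid (must cover
#'   the largest rendered field of view).
#' @param grid_res_mm Resolution of the internal scene grid in mm.
#' @param seg_threshold_hi Upper segmentation threshold the intensity
#'   invariants are checked against (default 170).
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(center_mm = c(0, 0),
                         r_inner_mm = 17, r_outer_mm = 29,
                         myo_mean_intensity = 70, myo_texture_sd = 15,
                         texture_corr_length_mm = 3,
                         blood_intensity = 320, background_intensity = 20,
                         noise_sd = 4,
                         subject_jitter = c(radius = 0.06, intensity = 0.03),
                         seed = 20,
                         extent_mm = c(400, 320), grid_res_mm = 0.5,
                         seg_threshold_hi = 170) {
  spec <- structure(
    list(center_mm = as.numeric(center_mm), r_inner_mm = r_inner_mm,
         r_outer_mm = r_outer_mm, myo_mean_intensity = myo_mean_intensity,
         myo_texture_sd = myo_texture_sd,
         texture_corr_length_mm = texture_corr_length_mm,
         blood_intensity = blood_intensity,
         background_intensity = background_intensity, noise_sd = noise_sd,
         subject_jitter = jitter_coefs(subject_jitter),
         seed = as.integer(seed),
         extent_mm = as.numeric(extent_mm), grid_res_mm = grid_res_mm,
         seg_threshold_hi = seg_threshold_hi),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  num <- c("r_inner_mm", "r_outer_mm", "myo_mean_intensity",
           "myo_texture_sd", "texture_corr_length_mm", "blood_intensity",
           "background_intensity", "noise_sd", "grid_res_mm")
  for (f in num) {
    v <- spec[[f]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v < 0)
      stopf("invalid phantom spec: `%s` must be a finite non-negative scalar",
            f)
  }
  jt <- spec$subject_jitter
  if (!is.numeric(jt) || length(jt) != 2 || any(!is.finite(jt)) || any(jt < 0))
    stopf("invalid phantom spec: `subject_jitter` must be non-negative")
  if (!(spec$r_inner_mm > 0 && spec$r_inner_mm < spec$r_outer_mm))
    stopf("invalid phantom spec: requires 0 < r_inner_mm < r_outer_mm")
  if (spec$myo_mean_intensity + 3 * spec$myo_texture_sd >=
      spec$seg_threshold_hi)
    stopf(paste0("invalid phantom spec: myo_mean_intensity + 3 * ",
                 "myo_texture_sd must stay below the segmentation ",
                 "threshold (%g)"), spec$seg_threshold_hi)
  if (spec$blood_intensity <= spec$seg_threshold_hi)
    stopf(paste0("invalid phantom spec: blood_intensity must exceed the ",
                 "segmentation threshold (%g)"), spec$seg_threshold_hi)
  if (length(spec$extent_mm) != 2 || any(spec$extent_mm <= 0))
    stopf("invalid phantom spec: `extent_mm` must be two positive lengths")
  invisible(spec)
}

#' Acquisition specification
#'
#' Field of view, acquisition matrix and slice thickness of one rendering.
#' With a fixed matrix, the in-plane pixel spacing is `fov_mm / matrix_px`,
#' so a larger field of view yields coarser pixels. The FOV vector is
#' axis-aligned with the matrix vector (first entry with first matrix axis);
#' `label` keeps the conventional phase x read print order.
#'
#' @param fov_mm Length-2 field of view in mm, axis-aligned with
#'   `matrix_px`.
#' @param matrix_px Length-2 acquisition matrix (pixel counts, each >= 16).
#' @param slice_thickness_mm Slice thickness in mm, default 8.
#' @param label Optional label used in filenames and manifests.
#' @return An object of class `acquisition_spec`.
#' @export
#' @examples
#' # the protocol's middle field of view: 279 x 359 mm at 224 x 157 pixels
#' acquisition_spec(c(359, 279), label = "279x359")
acquisition_spec <- function(fov_mm, matrix_px = c(224, 157),
                             slice_thickness_mm = 8, label = NULL) {
  fov_mm <- as.numeric(fov_mm)
  matrix_px <- as.integer(matrix_px)
  if (length(fov_mm) != 2 || any(!is.finite(fov_mm)) || any(fov_mm <= 0))
    stopf("`fov_mm` must be two positive lengths in mm")
  if (length(matrix_px) != 2 || any(matrix_px < 16))
    stopf("`matrix_px` entries must be >= 16")
  if (!is.finite(slice_thickness_mm) || slice_thickness_mm <= 0)
    stopf("`slice_thickness_mm` must be positive")
  if (is.null(label))
    label <- sprintf("%.0fx%.0f", fov_mm[2], fov_mm[1])
  structure(
    list(fov_mm = fov_mm, matrix_px = matrix_px,
         slice_thickness_mm = slice_thickness_mm, label = label),
    class = "acquisition_spec"
  )
}

#' @export
print.acquisition_spec <- function(x, ...) {
  sp <- x$fov_mm / x$matrix_px
  cat(sprintf("<acquisition_spec> FOV %s mm, matrix %d x %d, spacing %.3f x %.3f mm\n",
              x$label, x$matrix_px[1], x$matrix_px[2], sp[1], sp[2]))
  invisible(x)
}

#' The three study fields of view
#'
#' The default acquisition list: a fixed 224 x 157 matrix at fields of view
#' 256 x 329, 279 x 359 and 302 x 390 mm (8 mm slices), so that only the
#' pixel spacing changes between renderings of the same subject.
#'
#' @return A list of three [acquisition_spec()] objects.
#' @export
default_acquisitions <- function() {
  list(
    acquisition_spec(c(329, 256), label = "256x329"),
    acquisition_spec(c(359, 279), label = "279x359"),
    acquisition_spec(c(390, 302), label = "302x390")
  )
}

# separable Gaussian blur on a matrix whose cells are `res` mm apart;
# truncated at 4 sigma, edge-renormalized (constant fields stay constant)
blur_matrix <- function(m, sigma_mm, res) {
  out <- m
  for (axis in 1:2) {
    s <- sigma_mm[axis] / res
    if (s < 1e-8) next
    r <- max(1L, ceiling(4 * s))
    k <- dnorm(-r:r, sd = s)
    n <- dim(out)[axis]
    band <- matrix(0, n, n)
    idx <- -r:r
    for (d in seq_along(idx)) {
      i <- seq_len(n)
      j <- i + idx[d]
      ok <- j >= 1 & j <= n
      band[cbind(i[ok], j[ok])] <- band[cbind(i[ok], j[ok])] + k[d]
    }
    band <- band / rowSums(band)
    out <- if (axis == 1) band %*% out else out %*% t(band)
  }
  out
}

#' Generate the resolution-independent scene of one subject
#'
#' Produces a continuous phantom: annulus geometry and tissue intensities
#' jittered per subject (a deterministic function of `spec$seed` and
#' `subject_id`) plus a band-limited Gaussian random texture field over the
#' myocardium with correlation length `texture_corr_length_mm`. The scene
#' lives on a fine internal grid (default 0.5 mm) and is rendered at any
#' field of view by [render_fov()].
#'
#' @param spec A [phantom_spec()].
#' @param subject_id Non-negative integer identifying the subject.
#' @return An object of class `continuous_phantom`.
#' @export
generate_subject_truth <- function(spec, subject_id) {
  validate_phantom_spec(spec)
  if (!is.numeric(subject_id) || length(subject_id) != 1 || subject_id < 0)
    stopf("`subject_id` must be a single non-negative integer")
  subject_id <- as.integer(subject_id)

  jit <- with_seed(mix_seed(spec$seed, subject_id, 1L), rnorm_trunc3(5))
  jr <- spec$subject_jitter[["radius"]]
  ji <- spec$subject_jitter[["intensity"]]
  radius_f <- 1 + jr * jit[1]
  myo_mean <- spec$myo_mean_intensity * (1 + ji * jit[2])
  blood <- spec$blood_intensity * (1 + ji * jit[3])
  center <- spec$center_mm + jr * 50 * jit[4:5]
  r_in <- spec$r_inner_mm * radius_f
  r_out <- spec$r_outer_mm * radius_f

  res <- spec$grid_res_mm
  n1 <- round(spec$extent_mm[1] / res)
  n2 <- round(spec$extent_mm[2] / res)
  org <- -c(n1 - 1, n2 - 1) * res / 2
  x1 <- org[1] + (seq_len(n1) - 1) * res
  x2 <- org[2] + (seq_len(n2) - 1) * res
  r2 <- outer((x1 - center[1])^2, (x2 - center[2])^2, `+`)

  tex <- with_seed(mix_seed(spec$seed, subject_id, 2L),
                   matrix(rnorm(n1 * n2), n1, n2))
  tex <- blur_matrix(tex, rep(spec$texture_corr_length_mm, 2), res)
  tex <- (tex - mean(tex)) / sd(tex) * spec$myo_texture_sd

  scene <- matrix(spec$background_intensity, n1, n2)
  myo <- r2 <= r_out^2 & r2 > r_in^2
  scene[myo] <- myo_mean + tex[myo]
  scene[r2 <= r_in^2] <- blood

  structure(
    list(grid = scene, grid_res_mm = res, grid_origin_mm = org,
         center_mm = center, r_inner_mm = r_in, r_outer_mm = r_out,
         myo_mean = myo_mean, blood = blood,
         noise_sd = spec$noise_sd,
         noise_seed = mix_seed(spec$seed, subject_id, 3L),
         subject_id = subject_id, spec = spec),
    class = "continuous_phantom"
  )
}

#' Render a phantom scene at a given field of view
#'
#' Convolves the continuous scene with an isotropic Gaussian whose width
#' scales with the pixel spacing (`sigma = 0.5 * spacing` per axis, a
#' partial-volume model of acquisition blur) and samples it at the pixel
#' centers of the requested field of view and matrix. Additive Gaussian
#' noise (`spec$noise_sd`) is drawn from a seed specific to the subject and
#' the field of view, so repeated renderings are bitwise identical.
#'
#' @param truth A `continuous_phantom` from [generate_subject_truth()].
#' @param acq An [acquisition_spec()].
#' @return An [image_slice()] of dimension `acq$matrix_px` with
#'   `spacing_mm = fov_mm / matrix_px`.
#' @export
render_fov <- function(truth, acq) {
  if (!inherits(truth, "continuous_phantom"))
    stopf("`truth` must be a continuous_phantom")
  if (!inherits(acq, "acquisition_spec"))
    stopf("`acq` must be an acquisition_spec")
  spacing <- acq$fov_mm / acq$matrix_px
  blurred <- blur_matrix(truth$grid, 0.5 * spacing, truth$grid_res_mm)

  m <- acq$matrix_px
  p1 <- -acq$fov_mm[1] / 2 + spacing[1] * (seq_len(m[1]) - 0.5)
  p2 <- -acq$fov_mm[2] / 2 + spacing[2] * (seq_len(m[2]) - 0.5)
  g1 <- (p1 - truth$grid_origin_mm[1]) / truth$grid_res_mm + 1
  g2 <- (p2 - truth$grid_origin_mm[2]) / truth$grid_res_mm + 1
  d <- dim(blurred)
  g1 <- pmin(pmax(g1, 1), d[1]); g2 <- pmin(pmax(g2, 1), d[2])
  i1 <- pmin(floor(g1), d[1] - 1); f1 <- g1 - i1
  i2 <- pmin(floor(g2), d[2] - 1); f2 <- g2 - i2
  # bilinear interpolation, vectorized over the full pixel grid
  F1 <- matrix(f1, m[1], m[2]); F2 <- matrix(f2, m[1], m[2], byrow = TRUE)
  px <- blurred[cbind(rep(i1, m[2]), rep(i2, each = m[1]))] * (1 - F1) * (1 - F2) +
    blurred[cbind(rep(i1 + 1, m[2]), rep(i2, each = m[1]))] * F1 * (1 - F2) +
    blurred[cbind(rep(i1, m[2]), rep(i2 + 1, each = m[1]))] * (1 - F1) * F2 +
    blurred[cbind(rep(i1 + 1, m[2]), rep(i2 + 1, each = m[1]))] * F1 * F2
  px <- matrix(px, m[1], m[2])
  if (truth$noise_sd > 0) {
    nseed <- mix_seed(truth$noise_seed, round(sum(acq$fov_mm) * 10), 0L)
    px <- px + with_seed(nseed, matrix(rnorm(length(px), sd = truth$noise_sd),
                                       m[1], m[2]))
  }
  image_slice(px, spacing_mm = spacing,
              slice_thickness_mm = acq$slice_thickness_mm,
              origin_mm = p1[1] * c(1, 0) + p2[1] * c(0, 1))
}

#' Generate a multi-subject, multi-FOV synthetic cohort
#'
#' Renders every subject's scene at every acquisition in `acq_list`,
#' yielding `n_subjects * length(acq_list)` images. Identical inputs give a
#' bitwise-identical cohort. When `out_dir` is given, each image is written
#' as `subjNN_fovLABEL.nrrd` together with a `manifest.csv`.
#'
#' @param spec A [phantom_spec()].
#' @param acq_list List of [acquisition_spec()] objects (one per field of
#'   view).
#' @param n_subjects Number of subjects (>= 1).
#' @param out_dir Optional output directory for NRRD files and the manifest.
#' @return A tibble with one row per (subject, FOV): `subject_id`,
#'   `fov_label`, `spacing_1`, `spacing_2`, the rendered `image`
#'   (list-column of [image_slice()]), the subject's true `center_1`,
#'   `center_2`, `r_inner_mm`, `r_outer_mm`, and `path` (NA when not
#'   written).
#' @export
#' @examples
#' spec <- phantom_spec(extent_mm = c(120, 120))
#' acq <- acquisition_spec(c(100, 100), matrix_px = c(64, 64))
#' cohort <- generate_cohort(spec, list(acq), n_subjects = 2)
#' nrow(cohort)
generate_cohort <- function(spec, acq_list = default_acquisitions(),
                            n_subjects = 12, out_dir = NULL) {
  validate_phantom_spec(spec)
  if (!length(acq_list)) stopf("`acq_list` must be non-empty")
  if (n_subjects < 1) stopf("`n_subjects` must be >= 1")
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir))
      stopf("cannot create output directory: %s", out_dir)
  }
  rows <- list()
  for (s in seq_len(n_subjects)) {
    truth <- generate_subject_truth(spec, s)
    for (a in seq_along(acq_list)) {
      acq <- acq_list[[a]]
      img <- render_fov(truth, acq)
      path <- NA_character_
      if (!is.null(out_dir)) {
        path <- file.path(out_dir, sprintf("subj%02d_fov%s.nrrd", s,
                                           acq$label))
        write_nrrd(img, path)
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        subject_id = s, fov_label = acq$label,
        spacing_1 = img$spacing_mm[1], spacing_2 = img$spacing_mm[2],
        image = list(img),
        center_1 = truth$center_mm[1], center_2 = truth$center_mm[2],
        r_inner_mm = truth$r_inner_mm, r_outer_mm = truth$r_outer_mm,
        path = path
      )
    }
  }
  cohort <- dplyr::bind_rows(rows)
  if (!is.null(out_dir)) {
    manifest <- dplyr::select(cohort, -"image")
    write.csv(manifest, file.path(out_dir, "manifest.csv"),
              row.names = FALSE)
  }
  cohort
}

# normalize subject_jitter to named c(radius, intensity)
jitter_coefs <- function(j) {
  if (length(j) == 1) return(c(radius = unname(j), intensity = unname(j)))
  if (length(j) == 2) {
    if (is.null(names(j)) || !all(c("radius", "intensity") %in% names(j)))
      names(j) <- c("radius", "intensity")
    return(c(radius = unname(j[["radius"]]),
             intensity = unname(j[["intensity"]])))
  }
  stopf("`subject_jitter` must have length 1 or 2")
}
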