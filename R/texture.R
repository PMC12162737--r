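# Texture-matrix feature classes. Each exported wrapper feeds the level
# matrix of a discretized_region to the native engine; per-angle classes
# (GLCM, GLRLM) average feature values over the angles on which the
# feature is defined, matching the reference convention.

check_region <- function(region) {
  if (!inherits(region, "discretized_region"))
    stopf("`region` must be a discretized_region (see discretize())")
}

avg_angles <- function(per_angle, names) {
  vals <- colMeans(per_angle, na.rm = TRUE)
  vals[!is.finite(vals)] <- NA_real_
  names(vals) <- names
  structure(vals, valid = stats::setNames(!is.na(vals), names))
}

as_named <- function(vals, names) {
  vals[!is.finite(vals)] <- NA_real_
  names(vals) <- names
  structure(vals, valid = stats::setNames(!is.na(vals), names))
}

#' Gray level co-occurrence matrix features
#'
#' For each configured angle, builds the (by default symmetric)
#' co-occurrence matrix of level pairs at `glcm_distance` over pixel pairs
#' that both lie in the mask, normalizes it, computes the 24 reference
#' features, and averages each feature over the angles on which it is
#' defined. Correlation is flagged undefined when the marginal variance is
#' zero (single occupied level).
#'
#' @param region A [discretize()]d region.
#' @param settings An [extraction_settings()].
#' @return Named numeric vector of 24 features with a `valid` attribute.
#' @export
glcm_features <- function(region, settings = extraction_settings()) {
  check_region(region)
  per <- cpp_glcm_features(region$levels, region$ng,
                           angle_offsets(settings$angles_2d),
                           settings$glcm_distance, settings$symmetric_glcm)
  avg_angles(per, paste0("glcm_", .glcm_names))
}

#' Gray level run-length matrix features
#'
#' Counts maximal runs of equal level along each angle (runs truncate at
#' the mask boundary), computes the 16 reference features per angle and
#' averages over angles.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features with a `valid` attribute.
#' @export
glrlm_features <- function(region, settings = extraction_settings()) {
  check_region(region)
  per <- cpp_glrlm_features(region$levels, region$ng,
                            angle_offsets(settings$angles_2d))
  avg_angles(per, paste0("glrlm_", .glrlm_names))
}

#' Gray level size zone matrix features
#'
#' Zones are 8-connected components of equal level within the mask; the
#' matrix is indexed by (level, zone size). Orientation-free, so no angle
#' averaging.
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 16 features with a `valid` attribute.
#' @export
glszm_features <- function(region, settings = extraction_settings()) {
  check_region(region)
  as_named(cpp_glszm_features(region$levels, region$ng),
           paste0("glszm_", .glszm_names))
}

#' Gray level dependence matrix features
#'
#' The dependence of a pixel is the number of its 8-connected in-mask
#' neighbors whose level differs by at most `gldm_alpha`; the matrix is
#' indexed by (level, dependence + 1).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 14 features with a `valid` attribute.
#' @export
gldm_features <- function(region, settings = extraction_settings()) {
  check_region(region)
  as_named(cpp_gldm_features(region$levels, region$ng,
                             as.integer(settings$gldm_alpha)),
           paste0("gldm_", .gldm_names))
}

#' Neighboring gray tone difference matrix features
#'
#' For each level, accumulates the absolute difference between the level
#' and the mean level of the pixel's valid in-mask neighbors. Pixels with
#' no in-mask neighbor are excluded; a single-pixel mask therefore yields
#' undefined features. Coarseness is capped at 1e6 when its denominator
#' vanishes (constant region).
#'
#' @inheritParams glcm_features
#' @return Named numeric vector of 5 features with a `valid` attribute.
#' @export
ngtdm_features <- function(region, settings = extraction_settings()) {
  check_region(region)
  as_named(cpp_ngtdm_features(region$levels, region$ng),
           paste0("ngtdm_", .ngtdm_names))
}

#' Extract the full 93-feature vector from one image and mask
#'
#' Conventional extraction: discretizes the masked intensities and computes
#' all 93 catalog features (18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM,
#' 16 GLSZM, 5 NGTDM). Features whose formula degenerates on the input
#' (for example skewness of a constant region) are returned as `NA` with
#' `valid = FALSE` rather than silently filled.
#'
#' @inheritParams discretize
#' @return A `feature_vector`: list with `values` (named numeric, length
#'   93), `valid` (named logical), `n_pixels` and `ng`. Use
#'   [tibble::as_tibble()] for a tidy (feature, class, value, valid) form.
#' @export
#' @examples
#' img <- image_slice(matrix(rnorm(64, 100, 20), 8), spacing_mm = c(1.5, 1.5))
#' mask <- circle_region(img, c(0, 0), 100)
#' fv <- extract_all(img, mask)
#' length(fv$values)
extract_all <- function(image, mask, settings = extraction_settings()) {
  reg <- discretize(image, mask, settings)
  extract_from_region(reg, settings)
}

extract_from_region <- function(reg, settings) {
  fo <- first_order_values(reg$values,
                           tabulate(reg$levels[!is.na(reg$levels)], reg$ng),
                           reg$pixel_area_mm2 * reg$slice_thickness_mm)
  offs <- angle_offsets(settings$angles_2d)
  glcm <- colMeans(cpp_glcm_features(reg$levels, reg$ng, offs,
                                     settings$glcm_distance,
                                     settings$symmetric_glcm), na.rm = TRUE)
  gldm <- cpp_gldm_features(reg$levels, reg$ng,
                            as.integer(settings$gldm_alpha))
  glrlm <- colMeans(cpp_glrlm_features(reg$levels, reg$ng, offs),
                    na.rm = TRUE)
  glszm <- cpp_glszm_features(reg$levels, reg$ng)
  ngtdm <- cpp_ngtdm_features(reg$levels, reg$ng)
  vals <- c(fo$values, glcm, gldm, glrlm, glszm, ngtdm)
  vals[!is.finite(vals)] <- NA_real_
  names(vals) <- .catalog_features()
  structure(
    list(values = vals,
         valid = stats::setNames(!is.na(vals), names(vals)),
         n_pixels = reg$n_pixels, ng = reg$ng),
    class = "feature_vector"
  )
}

#' @export
print.feature_vector <- function(x, ...) {
  cat(sprintf("<feature_vector> 93 features from %d px (Ng = %d); %d valid\n",
              x$n_pixels, x$ng, sum(x$valid)))
  invisible(x)
}

#' @export
as_tibble.feature_vector <- function(x, ...) {
  cat_tbl <- feature_catalog()
  tibble::tibble(feature = names(x$values), class = cat_tbl$class,
                 value = unname(x$values), valid = unname(x$valid))
}

#' @export
as.data.frame.feature_vector <- function(x, ...) {
  as.data.frame(as_tibble.feature_vector(x))
}
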