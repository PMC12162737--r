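#' Feature extraction settings
#'
#' Settings shared by all feature classes. Intensities are discretized with
#' a fixed bin width anchored at the masked minimum; co-occurrence is
#' evaluated at `glcm_distance` pixels along the four in-plane directions;
#' dependence, size-zone and neighborhood statistics use the 8-connected
#' neighborhood (Chebyshev distance 1).
#'
#' @param bin_width Intensity units per gray level bin (> 0), default 25.
#' @param glcm_distance Co-occurrence offset in pixels (>= 1), default 1.
#' @param angles_2d In-plane directions in degrees, subset of
#'   `c(0, 45, 90, 135)`; default all four.
#' @param gldm_alpha Dependence tolerance on the level difference,
#'   default 0.
#' @param symmetric_glcm Add each pixel pair in both orders (default TRUE).
#' @return An object of class `extraction_settings`.
#' @export
extraction_settings <- function(bin_width = 25, glcm_distance = 1,
                                angles_2d = c(0, 45, 90, 135),
                                gldm_alpha = 0, symmetric_glcm = TRUE) {
  if (!is.finite(bin_width) || bin_width <= 0)
    stopf("`bin_width` must be > 0")
  if (glcm_distance < 1) stopf("`glcm_distance` must be >= 1")
  if (!length(angles_2d) || !all(angles_2d %in% c(0, 45, 90, 135)))
    stopf("`angles_2d` must be a non-empty subset of c(0, 45, 90, 135)")
  structure(
    list(bin_width = bin_width, glcm_distance = as.integer(glcm_distance),
         angles_2d = angles_2d, gldm_alpha = gldm_alpha,
         symmetric_glcm = isTRUE(symmetric_glcm)),
    class = "extraction_settings"
  )
}

# (row, col) step per angle; 0 deg walks along axis 2 (within a row)
angle_offsets <- function(angles) {
  steps <- list(`0` = c(0L, 1L), `45` = c(-1L, 1L), `90` = c(-1L, 0L),
                `135` = c(-1L, -1L))
  do.call(rbind, steps[as.character(angles)])
}

#' Discretize masked intensities into gray levels
#'
#' Fixed-bin-width binning anchored at the masked minimum:
#' `level = floor((I - min) / bin_width) + 1`, with levels then re-indexed
#' to the consecutive occupied integers `1..Ng`. This is the prerequisite
#' of every texture-matrix class and of the histogram-based first-order
#' features.
#'
#' @param image An [image_slice()].
#' @param mask A `seg_mask` with at least one pixel.
#' @param settings An [extraction_settings()].
#' @return An object of class `discretized_region`: the level matrix (`NA`
#'   outside the mask), `ng`, pixel count and the geometry needed by
#'   volume-bearing features.
#' @export
discretize <- function(image, mask, settings = extraction_settings()) {
  if (!inherits(image, "image_slice")) stopf("`image` must be an image_slice")
  if (!inherits(mask, "seg_mask")) stopf("`mask` must be a seg_mask")
  check_same_geometry(image, mask, "image and mask")
  if (!any(mask$mask)) stopf("mask is empty")
  v <- image$pixels[mask$mask]
  if (!all(is.finite(v))) stopf("masked intensities contain non-finite values")
  lv <- discretize_values(v, settings$bin_width)
  L <- matrix(NA_integer_, nrow(image$pixels), ncol(image$pixels))
  L[mask$mask] <- lv$levels
  structure(
    list(levels = L, ng = lv$ng, n_pixels = length(v), values = v,
         pixel_area_mm2 = prod(image$spacing_mm),
         slice_thickness_mm = image$slice_thickness_mm,
         bin_width = settings$bin_width),
    class = "discretized_region"
  )
}

# raw binning + re-indexing to occupied levels, on a bare numeric vector
discretize_values <- function(v, bin_width) {
  raw <- floor((v - min(v)) / bin_width) + 1
  occ <- sort(unique(raw))
  list(levels = match(raw, occ), ng = length(occ))
}

#' @export
print.discretized_region <- function(x, ...) {
  cat(sprintf("<discretized_region> %d px, Ng = %d (bin width %g)\n",
              x$n_pixels, x$ng, x$bin_width))
  invisible(x)
}
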