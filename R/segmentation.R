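#' Circular region of interest in physical coordinates
#'
#' Marks the pixels whose centers lie within `radius_mm` of `center_mm`
#' (world mm coordinates). Because the test is geometric, the number of
#' selected pixels varies with the pixel spacing of the image. This is the
#' automated surrogate for the manual ROI drawn around the left ventricle.
#'
#' @param image An [image_slice()].
#' @param center_mm Length-2 center in mm.
#' @param radius_mm Radius in mm (> 0).
#' @return A `seg_mask`.
#' @export
circle_region <- function(image, center_mm, radius_mm) {
  if (!inherits(image, "image_slice")) stopf("`image` must be an image_slice")
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stopf("`radius_mm` must be positive")
  co <- pixel_coords(image)
  r2 <- outer((co$x1 - center_mm[1])^2, (co$x2 - center_mm[2])^2, `+`)
  mask <- r2 <= radius_mm^2
  if (!any(mask))
    stopf("circle (center %.1f, %.1f mm; radius %g mm) does not intersect the image",
          center_mm[1], center_mm[2], radius_mm)
  new_seg_mask(mask, image)
}

#' Threshold-based myocardium segmentation within a region
#'
#' Reproduces the semi-automated workflow: restrict to a coarse region,
#' keep pixels whose intensity lies in the closed interval `[lo, hi]`
#' (default 0--170, the window separating myocardium from the bright blood
#' pool), then retain only the largest 8-connected component.
#'
#' @param image An [image_slice()].
#' @param region A `seg_mask` (e.g. from [circle_region()]).
#' @param lo,hi Closed intensity window; defaults 0 and 170.
#' @return A `seg_mask` with at least one pixel.
#' @export
threshold_segment <- function(image, region, lo = 0, hi = 170) {
  if (!inherits(image, "image_slice")) stopf("`image` must be an image_slice")
  if (!inherits(region, "seg_mask")) stopf("`region` must be a seg_mask")
  check_same_geometry(image, region, "image and region")
  if (lo > hi) stopf("`lo` must be <= `hi`")
  cand <- region$mask & image$pixels >= lo & image$pixels <= hi
  if (!any(cand))
    stopf(paste0("threshold segmentation is empty; review the threshold ",
                 "window [%g, %g] and the region placement"), lo, hi)
  mask <- largest_component(cand)
  new_seg_mask(mask, image)
}

# largest 8-connected component of a logical matrix (ties: first label)
largest_component <- function(mask) {
  L <- matrix(NA_integer_, nrow(mask), ncol(mask))
  L[mask] <- 1L
  lab <- cpp_label_components(L)
  sizes <- tabulate(lab[lab > 0])
  lab == which.max(sizes)
}

#' Rasterize the true annulus of a phantom scene
#'
#' Ground-truth myocardium mask on an image grid: pixels whose centers fall
#' in the (jittered) annulus of the subject's scene. Used to validate
#' threshold segmentation against the known geometry.
#'
#' @param image An [image_slice()].
#' @param truth A `continuous_phantom`, or a list with `center_mm`,
#'   `r_inner_mm`, `r_outer_mm`.
#' @return A `seg_mask`.
#' @export
annulus_mask <- function(image, truth) {
  co <- pixel_coords(image)
  r2 <- outer((co$x1 - truth$center_mm[1])^2,
              (co$x2 - truth$center_mm[2])^2, `+`)
  new_seg_mask(r2 <= truth$r_outer_mm^2 & r2 > truth$r_inner_mm^2, image)
}
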