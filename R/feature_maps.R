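#' Build a tile grid over an image
#'
#' Partitions the pixel grid into tiles of a fixed physical size (default
#' 3 x 3 mm in plane, 8 mm through-plane, i.e. the slice thickness). The
#' per-axis tile edge in pixels is `round(tile_size_mm / spacing_mm)`,
#' clamped to at least 1; tiles are anchored at the image origin and
#' trailing partial tiles are kept. Because the physical tile size is
#' fixed, the pixel count per tile is (near) constant across fields of
#' view — the property that makes map-based extraction robust to spacing.
#'
#' @param image An [image_slice()].
#' @param tile_size_mm Length-3 tile size in mm (x, y, z); the third entry
#'   documents the slab thickness and does not affect 2D tiling.
#' @return An object of class `tile_grid`.
#' @export
#' @examples
#' img <- image_slice(matrix(0, 224, 157), spacing_mm = c(329 / 224, 256 / 157))
#' build_tile_grid(img)$tile_px
build_tile_grid <- function(image, tile_size_mm = c(3, 3, 8)) {
  if (!inherits(image, "image_slice")) stopf("`image` must be an image_slice")
  if (any(tile_size_mm <= 0)) stopf("`tile_size_mm` entries must be > 0")
  tile_px <- pmax(1L, as.integer(round(tile_size_mm[1:2] / image$spacing_mm)))
  d <- dim(image$pixels)
  n_tiles <- as.integer(ceiling(d / tile_px))
  structure(
    list(tile_size_mm = tile_size_mm, tile_px = tile_px, n_tiles = n_tiles,
         dim = d, spacing_mm = image$spacing_mm,
         origin_mm = image$origin_mm,
         slice_thickness_mm = image$slice_thickness_mm),
    class = "tile_grid"
  )
}

#' @export
print.tile_grid <- function(x, ...) {
  cat(sprintf("<tile_grid> %d x %d tiles of %d x %d px (%g x %g mm)\n",
              x$n_tiles[1], x$n_tiles[2], x$tile_px[1], x$tile_px[2],
              x$tile_size_mm[1], x$tile_size_mm[2]))
  invisible(x)
}

# integer tile id per pixel, column-major over (tile row, tile col)
tile_id_matrix <- function(grid) {
  t1 <- (seq_len(grid$dim[1]) - 1L) %/% grid$tile_px[1]
  t2 <- (seq_len(grid$dim[2]) - 1L) %/% grid$tile_px[2]
  outer(t1, t2 * grid$n_tiles[1], `+`) + 1L
}

# Per-tile feature values for the requested classes. Tiles with fewer than
# `min_texture_px` pixels get undefined texture features (first-order is
# always computed). Returns values/valid matrices of n_tiles x n_features.
tile_feature_values <- function(image, grid, settings = extraction_settings(),
                                classes = names(.class_names),
                                min_texture_px = 4L) {
  classes <- intersect(names(.class_names), classes)  # canonical order
  feats <- unlist(lapply(classes, function(cl)
    paste(cl, .class_names[[cl]], sep = "_")), use.names = FALSE)
  nt <- prod(grid$n_tiles)
  vals <- matrix(NA_real_, nt, length(feats),
                 dimnames = list(NULL, feats))
  offs <- angle_offsets(settings$angles_2d)
  vol <- prod(image$spacing_mm) * image$slice_thickness_mm
  px <- image$pixels
  tp <- grid$tile_px
  d <- grid$dim
  want_texture <- setdiff(classes, "firstorder")
  k <- 0L
  for (t2 in seq_len(grid$n_tiles[2])) {
    c0 <- (t2 - 1L) * tp[2] + 1L
    c1 <- min(t2 * tp[2], d[2])
    for (t1 in seq_len(grid$n_tiles[1])) {
      k <- k + 1L
      r0 <- (t1 - 1L) * tp[1] + 1L
      r1 <- min(t1 * tp[1], d[1])
      tile <- px[r0:r1, c0:c1, drop = FALSE]
      v <- as.vector(tile)
      lv <- discretize_values(v, settings$bin_width)
      row <- numeric(0)
      if ("firstorder" %in% classes)
        row <- first_order_values(v, tabulate(lv$levels, lv$ng), vol)$values
      if (length(want_texture)) {
        if (length(v) >= min_texture_px) {
          L <- matrix(lv$levels, nrow(tile), ncol(tile))
          for (cl in want_texture) {
            f <- switch(cl,
              glcm = colMeans(cpp_glcm_features(L, lv$ng, offs,
                                                settings$glcm_distance,
                                                settings$symmetric_glcm),
                              na.rm = TRUE),
              gldm = cpp_gldm_features(L, lv$ng,
                                       as.integer(settings$gldm_alpha)),
              glrlm = colMeans(cpp_glrlm_features(L, lv$ng, offs),
                               na.rm = TRUE),
              glszm = cpp_glszm_features(L, lv$ng),
              ngtdm = cpp_ngtdm_features(L, lv$ng))
            row <- c(row, f)
          }
        } else {
          row <- c(row, rep(NA_real_,
                            sum(lengths(.class_names[want_texture]))))
        }
      }
      row[!is.finite(row)] <- NA_real_
      vals[k, ] <- row
    }
  }
  list(values = vals, valid = !is.na(vals))
}

new_parametric_map <- function(values, valid, feature_name, image) {
  structure(
    list(feature_name = feature_name, values = values, valid = valid,
         spacing_mm = image$spacing_mm, origin_mm = image$origin_mm,
         slice_thickness_mm = image$slice_thickness_mm),
    class = "parametric_map"
  )
}

#' @export
print.parametric_map <- function(x, ...) {
  cat(sprintf("<parametric_map> %s, %d x %d px (%.1f%% valid)\n",
              x$feature_name, nrow(x$values), ncol(x$values),
              100 * mean(x$valid)))
  invisible(x)
}

#' Compute one parametric feature map
#'
#' Runs the feature computation on every tile of the grid (each tile
#' treated as an independent region covering all of its pixels, with its
#' own minimum-anchored discretization) and broadcasts the tile value to
#' the tile's pixels, so the map shares the source image's geometry and an
#' ROI defined on the original image can be copied onto it unchanged.
#' Tiles on which the feature is undefined are marked invalid.
#'
#' @param image An [image_slice()].
#' @param grid A [build_tile_grid()] result for `image`.
#' @param feature_name One of the 93 catalog names (see
#'   [feature_catalog()]).
#' @param settings An [extraction_settings()].
#' @return A `parametric_map`.
#' @export
compute_feature_map <- function(image, grid, feature_name,
                                settings = extraction_settings()) {
  catalog <- .catalog_features()
  if (!is.character(feature_name) || length(feature_name) != 1 ||
      !feature_name %in% catalog)
    stopf("unknown feature '%s'; valid names are: %s",
          as.character(feature_name)[1], paste(catalog, collapse = ", "))
  cl <- sub("_.*$", "", feature_name)
  tf <- tile_feature_values(image, grid, settings, classes = cl)
  tid <- tile_id_matrix(grid)
  vals <- matrix(tf$values[, feature_name][tid], grid$dim[1], grid$dim[2])
  valid <- matrix(tf$valid[, feature_name][tid], grid$dim[1], grid$dim[2])
  new_parametric_map(vals, valid, feature_name, image)
}

#' Compute parametric maps for all catalog features
#'
#' One map per feature (93 by default), each sharing the source image's
#' geometry.
#'
#' @inheritParams compute_feature_map
#' @param features `"all"` or a character vector of catalog feature names.
#' @return A named list of `parametric_map` objects.
#' @export
compute_all_maps <- function(image, grid, settings = extraction_settings(),
                             features = "all") {
  catalog <- .catalog_features()
  if (identical(features, "all")) features <- catalog
  bad <- setdiff(features, catalog)
  if (length(bad))
    stopf("unknown feature(s): %s; valid names are: %s",
          paste(bad, collapse = ", "), paste(catalog, collapse = ", "))
  classes <- unique(sub("_.*$", "", features))
  tf <- tile_feature_values(image, grid, settings, classes = classes)
  tid <- tile_id_matrix(grid)
  maps <- lapply(features, function(f) {
    vals <- matrix(tf$values[, f][tid], grid$dim[1], grid$dim[2])
    valid <- matrix(tf$valid[, f][tid], grid$dim[1], grid$dim[2])
    new_parametric_map(vals, valid, f, image)
  })
  stats::setNames(maps, features)
}

#' ROI readout from a parametric map
#'
#' The feature quantity is read from the map exactly as from a quantitative
#' map in a viewer: the unweighted mean of the map values over the masked
#' pixels, restricted to pixels whose tiles carry a defined value. The
#' fraction of masked pixels lost to invalid tiles is attached as the
#' `invalid_fraction` attribute.
#'
#' @param map A `parametric_map`.
#' @param mask A `seg_mask` on the same grid.
#' @return A scalar (NA if every masked pixel lies on an invalid tile) with
#'   attribute `invalid_fraction`.
#' @export
map_roi_mean <- function(map, mask) {
  if (!inherits(map, "parametric_map")) stopf("`map` must be a parametric_map")
  if (!inherits(mask, "seg_mask")) stopf("`mask` must be a seg_mask")
  check_same_geometry(map, mask, "map and mask")
  if (!any(mask$mask)) stopf("mask is empty")
  ok <- mask$mask & map$valid
  inv <- 1 - sum(ok) / sum(mask$mask)
  val <- if (any(ok)) mean(map$values[ok]) else NA_real_
  structure(val, invalid_fraction = inv)
}

# Map-based feature vector for one image + mask: per-tile features, then
# masked-pixel-weighted tile means (algebraically identical to broadcasting
# to pixel resolution and averaging over the masked pixels).
map_feature_vector <- function(image, mask, grid,
                               settings = extraction_settings()) {
  tf <- tile_feature_values(image, grid, settings)
  tid <- tile_id_matrix(grid)
  w <- tabulate(tid[mask$mask], nbins = nrow(tf$values))
  vals <- vapply(colnames(tf$values), function(f) {
    v <- tf$values[, f]
    ok <- !is.na(v) & w > 0
    if (!any(ok)) return(NA_real_)
    sum(v[ok] * w[ok]) / sum(w[ok])
  }, numeric(1))
  structure(
    list(values = vals, valid = stats::setNames(!is.na(vals), names(vals)),
         n_pixels = sum(mask$mask), ng = NA_integer_),
    class = "feature_vector"
  )
}
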