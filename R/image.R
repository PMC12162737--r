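#' Construct a 2D image slice with physical geometry
#'
#' The unit every stage of the pipeline consumes: a 2D intensity grid with
#' in-plane pixel spacing in mm, a slice thickness and the world coordinate
#' of the first pixel center. Axis 1 corresponds to matrix rows, axis 2 to
#' columns; the position of pixel `(i, j)` is
#' `origin_mm + (c(i, j) - 1) * spacing_mm`.
#'
#' @param pixels Numeric matrix of intensities (arbitrary units), all finite.
#' @param spacing_mm Length-2 positive numeric, mm per pixel along each axis.
#' @param slice_thickness_mm Slice thickness in mm (enters volume-bearing
#'   features such as total energy). Default 8, the cine protocol value.
#' @param origin_mm World coordinate (mm) of the center of pixel (1, 1).
#'   Defaults to placing the grid center at the world origin.
#' @return An object of class `image_slice`.
#' @export
image_slice <- function(pixels, spacing_mm, slice_thickness_mm = 8,
                        origin_mm = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels) || !length(pixels))
    stopf("`pixels` must be a non-empty numeric matrix")
  if (!all(is.finite(pixels)))
    stopf("`pixels` contains non-finite intensities")
  spacing_mm <- as.numeric(spacing_mm)
  if (length(spacing_mm) != 2 || any(!is.finite(spacing_mm)) ||
      any(spacing_mm <= 0))
    stopf("`spacing_mm` must be two strictly positive values")
  if (!is.finite(slice_thickness_mm) || slice_thickness_mm <= 0)
    stopf("`slice_thickness_mm` must be positive")
  if (is.null(origin_mm))
    origin_mm <- -(dim(pixels) - 1) * spacing_mm / 2
  structure(
    list(pixels = pixels, spacing_mm = spacing_mm,
         slice_thickness_mm = slice_thickness_mm,
         origin_mm = as.numeric(origin_mm)),
    class = "image_slice"
  )
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("<image_slice> %d x %d px, spacing %.3f x %.3f mm, thickness %g mm\n",
              nrow(x$pixels), ncol(x$pixels), x$spacing_mm[1], x$spacing_mm[2],
              x$slice_thickness_mm))
  invisible(x)
}

#' @export
dim.image_slice <- function(x) dim(x$pixels)

# world coordinates of pixel centers along each axis
pixel_coords <- function(image) {
  d <- dim(image$pixels)
  list(
    x1 = image$origin_mm[1] + (seq_len(d[1]) - 1) * image$spacing_mm[1],
    x2 = image$origin_mm[2] + (seq_len(d[2]) - 1) * image$spacing_mm[2]
  )
}

new_seg_mask <- function(mask, image) {
  structure(
    list(mask = mask, spacing_mm = image$spacing_mm,
         origin_mm = image$origin_mm),
    class = "seg_mask"
  )
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("<seg_mask> %d x %d px, %d in mask\n",
              nrow(x$mask), ncol(x$mask), sum(x$mask)))
  invisible(x)
}

check_same_geometry <- function(a, b, what = "objects") {
  dim_a <- if (is.matrix(a$pixels %||% NULL)) dim(a$pixels) else
    dim(a$mask %||% a$values)
  dim_b <- if (is.matrix(b$pixels %||% NULL)) dim(b$pixels) else
    dim(b$mask %||% b$values)
  if (!identical(dim_a, dim_b))
    stopf("%s have different grid dimensions (%s vs %s)", what,
          paste(dim_a, collapse = "x"), paste(dim_b, collapse = "x"))
  if (max(abs(a$spacing_mm - b$spacing_mm)) > 1e-9)
    stopf("%s have different pixel spacing", what)
  invisible(TRUE)
}

#' Dice overlap between two masks
#'
#' @param a,b `seg_mask` objects (or logical matrices) on the same grid.
#' @return Dice coefficient in \[0, 1\]; `NaN` if both masks are empty.
#' @export
dice_coefficient <- function(a, b) {
  ma <- if (inherits(a, "seg_mask")) a$mask else a
  mb <- if (inherits(b, "seg_mask")) b$mask else b
  if (!identical(dim(ma), dim(mb)))
    stopf("masks have different dimensions")
  2 * sum(ma & mb) / (sum(ma) + sum(mb))
}

# ---------------------------------------------------------------------------
# NRRD I/O (2D, raw little-endian encoding, spacing in `space directions`)
# ---------------------------------------------------------------------------

#' Write a 2D image, mask or map as NRRD
#'
#' Writes an NRRD0004 file with `space directions` carrying the pixel
#' spacing (mm), `space origin` the first pixel center, and the slice
#' thickness as the key `slice thickness mm`. Data are raw little-endian;
#' masks are written as 8-bit integers, everything else as doubles.
#'
#' @param x An `image_slice`, `seg_mask` or `parametric_map`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_nrrd <- function(x, path) {
  if (inherits(x, "seg_mask")) {
    m <- x$mask; storage <- "uint8"; thick <- NA
  } else if (inherits(x, "parametric_map")) {
    m <- x$values; storage <- "double"; thick <- x$slice_thickness_mm
  } else if (inherits(x, "image_slice")) {
    m <- x$pixels; storage <- "double"; thick <- x$slice_thickness_mm
  } else stopf("cannot write object of class %s as NRRD", class(x)[1])
  hdr <- c(
    "NRRD0004",
    sprintf("type: %s", if (storage == "uint8") "unsigned char" else "double"),
    "dimension: 2",
    "space dimension: 2",
    sprintf("sizes: %d %d", nrow(m), ncol(m)),
    sprintf("space directions: (%.10g,0) (0,%.10g)",
            x$spacing_mm[1], x$spacing_mm[2]),
    sprintf("space origin: (%.10g,%.10g)", x$origin_mm[1], x$origin_mm[2]),
    "endian: little",
    "encoding: raw"
  )
  if (!is.na(thick)) hdr <- c(hdr, sprintf("slice thickness mm:=%.10g", thick))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")
  if (storage == "uint8") {
    writeBin(as.integer(m), con, size = 1L)
  } else {
    writeBin(as.double(m), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a 2D NRRD file
#'
#' Supports the subset of NRRD written by [write_nrrd()] plus common scalar
#' types (`double`, `float`, integer types) with raw encoding.
#'
#' @param path File path.
#' @param as One of `"image"` (default) or `"mask"`.
#' @return An `image_slice` or `seg_mask`.
#' @export
read_nrrd <- function(path, as = c("image", "mask")) {
  as <- match.arg(as)
  if (!file.exists(path)) stopf("NRRD file not found: %s", path)
  con <- file(path, open = "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stopf("%s is not an NRRD file", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1)
    if (!length(line) || line == "") break
    if (grepl("^#", line)) next
    kv <- if (grepl(":=", line, fixed = TRUE))
      strsplit(line, ":=", fixed = TRUE)[[1]] else
      strsplit(line, ": ", fixed = TRUE)[[1]]
    fields[[trimws(kv[1])]] <- trimws(kv[2])
  }
  sizes <- as.integer(strsplit(fields$sizes, "\\s+")[[1]])
  if (length(sizes) != 2) stopf("only 2D NRRD supported (sizes: %s)",
                                fields$sizes)
  type <- fields$type
  enc <- fields$encoding %||% "raw"
  if (enc != "raw") stopf("unsupported NRRD encoding '%s'", enc)
  n <- prod(sizes)
  vals <- switch(type,
    "double" = readBin(con, "double", n = n, size = 8, endian = "little"),
    "float" = readBin(con, "double", n = n, size = 4, endian = "little"),
    "unsigned char" = , "uchar" = , "uint8" =
      readBin(con, "integer", n = n, size = 1, signed = FALSE),
    "short" = , "int16" = readBin(con, "integer", n = n, size = 2,
                                  endian = "little"),
    "int" = , "int32" = readBin(con, "integer", n = n, size = 4,
                                endian = "little"),
    stopf("unsupported NRRD type '%s'", type)
  )
  m <- matrix(as.double(vals), nrow = sizes[1], ncol = sizes[2])
  parse_vecs <- function(s) {
    v <- regmatches(s, gregexpr("-?[0-9.eE+]+", s))[[1]]
    as.numeric(v)
  }
  sp <- c(1, 1); org <- c(0, 0)
  if (!is.null(fields[["space directions"]])) {
    v <- parse_vecs(fields[["space directions"]])
    sp <- c(v[1], v[4])
  }
  if (!is.null(fields[["space origin"]]))
    org <- parse_vecs(fields[["space origin"]])
  thick <- as.numeric(fields[["slice thickness mm"]] %||% "8")
  img <- image_slice(m, spacing_mm = abs(sp), slice_thickness_mm = thick,
                     origin_mm = org)
  if (as == "mask") new_seg_mask(img$pixels > 0.5, img) else img
}
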