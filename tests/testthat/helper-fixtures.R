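# shared small fixtures (built in code; nothing on disk)

img_from <- function(m, spacing = c(1, 1), thickness = 8) {
  image_slice(m, spacing_mm = spacing, slice_thickness_mm = thickness)
}

full_mask <- function(img) {
  radiomap:::new_seg_mask(matrix(TRUE, nrow(img$pixels), ncol(img$pixels)),
                          img)
}

# settings that make integer-valued test images map to levels one-to-one
unit_settings <- function(...) extraction_settings(bin_width = 1, ...)

# small phantom + acquisitions for fast pipeline tests: same anatomy and
# intensity model as the defaults, rendered on a small matrix
small_spec <- function(...) {
  phantom_spec(extent_mm = c(130, 130), ...)
}

small_acq <- function(fov = 100, n = 64, label = NULL) {
  acquisition_spec(c(fov, fov), matrix_px = c(n, n), label = label)
}

# wide feature table with constant provenance, for reproducibility tests:
# `maker(subject, fov_index, feature_index)` -> value
make_feature_table <- function(n_subjects, fov_labels, method, maker) {
  feats <- feature_catalog()$feature
  rows <- list()
  for (s in seq_len(n_subjects)) {
    for (f in seq_along(fov_labels)) {
      vals <- vapply(seq_along(feats), function(k) maker(s, f, k), 0)
      names(vals) <- feats
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(subject_id = s, fov_label = fov_labels[f],
                       method = method),
        tibble::as_tibble_row(vals))
    }
  }
  dplyr::bind_rows(rows)
}
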