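#' Configuration of a full reproducibility run
#'
#' Bundles every knob of the pipeline. Defaults encode the study
#' conditions: 3 x 3 x 8 mm tiles, a 0--170 segmentation window, a 10% COV
#' cutoff, the 224 x 157 acquisition matrix, 8 mm slices, and — for the
#' experimental design — the three fields of view with 12 subjects, or —
#' for the clinical design — 61 subjects each imaged at one field of view
#' drawn uniformly between the smallest and largest protocol FOV.
#'
#' @param design `"experimental"` (every subject at every FOV) or
#'   `"clinical"` (one subject-specific FOV each).
#' @param phantom A [phantom_spec()].
#' @param acquisitions List of [acquisition_spec()]s (experimental design
#'   requires at least two).
#' @param n_subjects Cohort size; default 12 (experimental) or 61
#'   (clinical).
#' @param tile_size_mm Tile size for the parametric maps, mm.
#' @param settings An [extraction_settings()].
#' @param threshold_lo,threshold_hi Segmentation window, default 0--170.
#' @param cov_threshold Stability cutoff, default 0.10.
#' @param seed Integer seed governing all randomness of the run; defaults
#'   to the phantom spec's seed.
#' @param fov_range_mm For the clinical design: list with `min` and `max`
#'   length-2 FOVs (mm) between which each subject's FOV is interpolated
#'   uniformly.
#' @param matrix_px Acquisition matrix for clinical-design FOVs.
#' @param out_dir Optional directory; when set, images, feature tables and
#'   reports are written there.
#' @return An object of class `run_config`.
#' @export
run_config <- function(design = c("experimental", "clinical"),
                       phantom = phantom_spec(),
                       acquisitions = default_acquisitions(),
                       n_subjects = NULL,
                       tile_size_mm = c(3, 3, 8),
                       settings = extraction_settings(),
                       threshold_lo = 0, threshold_hi = 170,
                       cov_threshold = 0.10,
                       seed = NULL,
                       fov_range_mm = list(min = c(329, 256),
                                           max = c(390, 302)),
                       matrix_px = c(224, 157),
                       out_dir = NULL) {
  design <- match.arg(design)
  n_subjects <- n_subjects %||% if (design == "experimental") 12L else 61L
  seed <- as.integer(seed %||% phantom$seed)
  if (design == "experimental" && length(acquisitions) < 2)
    stopf("experimental design requires >= 2 acquisitions")
  if (design == "clinical" && n_subjects < 2)
    stopf("clinical design needs >= 2 subjects for across-subject COVs")
  phantom$seed <- seed
  structure(
    list(design = design, phantom = phantom, acquisitions = acquisitions,
         n_subjects = as.integer(n_subjects), tile_size_mm = tile_size_mm,
         settings = settings, threshold_lo = threshold_lo,
         threshold_hi = threshold_hi, cov_threshold = cov_threshold,
         seed = seed, fov_range_mm = fov_range_mm,
         matrix_px = as.integer(matrix_px), out_dir = out_dir),
    class = "run_config"
  )
}

#' Read a run configuration from YAML
#'
#' Keys mirror the arguments of [run_config()]; `phantom`, `settings` and
#' `acquisitions` entries are passed on to their constructors. Unknown
#' keys raise an error.
#'
#' @param path YAML file path.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("design", "phantom", "acquisitions", "n_subjects",
             "tile_size_mm", "settings", "threshold_lo", "threshold_hi",
             "cov_threshold", "seed", "fov_range_mm", "matrix_px", "out_dir")
  bad <- setdiff(names(y), known)
  if (length(bad)) stopf("unknown config key(s): %s", paste(bad, collapse = ", "))
  args <- y
  if (!is.null(y$phantom)) args$phantom <- do.call(phantom_spec, y$phantom)
  if (!is.null(y$settings))
    args$settings <- do.call(extraction_settings, y$settings)
  if (!is.null(y$acquisitions))
    args$acquisitions <- lapply(y$acquisitions, function(a)
      do.call(acquisition_spec, a))
  if (!is.null(y$fov_range_mm))
    args$fov_range_mm <- lapply(y$fov_range_mm, as.numeric)
  do.call(run_config, args)
}

segment_cohort_row <- function(image, center, r_outer, lo, hi) {
  region <- circle_region(image, center, r_outer)
  threshold_segment(image, region, lo, hi)
}

#' Extract conventional and map-based features for a cohort
#'
#' For every image of the cohort: segments the myocardium (circular region
#' at the subject's true center and epicardial radius, then the intensity
#' window and largest-component cleanup), extracts the 93 features from
#' the ROI on the original image (`method = "conventional"`), and reads
#' the same 93 features as ROI means from tile-based parametric maps
#' (`method = "map"`).
#'
#' @param cohort A cohort tibble from [generate_cohort()].
#' @param settings An [extraction_settings()].
#' @param tile_size_mm Tile size for the maps, mm.
#' @param threshold_lo,threshold_hi Segmentation window.
#' @param methods Which extraction methods to run.
#' @return A feature table: one row per (subject, fov, method) with
#'   provenance columns and the 93 feature columns.
#' @export
extract_cohort_features <- function(cohort,
                                    settings = extraction_settings(),
                                    tile_size_mm = c(3, 3, 8),
                                    threshold_lo = 0, threshold_hi = 170,
                                    methods = c("conventional", "map")) {
  rows <- vector("list", nrow(cohort) * length(methods))
  k <- 0L
  for (i in seq_len(nrow(cohort))) {
    img <- cohort$image[[i]]
    mask <- segment_cohort_row(
      img, c(cohort$center_1[i], cohort$center_2[i]),
      cohort$r_outer_mm[i], threshold_lo, threshold_hi)
    base <- tibble::tibble(subject_id = cohort$subject_id[i],
                           fov_label = cohort$fov_label[i])
    if ("conventional" %in% methods) {
      fv <- extract_all(img, mask, settings)
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(base, method = "conventional",
                                    tibble::as_tibble_row(fv$values))
    }
    if ("map" %in% methods) {
      grid <- build_tile_grid(img, tile_size_mm)
      fv <- map_feature_vector(img, mask, grid, settings)
      k <- k + 1L
      rows[[k]] <- dplyr::bind_cols(base, method = "map",
                                    tibble::as_tibble_row(fv$values))
    }
  }
  dplyr::bind_rows(rows[seq_len(k)])
}

run_pipeline <- function(config) {
  t0 <- Sys.time()
  msg <- function(stage) message(sprintf("[radiomap] %s (%.1fs elapsed)",
                                         stage,
                                         as.numeric(Sys.time() - t0,
                                                    units = "secs")))
  if (config$design == "experimental") {
    acqs <- config$acquisitions
    cohort <- generate_cohort(config$phantom, acqs, config$n_subjects,
                              out_dir = if (!is.null(config$out_dir))
                                file.path(config$out_dir, "images"))
  } else {
    # one subject-specific FOV each, interpolated uniformly over the range
    t <- with_seed(mix_seed(config$seed, 9L, 9L), runif(config$n_subjects))
    lo <- config$fov_range_mm$min; hi <- config$fov_range_mm$max
    parts <- lapply(seq_len(config$n_subjects), function(s) {
      fov <- lo + t[s] * (hi - lo)
      acq <- acquisition_spec(fov, matrix_px = config$matrix_px)
      truth <- generate_subject_truth(config$phantom, s)
      img <- render_fov(truth, acq)
      tibble::tibble(subject_id = s, fov_label = acq$label,
                     spacing_1 = img$spacing_mm[1],
                     spacing_2 = img$spacing_mm[2], image = list(img),
                     center_1 = truth$center_mm[1],
                     center_2 = truth$center_mm[2],
                     r_inner_mm = truth$r_inner_mm,
                     r_outer_mm = truth$r_outer_mm, path = NA_character_)
    })
    cohort <- dplyr::bind_rows(parts)
  }
  msg(sprintf("generated %d images (%s design)", nrow(cohort),
              config$design))
  features <- extract_cohort_features(
    cohort, config$settings, config$tile_size_mm,
    config$threshold_lo, config$threshold_hi)
  msg("extracted conventional and map features")
  cov_fun <- if (config$design == "experimental")
    experimental_design_covs else clinical_design_covs
  cov_conventional <- cov_fun(features, "conventional",
                              config$cov_threshold)
  cov_map <- cov_fun(features, "map", config$cov_threshold)
  comparison <- compare_methods(cov_conventional, cov_map)
  msg("computed COV reports and method comparison")
  run <- structure(
    list(config = config, manifest = dplyr::select(cohort, -"image"),
         features = features, cov_conventional = cov_conventional,
         cov_map = cov_map, comparison = comparison),
    class = "radiomap_run"
  )
  if (!is.null(config$out_dir)) write_run_outputs(run, config$out_dir)
  run
}

#' Run the experimental reproducibility study
#'
#' End to end: renders every subject at every configured field of view,
#' segments, extracts features conventionally and via parametric maps,
#' computes per-subject COVs across fields of view for both methods, and
#' compares the methods. Fully reproducible from `(config, seed)`.
#'
#' @param config A [run_config()] with `design = "experimental"`.
#' @return A `radiomap_run`: config, cohort manifest, feature table, the
#'   two `repro_report`s and the `radiomap_comparison`.
#' @export
run_experimental <- function(config = run_config("experimental")) {
  if (config$design != "experimental")
    stopf("config has design '%s'; expected 'experimental'", config$design)
  run_pipeline(config)
}

#' Run the clinical reproducibility study
#'
#' Each subject is rendered once at a subject-specific field of view drawn
#' deterministically (seeded) from the configured range, mimicking routine
#' imaging where the FOV follows the patient's size; COVs are computed
#' across subjects per method and the methods compared.
#'
#' @param config A [run_config()] with `design = "clinical"`.
#' @return A `radiomap_run`.
#' @export
run_clinical <- function(config = run_config("clinical")) {
  if (config$design != "clinical")
    stopf("config has design '%s'; expected 'clinical'", config$design)
  run_pipeline(config)
}

#' @export
print.radiomap_run <- function(x, ...) {
  cat(sprintf("<radiomap_run> %s design: %d subjects, %d images\n",
              x$config$design, x$config$n_subjects, nrow(x$manifest)))
  print(x$comparison)
  invisible(x)
}

#' @export
glance.radiomap_run <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(design = x$config$design,
                   n_subjects = x$config$n_subjects,
                   n_images = nrow(x$manifest),
                   n_covs_per_method = nrow(x$cov_conventional)),
    glance(x$comparison)
  )
}

#' Write the artifact bundle of a run
#'
#' Writes `manifest.csv`, `features.csv`, `covs_conventional.csv`,
#' `covs_map.csv`, `comparison_by_feature.csv` and `summary.json` under
#' `dir`.
#'
#' @param run A `radiomap_run`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_run_outputs <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name)
    write.csv(df, file.path(dir, name), row.names = FALSE)
  wr(run$manifest, "manifest.csv")
  wr(run$features, "features.csv")
  wr(tidy(run$cov_conventional), "covs_conventional.csv")
  wr(tidy(run$cov_map), "covs_map.csv")
  if (!is.null(run$comparison$by_feature))
    wr(run$comparison$by_feature, "comparison_by_feature.csv")
  summary <- c(list(design = run$config$design, seed = run$config$seed,
                    n_subjects = run$config$n_subjects,
                    n_images = nrow(run$manifest)),
               as.list(run$comparison$summary))
  jsonlite::write_json(summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
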