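#' Coefficient of variation
#'
#' The study's reproducibility metric: the sample standard deviation
#' (n - 1 denominator) divided by the absolute mean, so sign-crossing
#' features still get a defined value. When the mean is numerically zero
#' relative to the data (|mean| < 1e-12 * max|x|) the COV is returned as
#' `NA` (flagged missing downstream) rather than as an arbitrarily large
#' number. Non-finite inputs are dropped; fewer than two finite values
#' after dropping also yield `NA`.
#'
#' @param x Numeric vector with at least two elements.
#' @return A non-negative scalar, or `NA`.
#' @export
#' @examples
#' cov_value(c(8, 10, 12))  # 0.2
cov_value <- function(x) {
  if (length(x) < 2) stopf("cov_value() needs at least 2 values")
  x <- x[is.finite(x)]
  if (length(x) < 2) return(NA_real_)
  m <- mean(x)
  if (abs(m) < 1e-12 * max(abs(x))) return(NA_real_)
  sd(x) / abs(m)
}

#' Classify a COV as stable
#'
#' Applies the 10% stability cutoff: `cov <= threshold` counts as stable
#' ("up to 10%" read inclusively). An undefined (`NA`) COV is classified
#' as not stable and should be tracked as missing, not as unstable.
#'
#' @param cov_value Numeric vector of COVs (may contain `NA`).
#' @param threshold Stability cutoff, default 0.10.
#' @return Logical vector (`FALSE` for `NA` input).
#' @export
classify_stable <- function(cov_value, threshold = 0.10) {
  !is.na(cov_value) & cov_value <= threshold
}

check_feature_table <- function(table) {
  need <- c("subject_id", "fov_label", "method")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stopf("feature table lacks column(s): %s", paste(miss, collapse = ", "))
  feats <- intersect(.catalog_features(), names(table))
  if (length(feats) != 93)
    stopf("feature table must carry the 93 catalog feature columns (found %d)",
          length(feats))
  if (anyDuplicated(table[c("subject_id", "fov_label", "method")]))
    stopf("feature table has duplicate (subject, fov, method) rows")
  feats
}

new_repro_report <- function(df, design, method, threshold) {
  structure(df, class = c("repro_report", class(df)),
            design = design, method = method, threshold = threshold)
}

#' Across-subject COVs (clinical design)
#'
#' One COV per feature across all subjects, for cohorts in which each
#' subject contributes a single field of view (the field of view varies
#' between, not within, subjects). Undefined feature values are dropped
#' before the COV; `n_used` records how many subjects entered each COV.
#'
#' @param table A feature table: one row per (subject, fov, method) with
#'   the 93 feature columns, as produced by [extract_cohort_features()].
#' @param method `"conventional"` or `"map"`.
#' @param threshold Stability cutoff on the COV, default 0.10.
#' @return A `repro_report` tibble with one row per feature: `feature`,
#'   `method`, `cov`, `n_used`, `stable`, `missing`.
#' @export
clinical_design_covs <- function(table, method = c("conventional", "map"),
                                 threshold = 0.10) {
  method <- match.arg(method)
  feats <- check_feature_table(table)
  tab <- dplyr::filter(table, .data$method == !!method)
  if (!nrow(tab)) stopf("no rows for method '%s'", method)
  if (anyDuplicated(tab$subject_id))
    stopf("clinical design expects one field of view per subject")
  if (nrow(tab) < 2) stopf("COVs need at least 2 subjects")
  df <- purrr::map_dfr(feats, function(f) {
    v <- tab[[f]]
    cv <- cov_value(v)
    tibble::tibble(feature = f, method = method, cov = cv,
                   n_used = sum(is.finite(v)))
  })
  df$stable <- classify_stable(df$cov, threshold)
  df$missing <- is.na(df$cov)
  new_repro_report(df, "clinical", method, threshold)
}

#' Per-subject COVs across fields of view (experimental design)
#'
#' One COV per (subject, feature) across that subject's fields of view:
#' with 12 subjects and 93 features this yields 1116 COVs per extraction
#' method. A feature's cohort-level verdict (see [stable_features()])
#' requires stability for every subject.
#'
#' @inheritParams clinical_design_covs
#' @return A `repro_report` tibble with one row per (subject, feature):
#'   `feature`, `subject_id`, `method`, `cov`, `n_used`, `stable`,
#'   `missing`.
#' @export
experimental_design_covs <- function(table,
                                     method = c("conventional", "map"),
                                     threshold = 0.10) {
  method <- match.arg(method)
  feats <- check_feature_table(table)
  tab <- dplyr::filter(table, .data$method == !!method)
  if (!nrow(tab)) stopf("no rows for method '%s'", method)
  n_fov <- table(tab$subject_id)
  if (any(n_fov < 2))
    stopf("experimental design needs >= 2 fields of view per subject")
  long <- tidyr::pivot_longer(tab[c("subject_id", "fov_label", feats)],
                              dplyr::all_of(feats),
                              names_to = "feature", values_to = "value")
  df <- long |>
    dplyr::group_by(.data$subject_id, .data$feature) |>
    dplyr::summarise(cov = cov_value(.data$value),
                     n_used = sum(is.finite(.data$value)),
                     .groups = "drop") |>
    dplyr::mutate(method = method, feature = factor(.data$feature,
                                                    levels = feats)) |>
    dplyr::arrange(.data$feature, .data$subject_id) |>
    dplyr::mutate(feature = as.character(.data$feature)) |>
    dplyr::select("feature", "subject_id", "method", "cov", "n_used")
  df$stable <- classify_stable(df$cov, threshold)
  df$missing <- is.na(df$cov)
  new_repro_report(df, "experimental", method, threshold)
}

#' Cohort-level feature verdicts from a reproducibility report
#'
#' For a clinical report the verdict is the per-feature stability flag
#' itself; for an experimental report a feature counts as reproducible only
#' when its COV is defined and within the cutoff for *every* subject.
#'
#' @param report A `repro_report`.
#' @return A tibble with `feature` and logical `stable`.
#' @export
stable_features <- function(report) {
  if (!inherits(report, "repro_report")) stopf("`report` must be a repro_report")
  if (attr(report, "design") == "clinical")
    return(tibble::tibble(feature = report$feature, stable = report$stable))
  tibble::as_tibble(report) |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(stable = all(.data$stable), .groups = "drop")
}

#' @export
tidy.repro_report <- function(x, ...) {
  tibble::as_tibble(unclass_report(x))
}

unclass_report <- function(x) {
  class(x) <- setdiff(class(x), "repro_report")
  x
}

#' @export
glance.repro_report <- function(x, ...) {
  verdict <- stable_features(x)
  tibble::tibble(
    design = attr(x, "design"), method = attr(x, "method"),
    threshold = attr(x, "threshold"),
    n_features = length(unique(x$feature)),
    n_covs = nrow(x),
    n_covs_stable = sum(x$stable),
    n_covs_missing = sum(x$missing),
    frac_covs_stable = mean(x$stable),
    n_features_stable = sum(verdict$stable)
  )
}

#' Compare conventional and map-based extraction
#'
#' Pairs the two reproducibility reports feature by feature and counts how
#' many features are stable under each method, how many improved (lower
#' COV under map extraction) and how many crossed from unstable to stable.
#' For experimental reports the per-feature COV used in the improvement
#' comparison is the mean of the subject COVs; stability verdicts use the
#' all-subjects rule. The relative increase of the stable-feature count is
#' reported as a half-up-rounded percentage. Numeric scalars may be passed
#' instead of reports to compare plain stable counts.
#'
#' @param conv,map `repro_report`s of the two methods on the same cohort
#'   and design, or two numeric stable-feature counts.
#' @return A `radiomap_comparison`: list with `by_feature` (tibble, absent
#'   for numeric input) and `summary` (one-row tibble). `tidy()` returns
#'   the per-feature table, `glance()` the summary.
#' @export
#' @examples
#' glance(compare_methods(29, 48))$relative_increase_pct  # 66
compare_methods <- function(conv, map) {
  if (is.numeric(conv) && is.numeric(map)) {
    summary <- tibble::tibble(
      n_stable_conventional = as.numeric(conv),
      n_stable_map = as.numeric(map),
      n_improved = NA_integer_, n_crossed_to_stable = NA_integer_,
      relative_increase_pct =
        round_half_up((map - conv) / conv * 100)
    )
    return(structure(list(by_feature = NULL, summary = summary,
                          design = NA_character_),
                     class = "radiomap_comparison"))
  }
  if (!inherits(conv, "repro_report") || !inherits(map, "repro_report"))
    stopf("`conv` and `map` must be repro_reports (or two numeric counts)")
  if (!identical(attr(conv, "design"), attr(map, "design")))
    stopf("reports come from different designs")
  design <- attr(conv, "design")
  per_feature_cov <- function(r) {
    tibble::as_tibble(unclass_report(r)) |>
      dplyr::group_by(.data$feature) |>
      dplyr::summarise(cov = mean(.data$cov, na.rm = TRUE),
                       .groups = "drop") |>
      dplyr::mutate(cov = ifelse(is.nan(.data$cov), NA_real_, .data$cov))
  }
  cc <- per_feature_cov(conv); cm <- per_feature_cov(map)
  sc <- stable_features(conv); sm <- stable_features(map)
  by_feature <- tibble::tibble(
    feature = cc$feature,
    cov_conventional = cc$cov,
    cov_map = cm$cov[match(cc$feature, cm$feature)],
    stable_conventional = sc$stable[match(cc$feature, sc$feature)],
    stable_map = sm$stable[match(cc$feature, sm$feature)]
  ) |>
    dplyr::mutate(
      improved = !is.na(.data$cov_conventional) & !is.na(.data$cov_map) &
        .data$cov_map < .data$cov_conventional,
      crossed_to_stable = !.data$stable_conventional & .data$stable_map
    )
  n_sc <- sum(by_feature$stable_conventional)
  n_sm <- sum(by_feature$stable_map)
  summary <- tibble::tibble(
    n_stable_conventional = n_sc, n_stable_map = n_sm,
    n_improved = sum(by_feature$improved),
    n_crossed_to_stable = sum(by_feature$crossed_to_stable),
    relative_increase_pct = if (n_sc > 0)
      round_half_up((n_sm - n_sc) / n_sc * 100) else NA_real_,
    frac_covs_stable_conventional = mean(conv$stable),
    frac_covs_stable_map = mean(map$stable)
  )
  structure(list(by_feature = by_feature, summary = summary,
                 design = design),
            class = "radiomap_comparison")
}

#' @export
print.radiomap_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<radiomap_comparison> stable features: %g (conventional) -> %g (map), +%g%%\n",
              s$n_stable_conventional, s$n_stable_map,
              s$relative_increase_pct))
  if (!is.na(s$n_improved[1]) && !is.null(x$by_feature))
    cat(sprintf("  improved COV: %d features; crossed to stable: %d\n",
                s$n_improved, s$n_crossed_to_stable))
  invisible(x)
}

#' @export
tidy.radiomap_comparison <- function(x, ...) {
  if (is.null(x$by_feature))
    stopf("comparison of plain counts has no per-feature table")
  x$by_feature
}

#' @export
glance.radiomap_comparison <- function(x, ...) x$summary
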