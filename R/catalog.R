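# The 93-feature catalog: 18 first-order, 24 GLCM, 14 GLDM, 16 GLRLM,
# 16 GLSZM and 5 NGTDM features, named `<class>_<FeatureName>` after the
# public reference definitions. Order within a class is fixed and matches
# the native feature engines.

.fo_names <- c(
  "10Percentile", "90Percentile", "Energy", "Entropy", "InterquartileRange",
  "Kurtosis", "Maximum", "Mean", "MeanAbsoluteDeviation", "Median",
  "Minimum", "Range", "RobustMeanAbsoluteDeviation", "RootMeanSquared",
  "Skewness", "TotalEnergy", "Uniformity", "Variance"
)

.glcm_names <- c(
  "Autocorrelation", "ClusterProminence", "ClusterShade", "ClusterTendency",
  "Contrast", "Correlation", "DifferenceAverage", "DifferenceEntropy",
  "DifferenceVariance", "Id", "Idm", "Idmn", "Idn", "Imc1", "Imc2",
  "InverseVariance", "JointAverage", "JointEnergy", "JointEntropy", "MCC",
  "MaximumProbability", "SumAverage", "SumEntropy", "SumSquares"
)

.gldm_names <- c(
  "DependenceEntropy", "DependenceNonUniformity",
  "DependenceNonUniformityNormalized", "DependenceVariance",
  "GrayLevelNonUniformity", "GrayLevelVariance", "HighGrayLevelEmphasis",
  "LargeDependenceEmphasis", "LargeDependenceHighGrayLevelEmphasis",
  "LargeDependenceLowGrayLevelEmphasis", "LowGrayLevelEmphasis",
  "SmallDependenceEmphasis", "SmallDependenceHighGrayLevelEmphasis",
  "SmallDependenceLowGrayLevelEmphasis"
)

.glrlm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelRunEmphasis", "LongRunEmphasis",
  "LongRunHighGrayLevelEmphasis", "LongRunLowGrayLevelEmphasis",
  "LowGrayLevelRunEmphasis", "RunEntropy", "RunLengthNonUniformity",
  "RunLengthNonUniformityNormalized", "RunPercentage", "RunVariance",
  "ShortRunEmphasis", "ShortRunHighGrayLevelEmphasis",
  "ShortRunLowGrayLevelEmphasis"
)

# order matches the shared (level, size) engine: entropy/percentage/variance
# slots carry the zone-based names
.glszm_names <- c(
  "GrayLevelNonUniformity", "GrayLevelNonUniformityNormalized",
  "GrayLevelVariance", "HighGrayLevelZoneEmphasis", "LargeAreaEmphasis",
  "LargeAreaHighGrayLevelEmphasis", "LargeAreaLowGrayLevelEmphasis",
  "LowGrayLevelZoneEmphasis", "ZoneEntropy", "SizeZoneNonUniformity",
  "SizeZoneNonUniformityNormalized", "ZonePercentage", "ZoneVariance",
  "SmallAreaEmphasis", "SmallAreaHighGrayLevelEmphasis",
  "SmallAreaLowGrayLevelEmphasis"
)

.ngtdm_names <- c("Busyness", "Coarseness", "Complexity", "Contrast",
                  "Strength")

.class_names <- list(
  firstorder = .fo_names, glcm = .glcm_names, gldm = .gldm_names,
  glrlm = .glrlm_names, glszm = .glszm_names, ngtdm = .ngtdm_names
)

#' Radiomic feature catalog
#'
#' The fixed catalog of the 93 features computed by [extract_all()]:
#' 18 first-order intensity statistics plus 75 texture features from the
#' gray level co-occurrence (GLCM, 24), dependence (GLDM, 14), run-length
#' (GLRLM, 16) and size-zone (GLSZM, 16) matrices and the neighboring gray
#' tone difference matrix (NGTDM, 5). Shape descriptors are deliberately
#' absent: the analysis varies the field of view, not the ROI outline.
#'
#' @return A tibble with columns `feature` (qualified name,
#'   e.g. `"glcm_Contrast"`), `class` and `name`.
#' @export
#' @examples
#' feature_catalog()
feature_catalog <- function() {
  tibble::tibble(
    class = rep(names(.class_names), lengths(.class_names)),
    name = unlist(.class_names, use.names = FALSE)
  ) |>
    dplyr::mutate(feature = paste(.data$class, .data$name, sep = "_"),
                  .before = 1)
}

.catalog_features <- function() {
  unlist(lapply(names(.class_names), function(cl) {
    paste(cl, .class_names[[cl]], sep = "_")
  }), use.names = FALSE)
}
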