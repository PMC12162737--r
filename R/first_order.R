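#' First-order intensity statistics
#'
#' The 18 histogram and moment statistics of the masked intensities. Entropy
#' and uniformity are computed on the fixed-bin-width discretized histogram;
#' total energy scales energy by the per-voxel volume (pixel area times
#' slice thickness); variance is the population variance and kurtosis is
#' uncorrected (a normal distribution scores 3). Skewness and kurtosis are
#' flagged undefined when the variance is zero.
#'
#' @inheritParams discretize
#' @return A named numeric vector of length 18 with a logical `valid`
#'   attribute.
#' @export
#' @examples
#' img <- image_slice(matrix(c(1, 2, 3, 4), 2), spacing_mm = c(1, 1))
#' mask <- circle_region(img, c(0, 0), 100)
#' fo <- first_order(img, mask)
#' fo[["firstorder_Mean"]]
first_order <- function(image, mask, settings = extraction_settings()) {
  reg <- discretize(image, mask, settings)
  fo <- first_order_values(reg$values, tabulate(reg$levels[!is.na(reg$levels)],
                                                reg$ng),
                           reg$pixel_area_mm2 * reg$slice_thickness_mm)
  names(fo$values) <- paste0("firstorder_", .fo_names)
  structure(fo$values, valid = stats::setNames(fo$valid, names(fo$values)))
}

# core on a bare vector; `hist_counts` is the discretized histogram and
# `voxel_volume` the mm^3 per pixel. Returns values in .fo_names order.
first_order_values <- function(v, hist_counts, voxel_volume) {
  n <- length(v)
  srt <- sort(v)
  qt <- function(p) {  # linear-interpolation quantile on the sorted vector
    h <- (n - 1) * p
    lo <- floor(h)
    srt[lo + 1] + (h - lo) * (srt[min(lo + 2, n)] - srt[lo + 1])
  }
  p10 <- qt(0.10); p25 <- qt(0.25); p50 <- qt(0.50)
  p75 <- qt(0.75); p90 <- qt(0.90)
  mu <- sum(v) / n
  cen <- v - mu
  m2 <- sum(cen^2) / n
  m3 <- sum(cen^3) / n
  m4 <- sum(cen^4) / n
  energy <- sum(v^2)
  w <- v[v >= p10 & v <= p90]
  pr <- hist_counts / n
  prp <- pr[pr > 0]
  vals <- c(
    p10, p90, energy,
    -sum(prp * log2(prp)),                      # Entropy
    p75 - p25,                                  # InterquartileRange
    if (m2 > 0) m4 / m2^2 else NA_real_,        # Kurtosis
    srt[n], mu,
    sum(abs(cen)) / n,                          # MeanAbsoluteDeviation
    p50, srt[1], srt[n] - srt[1],
    mean(abs(w - mean(w))),                     # RobustMeanAbsoluteDeviation
    sqrt(energy / n),                           # RootMeanSquared
    if (m2 > 0) m3 / m2^1.5 else NA_real_,      # Skewness
    energy * voxel_volume,                      # TotalEnergy
    sum(pr^2),                                  # Uniformity
    m2                                          # Variance
  )
  list(values = vals, valid = !is.na(vals))
}
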