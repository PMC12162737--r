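# ggplot2 display methods

raster_df <- function(values, spacing, origin) {
  d <- dim(values)
  tibble::tibble(
    x1 = rep(origin[1] + (seq_len(d[1]) - 1) * spacing[1], d[2]),
    x2 = rep(origin[2] + (seq_len(d[2]) - 1) * spacing[2], each = d[1]),
    value = as.vector(values)
  )
}

#' @export
autoplot.image_slice <- function(object, ...) {
  df <- raster_df(object$pixels, object$spacing_mm, object$origin_mm)
  ggplot2::ggplot(df, ggplot2::aes(.data$x2, .data$x1,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = "intensity") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.parametric_map <- function(object, ...) {
  vals <- object$values
  vals[!object$valid] <- NA
  df <- raster_df(vals, object$spacing_mm, object$origin_mm)
  ggplot2::ggplot(df, ggplot2::aes(.data$x2, .data$x1,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 name = object$feature_name,
                                 na.value = "grey40") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "mm", y = "mm", title = object$feature_name) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.repro_report <- function(object, ...) {
  df <- tidy(object)
  df$feature <- factor(df$feature, levels = unique(df$feature))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$cov))
  if ("subject_id" %in% names(df)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(group = .data$subject_id),
                                alpha = 0.4)
  } else {
    p <- p + ggplot2::geom_point()
  }
  p +
    ggplot2::geom_hline(yintercept = attr(object, "threshold"),
                        linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "COV",
                  title = sprintf("%s extraction (%s design)",
                                  attr(object, "method"),
                                  attr(object, "design"))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       size = 5))
}

#' Paired COV plot for the two extraction methods
#'
#' Per-feature COVs of conventional and map-based extraction side by side
#' with the stability cutoff, the standard display for judging which
#' features gain reproducibility from the parametric maps.
#'
#' @param object A `radiomap_comparison` from [compare_methods()].
#' @param threshold Cutoff line, default 0.10.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radiomap_comparison <- function(object, threshold = 0.10, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("cov_conventional", "cov_map"),
                        names_to = "method", names_prefix = "cov_",
                        values_to = "cov")
  df$feature <- factor(df$feature, levels = unique(df$feature))
  ggplot2::ggplot(df, ggplot2::aes(.data$feature, .data$cov,
                                   color = .data$method,
                                   group = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = threshold, linetype = "dotted") +
    ggplot2::labs(x = NULL, y = "COV") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       hjust = 1,
                                                       size = 5))
}
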