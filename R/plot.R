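# ggplot2 views of the package's result types.

mask_to_df <- function(mask, value_name = "value") {
  df <- data.frame(row = rep(seq_len(nrow(mask)), times = ncol(mask)),
                   col = rep(seq_len(ncol(mask)), each = nrow(mask)),
                   value = as.vector(mask))
  names(df)[3] <- value_name
  df
}

#' Plot a synthetic scene and its ground truth
#'
#' @param object An `ear_scene`.
#' @param ... Unused.
#' @return A ggplot showing the RGB image with ground-truth ear outlines.
#' @export
autoplot.ear_scene <- function(object, ...) {
  img <- object$image
  df <- mask_to_df(object$mask, "ear")
  df$fill <- grDevices::rgb(as.vector(img[, , 1]), as.vector(img[, , 2]),
                            as.vector(img[, , 3]), maxColorValue = 255)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_point(data = object$centroids,
                        ggplot2::aes(x = .data$col, y = .data$row),
                        colour = "red", shape = 3, size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("synthetic scene: %d ears (%s light)",
                                  object$count, object$config$illumination),
                  x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot a segmentation result mask
#'
#' @param object A `segmentation_result`.
#' @param ... Unused.
#' @return A ggplot of the binary mask with region centroids marked.
#' @export
autoplot.segmentation_result <- function(object, ...) {
  df <- mask_to_df(object$mask, "ear")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$ear))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "grey15", `1` = "wheat"),
                               name = NULL,
                               labels = c("background", "ear")) +
    ggplot2::geom_point(data = object$regions,
                        ggplot2::aes(x = .data$centroid_col,
                                     y = .data$centroid_row),
                        inherit.aes = FALSE, colour = "red", shape = 1) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%d ear region(s)", object$count),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Scatter + fit line for a count regression
#'
#' @param object A [count_regression()] result.
#' @param ... Unused.
#' @return A ggplot of predicted vs. true counts with the OLS line and the
#'   identity line.
#' @export
autoplot.count_regression <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$true, y = .data$pred)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50") +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "manual (true) count", y = "algorithm count",
                  title = sprintf("slope %.2f, R² = %.3f, SD = %.2f",
                                  object$slope, object$r_squared,
                                  object$sd_residuals)) +
    ggplot2::theme_minimal()
}

#' Bar chart of batch evaluation indicators
#'
#' @param object An [evaluate_batch()] report.
#' @param ... Unused.
#' @return A ggplot of per-indicator means with standard-deviation bars.
#' @export
autoplot.ear_eval_report <- function(object, ...) {
  s <- object$summary
  metrics <- setdiff(names(s), "statistic")
  df <- data.frame(metric = factor(metrics, levels = metrics),
                   mean = as.numeric(s[s$statistic == "mean", metrics]),
                   sd = as.numeric(s[s$statistic == "sd", metrics]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$mean)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           width = 0.25) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "indicator value") +
    ggplot2::theme_minimal()
}
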