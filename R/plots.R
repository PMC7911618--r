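#' Plot a raster layer
#'
#' @param object A [raster_layer()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raster_layer <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$longitude, .data$latitude,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$name) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "Longitude", y = "Latitude",
                  title = object$name,
                  subtitle = if (nzchar(object$units)) object$units) +
    ggplot2::theme_minimal()
}

#' Plot a response curve
#'
#' @param object A [response_curve()] tibble.
#' @param threshold Optional horizontal reference (e.g. the highly
#'   suitable cut 0.6).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_curve <- function(object, threshold = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(.data$value,
                                            .data$suitability)) +
    ggplot2::geom_line(linewidth = 0.8, colour = "#2c7fb8") +
    ggplot2::labs(x = object$variable[1], y = "Predicted suitability") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = 2)
  }
  p
}

#' Bar chart of a variable-screening q table
#'
#' @param q_table Output of [screen_variables()].
#' @param q_threshold Retention threshold drawn as a reference line.
#' @return A ggplot.
#' @export
plot_q_table <- function(q_table, q_threshold = 0.1) {
  ggplot2::ggplot(q_table,
                  ggplot2::aes(stats::reorder(.data$variable, .data$q),
                               .data$q, fill = .data$retained)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = q_threshold, linetype = 2) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Geodetector q") +
    ggplot2::theme_minimal()
}

#' ROC curve for presence/background scores
#'
#' @param presence_scores,background_scores Score vectors.
#' @return A ggplot with the AUC in the subtitle.
#' @export
plot_roc <- function(presence_scores, background_scores) {
  thr <- sort(unique(c(presence_scores, background_scores, -Inf, Inf)),
              decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(presence_scores >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(background_scores >= t), numeric(1))
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = 3) +
    ggplot2::labs(x = "False positive rate (1 - specificity)",
                  y = "True positive rate",
                  subtitle = sprintf("AUC = %.3f",
                                     roc_auc(presence_scores,
                                             background_scores))) +
    ggplot2::theme_minimal()
}
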