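#' Plot the embedding with the clinical decision boundary
#'
#' Scatter of the 2-D embedding colored by clinical status, with the
#' p = threshold boundary line overlaid. Requires ggplot2.
#'
#' @param embedding An `hdss_embedding`.
#' @param boundary An `hdss_boundary`.
#' @param clinical Logical vector per embedded point.
#' @return A ggplot object.
#' @export
plot_boundary <- function(embedding, boundary, clinical) {
  need_ggplot()
  df <- data.frame(dim1 = embedding$points[, 1L],
                   dim2 = embedding$points[, 2L],
                   status = ifelse(clinical, "clinical", "non-clinical"))
  b <- boundary
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dim1, .data$dim2,
                                        colour = .data$status)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_colour_manual(values = c(clinical = "#1b9e77",
                                            `non-clinical` = "grey55")) +
    ggplot2::labs(x = "dimension 1", y = "dimension 2", colour = NULL) +
    ggplot2::theme_minimal()
  if (abs(b$coefficients[2L]) > 1e-12) {
    logit_thr <- stats::qlogis(b$threshold)
    p <- p + ggplot2::geom_abline(
      intercept = (logit_thr - b$intercept) / b$coefficients[2L],
      slope = -b$coefficients[1L] / b$coefficients[2L])
  }
  p
}

#' Rose diagram of centroid distances for a disorder sample
#'
#' One bar per sampled person; stacked segments are centroid distances at
#' successive timepoints, filled by diagnosis count.
#'
#' @param rose Data frame from [rose_data()].
#' @return A ggplot object.
#' @export
plot_rose <- function(rose) {
  need_ggplot()
  rose$person_id <- factor(rose$person_id)
  ggplot2::ggplot(rose,
                  ggplot2::aes(x = .data$person_id, y = .data$segment_length,
                               fill = .data$diagnosis_count,
                               group = .data$timepoint)) +
    ggplot2::geom_col(position = "stack", width = 0.9, colour = "white",
                      linewidth = 0.1) +
    ggplot2::coord_polar() +
    ggplot2::scale_fill_gradient(low = "#fee8c8", high = "#b30000") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank()) +
    ggplot2::labs(x = NULL, y = "distance from average person",
                  fill = "diagnoses")
}

#' Heatmap of within/between category distances
#'
#' @param summary An `hdss_category_distance`.
#' @return A ggplot object.
#' @export
plot_category_heatmap <- function(summary) {
  need_ggplot()
  m <- summary$means
  df <- data.frame(from = rep(rownames(m), times = ncol(m)),
                   to = rep(colnames(m), each = nrow(m)),
                   distance = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$from, .data$to,
                                   fill = .data$distance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "mean distance")
}

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
}
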