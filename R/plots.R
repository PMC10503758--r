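#' Plot a coherence profile
#'
#' Mean UMass coherence against the number of topics, with the plateau
#' cutoff and the chosen K marked.
#'
#' @param object A `coherence_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.coherence_profile <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$K, y = .data$coherence)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2.5) +
    ggplot2::geom_hline(yintercept = object$cutoff, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "Number of topics", y = "Mean UMass coherence",
                  title = paste0("Coherence plateau (chosen K = ",
                                 object$chosen_k, ")")) +
    ggplot2::theme_minimal()
}

#' Plot cluster-selection metrics
#'
#' @param object A `k_selection`.
#' @param ... Unused.
#' @return A ggplot of mean silhouette and Dunn index against k.
#' @exportS3Method ggplot2::autoplot
autoplot.k_selection <- function(object, ...) {
  df <- tidyr::pivot_longer(tidy(object), c("silhouette", "dunn"),
                            names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$chosen), size = 2) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey30"),
                                 guide = "none") +
    ggplot2::labs(x = "Number of clusters", y = NULL,
                  title = paste0("Cluster-count selection (chosen k = ",
                                 object$chosen_k, ")")) +
    ggplot2::theme_minimal()
}

#' Plot per-cluster Kaplan-Meier curves
#'
#' @param object A `cluster_outcomes`.
#' @param ... Unused.
#' @return A ggplot of the per-cluster survival step curves.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_outcomes <- function(object, ...) {
  df <- dplyr::mutate(object$km_curves, cluster = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$cluster)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Days since discharge", y = "Survival",
                  colour = "Cluster",
                  title = "Kaplan-Meier survival by phenotype cluster") +
    ggplot2::theme_minimal()
}

#' Relative-risk heatmap across clusters
#'
#' The profile view of cluster phenotypes: per-cluster relative risk of each
#' variable versus the remaining population, drawn as a red (enriched) /
#' teal (depleted) tile map.
#'
#' @param rr_table Tibble with columns `cluster`, `variable`, `rr`.
#' @param max_rr Cap for the colour scale; default 3.
#' @return A ggplot.
#' @export
plot_rr_heatmap <- function(rr_table, max_rr = 3) {
  df <- dplyr::mutate(rr_table,
                      rr_capped = pmin(.data$rr, max_rr),
                      cluster = factor(.data$cluster))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cluster, y = .data$variable,
                                   fill = .data$rr_capped)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#008080",
                                  mid = "white", high = "firebrick",
                                  name = "RR") +
    ggplot2::labs(x = "Cluster", y = NULL,
                  title = "Relative risk of structured variables by cluster") +
    ggplot2::theme_minimal()
}

#' Ranked top-word profile of each topic
#'
#' Text summary replacing word-cloud images: the top `m` words of each topic
#' with probabilities proportional to bar length.
#'
#' @param model An `lda_fit`.
#' @param m Words per topic; default 10.
#' @return A ggplot of faceted word-probability bars.
#' @export
plot_top_words <- function(model, m = 10) {
  df <- purrr::map_dfr(seq_len(model$K), function(k) {
    dplyr::mutate(top_words(model, k, m = m), topic = k,
                  rank = dplyr::row_number())
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$probability,
                                   y = stats::reorder(paste(.data$topic, .data$word),
                                                      .data$probability))) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(~topic, scales = "free_y") +
    ggplot2::scale_y_discrete(labels = function(z) sub("^\\S+ ", "", z)) +
    ggplot2::labs(x = "P(word | topic)", y = NULL,
                  title = "Top words per topic") +
    ggplot2::theme_minimal()
}
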