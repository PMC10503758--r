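#' Tidy an LDA fit
#'
#' @param x An `lda_fit`.
#' @param matrix `"beta"` for topic-word probabilities (one row per topic x
#'   word) or `"gamma"` for document-topic proportions (one row per document
#'   x topic), following the broom convention for topic models.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::tidy
tidy.lda_fit <- function(x, matrix = c("beta", "gamma"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "beta") {
    tibble(topic = rep(seq_len(x$K), times = length(x$vocabulary)),
           term = rep(x$vocabulary, each = x$K),
           beta = as.vector(x$phi))
  } else {
    tibble(document = rep(x$encounter_ids, times = x$K),
           topic = rep(seq_len(x$K), each = length(x$encounter_ids)),
           gamma = as.vector(x$theta))
  }
}

#' @rdname tidy.lda_fit
#' @exportS3Method generics::glance
glance.lda_fit <- function(x, ...) {
  tibble(k = x$K, alpha = x$alpha, beta = x$beta,
         n_documents = length(x$encounter_ids),
         n_terms = length(x$vocabulary),
         n_tokens = sum(x$n_k), iterations = x$n_iter, seed = x$seed)
}

#' Tidy a cluster assignment
#'
#' @param x A `cluster_assignment`.
#' @param ... Unused.
#' @return One row per encounter: `encounter_id`, `cluster`, `silhouette`.
#' @exportS3Method generics::tidy
tidy.cluster_assignment <- function(x, ...) {
  dplyr::mutate(x$assignments, silhouette = x$per_point_silhouette)
}

#' @rdname tidy.cluster_assignment
#' @exportS3Method generics::glance
glance.cluster_assignment <- function(x, ...) {
  tibble(k = x$k, inertia = x$inertia, silhouette = x$silhouette,
         dunn = x$dunn, n = nrow(x$assignments), n_init = x$n_init,
         seed = x$seed)
}

#' Tidy a coherence profile
#'
#' @param x A `coherence_profile`.
#' @param ... Unused.
#' @return The per-K coherence tibble with a `chosen` flag.
#' @exportS3Method generics::tidy
tidy.coherence_profile <- function(x, ...) {
  dplyr::mutate(x$profile, chosen = .data$K == x$chosen_k)
}

#' Tidy a k-selection result
#'
#' @param x A `k_selection`.
#' @param ... Unused.
#' @return The per-k metrics tibble with a `chosen` flag.
#' @exportS3Method generics::tidy
tidy.k_selection <- function(x, ...) {
  dplyr::mutate(x$metrics, chosen = .data$k == x$chosen_k)
}

#' Tidy cluster outcome profiles
#'
#' @param x A `cluster_outcomes`.
#' @param ... Unused.
#' @return Long tibble: `cluster`, `variable`, `value` for every rate and
#'   index in the per-cluster summary.
#' @exportS3Method generics::tidy
tidy.cluster_outcomes <- function(x, ...) {
  tidyr::pivot_longer(x$summary, -c("cluster", "n"),
                      names_to = "variable", values_to = "value")
}

#' @rdname tidy.cluster_outcomes
#' @exportS3Method generics::glance
glance.cluster_outcomes <- function(x, ...) {
  tibble(n_clusters = nrow(x$summary), n = sum(x$summary$n),
         horizon = x$horizon,
         min_survival = min(x$summary$survival_1yr),
         max_survival = max(x$summary$survival_1yr))
}
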