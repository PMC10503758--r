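#' UMass topic coherence
#'
#' Intrinsic coherence of each topic from document co-occurrence of its top
#' words: for the `top_m` highest-probability words of a topic, ranked w_1,
#' w_2, ..., the score is the sum over ordered pairs i < j of
#' log((D(w_i, w_j) + 1) / D(w_j)), where D(w) counts documents containing w
#' and D(w_i, w_j) counts documents containing both. Values are negative;
#' closer to zero means the topic's words genuinely co-occur.
#'
#' @param model An `lda_fit`.
#' @param corpus The corpus the model was fitted on.
#' @param top_m Number of top words per topic (clamped to the vocabulary size
#'   with a warning).
#' @return A list with `per_topic` (numeric vector, one score per topic) and
#'   `mean` (their mean).
#' @export
topic_coherence <- function(model, corpus, top_m = 10) {
  stopifnot(inherits(model, "lda_fit"))
  counts <- if (inherits(corpus, "tf_corpus")) corpus$counts else corpus
  V <- length(model$vocabulary)
  if (top_m > V) {
    warning("top_m exceeds vocabulary size; clamped to ", V)
    top_m <- V
  }
  # document presence sets per word
  pres <- counts %>%
    dplyr::filter(.data$token %in% model$vocabulary) %>%
    dplyr::distinct(.data$encounter_id, .data$token)
  doc_sets <- split(pres$encounter_id, pres$token)

  per_topic <- vapply(seq_len(model$K), function(k) {
    words <- top_words(model, k, m = top_m)$word
    score <- 0
    if (length(words) < 2) return(score)
    for (j in 2:length(words)) {
      dj <- doc_sets[[words[j]]]
      Dj <- length(dj)
      if (Dj == 0) next # smoothed-only word never observed in the corpus
      for (i in seq_len(j - 1)) {
        Dij <- length(intersect(doc_sets[[words[i]]], dj))
        score <- score + log((Dij + 1) / Dj)
      }
    }
    score
  }, numeric(1))
  list(per_topic = per_topic, mean = mean(per_topic))
}

#' Choose the number of topics by the coherence plateau
#'
#' Fits an LDA model for every K in `k_grid` (optionally under several
#' seeds, averaging the mean coherence across them) and operationalizes the
#' coherence-plateau rule: the chosen K is the smallest grid value whose
#' mean coherence is within `plateau_epsilon` times the coherence range of
#' the grid maximum.
#'
#' @param corpus A `tf_corpus` or count tibble.
#' @param k_grid Ascending integer vector of candidate topic counts.
#' @param plateau_epsilon Plateau tolerance as a fraction of the coherence
#'   range over the grid; default 0.05.
#' @param seeds Integer vector of seeds; each K is fitted once per seed with
#'   an identical iteration policy.
#' @param n_iter,burn_in Gibbs sweeps per fit (model ranking needs fewer
#'   sweeps than a final fit).
#' @param beta Topic-word concentration passed to [fit_lda()]; alpha follows
#'   the 5 / K default.
#' @param top_m Top words per topic for the coherence computation.
#' @return An object of class `coherence_profile`: tibble `profile` (`K`,
#'   `coherence`, and per-seed columns), `chosen_k`, `per_topic` (list of
#'   per-topic scores), and the rule parameters.
#' @export
select_topic_count <- function(corpus, k_grid, plateau_epsilon = 0.05,
                               seeds = 1L, n_iter = 500, burn_in = 100,
                               beta = 0.01, top_m = 10) {
  if (length(k_grid) == 0) stop("k_grid is empty", call. = FALSE)
  k_grid <- sort(unique(as.integer(k_grid)))
  if (length(k_grid) == 1) {
    warning("k_grid has a single value; choosing K = ", k_grid)
  }
  coh <- matrix(NA_real_, length(k_grid), length(seeds))
  per_topic <- vector("list", length(k_grid))
  for (i in seq_along(k_grid)) {
    K <- k_grid[i]
    scores <- vector("list", length(seeds))
    for (s in seq_along(seeds)) {
      fit <- fit_lda(corpus, K = K, beta = beta, n_iter = n_iter,
                     burn_in = burn_in, seed = seeds[s])
      ch <- topic_coherence(fit, corpus, top_m = top_m)
      coh[i, s] <- ch$mean
      scores[[s]] <- ch$per_topic
    }
    per_topic[[i]] <- scores
  }
  mean_coh <- rowMeans(coh)
  chosen <- plateau_choice(k_grid, mean_coh, plateau_epsilon)
  cutoff <- max(mean_coh) - plateau_epsilon * (max(mean_coh) - min(mean_coh))
  profile <- tibble(K = k_grid, coherence = mean_coh)
  if (length(seeds) > 1) {
    for (s in seq_along(seeds)) profile[[paste0("seed_", seeds[s])]] <- coh[, s]
  }
  structure(list(profile = profile, chosen_k = chosen,
                 per_topic = setNames(per_topic, paste0("K", k_grid)),
                 plateau_epsilon = plateau_epsilon, cutoff = cutoff,
                 seeds = seeds, n_iter = n_iter, top_m = top_m),
            class = "coherence_profile")
}

#' The coherence-plateau decision rule
#'
#' Given mean coherence per candidate K, returns the smallest K whose
#' coherence is at least the grid maximum minus `epsilon` times the
#' coherence range. With a flat profile (range 0) the smallest K wins.
#'
#' @param k_grid Candidate topic counts (ascending).
#' @param coherence Mean coherence per grid value.
#' @param epsilon Plateau tolerance as a fraction of the range.
#' @return The chosen K.
#' @export
plateau_choice <- function(k_grid, coherence, epsilon = 0.05) {
  stopifnot(length(k_grid) == length(coherence), length(k_grid) >= 1)
  rng <- max(coherence) - min(coherence)
  cutoff <- max(coherence) - epsilon * rng
  k_grid[which(coherence >= cutoff)[1]]
}

#' @export
print.coherence_profile <- function(x, ...) {
  cat("<coherence_profile> chosen K =", x$chosen_k, "\n")
  print(x$profile)
  invisible(x)
}
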