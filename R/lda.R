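# convert a tf_corpus (or bare count tibble) into token streams for the
# collapsed Gibbs sampler; ordering is fixed (roster order, then token) so a
# given seed always sees the identical stream
corpus_streams <- function(corpus) {
  if (inherits(corpus, "tf_corpus")) {
    counts <- corpus$counts
    roster <- corpus$encounter_ids
    vocab <- corpus$vocabulary
  } else {
    stopifnot(all(c("encounter_id", "token", "count") %in% names(corpus)))
    counts <- corpus
    roster <- unique(corpus$encounter_id)
    vocab <- sort(unique(corpus$token))
  }
  counts <- dplyr::arrange(counts, match(.data$encounter_id, roster), .data$token)
  doc <- rep(match(counts$encounter_id, roster), counts$count) - 1L
  word <- rep(match(counts$token, vocab), counts$count) - 1L
  list(doc = doc, word = word, roster = roster, vocab = vocab)
}

#' Fit latent Dirichlet allocation by collapsed Gibbs sampling
#'
#' Token-level topic assignments are resampled for `n_iter` full sweeps from
#' the collapsed conditional p(z = k) proportional to
#' (n_dk + alpha) (n_kw + beta) / (n_k + V beta), with the current token
#' excluded from all counts. Topic-word (`phi`) and document-topic (`theta`)
#' distributions are the posterior means of the final assignment state;
#' `average = TRUE` instead averages those posterior means over all
#' post-burn-in sweeps. A fixed seed yields a bit-identical model.
#'
#' @param corpus A `tf_corpus` from [build_corpus()], or a tibble with
#'   columns `encounter_id`, `token`, `count`.
#' @param K Number of topics (>= 1).
#' @param alpha Symmetric document-topic concentration; default 5 / K
#'   (Mallet's default total document-topic mass of 5 shared over topics).
#' @param beta Symmetric topic-word concentration; default 0.01.
#' @param n_iter Gibbs sweeps; default 1000.
#' @param burn_in Sweeps discarded when `average = TRUE`; default 200.
#' @param average Average posterior means over post-burn-in sweeps instead of
#'   using the final state.
#' @param seed Integer seed.
#' @return An object of class `lda_fit`: matrices `phi` (K x V) and `theta`
#'   (D x K), count matrices `n_dk`, `n_kw`, vector `n_k`, the vocabulary,
#'   document roster and fitting parameters. Documents with no tokens get a
#'   uniform theta row.
#' @export
fit_lda <- function(corpus, K, alpha = 5 / K, beta = 0.01,
                    n_iter = 1000, burn_in = 200, average = FALSE,
                    seed = 1L) {
  stopifnot(K >= 1, alpha > 0, beta > 0, n_iter >= 1)
  st <- corpus_streams(corpus)
  if (length(st$doc) == 0) stop("corpus has no tokens", call. = FALSE)
  V <- length(st$vocab)
  D <- length(st$roster)
  if (K > V) warning("K exceeds the number of distinct tokens (", V, ")")
  set.seed(seed)
  res <- lda_gibbs_cpp(st$doc, st$word, D, V, as.integer(K),
                       alpha, beta, as.integer(n_iter), as.integer(burn_in),
                       isTRUE(average))
  phi <- res$phi
  theta <- res$theta
  colnames(phi) <- st$vocab
  rownames(theta) <- st$roster
  structure(list(K = as.integer(K), alpha = alpha, beta = beta,
                 phi = phi, theta = theta,
                 n_dk = res$n_dk, n_kw = res$n_kw, n_k = as.integer(res$n_k),
                 vocabulary = st$vocab, encounter_ids = st$roster,
                 n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 average = isTRUE(average), seed = as.integer(seed)),
            class = "lda_fit")
}

#' @export
print.lda_fit <- function(x, ...) {
  cat("<lda_fit> K =", x$K, "topics,", length(x$encounter_ids), "documents,",
      length(x$vocabulary), "vocabulary;", x$n_iter, "Gibbs sweeps (seed",
      paste0(x$seed, ")"), "\n")
  invisible(x)
}

#' Top words of a topic
#'
#' @param model An `lda_fit`.
#' @param topic Topic index (1-based).
#' @param m Maximum number of words; default 30.
#' @return Tibble `word`, `probability`, sorted by probability descending
#'   with ties broken lexicographically.
#' @export
top_words <- function(model, topic, m = 30) {
  stopifnot(inherits(model, "lda_fit"))
  if (m <= 0) stop("m must be positive", call. = FALSE)
  if (topic < 1 || topic > model$K) {
    stop("topic must be in 1..", model$K, call. = FALSE)
  }
  p <- model$phi[topic, ]
  ord <- order(-p, names(p))
  take <- head(ord, m)
  tibble(word = names(p)[take], probability = unname(p[take]))
}

#' Embed encounters on the topic simplex
#'
#' The embedding of an encounter is its posterior-mean topic-proportion
#' vector: dimension i is the share of topic i within the encounter's notes
#' relative to all other topics, so every embedding sums to one. Documents
#' with no tokens fall back to the uniform vector 1/K.
#'
#' @param model An `lda_fit`.
#' @param corpus The corpus the model was fitted on (used to verify document
#'   identity), or NULL to trust the model's roster.
#' @return Tibble with `encounter_id` and columns `topic_1` ... `topic_K`.
#' @export
embed_encounters <- function(model, corpus = NULL) {
  stopifnot(inherits(model, "lda_fit"))
  if (!is.null(corpus)) {
    roster <- if (inherits(corpus, "tf_corpus")) corpus$encounter_ids else
      unique(corpus$encounter_id)
    if (!setequal(roster, model$encounter_ids)) {
      stop("corpus encounters do not match the fitted model", call. = FALSE)
    }
  }
  emb <- as_tibble(model$theta, .name_repair = ~ paste0("topic_", seq_len(model$K)))
  dplyr::bind_cols(tibble(encounter_id = model$encounter_ids), emb)
}

#' @describeIn embed_encounters Matrix of embeddings (encounters x topics).
#' @export
embedding_matrix <- function(model) {
  stopifnot(inherits(model, "lda_fit"))
  model$theta
}
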