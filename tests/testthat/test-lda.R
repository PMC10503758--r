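small_corpus <- function(seed = 5) {
  simulate_corpus(n_docs = 120, n_topics = 3, vocab_size = 60,
                  doc_length = 50, seed = seed)
}

test_that("K = 1 forces unit theta and the smoothed corpus word distribution", {
  sc <- small_corpus()
  fit <- fit_lda(sc$corpus, K = 1, n_iter = 5, seed = 1)
  expect_true(all(fit$theta == 1))
  counts <- dplyr::count(sc$corpus, token, wt = count)
  counts <- counts[match(fit$vocabulary, counts$token), ]
  expected <- (counts$n + fit$beta) / (sum(counts$n) + length(fit$vocabulary) * fit$beta)
  expect_equal(unname(fit$phi[1, ]), expected, tolerance = 1e-12)
})

test_that("phi and theta are the posterior means of the final counts", {
  sc <- small_corpus()
  fit <- fit_lda(sc$corpus, K = 3, alpha = 0.1, beta = 0.05, n_iter = 30, seed = 2)
  V <- length(fit$vocabulary)
  expect_equal(unname(fit$phi),
               unname((fit$n_kw + 0.05) / (fit$n_k + V * 0.05)),
               tolerance = 1e-12)
  doc_len <- rowSums(fit$n_dk)
  expect_equal(unname(fit$theta),
               unname((fit$n_dk + 0.1) / (doc_len + 3 * 0.1)),
               tolerance = 1e-12)
  # worked example of the estimator: 10 tokens on one topic, K = 2, alpha = 0.1
  expect_equal((10 + 0.1) / (10 + 0.2), 0.990196, tolerance = 1e-6)
})

test_that("sampler counts stay consistent with document lengths and totals", {
  sc <- small_corpus()
  fit <- fit_lda(sc$corpus, K = 4, n_iter = 20, seed = 3)
  totals <- dplyr::count(sc$corpus, encounter_id, wt = count)
  expect_equal(unname(rowSums(fit$n_dk)),
               totals$n[match(fit$encounter_ids, totals$encounter_id)])
  expect_equal(unname(rowSums(fit$n_kw)), fit$n_k)
  expect_equal(sum(fit$n_k), sum(sc$corpus$count))
  expect_true(all(abs(rowSums(fit$phi) - 1) < 1e-9))
  expect_true(all(abs(rowSums(fit$theta) - 1) < 1e-9))
})

test_that("a fixed seed reproduces the model bit for bit", {
  sc <- small_corpus()
  f1 <- fit_lda(sc$corpus, K = 3, n_iter = 50, seed = 42)
  f2 <- fit_lda(sc$corpus, K = 3, n_iter = 50, seed = 42)
  expect_identical(f1$phi, f2$phi)
  expect_identical(f1$theta, f2$theta)
  f3 <- fit_lda(sc$corpus, K = 3, n_iter = 50, seed = 43)
  expect_false(identical(f1$phi, f3$phi))
})

test_that("empty documents embed as the uniform simplex point", {
  bags <- make_bags(list(E1 = c(a = 5, b = 3), E2 = c(a = 2)))
  corpus <- build_corpus(bags, keep = c("a", "b"),
                         encounter_ids = c("E1", "E2", "E3"))
  fit <- fit_lda(corpus, K = 2, n_iter = 20, seed = 1)
  emb <- embed_encounters(fit, corpus)
  expect_equal(nrow(emb), 3)
  e3 <- as.numeric(emb[emb$encounter_id == "E3", -1])
  expect_equal(e3, c(0.5, 0.5))
  expect_true(all(abs(rowSums(as.matrix(emb[, -1])) - 1) < 1e-9))
  expect_error(embed_encounters(fit, build_corpus(bags, keep = c("a", "b"))),
               "do not match")
})

test_that("top words sort by probability with lexicographic tie-break", {
  fake <- structure(list(K = 1L,
                         phi = matrix(c(0.3, 0.2, 0.5), 1,
                                      dimnames = list(NULL, c("a", "b", "c"))),
                         vocabulary = c("a", "b", "c")),
                    class = "lda_fit")
  tw <- top_words(fake, 1, m = 2)
  expect_equal(tw$word, c("c", "a"))
  expect_equal(tw$probability, c(0.5, 0.3))
  tied <- structure(list(K = 1L,
                         phi = matrix(c(0.25, 0.5, 0.25), 1,
                                      dimnames = list(NULL, c("zeb", "mid", "ant"))),
                         vocabulary = c("zeb", "mid", "ant")),
                    class = "lda_fit")
  expect_equal(top_words(tied, 1, m = 10)$word, c("mid", "ant", "zeb"))
  expect_error(top_words(fake, 1, m = 0), "positive")
  expect_error(top_words(fake, 2, m = 1), "topic")
})

test_that("UMass coherence evaluates the pair formula directly", {
  # planted model: one topic whose two top words never co-occur,
  # with D(w2) = 50 -> coherence log(1 / 50)
  docs <- c(sprintf("A%02d", 1:30), sprintf("B%02d", 1:50))
  corpus <- tibble::tibble(
    encounter_id = docs,
    token = c(rep("w1", 30), rep("w2", 50)),
    count = 1L)
  fake <- structure(list(K = 1L,
                         phi = matrix(c(0.6, 0.4), 1,
                                      dimnames = list(NULL, c("w1", "w2"))),
                         vocabulary = c("w1", "w2")),
                    class = "lda_fit")
  ch <- topic_coherence(fake, corpus, top_m = 2)
  expect_equal(ch$per_topic, log(1 / 50), tolerance = 1e-12)
  # perfectly co-occurring words score log((D+1)/D), near the maximum 0
  corpus2 <- tibble::tibble(encounter_id = rep(sprintf("C%02d", 1:40), each = 2),
                            token = rep(c("w1", "w2"), 40), count = 1L)
  ch2 <- topic_coherence(fake, corpus2, top_m = 2)
  expect_equal(ch2$per_topic, log(41 / 40), tolerance = 1e-12)
})

test_that("coherence of a fitted model matches a brute-force pair-counting oracle", {
  sc <- small_corpus()
  fit <- fit_lda(sc$corpus, K = 3, n_iter = 60, seed = 9)
  ch <- topic_coherence(fit, sc$corpus, top_m = 8)
  pres <- dplyr::distinct(sc$corpus, encounter_id, token)
  for (k in 1:3) {
    words <- top_words(fit, k, m = 8)$word
    oracle <- 0
    for (j in 2:length(words)) {
      for (i in 1:(j - 1)) {
        di <- pres$encounter_id[pres$token == words[i]]
        dj <- pres$encounter_id[pres$token == words[j]]
        oracle <- oracle + log((length(intersect(di, dj)) + 1) / length(dj))
      }
    }
    expect_equal(ch$per_topic[k], oracle, tolerance = 1e-10)
  }
})

test_that("the plateau rule picks the smallest K within epsilon of the max", {
  expect_equal(plateau_choice(c(10, 20, 30, 40), c(-5, -3, -2.9, -2.85),
                              epsilon = 0.1), 20)
  expect_equal(plateau_choice(c(5, 10, 15), c(-2, -2, -2)), 5)
  expect_equal(plateau_choice(c(2, 4), c(-10, -1), epsilon = 0.05), 4)
})

test_that("planted topics are recovered up to permutation across seeds", {
  sc <- simulate_corpus(n_docs = 250, n_topics = 3, vocab_size = 90,
                        doc_length = 80, seed = 12)
  f1 <- fit_lda(sc$corpus, K = 3, n_iter = 400, seed = 1)
  m1 <- match_topics(f1$phi[, colnames(sc$phi)], sc$phi)
  expect_lte(m1$mean_tv, 0.10)
  sp <- vapply(1:3, function(k) {
    cor(f1$theta[, m1$perm[k]], sc$theta[, k], method = "spearman")
  }, numeric(1))
  expect_gte(mean(sp), 0.8)
  # label-permutation equivalence between seeds
  f2 <- fit_lda(sc$corpus, K = 3, n_iter = 400, seed = 2)
  m12 <- match_topics(f2$phi, f1$phi)
  expect_lte(m12$mean_tv, 0.15)
})
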