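# Independent oracles used across tests. These deliberately avoid the code
# paths they check: chi-square via expected counts, Kaplan-Meier via explicit
# risk-set enumeration, silhouette via raw pairwise distances.

oracle_chisq <- function(m) {
  # brute-force Pearson statistic sum((O - E)^2 / E) on a 2x2 table
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  stat <- sum((m - E)^2 / E)
  list(statistic = stat, p_value = pchisq(stat, df = 1, lower.tail = FALSE))
}

oracle_km <- function(times, events, at) {
  # product-limit by walking event times and counting risk sets directly
  ts <- sort(unique(times[events == 1]))
  s <- 1
  for (t in ts) {
    if (t > at) break
    n_risk <- sum(times >= t)
    d <- sum(times == t & events == 1)
    s <- s * (1 - d / n_risk)
  }
  s
}

oracle_silhouette <- function(x, labels) {
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(rowSums((x - matrix(x[i, ], n, ncol(x), byrow = TRUE))^2))
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- mean(di[own & seq_len(n) != i])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(di[labels == cl]), numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

# bag tibble from a named list of token count vectors
make_bags <- function(lst) {
  purrr::imap_dfr(lst, function(counts, id) {
    tibble::tibble(encounter_id = id, token = names(counts),
                   count = as.integer(counts))
  })
}

# bags for n docs where each token in `present` appears in the given number
# of documents (one count each)
bags_with_docfreq <- function(n_docs, present, prefix = "d") {
  rows <- purrr::imap_dfr(present, function(n_with, tok) {
    tibble::tibble(encounter_id = paste0(prefix, seq_len(n_with)), token = tok,
                   count = 1L)
  })
  filler <- tibble::tibble(encounter_id = paste0(prefix, seq_len(n_docs)),
                           token = "anchor", count = 1L)
  dplyr::bind_rows(rows, filler)
}

write_lexicon_csv <- function(rows) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  m <- do.call(rbind, rows)
  df <- as.data.frame(m, stringsAsFactors = FALSE)
  colnames(df) <- c("surface_form", "concept_id", "name", "semantic_type")
  write.csv(df, path, row.names = FALSE)
  path
}
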