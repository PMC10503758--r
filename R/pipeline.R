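#' Render token notes as plain text
#'
#' Interleaves each note's concept tokens with filler words at a configured
#' rate, producing free text suitable for exercising the concept extractor.
#' Tokens become their own surface forms; [sim_lexicon()] builds the
#' matching lexicon.
#'
#' @param notes Notes tibble with a `tokens` list-column.
#' @param filler_rate Expected filler words per concept token; default 0.5.
#' @param seed Integer seed for the filler interleaving.
#' @return The notes tibble with a `text` column added.
#' @export
render_notes <- function(notes, filler_rate = 0.5, seed = 1L) {
  filler <- c("the", "pt", "with", "and", "of", "noted", "on", "exam", "today")
  set.seed(seed)
  notes$text <- purrr::map_chr(notes$tokens, function(tk) {
    if (length(tk) == 0) return("")
    n_fill <- stats::rpois(1, filler_rate * length(tk))
    words <- c(tk, sample(filler, n_fill, replace = TRUE))
    paste(sample(words), collapse = " ")
  })
  notes
}

#' Build a lexicon covering a synthetic dataset's vocabulary
#'
#' Every simulated vocabulary token becomes a lexicon entry whose surface
#' form is the token itself, with synthetic concept ids and semantic types
#' cycled from the default allow-list, so text rendered by [render_notes()]
#' round-trips through [extract_concepts()].
#'
#' @param dataset An `ehr_dataset`.
#' @return A `concept_lexicon` tibble.
#' @export
sim_lexicon <- function(dataset) {
  voc <- dataset$truth$vocabulary
  vocab <- c(voc$content, voc$background, voc$common)
  types <- default_semantic_types()
  out <- tibble(
    surface_norm = normalize_text(vocab),
    n_words = 1L,
    concept_id = sprintf("SYN%06d", seq_along(vocab)),
    name = vocab,
    semantic_type = types[((seq_along(vocab) - 1) %% length(types)) + 1]
  )
  class(out) <- c("concept_lexicon", class(out))
  out
}

#' Run the full phenotyping pipeline
#'
#' Orchestrates simulate (or user-supplied data) -> concept tokens ->
#' corpus filtering -> LDA -> simplex embedding -> K-means -> outcomes, and
#' optionally writes every intermediate artifact plus a JSON run manifest
#' (parameters, seeds, file checksums). Rerunning with the same
#' configuration and seed reproduces identical artifacts.
#'
#' @param sim A [sim_config()] describing the synthetic dataset, or an
#'   existing `ehr_dataset`.
#' @param out_dir Directory for artifacts, or NULL to run in memory.
#' @param freq_threshold Two-cohort document-frequency threshold.
#' @param alpha Chi-square keep-word significance level.
#' @param n_topics Fixed topic count, or NULL to select from `topic_grid`.
#' @param topic_grid Candidate topic counts for [select_topic_count()].
#' @param topic_seeds Seeds used during topic-count selection.
#' @param n_iter Gibbs sweeps for the final LDA fit.
#' @param select_iter Gibbs sweeps per fit during topic-count selection.
#' @param n_clusters Fixed cluster count, or NULL to select from
#'   `cluster_grid`.
#' @param cluster_grid Candidate cluster counts for [select_k()].
#' @param use_text_extraction Render notes as text and run the lexicon
#'   extractor instead of using token notes directly.
#' @param seed Master seed for model fitting and clustering.
#' @return A list of class `phenotype_run`: the dataset, vocabulary
#'   `decisions`, `corpus`, `model`, `embeddings`, `clusters`
#'   (`cluster_assignment` or `k_selection`), `outcomes`
#'   (`cluster_outcomes`), and `manifest`.
#' @export
run_pipeline <- function(sim = sim_config(),
                         out_dir = NULL,
                         freq_threshold = 0.05,
                         alpha = 0.05,
                         n_topics = NULL,
                         topic_grid = c(2, 5, 10),
                         topic_seeds = 1L,
                         n_iter = 500,
                         select_iter = 300,
                         n_clusters = NULL,
                         cluster_grid = 2:8,
                         use_text_extraction = FALSE,
                         seed = 1L) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  dataset <- stage("simulate", {
    if (inherits(sim, "ehr_dataset")) sim else simulate_ehr(sim)
  })
  cfg <- dataset$truth$config

  notes <- dataset$notes
  if (use_text_extraction) {
    notes <- stage("extract", {
      rendered <- render_notes(notes, seed = seed)
      lex <- sim_lexicon(dataset)
      mentions <- purrr::map_dfr(seq_len(nrow(rendered)), function(i) {
        extract_concepts(rendered$text[i], lex,
                         encounter_id = rendered$encounter_id[i],
                         note_index = i)
      })
      mentions <- filter_semantic_types(mentions)
      mentions_to_tokens(mentions)
    })
  }

  corpus_parts <- stage("corpus", {
    groups <- dataset$diagnoses %>%
      dplyr::inner_join(dplyr::select(cfg$icd10_pool, "code", "group"),
                        by = "code")
    enc <- dataset$encounters
    op_ids <- enc$encounter_id[enc$cohort == "opioid"]
    bg_ids <- enc$encounter_id[enc$cohort == "background"]
    lab_ref <- compute_lab_reference(
      dataset$labs[dataset$labs$encounter_id %in% bg_ids, ])
    bags <- build_encounter_bags(
      notes = notes,
      diagnoses = groups, medications = dataset$medications,
      labs = dataset$labs, lab_reference = lab_ref)
    op_bags <- bags[bags$encounter_id %in% op_ids, ]
    bg_bags <- bags[bags$encounter_id %in% bg_ids, ]
    removed <- frequency_filter(op_bags, bg_bags, threshold = freq_threshold)
    decisions <- chisq_keep_words(op_bags, bg_bags, removed, alpha = alpha)
    keep <- decisions$token[decisions$keep]
    corpus <- build_corpus(op_bags, keep, encounter_ids = op_ids)
    list(corpus = corpus, decisions = decisions, lab_ref = lab_ref,
         removed = removed)
  })
  corpus <- corpus_parts$corpus

  topic_sel <- NULL
  K <- n_topics
  if (is.null(K)) {
    topic_sel <- stage("topics",
                       select_topic_count(corpus, topic_grid, seeds = topic_seeds,
                                          n_iter = select_iter))
    K <- topic_sel$chosen_k
  }
  model <- stage("topics", fit_lda(corpus, K = K, n_iter = n_iter, seed = seed))

  embeddings <- stage("embed", embed_encounters(model, corpus))

  clusters <- stage("cluster", {
    if (is.null(n_clusters)) {
      select_k(embeddings, cluster_grid, seed = seed)
    } else {
      cluster_embeddings(embeddings, k = n_clusters, seed = seed)
    }
  })
  assignment <- if (inherits(clusters, "k_selection")) clusters$best_fit else clusters
  labels <- assignment$assignments

  outcomes <- stage("outcomes", {
    cluster_outcomes(dataset$outcomes, dataset$returns, dataset$diagnoses,
                     labels)
  })

  manifest <- list(
    created = "run",
    seed = seed,
    parameters = list(freq_threshold = freq_threshold, alpha = alpha,
                      n_topics = model$K, n_iter = n_iter,
                      k_clusters = assignment$k,
                      sim_seed = cfg$seed,
                      n_opioid = cfg$n_opioid, n_background = cfg$n_background),
    stages = c("simulate", "extract", "corpus", "topics", "embed",
               "cluster", "outcomes"),
    n_keep_words = length(corpus$vocabulary),
    n_removed_by_frequency = length(corpus_parts$removed)
  )

  run <- structure(list(dataset = dataset, decisions = corpus_parts$decisions,
                        corpus = corpus, topic_selection = topic_sel,
                        model = model, embeddings = embeddings,
                        clusters = clusters, assignment = labels,
                        outcomes = outcomes, manifest = manifest),
                   class = "phenotype_run")
  if (!is.null(out_dir)) {
    run$manifest <- write_run(run, out_dir)
  }
  run
}

# write every stage artifact as plain text plus a JSON manifest with
# checksums so reruns can be compared file by file
write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  ds <- run$dataset
  paths <- character()
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.csv(df, p, row.names = FALSE)
    paths[[name]] <<- p
  }
  wcsv(ds$encounters, "encounters.csv")
  wcsv(ds$diagnoses, "diagnoses.csv")
  wcsv(ds$labs, "labs.csv")
  wcsv(ds$medications, "medications.csv")
  wcsv(dplyr::mutate(ds$outcomes,
                     dplyr::across(dplyr::where(lubridate_is_date), as.character)),
       "outcomes.csv")
  wcsv(ds$returns, "returns.csv")
  notes_path <- file.path(out_dir, "notes.jsonl")
  writeLines(vapply(seq_len(nrow(ds$notes)), function(i) {
    jsonlite::toJSON(list(encounter_id = ds$notes$encounter_id[i],
                          note_type = ds$notes$note_type[i],
                          tokens = ds$notes$tokens[[i]]), auto_unbox = TRUE)
  }, character(1)), notes_path)
  paths[["notes.jsonl"]] <- notes_path
  wcsv(run$decisions, "vocabulary_decisions.csv")
  wcsv(run$corpus$counts, "corpus.csv")
  wcsv(run$embeddings, "embeddings.csv")
  wcsv(run$assignment, "clusters.csv")
  wcsv(run$outcomes$summary, "cluster_outcomes.csv")
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(list(cluster = as.list(ds$truth$cluster)),
                       truth_path, auto_unbox = TRUE)
  paths[["truth.json"]] <- truth_path
  manifest <- run$manifest
  manifest$files <- lapply(paths, function(p) unname(tools::md5sum(p)))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  manifest
}

lubridate_is_date <- function(x) inherits(x, "Date")

#' @export
print.phenotype_run <- function(x, ...) {
  cat("<phenotype_run>\n")
  cat("  keep words:", length(x$corpus$vocabulary),
      "| topics:", x$model$K,
      "| clusters:", length(unique(x$assignment$cluster)), "\n")
  invisible(x)
}
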