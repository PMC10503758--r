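#' Normalize clinical text for lexicon matching
#'
#' Lowercases, replaces punctuation with spaces, and collapses whitespace.
#' The same normalization is applied to lexicon surface forms and note text,
#' so matching is exact on normalized token sequences.
#'
#' @param x Character vector.
#' @return Normalized character vector.
#' @export
normalize_text <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(gsub("\\s+", " ", x))
}

#' Load a concept lexicon
#'
#' Reads a CSV with columns `surface_form`, `concept_id`, `name`,
#' `semantic_type` and indexes it by normalized surface form. Two surface
#' forms that collide after normalization (e.g. "ABD PAIN" and "abd pain")
#' are rejected, naming the collision.
#'
#' @param path Path to the lexicon CSV. The package ships a small clinical
#'   demo lexicon at `system.file("extdata", "demo_lexicon.csv", package =
#'   "edphenotype")`.
#' @return A tibble of class `concept_lexicon` with columns `surface_norm`,
#'   `n_words`, `concept_id`, `name`, `semantic_type`.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path, call. = FALSE)
  raw <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("surface_form", "concept_id", "name", "semantic_type")
  if (!all(need %in% names(raw))) {
    stop("lexicon must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  if (nrow(raw) == 0) stop("lexicon file is empty: ", path, call. = FALSE)
  if (any(!nzchar(raw$semantic_type))) {
    stop("every lexicon entry needs a non-empty semantic_type", call. = FALSE)
  }
  lex <- raw %>%
    dplyr::mutate(surface_norm = normalize_text(.data$surface_form),
                  n_words = lengths(strsplit(.data$surface_norm, " ", fixed = TRUE)))
  dup <- lex$surface_norm[duplicated(lex$surface_norm)]
  if (length(dup)) {
    stop("duplicate surface forms after normalization: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  out <- dplyr::select(lex, "surface_norm", "n_words", "concept_id", "name",
                       "semantic_type")
  class(out) <- c("concept_lexicon", class(out))
  out
}

#' Extract concept mentions from note text
#'
#' Deterministic greedy longest-match dictionary extraction: the normalized
#' text is scanned left to right on token boundaries; at each position the
#' longest lexicon phrase starting there is taken (so matches never overlap),
#' and unmatched tokens are skipped. Substrings of words never match — a
#' lexicon entry "tension" does not fire inside "hypertension".
#'
#' @param text A single character string (may be empty).
#' @param lexicon A `concept_lexicon` from [read_lexicon()].
#' @param encounter_id,note_index Optional identifiers carried through to the
#'   output.
#' @return A tibble of mentions ordered by span start: `encounter_id`,
#'   `note_index`, `concept_id`, `surface`, `start`, `end` (0-based,
#'   half-open, in the original text), `semantic_type`.
#' @export
extract_concepts <- function(text, lexicon, encounter_id = NA_character_,
                             note_index = 1L) {
  stopifnot(inherits(lexicon, "concept_lexicon"), length(text) == 1)
  empty <- tibble(encounter_id = character(), note_index = integer(),
                  concept_id = character(), surface = character(),
                  start = integer(), end = integer(), semantic_type = character())
  if (is.na(text) || !nzchar(text)) return(empty)

  # token positions in the ORIGINAL text: runs of alphanumeric characters
  m <- gregexpr("[A-Za-z0-9]+", text)[[1]]
  if (m[1] == -1) return(empty)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  words <- tolower(substring(text, starts, starts + lens - 1))
  n <- length(words)
  max_len <- max(lexicon$n_words)
  idx <- setNames(seq_len(nrow(lexicon)), lexicon$surface_norm)

  hits <- list()
  i <- 1
  while (i <= n) {
    matched <- 0L
    for (L in seq(min(max_len, n - i + 1), 1)) {
      phrase <- paste(words[i:(i + L - 1)], collapse = " ")
      j <- idx[phrase]
      if (!is.na(j)) {
        hits[[length(hits) + 1]] <- tibble(
          encounter_id = encounter_id, note_index = as.integer(note_index),
          concept_id = lexicon$concept_id[j], surface = phrase,
          start = starts[i] - 1L,
          end = starts[i + L - 1] + lens[i + L - 1] - 1L,
          semantic_type = lexicon$semantic_type[j])
        matched <- L
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  if (!length(hits)) return(empty)
  dplyr::bind_rows(hits)
}

#' Filter concept mentions by semantic type
#'
#' Keeps only mentions whose semantic type is in the allow-list; order is
#' preserved. Downstream, only surviving mentions' concept tokens enter the
#' corpus, which is how non-clinical note text is discarded.
#'
#' @param mentions A mentions tibble from [extract_concepts()].
#' @param allowlist Character vector of semantic-type names. The packaged
#'   default (disorders, findings, procedures, chemicals/drugs, anatomy) is
#'   returned by [default_semantic_types()].
#' @return The filtered mentions tibble.
#' @export
filter_semantic_types <- function(mentions, allowlist = default_semantic_types()) {
  if (length(allowlist) == 0) {
    warning("empty semantic-type allow-list; all mentions removed")
    return(mentions[0, ])
  }
  dplyr::filter(mentions, .data$semantic_type %in% allowlist)
}

#' Default semantic-type allow-list
#'
#' Read from the editable packaged YAML config
#' (`extdata/semantic_types.yaml`), covering disorders, findings, procedures,
#' chemicals/drugs and anatomical types.
#'
#' @return Character vector of semantic-type names.
#' @export
default_semantic_types <- function() {
  path <- system.file("extdata", "semantic_types.yaml", package = "edphenotype")
  unlist(yaml::read_yaml(path)$allowlist)
}

#' Turn extracted mentions into per-note concept token lists
#'
#' @param mentions A mentions tibble (typically already filtered by
#'   [filter_semantic_types()]).
#' @param token Which field becomes the token: the concept's normalized
#'   surface form (default, readable) or its concept id.
#' @return Tibble `encounter_id`, `note_index`, `tokens` (list-column).
#' @export
mentions_to_tokens <- function(mentions, token = c("surface", "concept_id")) {
  token <- match.arg(token)
  mentions %>%
    dplyr::group_by(.data$encounter_id, .data$note_index) %>%
    dplyr::summarise(tokens = list(.data[[token]]), .groups = "drop")
}
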