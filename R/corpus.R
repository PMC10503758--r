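#' Compute background-cohort laboratory reference ranges
#'
#' Per-lab sample mean and sample standard deviation (denominator n - 1) on
#' the matched background cohort; these anchor the "high"/"low" lab modifier
#' tokens at two standard deviations from the background mean.
#'
#' @param background_labs Tibble with columns `lab` and `value` (background
#'   cohort measurements only).
#' @return A tibble of class `lab_reference`: `lab`, `mean`, `sd`, `n`.
#'   A lab observed once gets `sd = 0` with a warning.
#' @export
compute_lab_reference <- function(background_labs) {
  stopifnot(all(c("lab", "value") %in% names(background_labs)))
  if (nrow(background_labs) == 0) {
    stop("background lab table is empty", call. = FALSE)
  }
  ref <- background_labs %>%
    dplyr::group_by(.data$lab) %>%
    dplyr::summarise(mean = mean(.data$value),
                     sd = ifelse(dplyr::n() < 2, 0, sd(.data$value)),
                     n = dplyr::n(), .groups = "drop")
  if (any(ref$n < 2)) {
    warning("labs with a single observation get sd = 0: ",
            paste(ref$lab[ref$n < 2], collapse = ", "))
  }
  class(ref) <- c("lab_reference", class(ref))
  ref
}

#' Structured-data tokens for one encounter
#'
#' Converts structured EHR rows into corpus tokens: one token per diagnosis
#' group and medication class present, and for each lab measurement the
#' plain lab-name token plus a combined `"high <name>"` / `"low <name>"`
#' token when the value is strictly more than two standard deviations above
#' / below the background mean. A value exactly at a boundary gets no
#' modifier.
#'
#' @param diagnosis_groups Character vector of diagnosis group names present.
#' @param medication_classes Character vector of medication class names.
#' @param labs Tibble with columns `lab`, `value` for this encounter (may be
#'   empty).
#' @param lab_reference A `lab_reference` from [compute_lab_reference()]; it
#'   must cover every lab present. A reference sd of 0 yields only the plain
#'   token, with a warning.
#' @return Character vector of tokens.
#' @export
structured_tokens <- function(diagnosis_groups = character(),
                              medication_classes = character(),
                              labs = NULL, lab_reference = NULL) {
  tokens <- c(as.character(diagnosis_groups), as.character(medication_classes))
  if (!is.null(labs) && nrow(labs) > 0) {
    if (is.null(lab_reference)) {
      stop("lab_reference is required when labs are present", call. = FALSE)
    }
    unknown <- setdiff(unique(labs$lab), lab_reference$lab)
    if (length(unknown)) {
      stop("labs missing from the reference: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    j <- match(labs$lab, lab_reference$lab)
    mu <- lab_reference$mean[j]
    sigma <- lab_reference$sd[j]
    if (any(sigma == 0)) {
      warning("reference sd = 0 for: ",
              paste(unique(labs$lab[sigma == 0]), collapse = ", "),
              "; only plain lab tokens emitted")
    }
    tokens <- c(tokens, labs$lab)
    hi <- labs$lab[sigma > 0 & labs$value > mu + 2 * sigma]
    lo <- labs$lab[sigma > 0 & labs$value < mu - 2 * sigma]
    if (length(hi)) tokens <- c(tokens, paste("high", hi))
    if (length(lo)) tokens <- c(tokens, paste("low", lo))
  }
  tokens
}

#' Combine note and structured tokens into one encounter bag
#'
#' Multiset union: every note's concept tokens and all structured tokens are
#' pooled, and repeated mentions each increment the term frequency.
#'
#' @param note_tokens List of character vectors, one per note.
#' @param structured Character vector of structured tokens.
#' @param encounter_id Encounter identifier stamped on the bag.
#' @return Tibble `encounter_id`, `token`, `count`.
#' @export
combine_encounter_tokens <- function(note_tokens = list(),
                                     structured = character(),
                                     encounter_id) {
  all_tokens <- c(unlist(note_tokens, use.names = FALSE), structured)
  if (length(all_tokens) == 0) {
    return(tibble(encounter_id = encounter_id, token = character(),
                  count = integer())[0, ])
  }
  tab <- table(all_tokens)
  tibble(encounter_id = encounter_id, token = names(tab),
         count = as.integer(tab))
}

#' Build term-frequency bags for a whole cohort
#'
#' Convenience wrapper that assembles one bag per encounter from a notes
#' table (list-column of tokens), a diagnosis-group table, a medications
#' table and a labs table.
#'
#' @param notes Tibble `encounter_id`, `tokens` (list-column); multiple notes
#'   per encounter are combined.
#' @param diagnoses Tibble `encounter_id`, `group` (plaintext diagnosis-group
#'   names), or NULL.
#' @param medications Tibble `encounter_id`, `drug`, or NULL.
#' @param labs Tibble `encounter_id`, `lab`, `value`, or NULL.
#' @param lab_reference A `lab_reference`; required when `labs` given.
#' @param encounter_ids Optional full roster of encounter ids, so encounters
#'   without any tokens still appear downstream.
#' @return Tibble `encounter_id`, `token`, `count` (the cohort's bags).
#' @export
build_encounter_bags <- function(notes, diagnoses = NULL, medications = NULL,
                                 labs = NULL, lab_reference = NULL,
                                 encounter_ids = NULL) {
  pieces <- list()
  if (!is.null(notes) && nrow(notes) > 0) {
    pieces$notes <- notes %>%
      dplyr::select("encounter_id", "tokens") %>%
      tidyr::unnest_longer("tokens", values_to = "token") %>%
      dplyr::select("encounter_id", "token")
  }
  if (!is.null(diagnoses) && nrow(diagnoses) > 0) {
    pieces$dx <- tibble(encounter_id = diagnoses$encounter_id,
                        token = diagnoses$group)
  }
  if (!is.null(medications) && nrow(medications) > 0) {
    pieces$rx <- tibble(encounter_id = medications$encounter_id,
                        token = medications$drug)
  }
  if (!is.null(labs) && nrow(labs) > 0) {
    if (is.null(lab_reference)) stop("lab_reference required", call. = FALSE)
    unknown <- setdiff(unique(labs$lab), lab_reference$lab)
    if (length(unknown)) {
      stop("labs missing from the reference: ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    j <- match(labs$lab, lab_reference$lab)
    mu <- lab_reference$mean[j]
    sigma <- lab_reference$sd[j]
    mod <- dplyr::case_when(
      sigma > 0 & labs$value > mu + 2 * sigma ~ paste("high", labs$lab),
      sigma > 0 & labs$value < mu - 2 * sigma ~ paste("low", labs$lab),
      TRUE ~ NA_character_
    )
    pieces$labs <- tibble(encounter_id = rep(labs$encounter_id, 2),
                          token = c(labs$lab, mod)) %>%
      dplyr::filter(!is.na(.data$token))
  }
  long <- dplyr::bind_rows(pieces)
  bags <- long %>%
    dplyr::count(.data$encounter_id, .data$token, name = "count") %>%
    dplyr::arrange(.data$encounter_id, .data$token)
  if (!is.null(encounter_ids)) {
    missing <- setdiff(encounter_ids, bags$encounter_id)
    # encounters with no tokens at all stay in the roster with empty bags
    attr(bags, "empty_encounters") <- missing
  }
  bags
}

#' Two-cohort document-frequency filter
#'
#' Removes tokens that are ubiquitous in both cohorts: a token is removed iff
#' its document frequency (fraction of encounters whose bag contains it)
#' strictly exceeds `threshold` in the opioid corpus AND in the background
#' corpus. Tokens common in only one cohort are retained — those are exactly
#' the cohort-discriminating tokens the downstream chi-square test assesses.
#'
#' @param opioid_bags,background_bags Bag tibbles (`encounter_id`, `token`,
#'   `count`).
#' @param threshold Document-frequency threshold in (0, 1); default 0.05.
#' @return Character vector of removed tokens.
#' @export
frequency_filter <- function(opioid_bags, background_bags, threshold = 0.05) {
  if (threshold <= 0 || threshold >= 1) {
    stop("threshold must be in (0, 1)", call. = FALSE)
  }
  if (nrow(opioid_bags) == 0 || nrow(background_bags) == 0) {
    stop("both corpora must be non-empty", call. = FALSE)
  }
  df_op <- doc_freq(opioid_bags)
  df_bg <- doc_freq(background_bags)
  both <- dplyr::inner_join(df_op, df_bg, by = "token",
                            suffix = c("_op", "_bg"))
  sort(both$token[both$df_op > threshold & both$df_bg > threshold])
}

doc_freq <- function(bags) {
  n_docs <- dplyr::n_distinct(bags$encounter_id)
  bags %>%
    dplyr::distinct(.data$encounter_id, .data$token) %>%
    dplyr::count(.data$token, name = "n_docs_with") %>%
    dplyr::mutate(df = .data$n_docs_with / n_docs)
}

#' Chi-square keep-word selection between cohorts
#'
#' For every token surviving the frequency filter, builds the 2x2
#' document-level contingency table (cohort x token presence) and tests
#' independence with Pearson's chi-square (1 df, no continuity correction).
#' Tokens with p below `alpha` are "keep" words. All decisions (kept and
#' not) are returned for audit.
#'
#' @param opioid_bags,background_bags Bag tibbles.
#' @param removed Character vector from [frequency_filter()].
#' @param alpha Significance level; default 0.05.
#' @return A tibble of class `vocab_decisions`: `token`, `df_opioid`,
#'   `df_background` (document frequencies), `removed_by_frequency`,
#'   `statistic`, `p_value`, `keep`.
#' @export
chisq_keep_words <- function(opioid_bags, background_bags, removed = character(),
                             alpha = 0.05) {
  n_op <- dplyr::n_distinct(opioid_bags$encounter_id)
  n_bg <- dplyr::n_distinct(background_bags$encounter_id)
  pres_op <- dplyr::count(dplyr::distinct(opioid_bags, .data$encounter_id, .data$token),
                          .data$token, name = "a")
  pres_bg <- dplyr::count(dplyr::distinct(background_bags, .data$encounter_id, .data$token),
                          .data$token, name = "b")
  tab <- dplyr::full_join(pres_op, pres_bg, by = "token") %>%
    tidyr::replace_na(list(a = 0L, b = 0L)) %>%
    dplyr::arrange(.data$token)
  degenerate <- tab$a == 0 & tab$b == 0
  if (any(degenerate)) {
    warning("tokens absent from both corpora skipped: ",
            paste(tab$token[degenerate], collapse = ", "))
    tab <- tab[!degenerate, ]
  }
  surviving <- !(tab$token %in% removed)
  stat <- rep(NA_real_, nrow(tab))
  pval <- rep(NA_real_, nrow(tab))
  for (i in which(surviving)) {
    m <- matrix(c(tab$a[i], n_op - tab$a[i], tab$b[i], n_bg - tab$b[i]),
                nrow = 2, byrow = TRUE)
    if (any(colSums(m) == 0)) { # token in every doc of both cohorts etc.
      stat[i] <- 0
      pval[i] <- 1
    } else {
      ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
      stat[i] <- unname(ct$statistic)
      pval[i] <- unname(ct$p.value)
    }
  }
  out <- tibble(
    token = tab$token,
    df_opioid = tab$a / n_op,
    df_background = tab$b / n_bg,
    removed_by_frequency = !surviving,
    statistic = stat,
    p_value = pval,
    keep = surviving & !is.na(pval) & pval < alpha
  )
  class(out) <- c("vocab_decisions", class(out))
  out
}

#' Restrict encounter bags to the keep vocabulary
#'
#' Produces the term-frequency corpus for topic modelling: each bag is
#' restricted to keep words. Encounters whose restricted bag is empty are
#' retained in the roster and flagged so that every encounter still gets an
#' embedding downstream (their document-topic vector falls back to the
#' uniform prior).
#'
#' @param bags Bag tibble (`encounter_id`, `token`, `count`).
#' @param keep Character vector of keep words (non-empty).
#' @param encounter_ids Optional full roster; defaults to the encounters in
#'   `bags`.
#' @return A list of class `tf_corpus`: `counts` (tibble `encounter_id`,
#'   `token`, `count`), `vocabulary` (lexicographically sorted),
#'   `encounter_ids` (roster order), `empty_encounters`.
#' @export
build_corpus <- function(bags, keep, encounter_ids = NULL) {
  if (length(keep) == 0) stop("keep set is empty", call. = FALSE)
  if (is.null(encounter_ids)) encounter_ids <- unique(bags$encounter_id)
  counts <- bags %>%
    dplyr::filter(.data$token %in% keep) %>%
    dplyr::arrange(.data$encounter_id, .data$token)
  vocabulary <- sort(intersect(keep, unique(counts$token)))
  empty <- setdiff(encounter_ids, unique(counts$encounter_id))
  structure(list(counts = counts, vocabulary = vocabulary,
                 encounter_ids = encounter_ids, empty_encounters = empty),
            class = "tf_corpus")
}

#' @export
print.tf_corpus <- function(x, ...) {
  cat("<tf_corpus> ", length(x$encounter_ids), " encounters (",
      length(x$empty_encounters), " empty), vocabulary ",
      length(x$vocabulary), ", total tokens ", sum(x$counts$count), "\n",
      sep = "")
  invisible(x)
}
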