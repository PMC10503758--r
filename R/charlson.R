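#' Load a Charlson comorbidity ICD-10 mapping
#'
#' Reads a prefix-to-category mapping with integer weights. The packaged
#' default (`extdata/charlson_icd10_quan.csv`) is the Quan (2005) ICD-10
#' coding algorithm with the original Charlson weights; it is an editable
#' CSV so sites can substitute their own mapping.
#'
#' @param path CSV with columns `prefix` (ICD-10 code prefix, dots
#'   optional), `category`, `weight`.
#' @return Tibble of class `charlson_map` with normalized (dot-free,
#'   uppercase) prefixes.
#' @export
read_charlson_map <- function(path = system.file("extdata", "charlson_icd10_quan.csv",
                                                 package = "edphenotype")) {
  map <- as_tibble(read.csv(path, stringsAsFactors = FALSE))
  stopifnot(all(c("prefix", "category", "weight") %in% names(map)))
  map$prefix <- toupper(gsub("\\.", "", map$prefix))
  w <- unique(map[, c("category", "weight")])
  if (any(duplicated(w$category))) {
    stop("each Charlson category must have exactly one weight", call. = FALSE)
  }
  if (!all(map$weight %in% c(1L, 2L, 3L, 6L))) {
    stop("Charlson weights must be in {1, 2, 3, 6}", call. = FALSE)
  }
  class(map) <- c("charlson_map", class(map))
  map
}

# categories suppressed when a more severe one is present
charlson_hierarchy <- list(
  c(keep = "metastatic_cancer", drop = "malignancy"),
  c(keep = "severe_liver_disease", drop = "mild_liver_disease"),
  c(keep = "diabetes_complicated", drop = "diabetes_uncomplicated")
)

#' Charlson comorbidity index for one diagnosis-code set
#'
#' Each ICD-10 code is matched to its longest map prefix; each comorbidity
#' category counts at most once regardless of how many codes hit it, and the
#' severity hierarchy is applied (metastatic cancer supersedes other
#' malignancy, moderate/severe liver disease supersedes mild, complicated
#' diabetes supersedes uncomplicated). Unmatched codes contribute nothing.
#'
#' @param codes Character vector of ICD-10 codes (dots optional).
#' @param map A `charlson_map` from [read_charlson_map()].
#' @return Integer score.
#' @export
charlson_index <- function(codes, map = read_charlson_map()) {
  if (length(codes) == 0) return(0L)
  codes <- toupper(gsub("\\.", "", codes))
  cats <- unique(unlist(lapply(codes, function(code) {
    hits <- map$prefix[startsWith(code, map$prefix)]
    if (!length(hits)) return(NULL)
    best <- hits[which.max(nchar(hits))]
    map$category[map$prefix == best][1]
  })))
  for (h in charlson_hierarchy) {
    if (h[["keep"]] %in% cats) cats <- setdiff(cats, h[["drop"]])
  }
  w <- unique(map[, c("category", "weight")])
  sum(w$weight[w$category %in% cats])
}

#' Charlson scores for a whole diagnosis table
#'
#' @param diagnoses Tibble `encounter_id`, `code`.
#' @param map A `charlson_map`.
#' @param encounter_ids Optional roster; encounters without diagnoses score 0.
#' @return Tibble `encounter_id`, `cci`.
#' @export
charlson_scores <- function(diagnoses, map = read_charlson_map(),
                            encounter_ids = NULL) {
  # map each distinct code once, then aggregate per encounter
  codes <- unique(toupper(gsub("\\.", "", diagnoses$code)))
  cat_of <- vapply(codes, function(code) {
    hits <- map$prefix[startsWith(code, map$prefix)]
    if (!length(hits)) return(NA_character_)
    best <- hits[which.max(nchar(hits))]
    map$category[map$prefix == best][1]
  }, character(1))
  w <- unique(map[, c("category", "weight")])
  dx <- tibble(encounter_id = diagnoses$encounter_id,
               category = unname(cat_of[toupper(gsub("\\.", "", diagnoses$code))])) %>%
    dplyr::filter(!is.na(.data$category)) %>%
    dplyr::distinct()
  scores <- dx %>%
    dplyr::group_by(.data$encounter_id) %>%
    dplyr::summarise(cci = {
      cats <- .data$category
      for (h in charlson_hierarchy) {
        if (h[["keep"]] %in% cats) cats <- setdiff(cats, h[["drop"]])
      }
      as.integer(sum(w$weight[w$category %in% cats]))
    }, .groups = "drop")
  if (!is.null(encounter_ids)) {
    scores <- tibble(encounter_id = encounter_ids) %>%
      dplyr::left_join(scores, by = "encounter_id") %>%
      tidyr::replace_na(list(cci = 0L))
  }
  scores
}
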