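#' Opioid-related ICD-10 code list
#'
#' The configurable code list defining the opioid cohort (and, when
#' diagnosis codes accompany ED return visits, what counts as an
#' opioid-related return). The packaged default covers opioid abuse,
#' dependence and use (F11.x) plus opioid poisoning (T40.0-T40.6);
#' substitute a site-specific list by pointing `path` at an edited copy.
#'
#' @param path CSV with columns `code`, `description`.
#' @return Tibble `code`, `description`.
#' @export
opioid_code_list <- function(path = system.file("extdata", "opioid_icd10_codes.csv",
                                                package = "edphenotype")) {
  as_tibble(read.csv(path, stringsAsFactors = FALSE))
}

#' Published ED opioid cohort feature counts
#'
#' Per-cluster feature counts from a published nine-cluster feature
#' breakdown of 82,577 opioid-related ED encounters, shipped as a worked
#' example for [summary_from_counts()] and [relative_risk()].
#'
#' @return Tibble with column `variable` and count columns `overall`,
#'   `cluster_1` ... `cluster_9`; the `"n"` row holds each column's
#'   denominator.
#' @export
ed_cohort_counts <- function() {
  as_tibble(read.csv(system.file("extdata", "ed_cohort_feature_counts.csv",
                                 package = "edphenotype"),
                     stringsAsFactors = FALSE))
}
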