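#' Configuration for the synthetic EHR generator
#'
#' Builds the parameter set that [simulate_ehr()] consumes. The defaults
#' describe two ED cohorts: an "opioid" cohort whose notes are mixtures over
#' `n_topics` planted topics (with topic weights set by the encounter's
#' planted cluster) and a demographically matched background cohort drawn
#' from a separate background topic. A block of common "template" words is
#' given substantial mass in every topic so that the 5% two-cohort
#' document-frequency filter has real work to do.
#'
#' @param n_opioid,n_background Encounter counts for the two cohorts.
#' @param n_topics Number of planted opioid topics (K*).
#' @param n_clusters Number of planted clusters (C*).
#' @param vocab_size Number of content vocabulary tokens shared out among the
#'   planted topics.
#' @param n_background_words,n_common_words Sizes of the background-specific
#'   and common (template) vocabulary blocks.
#' @param doc_length_mean,doc_length_dispersion Negative-binomial note length
#'   (tokens per encounter); `doc_length_dispersion` is the `size` parameter.
#' @param cluster_probs Marginal probabilities of the planted clusters.
#' @param cluster_topic_profiles Optional C* x K* row-stochastic matrix; rows
#'   are each cluster's mean topic weights. The default concentrates 0.7 on
#'   one "own" topic per cluster (recycled if C* > K*) and spreads 0.3
#'   uniformly, giving pairwise total-variation separation of about 0.7.
#' @param theta_concentration Dirichlet precision around the cluster profile:
#'   an encounter in cluster c draws theta ~ Dirichlet(conc * profile\[c, \]).
#' @param anchor_mass,content_spread_mass,common_mass Topic-word mass placed
#'   on a topic's own anchor block, on the remaining content words, and on
#'   the common block (must sum to 1).
#' @param lab_catalog Tibble with columns `lab`, `bg_mean`, `bg_sd`,
#'   `opioid_shift`, `rate` (probability the lab is measured).
#' @param outcome_params Tibble with one row per cluster: `hazard` (exponential
#'   death hazard per day), `p_return6`, `p_return12`, `p_opioid_return6`,
#'   `p_opioid_return12`, `p_buprenorphine`, `p_methadone`, `p_naloxone`.
#'   Defaults emulate published ED opioid-cohort ranges (one-year survival
#'   roughly 84--97%, twelve-month returns 9--34%, methadone up to 43%).
#' @param icd10_pool Tibble with columns `code`, `group`, a `bg_prev`
#'   column and one `prev_cluster_<c>` column per cluster.
#' @param followup_days Administrative censoring horizon after discharge.
#' @param note_split_prob Probability an encounter's tokens are split across
#'   a provider and a nursing note rather than a single provider note.
#' @param seed Integer seed; the same config and seed reproduce the dataset
#'   exactly.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_opioid = 2000,
                       n_background = 2000,
                       n_topics = 5,
                       n_clusters = 4,
                       vocab_size = 200,
                       n_background_words = 30,
                       n_common_words = 10,
                       doc_length_mean = 100,
                       doc_length_dispersion = 20,
                       cluster_probs = NULL,
                       cluster_topic_profiles = NULL,
                       theta_concentration = 30,
                       anchor_mass = 0.75,
                       content_spread_mass = 0.10,
                       common_mass = 0.15,
                       lab_catalog = default_lab_catalog(),
                       outcome_params = default_outcome_params(n_clusters),
                       icd10_pool = default_icd10_pool(n_clusters),
                       followup_days = 730,
                       note_split_prob = 0.5,
                       seed = 1L) {
  if (n_topics < 1 || n_clusters < 1 || vocab_size < 1) {
    stop("n_topics, n_clusters and vocab_size must all be >= 1", call. = FALSE)
  }
  if (is.null(cluster_probs)) cluster_probs <- rep(1 / n_clusters, n_clusters)
  if (length(cluster_probs) != n_clusters || any(cluster_probs < 0)) {
    stop("cluster_probs must be ", n_clusters, " non-negative values", call. = FALSE)
  }
  cluster_probs <- cluster_probs / sum(cluster_probs)
  if (is.null(cluster_topic_profiles)) {
    cluster_topic_profiles <- default_cluster_profiles(n_clusters, n_topics)
  }
  cluster_topic_profiles <- as.matrix(cluster_topic_profiles)
  if (!all(dim(cluster_topic_profiles) == c(n_clusters, n_topics))) {
    stop("cluster_topic_profiles must be ", n_clusters, " x ", n_topics, call. = FALSE)
  }
  if (any(cluster_topic_profiles < 0) ||
      any(abs(rowSums(cluster_topic_profiles) - 1) > 1e-9)) {
    stop("cluster_topic_profiles rows must be probability simplex rows (sum 1 within 1e-9)",
         call. = FALSE)
  }
  if (abs(anchor_mass + content_spread_mass + common_mass - 1) > 1e-9) {
    stop("anchor_mass + content_spread_mass + common_mass must equal 1", call. = FALSE)
  }
  op <- outcome_params
  prob_cols <- setdiff(names(op), c("cluster", "hazard"))
  if (nrow(op) != n_clusters || any(op$hazard < 0) ||
      any(unlist(op[prob_cols]) < 0) || any(unlist(op[prob_cols]) > 1)) {
    stop("outcome_params needs one row per cluster, hazards >= 0, probabilities in [0,1]",
         call. = FALSE)
  }
  if (any(op$p_return6 > op$p_return12) ||
      any(op$p_opioid_return6 > op$p_opioid_return12)) {
    stop("6-month return probabilities cannot exceed 12-month ones", call. = FALSE)
  }
  structure(
    list(n_opioid = n_opioid, n_background = n_background,
         n_topics = n_topics, n_clusters = n_clusters,
         vocab_size = vocab_size,
         n_background_words = n_background_words,
         n_common_words = n_common_words,
         doc_length_mean = doc_length_mean,
         doc_length_dispersion = doc_length_dispersion,
         cluster_probs = cluster_probs,
         cluster_topic_profiles = cluster_topic_profiles,
         theta_concentration = theta_concentration,
         anchor_mass = anchor_mass,
         content_spread_mass = content_spread_mass,
         common_mass = common_mass,
         lab_catalog = lab_catalog,
         outcome_params = op,
         icd10_pool = icd10_pool,
         followup_days = followup_days,
         note_split_prob = note_split_prob,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Default generator catalogues
#'
#' Building blocks for [sim_config()], exported so users can start from the
#' defaults and modify them: cluster topic profiles (0.7 mass on one "own"
#' topic per cluster), a four-lab catalogue with cohort shifts, per-cluster
#' outcome parameters emulating published ED opioid-cohort ranges, and an
#' ICD-10 pool with cluster-conditional prevalences.
#'
#' @param C,K Numbers of clusters and topics.
#' @param n_clusters Number of planted clusters.
#' @return A matrix (`default_cluster_profiles`) or tibble (the others).
#' @export
default_cluster_profiles <- function(C, K) {
  prof <- matrix(0.3 / K, C, K)
  for (c in seq_len(C)) {
    own <- ((c - 1) %% K) + 1
    prof[c, own] <- prof[c, own] + 0.7
  }
  prof
}

#' @rdname default_cluster_profiles
#' @export
default_lab_catalog <- function() {
  tibble(
    lab = c("pao2", "creatinine", "hemoglobin", "sodium"),
    bg_mean = c(90, 1.0, 13.5, 140),
    bg_sd = c(10, 0.3, 1.8, 3),
    opioid_shift = c(-8, 0.2, -0.8, -1),
    rate = c(0.4, 0.8, 0.8, 0.8)
  )
}

#' @rdname default_cluster_profiles
#' @export
default_outcome_params <- function(n_clusters) {
  # one-year survivals ~ 96.9 / 94.3 / 89.3 / 84.2 %, recycled beyond 4 clusters
  base <- tibble(
    hazard = c(8.6e-05, 1.6e-04, 3.1e-04, 4.7e-04),
    p_return6 = c(0.08, 0.13, 0.18, 0.24),
    p_return12 = c(0.12, 0.20, 0.28, 0.34),
    p_opioid_return6 = c(0.06, 0.08, 0.09, 0.11),
    p_opioid_return12 = c(0.10, 0.13, 0.15, 0.17),
    p_buprenorphine = c(0.25, 0.20, 0.15, 0.10),
    p_methadone = c(0.43, 0.30, 0.20, 0.17),
    p_naloxone = c(0.15, 0.12, 0.17, 0.16)
  )
  idx <- ((seq_len(n_clusters) - 1) %% nrow(base)) + 1
  out <- base[idx, ]
  out$cluster <- seq_len(n_clusters)
  dplyr::relocate(out, "cluster")
}

#' @rdname default_cluster_profiles
#' @export
default_icd10_pool <- function(n_clusters) {
  # cluster-conditional prevalences for 4 planted clusters, recycled beyond;
  # groups double as CCS-style diagnosis-group names for structured tokens
  pool <- tibble(
    code = c("F11.20", "F10.20", "F32.9", "F03.90", "F20.9", "T14.91",
             "I21.9", "I50.9", "E11.9", "N18.3", "K70.30", "C78.00", "B20"),
    group = c("substance use disorders", "alcohol related disorders",
              "mood disorders", "delirium dementia", "schizophrenia",
              "suicide or self harm", "myocardial infarction",
              "congestive heart failure", "diabetes mellitus",
              "chronic kidney disease", "cirrhosis of liver",
              "metastatic cancer", "hiv infection"),
    bg_prev = c(0, 0.10, 0.20, 0.05, 0.03, 0.02,
                0.04, 0.05, 0.10, 0.03, 0.01, 0.01, 0.005)
  )
  prev <- rbind(
    c(0.60, 0.25, 0.50, 0.08, 0.10, 0.16, 0.05, 0.05, 0.10, 0.04, 0.02, 0.01, 0.02),
    c(0.75, 0.35, 0.60, 0.10, 0.15, 0.25, 0.08, 0.08, 0.12, 0.06, 0.04, 0.02, 0.03),
    c(0.85, 0.45, 0.65, 0.20, 0.20, 0.30, 0.15, 0.20, 0.20, 0.12, 0.06, 0.05, 0.06),
    c(0.90, 0.55, 0.75, 0.12, 0.26, 0.50, 0.10, 0.10, 0.15, 0.08, 0.08, 0.02, 0.07)
  )
  for (c in seq_len(n_clusters)) {
    pool[[paste0("prev_cluster_", c)]] <- prev[((c - 1) %% nrow(prev)) + 1, ]
  }
  pool
}

sim_vocabulary <- function(config) {
  list(
    content = sprintf("cw%03d", seq_len(config$vocab_size)),
    background = sprintf("bgw%02d", seq_len(config$n_background_words)),
    common = sprintf("tmpl%02d", seq_len(config$n_common_words))
  )
}

# planted topic-word matrix over the full vocabulary (content + background +
# common). Opioid topics anchor on disjoint content blocks with Zipf-shaped
# within-block weights; one extra background topic anchors on the background
# block. Every topic places `common_mass` uniformly on the template words.
sim_true_phi <- function(config) {
  voc <- sim_vocabulary(config)
  vocab <- c(voc$content, voc$background, voc$common)
  V <- config$vocab_size
  K <- config$n_topics
  Vtot <- length(vocab)
  phi <- matrix(0, K + 1, Vtot, dimnames = list(NULL, vocab))
  blocks <- split(seq_len(V), cut(seq_len(V), K, labels = FALSE))
  common_idx <- V + config$n_background_words + seq_len(config$n_common_words)
  bg_idx <- V + seq_len(config$n_background_words)
  for (k in seq_len(K)) {
    anchor <- blocks[[k]]
    zipf <- 1 / seq_along(anchor)
    phi[k, anchor] <- config$anchor_mass * zipf / sum(zipf)
    other <- setdiff(seq_len(V), anchor)
    phi[k, other] <- config$content_spread_mass / length(other)
    phi[k, common_idx] <- config$common_mass / length(common_idx)
  }
  zipf <- 1 / seq_along(bg_idx)
  phi[K + 1, bg_idx] <- config$anchor_mass * zipf / sum(zipf)
  phi[K + 1, seq_len(V)] <- config$content_spread_mass / V
  phi[K + 1, common_idx] <- config$common_mass / length(common_idx)
  phi
}

#' Generate a two-cohort synthetic EHR dataset with planted ground truth
#'
#' Draws an opioid cohort and a matched background cohort. Each opioid
#' encounter gets a planted cluster label, a document-topic vector drawn from
#' a Dirichlet centred on its cluster's topic profile, note tokens drawn
#' token-wise (topic from theta, word from the planted topic-word
#' distribution), diagnoses with cluster-conditional prevalences, labs from
#' cohort-specific normals, and outcomes (death, ED returns, medication
#' prescriptions) from its cluster's outcome parameters. Background
#' encounters draw from a separate background topic and carry no outcomes.
#' Demographics of the background cohort are resampled from the opioid
#' cohort's empirical distribution, emulating matching on age, sex and race.
#'
#' @param config A [sim_config()] object.
#' @return A list of class `ehr_dataset` with tibbles `encounters`, `notes`
#'   (list-column of token vectors), `diagnoses`, `labs`, `medications`,
#'   `outcomes`, `returns`, and a `truth` manifest (planted `phi`, per-opioid
#'   encounter `theta`, cluster labels, vocabulary blocks, config).
#' @export
simulate_ehr <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  voc <- sim_vocabulary(config)
  vocab <- c(voc$content, voc$background, voc$common)
  phi <- sim_true_phi(config)
  K <- config$n_topics
  n_op <- config$n_opioid
  n_bg <- config$n_background
  n_all <- n_op + n_bg

  if (n_op == 0) {
    if (n_bg > 0) warning("no opioid encounters requested; returning an empty dataset")
    return(empty_dataset(config, phi, vocab))
  }

  encounter_id <- sprintf("E%06d", seq_len(n_all))
  cohort <- c(rep("opioid", n_op), rep("background", n_bg))

  # opioid-cohort demographics; background resampled from them (matching)
  op_age <- pmin(pmax(round(rnorm(n_op, 48.7, 14)), 18), 95)
  op_sex <- sample(c("Male", "Female"), n_op, TRUE, prob = c(0.538, 0.462))
  op_race <- sample(c("White or Caucasian", "Black or African American", "Other"),
                    n_op, TRUE, prob = c(0.65, 0.21, 0.14))
  bg_idx <- if (n_bg > 0) sample.int(max(n_op, 1), n_bg, replace = TRUE) else integer(0)
  age <- c(op_age, op_age[bg_idx])
  sex <- c(op_sex, op_sex[bg_idx])
  race <- c(op_race, op_race[bg_idx])

  encounters <- tibble(
    encounter_id = encounter_id,
    patient_id = sprintf("P%06d", seq_len(n_all)),
    cohort = cohort,
    arrival_date = as.Date("2016-01-01") + sample.int(1460, n_all, TRUE) - 1L,
    age = age, sex = sex, race = race,
    ethnicity = sample(c("Non-Hispanic", "Hispanic or Latino"), n_all, TRUE,
                       prob = c(0.825, 0.175)),
    insurance = sample(c("Medicaid", "Medicare", "Commercial", "Other"),
                       n_all, TRUE, prob = c(0.55, 0.25, 0.12, 0.08)),
    esi = sample(1:5, n_all, TRUE, prob = c(0.015, 0.40, 0.44, 0.12, 0.025)),
    disposition = sample(c("discharge", "admit", "other"), n_all, TRUE,
                         prob = c(0.53, 0.41, 0.06))
  )

  # planted clusters and per-document topic weights
  cluster <- rcat(n_op, config$cluster_probs)
  theta_op <- matrix(0, n_op, K)
  for (i in seq_len(n_op)) {
    theta_op[i, ] <- rdirichlet1(
      config$theta_concentration * config$cluster_topic_profiles[cluster[i], ])
  }

  # token draws: topic ~ theta (background encounters use the bg topic),
  # word ~ phi[topic, ]
  doc_len <- rnbinom(n_all, size = config$doc_length_dispersion,
                     mu = config$doc_length_mean)
  doc_len <- pmax(doc_len, 5L)
  tokens <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    if (i <= n_op) {
      z <- rcat(doc_len[i], theta_op[i, ])
    } else {
      z <- rep(K + 1L, doc_len[i])
    }
    w <- integer(doc_len[i])
    for (k in unique(z)) {
      sel <- z == k
      w[sel] <- rcat(sum(sel), phi[k, ])
    }
    tokens[[i]] <- vocab[w]
  }

  # split tokens into provider (+ optional nursing) notes
  split_note <- runif(n_all) < config$note_split_prob
  notes <- purrr::map_dfr(seq_len(n_all), function(i) {
    tk <- tokens[[i]]
    if (split_note[i] && length(tk) >= 10) {
      cut <- floor(length(tk) * 0.6)
      tibble(encounter_id = encounter_id[i],
             note_type = c("provider", "nursing"),
             tokens = list(tk[seq_len(cut)], tk[-seq_len(cut)]))
    } else {
      tibble(encounter_id = encounter_id[i], note_type = "provider",
             tokens = list(tk))
    }
  })

  # diagnoses with cluster-conditional (opioid) or background prevalences
  pool <- config$icd10_pool
  diag_list <- vector("list", n_all)
  for (i in seq_len(n_all)) {
    if (i <= n_op) {
      prev <- vapply(seq_len(nrow(pool)), function(r) {
        pool[[paste0("prev_cluster_", cluster[i])]][r]
      }, numeric(1))
    } else {
      prev <- pool$bg_prev
    }
    hit <- runif(nrow(pool)) < prev
    codes <- pool$code[hit]
    if (i <= n_op && !"F11.20" %in% codes) codes <- c("F11.20", codes)
    if (length(codes)) diag_list[[i]] <- tibble(encounter_id = encounter_id[i],
                                                code = codes)
  }
  diagnoses <- dplyr::bind_rows(diag_list)

  # labs: cohort-specific normals
  lab_list <- vector("list", nrow(config$lab_catalog))
  for (r in seq_len(nrow(config$lab_catalog))) {
    cat_r <- config$lab_catalog[r, ]
    measured <- runif(n_all) < cat_r$rate
    mu <- cat_r$bg_mean + ifelse(cohort == "opioid", cat_r$opioid_shift, 0)
    vals <- rnorm(n_all, mu, cat_r$bg_sd)
    lab_list[[r]] <- tibble(encounter_id = encounter_id[measured],
                            lab = cat_r$lab, value = vals[measured])
  }
  labs <- dplyr::arrange(dplyr::bind_rows(lab_list), .data$encounter_id, .data$lab)

  # outpatient medication classes (structured tokens)
  med_classes <- c("opioid analgesics", "benzodiazepines", "antidepressants")
  med_prob <- c(0.35, 0.20, 0.30)
  med_list <- vector("list", length(med_classes))
  for (m in seq_along(med_classes)) {
    p <- ifelse(cohort == "opioid", med_prob[m], med_prob[m] * 0.5)
    hit <- runif(n_all) < p
    med_list[[m]] <- tibble(encounter_id = encounter_id[hit],
                            drug = med_classes[m])
  }
  medications <- dplyr::arrange(dplyr::bind_rows(med_list), .data$encounter_id)

  # outcomes for the opioid cohort, cluster-conditional
  op_enc <- encounter_id[seq_len(n_op)]
  opar <- config$outcome_params
  discharge <- encounters$arrival_date[seq_len(n_op)]
  hz <- opar$hazard[cluster]
  death_days <- ifelse(hz > 0, rexp(n_op, rate = pmax(hz, 1e-300)), Inf)
  died <- death_days <= config$followup_days
  outcomes <- tibble(
    encounter_id = op_enc,
    cluster_true = cluster,
    discharge_date = discharge,
    death_date = dplyr::if_else(died, discharge + ceiling(death_days), as.Date(NA)),
    censor_date = discharge + config$followup_days,
    buprenorphine = runif(n_op) < opar$p_buprenorphine[cluster],
    methadone = runif(n_op) < opar$p_methadone[cluster],
    naloxone = runif(n_op) < opar$p_naloxone[cluster]
  )

  returns <- dplyr::bind_rows(
    draw_returns(op_enc, discharge, opar$p_return6[cluster],
                 opar$p_return12[cluster], opioid_related = FALSE),
    draw_returns(op_enc, discharge, opar$p_opioid_return6[cluster],
                 opar$p_opioid_return12[cluster], opioid_related = TRUE)
  )

  truth <- list(
    phi = phi,
    theta = theta_op,
    cluster = setNames(cluster, op_enc),
    vocabulary = voc,
    cluster_topic_profiles = config$cluster_topic_profiles,
    outcome_params = opar,
    config = config
  )

  structure(list(encounters = encounters, notes = notes, diagnoses = diagnoses,
                 labs = labs, medications = medications, outcomes = outcomes,
                 returns = returns, truth = truth),
            class = "ehr_dataset")
}

# one all-cause (or opioid-related) return date per encounter, planted so the
# 6- and 12-month cumulative return probabilities match p6 / p12 exactly
draw_returns <- function(enc, discharge, p6, p12, opioid_related) {
  u <- runif(length(enc))
  in6 <- u < p6
  in12 <- !in6 & u < p12
  day <- integer(length(enc))
  day[in6] <- sample.int(183, sum(in6), replace = TRUE)
  day[in12] <- 183L + sample.int(182, sum(in12), replace = TRUE)
  keep <- in6 | in12
  tibble(encounter_id = enc[keep],
         return_date = discharge[keep] + day[keep],
         opioid_related = opioid_related)
}

empty_dataset <- function(config, phi, vocab) {
  structure(list(
    encounters = tibble(encounter_id = character(), patient_id = character(),
                        cohort = character(), arrival_date = as.Date(character()),
                        age = numeric(), sex = character(), race = character(),
                        ethnicity = character(), insurance = character(),
                        esi = integer(), disposition = character()),
    notes = tibble(encounter_id = character(), note_type = character(),
                   tokens = list()),
    diagnoses = tibble(encounter_id = character(), code = character()),
    labs = tibble(encounter_id = character(), lab = character(), value = numeric()),
    medications = tibble(encounter_id = character(), drug = character()),
    outcomes = tibble(encounter_id = character(), cluster_true = integer(),
                      discharge_date = as.Date(character()),
                      death_date = as.Date(character()),
                      censor_date = as.Date(character()),
                      buprenorphine = logical(), methadone = logical(),
                      naloxone = logical()),
    returns = tibble(encounter_id = character(),
                     return_date = as.Date(character()),
                     opioid_related = logical()),
    truth = list(phi = phi, theta = matrix(0, 0, config$n_topics),
                 cluster = setNames(integer(), character()),
                 vocabulary = sim_vocabulary(config),
                 cluster_topic_profiles = config$cluster_topic_profiles,
                 outcome_params = config$outcome_params, config = config)),
    class = "ehr_dataset")
}

#' Summarize the planted ground truth of a synthetic dataset
#'
#' @param dataset An `ehr_dataset` from [simulate_ehr()].
#' @return A tibble with one row per planted cluster: encounter count, mean
#'   planted topic weights (`mean_theta_<k>` columns), and empirical death /
#'   return / medication rates.
#' @export
summarize_truth <- function(dataset) {
  stopifnot(inherits(dataset, "ehr_dataset"))
  if (is.null(dataset$truth)) stop("dataset has no truth manifest", call. = FALSE)
  tr <- dataset$truth
  if (length(tr$cluster) == 0) {
    return(tibble(cluster = integer(), n = integer()))
  }
  out <- dataset$outcomes
  ret12 <- dataset$returns %>%
    dplyr::inner_join(dplyr::select(out, "encounter_id", "discharge_date"),
                      by = "encounter_id") %>%
    dplyr::filter(!.data$opioid_related,
                  as.integer(.data$return_date - .data$discharge_date) <= 365) %>%
    dplyr::distinct(.data$encounter_id)
  out$returned_12m <- out$encounter_id %in% ret12$encounter_id
  theta_means <- stats::aggregate(tr$theta, by = list(cluster = unname(tr$cluster)), FUN = mean)
  names(theta_means)[-1] <- paste0("mean_theta_", seq_len(ncol(tr$theta)))
  rates <- out %>%
    dplyr::group_by(cluster = .data$cluster_true) %>%
    dplyr::summarise(n = dplyr::n(),
                     death_rate = mean(!is.na(.data$death_date)),
                     return12_rate = mean(.data$returned_12m),
                     buprenorphine_rate = mean(.data$buprenorphine),
                     methadone_rate = mean(.data$methadone),
                     naloxone_rate = mean(.data$naloxone),
                     .groups = "drop")
  dplyr::left_join(rates, as_tibble(theta_means), by = "cluster")
}

#' Generate a bare planted-topic corpus for topic-model experiments
#'
#' A lighter companion to [simulate_ehr()]: documents are drawn directly from
#' `n_topics` well-separated planted topics over a content vocabulary (no
#' cohorts, labs or outcomes), which is the natural fixture for testing LDA
#' recovery in isolation.
#'
#' @param n_docs Number of documents.
#' @param n_topics Number of planted topics.
#' @param vocab_size Vocabulary size.
#' @param doc_length Tokens per document (fixed).
#' @param dirichlet_alpha Symmetric Dirichlet parameter for document-topic
#'   weights; small values give near-single-topic documents.
#' @param anchor_mass Topic mass on its own anchor block (rest spread
#'   uniformly).
#' @param seed Integer seed.
#' @return A list with `corpus` (tibble: `encounter_id`, `token`, `count`),
#'   `phi` (planted topic-word matrix), `theta` (planted document-topic
#'   matrix), and `vocabulary`.
#' @export
simulate_corpus <- function(n_docs = 500, n_topics = 5, vocab_size = 200,
                            doc_length = 100, dirichlet_alpha = 0.1,
                            anchor_mass = 0.9, seed = 1L) {
  set.seed(seed)
  vocab <- sprintf("w%03d", seq_len(vocab_size))
  phi <- matrix(0, n_topics, vocab_size, dimnames = list(NULL, vocab))
  blocks <- split(seq_len(vocab_size), cut(seq_len(vocab_size), n_topics, labels = FALSE))
  for (k in seq_len(n_topics)) {
    anchor <- blocks[[k]]
    zipf <- 1 / seq_along(anchor)
    phi[k, anchor] <- anchor_mass * zipf / sum(zipf)
    other <- setdiff(seq_len(vocab_size), anchor)
    phi[k, other] <- (1 - anchor_mass) / length(other)
  }
  theta <- t(vapply(seq_len(n_docs),
                    function(i) rdirichlet1(rep(dirichlet_alpha, n_topics)),
                    numeric(n_topics)))
  enc <- sprintf("D%05d", seq_len(n_docs))
  rows <- vector("list", n_docs)
  for (i in seq_len(n_docs)) {
    z <- rcat(doc_length, theta[i, ])
    w <- integer(doc_length)
    for (k in unique(z)) {
      sel <- z == k
      w[sel] <- rcat(sum(sel), phi[k, ])
    }
    tab <- table(vocab[w])
    rows[[i]] <- tibble(encounter_id = enc[i], token = names(tab),
                        count = as.integer(tab))
  }
  list(corpus = dplyr::bind_rows(rows), phi = phi, theta = theta,
       vocabulary = vocab)
}

#' @export
print.ehr_dataset <- function(x, ...) {
  cat("<ehr_dataset>\n")
  cat("  encounters:", nrow(x$encounters),
      sprintf("(%d opioid, %d background)",
              sum(x$encounters$cohort == "opioid"),
              sum(x$encounters$cohort == "background")), "\n")
  cat("  notes:", nrow(x$notes), " diagnoses:", nrow(x$diagnoses),
      " labs:", nrow(x$labs), "\n")
  cat("  planted topics:", x$truth$config$n_topics,
      " planted clusters:", x$truth$config$n_clusters, "\n")
  invisible(x)
}
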