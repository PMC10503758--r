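test_that("empty opioid cohort yields an empty dataset with an empty truth manifest", {
  cfg <- sim_config(n_opioid = 0, n_background = 0, seed = 1)
  ds <- simulate_ehr(cfg)
  expect_equal(nrow(ds$encounters), 0)
  expect_equal(nrow(ds$notes), 0)
  expect_equal(nrow(ds$truth$theta), 0)
  expect_equal(nrow(summarize_truth(ds)), 0)
  expect_warning(simulate_ehr(sim_config(n_opioid = 0, n_background = 5)),
                 "empty dataset")
})

test_that("identical config and seed reproduce the dataset exactly", {
  cfg <- sim_config(n_opioid = 150, n_background = 150, seed = 99)
  ds1 <- simulate_ehr(cfg)
  ds2 <- simulate_ehr(cfg)
  expect_identical(ds1, ds2)
  ds3 <- simulate_ehr(sim_config(n_opioid = 150, n_background = 150, seed = 100))
  expect_false(identical(ds1$notes, ds3$notes))
})

test_that("config validation rejects non-simplex profiles and bad sizes", {
  bad <- matrix(c(0.5, 0.4, 0.3, 0.7), 2, 2)
  expect_error(sim_config(n_clusters = 2, n_topics = 2,
                          cluster_topic_profiles = bad), "simplex")
  expect_error(sim_config(vocab_size = 0), ">= 1")
  op <- default_outcome_params(4)
  op$p_return6[1] <- 0.9 # above its 12-month value
  expect_error(sim_config(outcome_params = op), "cannot exceed")
})

test_that("planted theta and phi rows are probability vectors", {
  ds <- simulate_ehr(sim_config(n_opioid = 100, n_background = 50, seed = 3))
  expect_true(all(abs(rowSums(ds$truth$theta) - 1) < 1e-9))
  expect_true(all(abs(rowSums(ds$truth$phi) - 1) < 1e-9))
  expect_true(all(ds$truth$theta >= 0))
  expect_true(all(ds$truth$phi >= 0))
})

test_that("all child tables reference existing encounters and adults only", {
  ds <- simulate_ehr(sim_config(n_opioid = 200, n_background = 100, seed = 5))
  ids <- ds$encounters$encounter_id
  for (tab in list(ds$notes, ds$diagnoses, ds$labs, ds$medications,
                   ds$outcomes, ds$returns)) {
    expect_true(all(tab$encounter_id %in% ids))
  }
  expect_true(all(ds$encounters$age >= 18))
  expect_true(all(ds$encounters$esi %in% 1:5))
})

test_that("planted cluster sizes follow the configured categorical draw", {
  n <- 3000
  ds <- simulate_ehr(sim_config(n_opioid = n, n_background = 0, n_clusters = 3,
                                doc_length_mean = 10, seed = 17))
  counts <- table(ds$truth$cluster)
  bound <- 3 * sqrt(n * (1 / 3) * (2 / 3))
  expect_true(all(abs(counts - n / 3) <= bound))
})

test_that("token frequencies per planted topic converge to the planted phi", {
  # near-one-hot cluster profiles make documents essentially single-topic,
  # so each cluster's pooled tokens estimate one planted topic distribution
  K <- 2
  prof <- matrix(0.01 / K, K, K)
  diag(prof) <- 1 - 0.01 + 0.01 / K
  ds <- simulate_ehr(sim_config(
    n_opioid = 1200, n_background = 0, n_topics = K, n_clusters = K,
    cluster_topic_profiles = prof, theta_concentration = 5000, seed = 21))
  vocab <- colnames(ds$truth$phi)
  notes <- dplyr::inner_join(
    ds$notes,
    tibble::tibble(encounter_id = names(ds$truth$cluster),
                   cluster = unname(ds$truth$cluster)),
    by = "encounter_id")
  for (k in seq_len(K)) {
    toks <- unlist(notes$tokens[notes$cluster == k])
    expect_gt(length(toks), 50000)
    emp <- table(factor(toks, levels = vocab)) / length(toks)
    expect_lte(tv_distance(as.numeric(emp), ds$truth$phi[k, ]), 0.05)
  }
})

test_that("planted outcome rates are recovered by the truth summary", {
  op <- default_outcome_params(1)
  op$p_return12 <- 0.30
  op$p_return6 <- 0.18
  ds <- simulate_ehr(sim_config(n_opioid = 2000, n_background = 0,
                                n_clusters = 1, doc_length_mean = 10,
                                outcome_params = op, seed = 33))
  ts <- summarize_truth(ds)
  expect_equal(nrow(ts), 1)
  expect_equal(ts$n, 2000)
  se <- sqrt(0.3 * 0.7 / 2000)
  expect_lt(abs(ts$return12_rate - 0.30), 3 * se)
  se_m <- sqrt(op$p_methadone * (1 - op$p_methadone) / 2000)
  expect_lt(abs(ts$methadone_rate - op$p_methadone), 3 * se_m)
})

test_that("exponential death hazards reproduce the closed-form survival", {
  lam <- 4.7e-4
  op <- default_outcome_params(1)
  op$hazard <- lam
  ds <- simulate_ehr(sim_config(n_opioid = 2000, n_background = 0,
                                n_clusters = 1, doc_length_mean = 10,
                                outcome_params = op, seed = 41))
  out <- ds$outcomes
  died_1yr <- !is.na(out$death_date) &
    as.integer(out$death_date - out$discharge_date) <= 365
  s_hat <- 1 - mean(died_1yr)
  s_true <- exp(-365 * lam)
  expect_lt(abs(s_hat - s_true), 3 * sqrt(s_true * (1 - s_true) / 2000))
})

test_that("simulate_corpus plants row-stochastic topics and exact doc lengths", {
  sc <- simulate_corpus(n_docs = 50, n_topics = 3, vocab_size = 60,
                        doc_length = 40, seed = 2)
  expect_true(all(abs(rowSums(sc$phi) - 1) < 1e-9))
  expect_true(all(abs(rowSums(sc$theta) - 1) < 1e-9))
  totals <- dplyr::count(sc$corpus, encounter_id, wt = count)
  expect_true(all(totals$n == 40))
})
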