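cmap <- read_charlson_map()

test_that("Charlson scoring sums category weights with hierarchy rules", {
  expect_equal(charlson_index(character(), cmap), 0L)
  expect_equal(charlson_index(c("I21.9", "C78.00"), cmap), 7)    # MI + metastasis
  expect_equal(charlson_index(c("I21.9", "I21.0", "I22"), cmap), 1) # one category
  expect_equal(charlson_index(c("C50.9", "C78.0"), cmap), 6)     # metastatic supersedes
  expect_equal(charlson_index("C50.9", cmap), 2)
  expect_equal(charlson_index(c("K70.3", "K70.4"), cmap), 3)     # severe liver supersedes
  expect_equal(charlson_index(c("E11.9", "E11.2"), cmap), 2)     # complicated diabetes
  expect_equal(charlson_index("Z99.9", cmap), 0)                 # unmatched
  # vectorized version agrees
  dx <- tibble::tibble(encounter_id = c("A", "A", "B"),
                       code = c("I21.9", "C78.00", "B20"))
  sc <- charlson_scores(dx, cmap, encounter_ids = c("A", "B", "C"))
  expect_equal(sc$cci, c(7L, 6L, 0L))
})

test_that("the packaged map is a valid weighting", {
  expect_true(all(cmap$weight %in% c(1, 2, 3, 6)))
  w <- unique(cmap[, c("category", "weight")])
  expect_false(any(duplicated(w$category)))
})

test_that("Kaplan-Meier reproduces hand product-limit computations", {
  expect_equal(km_survival(rep(400, 10), rep(0, 10), horizon = 365)$s_horizon, 1)
  km <- km_survival(c(1, 2, 3), c(1, 0, 1), horizon = 365)
  s <- km$curve$survival[km$curve$time == 1]
  expect_equal(s, 2 / 3, tolerance = 1e-12)
  expect_equal(km$s_horizon, 0)
  expect_equal(km$curve$survival[km$curve$time == 3], 0)
  expect_error(km_survival(numeric(), numeric()), "no subjects")
})

test_that("Kaplan-Meier agrees with a risk-set enumeration oracle", {
  set.seed(19)
  n <- 200
  death <- rexp(n, 1 / 300)
  cens <- runif(n, 0, 800)
  times <- pmin(death, cens)
  events <- as.integer(death <= cens)
  km <- km_survival(times, events, horizon = 365)
  for (at in c(50, 180, 365)) {
    idx <- which(km$curve$time <= at & km$curve$n_event > 0)
    ours <- if (length(idx)) km$curve$survival[max(idx)] else 1
    expect_equal(ours, oracle_km(times, events, at), tolerance = 1e-12)
  }
  expect_equal(km$s_horizon, oracle_km(times, events, 365), tolerance = 1e-12)
})

test_that("return rates use an inclusive right boundary on day windows", {
  out <- tibble::tibble(encounter_id = c("A", "B", "C"),
                        discharge_date = as.Date("2020-01-01"))
  ret <- tibble::tibble(
    encounter_id = c("A", "B", "C"),
    return_date = as.Date("2020-01-01") + c(183, 184, 0),
    opioid_related = c(FALSE, FALSE, FALSE))
  rr <- return_rates(out, ret)
  expect_equal(rr$all_cause_rate[rr$window == 183], 1 / 3) # day 183 counts
  expect_equal(rr$all_cause_rate[rr$window == 365], 2 / 3) # day 0 never counts
  expect_equal(rr$opioid_rate, c(0, 0))
  none <- return_rates(out, ret[0, ])
  expect_equal(none$all_cause_rate, c(0, 0))
})

test_that("medication rates are simple flag fractions", {
  out <- tibble::tibble(encounter_id = as.character(1:10),
                        buprenorphine = rep(FALSE, 10),
                        methadone = c(rep(TRUE, 3), rep(FALSE, 7)),
                        naloxone = rep(FALSE, 10))
  mr <- medication_rates(out)
  expect_equal(mr$rate[mr$drug == "methadone"], 0.3)
  expect_equal(mr$rate[mr$drug == "buprenorphine"], 0)
})

test_that("relative risk follows the cluster-vs-rest formula exactly", {
  # worked examples from a published nine-cluster ED opioid cohort table
  expect_equal(relative_risk(3605, 6506, 28233, 82577),
               (3605 / 6506) / ((28233 - 3605) / (82577 - 6506)),
               tolerance = 1e-12)
  expect_equal(relative_risk(3605, 6506, 28233, 82577), 1.7115, tolerance = 1e-4)
  expect_equal(relative_risk(2069, 8634, 9487, 82577), 2.389, tolerance = 1e-3)
  # uniform distribution gives RR = 1
  expect_equal(relative_risk(10, 100, 100, 1000), 1)
  expect_warning(rr <- relative_risk(5, 10, 5, 100), "infinite")
  expect_identical(rr, Inf)
  expect_error(relative_risk(1, 0, 10, 100), "positive")
  expect_error(relative_risk(1, 100, 10, 100), "exceed")
  expect_error(relative_risk(20, 50, 10, 100), "at least")
})

test_that("rate comparison flags direction and is antisymmetric", {
  eq <- rate_comparison(20, 100, 20, 100)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p_value, 1)
  expect_equal(eq$direction, "neutral")
  up <- rate_comparison(300, 1000, 100, 1000)
  expect_equal(up$statistic, 125, tolerance = 1e-10)
  expect_equal(up$direction, "increased")
  down <- rate_comparison(100, 1000, 300, 1000)
  expect_equal(down$statistic, 125, tolerance = 1e-10)
  expect_equal(down$direction, "decreased")
  expect_warning(deg <- rate_comparison(0, 10, 0, 90), "degenerate")
  expect_equal(deg$direction, "neutral")
})

test_that("rate-comparison p-values match the oracle across random tables", {
  set.seed(23)
  for (i in 1:50) {
    n1 <- sample(20:200, 1); n2 <- sample(20:200, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    got <- rate_comparison(x1, n1, x2, n2)
    o <- oracle_chisq(matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE))
    expect_equal(got$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(got$p_value, o$p_value, tolerance = 1e-10)
  }
})

test_that("cohort summary percentages agree with their own counts", {
  ds <- simulate_ehr(sim_config(n_opioid = 300, n_background = 0,
                                doc_length_mean = 10, seed = 13))
  labels <- tibble::tibble(encounter_id = names(ds$truth$cluster),
                           cluster = unname(ds$truth$cluster))
  pool <- ds$truth$config$icd10_pool
  groups <- dplyr::inner_join(ds$diagnoses,
                              dplyr::select(pool, code, group), by = "code")
  cs <- cohort_summary(ds$encounters[ds$encounters$cohort == "opioid", ],
                       groups, labels)
  counted <- cs[!is.na(cs$count), ]
  expect_true(all(abs(counted$percent -
                        round(100 * counted$count / counted$n, 1)) < 1e-9))
  overall <- cs[cs$cluster == "overall" & cs$variable == "age", ]
  expect_equal(overall$n, 300)
  expect_error(cohort_summary(ds$encounters, groups, labels[-1, ]),
               "unlabeled|Unlabeled|needs")
})

test_that("published feature counts reproduce the printed percentages", {
  pct <- summary_from_counts(ed_cohort_counts())
  get <- function(v, c) pct$percent[pct$variable == v & pct$cohort == c]
  expect_equal(get("substance_use_disorders", "overall"), 76.8)
  expect_equal(get("substance_use_disorders", "cluster_9"), 90.2)
  expect_equal(get("alcohol_related_disorders", "cluster_9"), 55.4)
  expect_equal(get("male", "overall"), 53.8)
  expect_equal(get("mood_disorders", "overall"), 59.3)
  # empty variable convention
  empty <- summary_from_counts(tibble::tibble(variable = c("n", "x"),
                                              g = c(50, 0)))
  expect_equal(empty$percent, 0)
})

test_that("cluster outcomes recover planted cluster-specific parameters", {
  ds <- simulate_ehr(sim_config(n_opioid = 1200, n_background = 0,
                                doc_length_mean = 10, seed = 29))
  labels <- tibble::tibble(encounter_id = names(ds$truth$cluster),
                           cluster = unname(ds$truth$cluster))
  co <- cluster_outcomes(ds$outcomes, ds$returns, ds$diagnoses, labels,
                         charlson_map = cmap)
  opar <- ds$truth$outcome_params
  for (cl in co$summary$cluster) {
    row <- co$summary[co$summary$cluster == cl, ]
    p <- opar[opar$cluster == cl, ]
    s_true <- exp(-365 * p$hazard)
    expect_lt(abs(row$survival_1yr - s_true),
              3 * sqrt(s_true * (1 - s_true) / row$n) + 1e-9)
    se <- sqrt(p$p_return12 * (1 - p$p_return12) / row$n)
    expect_lt(abs(row$return12 - p$p_return12), 3 * se)
  }
  expect_equal(nrow(co$logrank), choose(4, 2))
  expect_true(all(co$rate_flags$direction %in%
                    c("increased", "decreased", "neutral")))
  expect_true(all(co$summary$cci_mean >= 0))
  # single cluster: report equals whole-cohort metrics, no log-rank
  one <- cluster_outcomes(ds$outcomes, ds$returns, ds$diagnoses,
                          dplyr::mutate(labels, cluster = 1),
                          charlson_map = cmap)
  expect_equal(nrow(one$summary), 1)
  expect_null(one$logrank)
  km_all <- km_survival(
    as.integer(dplyr::coalesce(ds$outcomes$death_date, ds$outcomes$censor_date) -
                 ds$outcomes$discharge_date),
    as.integer(!is.na(ds$outcomes$death_date)))
  expect_equal(one$summary$survival_1yr, km_all$s_horizon, tolerance = 1e-12)
})

test_that("log-rank on equal-hazard clusters rejects at roughly the nominal rate", {
  set.seed(37)
  rejections <- 0
  for (r in 1:200) {
    time <- pmin(rexp(200, 1 / 500), 730)
    event <- as.integer(time < 730)
    cl <- rep(1:2, each = 100)
    sd <- survival::survdiff(survival::Surv(time, event) ~ cl)
    p <- stats::pchisq(sd$chisq, 1, lower.tail = FALSE)
    if (p < 0.05) rejections <- rejections + 1
  }
  expect_gt(rejections / 200, 0.004)
  expect_lt(rejections / 200, 0.1)
})
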