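#' Kaplan-Meier survival estimate
#'
#' Product-limit estimator via the survival package, with the usual
#' convention that censoring at a tied time is ordered after the events.
#'
#' @param times Days since discharge (>= 0).
#' @param events 1 = death observed, 0 = censored.
#' @param horizon Evaluation time in days (default 365).
#' @return List with `curve` (tibble `time`, `n_risk`, `n_event`,
#'   `survival`) and `s_horizon`, the estimated S(horizon).
#' @export
km_survival <- function(times, events, horizon = 365) {
  if (length(times) == 0) stop("no subjects", call. = FALSE)
  stopifnot(length(times) == length(events), all(times >= 0),
            all(events %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  curve <- tibble(time = fit$time, n_risk = fit$n.risk,
                  n_event = fit$n.event, survival = fit$surv)
  s <- summary(fit, times = horizon, extend = TRUE)$surv
  list(curve = curve, s_horizon = unname(s))
}

#' ED return rates within fixed windows
#'
#' Fraction of encounters with at least one qualifying return within
#' `(0, window]` days of discharge (boundary day inclusive), separately for
#' all-cause and opioid-related returns.
#'
#' @param outcomes Tibble with `encounter_id`, `discharge_date`.
#' @param returns Tibble with `encounter_id`, `return_date`,
#'   `opioid_related` (logical).
#' @param windows Integer vector of day windows; default `c(183, 365)`
#'   (6 and 12 months).
#' @return Tibble `window`, `all_cause_rate`, `opioid_rate`.
#' @export
return_rates <- function(outcomes, returns, windows = c(183L, 365L)) {
  n <- nrow(outcomes)
  joined <- returns %>%
    dplyr::inner_join(dplyr::select(outcomes, "encounter_id", "discharge_date"),
                      by = "encounter_id") %>%
    dplyr::mutate(days = as.integer(.data$return_date - .data$discharge_date)) %>%
    dplyr::filter(.data$days > 0)
  purrr::map_dfr(windows, function(w) {
    inw <- dplyr::filter(joined, .data$days <= w)
    tibble(
      window = as.integer(w),
      all_cause_rate = if (n == 0) 0 else
        dplyr::n_distinct(inw$encounter_id[!inw$opioid_related]) / n,
      opioid_rate = if (n == 0) 0 else
        dplyr::n_distinct(inw$encounter_id[inw$opioid_related]) / n
    )
  })
}

#' Outpatient medication prescription rates
#'
#' @param outcomes Tibble with logical columns `buprenorphine`, `methadone`,
#'   `naloxone`.
#' @return Tibble `drug`, `rate` (fraction of encounters with the flag set).
#' @export
medication_rates <- function(outcomes) {
  drugs <- c("buprenorphine", "methadone", "naloxone")
  tibble(drug = drugs,
         rate = unname(vapply(drugs, function(d) {
           if (nrow(outcomes) == 0) 0 else mean(outcomes[[d]])
         }, numeric(1))))
}

#' Relative risk of a variable in one cluster versus the rest
#'
#' RR = (a / n_c) / ((A - a) / (N - n_c)): the rate of the variable inside
#' the cluster divided by its rate among all remaining encounters. When no
#' one outside the cluster has the variable (A = a), the RR is `Inf`.
#'
#' @param a Encounters with the variable inside the cluster.
#' @param n_c Cluster size (> 0).
#' @param A Encounters with the variable overall (`A >= a`).
#' @param N Total encounters (`N > n_c`).
#' @return Scalar relative risk.
#' @export
relative_risk <- function(a, n_c, A, N) {
  if (n_c <= 0) stop("cluster size must be positive", call. = FALSE)
  if (N <= n_c) stop("N must exceed the cluster size", call. = FALSE)
  if (A < a) stop("A must be at least a", call. = FALSE)
  rest <- (A - a) / (N - n_c)
  if (rest == 0) {
    warning("variable absent outside the cluster; RR is infinite")
    return(Inf)
  }
  (a / n_c) / rest
}

#' Compare a cluster's rate against the remaining population
#'
#' Pearson chi-square on the 2x2 table (cluster vs rest, success vs
#' failure), no continuity correction. The direction flag is `"increased"`
#' when p < alpha and the cluster rate exceeds the rest, `"decreased"` when
#' p < alpha and it is lower, otherwise `"neutral"`.
#'
#' @param x_cluster,n_cluster Successes and size in the cluster.
#' @param x_rest,n_rest Successes and size in the remaining population.
#' @param alpha Significance level; default 0.05.
#' @return Tibble `statistic`, `p_value`, `direction`.
#' @export
rate_comparison <- function(x_cluster, n_cluster, x_rest, n_rest,
                            alpha = 0.05) {
  stopifnot(n_cluster > 0, n_rest > 0, x_cluster <= n_cluster, x_rest <= n_rest)
  m <- matrix(c(x_cluster, n_cluster - x_cluster,
                x_rest, n_rest - x_rest), nrow = 2, byrow = TRUE)
  if (any(colSums(m) == 0)) {
    warning("degenerate table (all successes or all failures); flag is neutral")
    return(tibble(statistic = NA_real_, p_value = NA_real_,
                  direction = "neutral"))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  p <- unname(ct$p.value)
  rc <- x_cluster / n_cluster
  rr <- x_rest / n_rest
  direction <- if (!is.na(p) && p < alpha && rc > rr) "increased"
    else if (!is.na(p) && p < alpha && rc < rr) "decreased"
    else "neutral"
  tibble(statistic = unname(ct$statistic), p_value = p, direction = direction)
}

#' Cluster-by-cluster cohort summary
#'
#' A feature-breakdown table in the style of published cluster reports:
#' per cluster and overall, the encounter count, median \[Q1, Q3\] age, and
#' count with percentage (to one decimal) for sex, insurance, race,
#' ethnicity, ESI, disposition and every diagnosis-group variable.
#'
#' @param encounters Encounters tibble (`encounter_id`, `age`, `sex`,
#'   `insurance`, `race`, `ethnicity`, `esi`, `disposition`).
#' @param diagnosis_groups Tibble `encounter_id`, `group` (binary variables:
#'   presence of each group), or NULL.
#' @param labels Tibble `encounter_id`, `cluster`; every encounter must be
#'   labelled.
#' @return Tibble of class `cohort_summary` in long form: `cluster`
#'   (`"overall"` or the cluster id), `variable`, `level`, `n`, `count`,
#'   `percent` (1 decimal), plus age rows with `median`, `q1`, `q3`.
#' @export
cohort_summary <- function(encounters, diagnosis_groups = NULL, labels) {
  missing_lab <- setdiff(encounters$encounter_id, labels$encounter_id)
  if (length(missing_lab)) {
    stop("unlabeled encounters: ", paste(head(missing_lab, 5), collapse = ", "),
         call. = FALSE)
  }
  df <- dplyr::inner_join(encounters, labels, by = "encounter_id") %>%
    dplyr::mutate(cluster = as.character(.data$cluster))
  groups <- c(list(overall = df),
              split(df, paste0("cluster_", df$cluster)))

  summarize_one <- function(d, name) {
    n <- nrow(d)
    age <- tibble(cluster = name, variable = "age", level = NA_character_,
                  n = n, count = NA_integer_, percent = NA_real_,
                  median = median(d$age), q1 = unname(quantile(d$age, 0.25)),
                  q3 = unname(quantile(d$age, 0.75)))
    cat_var <- function(var) {
      d %>%
        dplyr::count(level = as.character(.data[[var]]), name = "count") %>%
        dplyr::mutate(cluster = name, variable = var, n = n,
                      percent = prevalence_pct(.data$count, n),
                      median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    }
    cats <- purrr::map_dfr(c("sex", "insurance", "race", "ethnicity",
                             "esi", "disposition"), cat_var)
    dx <- NULL
    if (!is.null(diagnosis_groups)) {
      dx <- diagnosis_groups %>%
        dplyr::filter(.data$encounter_id %in% d$encounter_id) %>%
        dplyr::distinct(.data$encounter_id, .data$group) %>%
        dplyr::count(.data$group, name = "count") %>%
        dplyr::right_join(tibble(group = sort(unique(diagnosis_groups$group))),
                          by = "group") %>%
        tidyr::replace_na(list(count = 0L)) %>%
        dplyr::transmute(cluster = name, variable = .data$group,
                         level = "present", n = n, count = .data$count,
                         percent = prevalence_pct(.data$count, n),
                         median = NA_real_, q1 = NA_real_, q3 = NA_real_)
    }
    dplyr::bind_rows(age, cats, dx)
  }
  out <- purrr::imap_dfr(groups, summarize_one) %>%
    dplyr::select("cluster", "variable", "level", "n", "count", "percent",
                  "median", "q1", "q3")
  class(out) <- c("cohort_summary", class(out))
  out
}

#' Percentage to one decimal from a count and denominator
#'
#' The rounding convention used throughout cluster feature-breakdown tables.
#'
#' @param count,n Counts and denominator.
#' @return `round(100 * count / n, 1)`.
#' @export
prevalence_pct <- function(count, n) {
  round(100 * count / n, 1)
}

#' Recompute a feature-breakdown percentage table from printed counts
#'
#' Takes a counts table whose first column names the variable and whose
#' remaining columns are per-cohort counts, with an `"n"` row giving each
#' column's denominator, and recomputes every percentage to one decimal.
#' The package ships such a table from a published nine-cluster ED opioid
#' cohort at `extdata/ed_cohort_feature_counts.csv`.
#'
#' @param counts Tibble: column `variable`, then one numeric column per
#'   cohort; must contain a row with `variable == "n"`.
#' @return Long tibble `variable`, `cohort`, `count`, `n`, `percent`.
#' @export
summary_from_counts <- function(counts) {
  stopifnot("variable" %in% names(counts), "n" %in% counts$variable)
  n_vec <- unlist(counts[counts$variable == "n", -1])
  long <- counts %>%
    dplyr::filter(.data$variable != "n") %>%
    tidyr::pivot_longer(-"variable", names_to = "cohort", values_to = "count")
  long$n <- unname(n_vec[long$cohort])
  dplyr::mutate(long, percent = prevalence_pct(.data$count, .data$n))
}

#' Full per-cluster outcome profile
#'
#' Assembles, for every cluster: size, Kaplan-Meier one-year survival (and
#' the full curve), median and mean Charlson comorbidity index, 6- and
#' 12-month all-cause and opioid-related ED return rates, medication
#' prescription rates, and for each rate a chi-square comparison against the
#' remaining population with an increased/decreased/neutral flag. Pairwise
#' log-rank tests back between-cluster survival statements.
#'
#' @param outcomes Tibble with `encounter_id`, `discharge_date`,
#'   `death_date` (NA = alive), `censor_date`, logical `buprenorphine`,
#'   `methadone`, `naloxone`.
#' @param returns Tibble `encounter_id`, `return_date`, `opioid_related`.
#' @param diagnoses Tibble `encounter_id`, `code` for Charlson scoring.
#' @param labels Tibble `encounter_id`, `cluster`.
#' @param charlson_map A `charlson_map`.
#' @param horizon Survival evaluation day; default 365.
#' @param alpha Significance level for rate flags.
#' @return Object of class `cluster_outcomes`: `summary` tibble (one row per
#'   cluster), `rate_flags` (long tibble of per-rate comparisons),
#'   `km_curves`, `logrank` (pairwise tibble), `horizon`.
#' @export
cluster_outcomes <- function(outcomes, returns, diagnoses, labels,
                             charlson_map = read_charlson_map(),
                             horizon = 365, alpha = 0.05) {
  df <- dplyr::inner_join(outcomes, labels, by = "encounter_id")
  if (nrow(df) < nrow(outcomes)) {
    stop("every outcome record needs a cluster label", call. = FALSE)
  }
  df <- df %>%
    dplyr::mutate(
      event = as.integer(!is.na(.data$death_date)),
      time = as.integer(dplyr::if_else(.data$event == 1L,
                                       .data$death_date - .data$discharge_date,
                                       .data$censor_date - .data$discharge_date))
    )
  cci <- charlson_scores(diagnoses, charlson_map,
                         encounter_ids = df$encounter_id)
  df <- dplyr::left_join(df, cci, by = "encounter_id")
  clusters <- sort(unique(df$cluster))
  small <- table(df$cluster)
  if (any(small < 2)) {
    warning("clusters with < 2 subjects: ",
            paste(names(small)[small < 2], collapse = ", "))
  }

  per_cluster <- purrr::map_dfr(clusters, function(cl) {
    d <- df[df$cluster == cl, ]
    km <- km_survival(d$time, d$event, horizon = horizon)
    rr <- return_rates(d, returns)
    mr <- medication_rates(d)
    tibble(cluster = cl, n = nrow(d),
           survival_1yr = km$s_horizon,
           cci_median = median(d$cci), cci_mean = mean(d$cci),
           return6 = rr$all_cause_rate[rr$window == 183],
           return12 = rr$all_cause_rate[rr$window == 365],
           opioid_return6 = rr$opioid_rate[rr$window == 183],
           opioid_return12 = rr$opioid_rate[rr$window == 365],
           buprenorphine = mr$rate[mr$drug == "buprenorphine"],
           methadone = mr$rate[mr$drug == "methadone"],
           naloxone = mr$rate[mr$drug == "naloxone"])
  })

  # chi-square flags vs the remaining population, per rate variable
  rate_vars <- c("return6", "return12", "opioid_return6", "opioid_return12",
                 "buprenorphine", "methadone", "naloxone")
  N <- nrow(df)
  rate_flags <- purrr::map_dfr(clusters, function(cl) {
    row <- per_cluster[per_cluster$cluster == cl, ]
    purrr::map_dfr(rate_vars, function(v) {
      if (length(clusters) < 2) { # no remaining population to compare with
        cmp <- tibble(statistic = NA_real_, p_value = NA_real_,
                      direction = "neutral")
      } else {
        a <- round(row[[v]] * row$n)
        tot <- round(sum(per_cluster[[v]] * per_cluster$n))
        cmp <- rate_comparison(a, row$n, tot - a, N - row$n, alpha = alpha)
      }
      dplyr::mutate(cmp, cluster = cl, variable = v, rate = row[[v]],
                    .before = 1)
    })
  })

  km_curves <- purrr::map_dfr(clusters, function(cl) {
    d <- df[df$cluster == cl, ]
    dplyr::mutate(km_survival(d$time, d$event, horizon = horizon)$curve,
                  cluster = cl, .before = 1)
  })

  logrank <- NULL
  if (length(clusters) >= 2) {
    pairs <- utils::combn(clusters, 2)
    logrank <- purrr::map_dfr(seq_len(ncol(pairs)), function(j) {
      a <- pairs[1, j]; b <- pairs[2, j]
      d <- df[df$cluster %in% c(a, b), ]
      sd <- survival::survdiff(survival::Surv(time, event) ~ cluster, data = d)
      p <- stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE)
      tibble(cluster_a = a, cluster_b = b, chisq = unname(sd$chisq), p_value = p)
    })
  }

  structure(list(summary = per_cluster, rate_flags = rate_flags,
                 km_curves = km_curves, logrank = logrank,
                 horizon = horizon, alpha = alpha),
            class = "cluster_outcomes")
}

#' @export
print.cluster_outcomes <- function(x, ...) {
  cat("<cluster_outcomes>", nrow(x$summary), "clusters; survival at day",
      x$horizon, "\n")
  print(x$summary)
  invisible(x)
}
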