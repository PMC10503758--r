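test_that("lab reference uses the n-1 sample standard deviation", {
  ref <- compute_lab_reference(tibble::tibble(lab = "x", value = c(8, 10, 12)))
  expect_equal(ref$mean, 10)
  expect_equal(ref$sd, 2)
  expect_warning(
    ref1 <- compute_lab_reference(tibble::tibble(lab = "y", value = 5)),
    "single")
  expect_equal(ref1$sd, 0)
  expect_error(compute_lab_reference(tibble::tibble(lab = character(),
                                                    value = numeric())),
               "empty")
})

test_that("lab modifier tokens fire strictly beyond two SDs", {
  ref <- compute_lab_reference(
    tibble::tibble(lab = "pao2", value = c(80, 90, 100)))
  ref$mean <- 90; ref$sd <- 10 # round reference for the worked example
  tok <- function(v) structured_tokens(labs = tibble::tibble(lab = "pao2", value = v),
                                       lab_reference = ref)
  expect_setequal(tok(60), c("pao2", "low pao2"))
  expect_setequal(tok(90), "pao2")
  expect_setequal(tok(110), "pao2")  # exactly mean + 2 SD: no modifier
  expect_setequal(tok(110.01), c("pao2", "high pao2"))
  expect_error(tok2 <- structured_tokens(
    labs = tibble::tibble(lab = "mystery", value = 1), lab_reference = ref),
    "missing from the reference")
  ref0 <- ref; ref0$sd <- 0
  expect_warning(t0 <- structured_tokens(labs = tibble::tibble(lab = "pao2", value = 999),
                                         lab_reference = ref0), "sd = 0")
  expect_setequal(t0, "pao2")
})

test_that("encounter bags are multiset unions of notes and structured tokens", {
  bag <- combine_encounter_tokens(
    note_tokens = list(c("a", "a"), c("a", "b")),
    structured = "c", encounter_id = "E1")
  expect_equal(dplyr::arrange(bag, token)$count, c(3L, 1L, 1L))
  bag2 <- combine_encounter_tokens(structured = c("c", "c"), encounter_id = "E2")
  expect_equal(bag2$count, 2L)
  # count conservation across multiple notes
  notes <- list(letters[1:5], letters[3:9], letters[1:2])
  bag3 <- combine_encounter_tokens(notes, character(), "E3")
  expect_equal(sum(bag3$count), sum(lengths(notes)))
})

test_that("frequency filter removes only tokens ubiquitous in BOTH cohorts", {
  op <- bags_with_docfreq(100, c(both6 = 6, op6 = 6, edge5 = 5), prefix = "o")
  bg <- bags_with_docfreq(100, c(both6 = 6, op6 = 2, edge5 = 5), prefix = "b")
  removed <- frequency_filter(op, bg, threshold = 0.05)
  expect_true("both6" %in% removed)     # > 5% in both
  expect_false("op6" %in% removed)      # > 5% in one cohort only
  expect_false("edge5" %in% removed)    # exactly 5%: strict inequality
  expect_true("anchor" %in% removed)    # 100% in both
  expect_error(frequency_filter(op, bg, threshold = 0), "threshold")
  expect_error(frequency_filter(op, bg, threshold = 1), "threshold")
})

test_that("keep-word chi-square matches the closed form and keeps p < alpha", {
  op <- bags_with_docfreq(100, c(hot = 30, flat = 20), prefix = "o")
  bg <- bags_with_docfreq(100, c(hot = 10, flat = 20), prefix = "b")
  dec <- chisq_keep_words(op, bg, removed = "anchor")
  hot <- dec[dec$token == "hot", ]
  expect_equal(hot$statistic, 12.5, tolerance = 1e-12)
  expect_equal(hot$p_value, pchisq(12.5, 1, lower.tail = FALSE), tolerance = 1e-12)
  expect_true(hot$keep)
  flat <- dec[dec$token == "flat", ]
  expect_equal(flat$statistic, 0, tolerance = 1e-12)
  expect_equal(flat$p_value, 1)
  expect_false(flat$keep)
  anchor <- dec[dec$token == "anchor", ]
  expect_true(anchor$removed_by_frequency)
  expect_false(anchor$keep)
  # invariant: keep implies survived the filter and significant
  expect_true(all(!dec$keep | (!dec$removed_by_frequency & dec$p_value < 0.05)))
})

test_that("keep-word statistics equal the expected-counts oracle on a 50-token fixture", {
  set.seed(7)
  n_op <- 120; n_bg <- 140
  toks <- sprintf("t%02d", 1:50)
  present <- stats::setNames(sample(1:60, 50, replace = TRUE), toks)
  present_bg <- stats::setNames(sample(1:60, 50, replace = TRUE), toks)
  op <- bags_with_docfreq(n_op, present, prefix = "o")
  bg <- bags_with_docfreq(n_bg, present_bg, prefix = "b")
  dec <- chisq_keep_words(op, bg, removed = character())
  for (tok in toks) {
    a <- present[[tok]]; b <- present_bg[[tok]]
    m <- matrix(c(a, n_op - a, b, n_bg - b), 2, byrow = TRUE)
    o <- oracle_chisq(m)
    row <- dec[dec$token == tok, ]
    expect_equal(row$statistic, o$statistic, tolerance = 1e-10)
    expect_equal(row$p_value, o$p_value, tolerance = 1e-10)
  }
})

test_that("vocabulary decisions are invariant to encounter ordering", {
  set.seed(11)
  op <- bags_with_docfreq(50, c(x = 20, y = 5, z = 40), prefix = "o")
  bg <- bags_with_docfreq(50, c(x = 5, y = 5, z = 38), prefix = "b")
  shuffle <- function(df) df[sample(nrow(df)), ]
  d1 <- chisq_keep_words(op, bg)
  d2 <- chisq_keep_words(shuffle(op), shuffle(bg))
  expect_equal(d1, d2)
  expect_equal(frequency_filter(op, bg), frequency_filter(shuffle(op), shuffle(bg)))
})

test_that("corpus restriction keeps empty encounters flagged and conserves counts", {
  bags <- make_bags(list(E1 = c(a = 3, b = 1), E2 = c(b = 2), E3 = c(c = 4)))
  corpus <- build_corpus(bags, keep = c("a", "b"),
                         encounter_ids = c("E1", "E2", "E3", "E4"))
  expect_s3_class(corpus, "tf_corpus")
  expect_equal(corpus$vocabulary, c("a", "b"))
  expect_setequal(corpus$empty_encounters, c("E3", "E4"))
  expect_equal(sum(corpus$counts$count), 3 + 1 + 2)
  expect_equal(corpus$counts$count[corpus$counts$encounter_id == "E1" &
                                     corpus$counts$token == "a"], 3L)
  expect_error(build_corpus(bags, keep = character()), "empty")
})
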