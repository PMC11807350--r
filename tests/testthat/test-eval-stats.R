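test_that("micro metrics pool decisions over sentences and labels", {
  m <- micro_prf(list("A", c("A", "B")), list("A", "B"))
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 2 / 3)
  expect_equal(m$f1, 0.8)

  perfect <- micro_prf(list(c("A", "B"), "C"), list(c("A", "B"), "C"))
  expect_equal(c(perfect$precision, perfect$recall, perfect$f1), c(1, 1, 1))

  none <- micro_prf(list("A"), list(character(0)))
  expect_true(none$undefined_precision)
  expect_equal(none$precision, 0)
  expect_error(micro_prf(list(character(0)), list(character(0))), "no gold")

  # micro P equals micro R when predicted and gold label counts match
  set.seed(13)
  for (i in 1:20) {
    gold <- random_label_sets(30, LETTERS[1:4], allow_empty = FALSE)
    pred <- gold[sample(30)]   # permuted: same total count
    m <- micro_prf(gold, pred)
    expect_equal(m$precision, m$recall, tolerance = 1e-12)
  }
})

test_that("macro metrics average per-label scores", {
  # two labels, F1 1 and 0 -> macro 0.5
  m <- macro_prf(list("A", "B"), list("A", "C"))
  expect_equal(m$f1, mean(c(1, 0, 0)))   # labels A, B, C observed
  m2 <- macro_prf(list("A", "A"), list("A", "A"))
  expect_equal(m2$f1, micro_prf(list("A", "A"), list("A", "A"))$f1)
  # labels absent everywhere are excluded and flagged
  m3 <- macro_prf(list("A"), list("A"), labels = c("A", "Z"))
  expect_identical(m3$excluded_labels, "Z")
})

test_that("micro and macro match brute-force oracles on random fixtures", {
  set.seed(41)
  for (rep in 1:40) {
    gold <- random_label_sets(25, LETTERS[1:5], allow_empty = FALSE)
    pred <- random_label_sets(25, LETTERS[1:5], allow_empty = TRUE)
    m <- micro_prf(gold, pred)
    o <- oracle_micro(gold, pred)
    expect_equal(m$precision, o$precision, tolerance = 1e-10)
    expect_equal(m$recall, o$recall, tolerance = 1e-10)
    expect_equal(m$f1, o$f1, tolerance = 1e-10)
    mm <- macro_prf(gold, pred)
    oo <- oracle_macro(gold, pred)
    expect_equal(mm$f1, oo$f1, tolerance = 1e-10)
    expect_equal(mm$precision, oo$precision, tolerance = 1e-10)
  }
})

test_that("McNemar handles discordant counts, exact mode and symmetry", {
  even <- mcnemar_test(b = 7, c = 7, exact_below = 0)
  expect_equal(even$statistic, 0)
  expect_equal(even$p_value, 1)

  m <- mcnemar_test(b = 10, c = 2, exact_below = 0)
  expect_equal(m$statistic, 16 / 3, tolerance = 1e-10)
  expect_equal(round(m$p_value, 4), 0.0209)
  ref <- stats::mcnemar.test(matrix(c(5, 10, 2, 5), 2, 2, byrow = TRUE),
                             correct = FALSE)
  expect_equal(m$statistic, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(m$p_value, ref$p.value, tolerance = 1e-10)

  # exact two-sided binomial below the cut-off
  ex <- mcnemar_test(b = 3, c = 1)
  expect_identical(ex$method, "exact-binomial")
  expect_equal(ex$p_value, stats::binom.test(3, 4, 0.5)$p.value,
               tolerance = 1e-12)

  zero <- mcnemar_test(b = 0, c = 0)
  expect_equal(zero$statistic, 0)
  expect_equal(zero$p_value, 1)

  # swapping the two systems leaves the statistic unchanged
  a <- c(TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  b <- c(TRUE, FALSE, TRUE, TRUE, FALSE, FALSE)
  m1 <- mcnemar_test(a, b, exact_below = 0)
  m2 <- mcnemar_test(b, a, exact_below = 0)
  expect_equal(m1$statistic, m2$statistic)
  expect_identical(c(m1$b, m1$c), c(m2$c, m2$b))
})

test_that("Bhapkar reduces to the McNemar identity on 2x2 tables", {
  tab <- matrix(c(10, 10, 2, 8), 2, 2, byrow = TRUE)
  bh <- bhapkar_test(table = tab)
  M <- (10 - 2)^2 / 12
  expect_equal(bh$statistic, M / (1 - M / 30), tolerance = 1e-10)
  expect_equal(bh$df, 1L)

  sym <- bhapkar_test(table = matrix(c(4, 3, 3, 5), 2, 2))
  expect_equal(sym$statistic, 0)
  expect_equal(sym$p_value, 1)

  # never below the uncorrected McNemar statistic on the same table
  set.seed(17)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 8) + 1, 2, 2)
    bh <- bhapkar_test(table = t2)
    M <- (t2[1, 2] - t2[2, 1])^2 / (t2[1, 2] + t2[2, 1])
    expect_gte(bh$statistic + 1e-10, M)
  }
})

test_that("Bhapkar matches the delta-method oracle on random tables", {
  set.seed(59)
  for (rep in 1:40) {
    k <- sample(3:4, 1)
    tab <- matrix(rpois(k * k, 6) + 1, k, k)
    bh <- bhapkar_test(table = tab)
    if (bh$df < k - 1) next
    expect_equal(bh$statistic, oracle_bhapkar(tab), tolerance = 1e-8)
    expect_equal(bh$p_value,
                 stats::pchisq(bh$statistic, k - 1, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
})

test_that("composite classes encode multi-label sets canonically", {
  expect_identical(composite_class(c("B", "A")), "A|B")
  expect_identical(composite_class(character(0)), "<empty>")
  a <- c("A|B", "A", "<empty>", "A")
  b <- c("A", "A|B", "A", "<empty>")
  bh <- bhapkar_test(a, b)
  expect_true(is.finite(bh$statistic))
  expect_equal(bh$df, 2L)
})

test_that("run aggregation reports mean and sample SD", {
  r <- aggregate_runs(rep(0.7, 5))
  expect_equal(r$mean, 0.7)
  expect_equal(r$sd, 0)
  r2 <- aggregate_runs(c(0.6, 0.8))
  expect_equal(r2$mean, 0.7)
  expect_equal(r2$sd, sqrt(0.02), tolerance = 1e-12)   # ~0.1414
  r1 <- aggregate_runs(0.5)
  expect_false(r1$sd_defined)
  expect_error(aggregate_runs(numeric(0)), "no runs")
})

test_that("corpus profiling counts types once per document", {
  fx <- fixture_models()
  corpus <- fixture_corpus()
  prof <- profile_corpus(corpus$articles, fx$binary, fx$type, fx$thresholds)
  expect_s3_class(prof, "sal_corpus_profile")
  expect_equal(prof$n_articles, length(corpus$articles))
  expect_true(all(prof$per_type$document_count <= prof$n_articles))
  expect_true(all(prof$per_type$document_pct <= 100))
  expect_equal(sum(prof$per_type$sentence_pct), 100, tolerance = 1e-9)
  expect_equal(nrow(prof$per_article), prof$n_articles)
  # per-article means come with finite t-based confidence bounds
  expect_true(all(is.finite(prof$means)))
  expect_true(prof$means["sal_sentences_per_article", "lo"] <=
                prof$means["sal_sentences_per_article", "mean"])
  # article order does not change document-level counts
  prof2 <- profile_corpus(rev(corpus$articles), fx$binary, fx$type,
                          fx$thresholds)
  m1 <- prof$per_type[order(prof$per_type$type), ]
  m2 <- prof2$per_type[order(prof2$per_type$type), ]
  expect_equal(m1$document_count, m2$document_count)
  expect_error(profile_corpus(list(), fx$binary, fx$type, fx$thresholds),
               "empty corpus")
})
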