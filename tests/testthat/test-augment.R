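mk_train <- function(counts, multi = NULL) {
  # build a minimal SAL training set: `counts` single-label sentences per
  # class, plus optional multi-label rows given as list of label vectors
  rows <- list()
  for (cl in names(counts)) {
    for (i in seq_len(counts[[cl]])) {
      rows[[length(rows) + 1L]] <- list(labs = cl)
    }
  }
  for (m in multi) rows[[length(rows) + 1L]] <- list(labs = m)
  n <- length(rows)
  out <- data.frame(
    article_id = paste0("T", seq_len(n)), section_index = 1L,
    char_start = 0L, char_end = 10L,
    text = vapply(seq_len(n), function(i) {
      paste("Sentence", i, "cues", paste(rows[[i]]$labs, collapse = " "))
    }, character(1)),
    top_header = "Discussion", innermost_header = "", is_sal = TRUE,
    stringsAsFactors = FALSE)
  out$types_top <- lapply(rows, function(r) sort(coarsen(r$labs)))
  out$types_fine <- lapply(rows, function(r) sort(r$labs))
  out
}

test_that("augmentation plans implement deficit and eligibility rules", {
  train <- mk_train(c(Population = 64, Blinding = 79),
                    multi = list(c("Funding", "Population"),
                                 c("Funding", "Blinding"),
                                 c("Funding", "Setting")))
  plan <- build_plan(train, target = 70)
  p <- function(cl, col) plan[[col]][plan$class == cl]
  expect_equal(p("Population", "deficit"), 5L)   # n = 64 + 1 multi
  expect_equal(p("Blinding", "deficit"), 0L)     # n = 80
  expect_false(p("Funding", "eligible"))
  # multi-label sentences count for class size but not as seeds
  expect_equal(p("Population", "n_seeds"), 64L)
  expect_equal(p("Population", "n"), 65L)
  # class whose only examples are multi-label: deficit recorded, no seeds
  expect_equal(p("Setting", "n_seeds"), 0L)
  expect_gt(p("Setting", "deficit"), 0L)
  expect_error(build_plan(train[0, ]), "empty")
})

test_that("oversampling duplicates minority originals up to the target", {
  train <- mk_train(c(Population = 60, Blinding = 70))
  plan <- build_plan(train, target = 70)
  aug <- oversample(train, plan, seed = 3)
  counts <- table(unlist(aug$types_top))
  expect_equal(unname(counts["Population"]), 70L)
  expect_equal(unname(counts["Blinding"]), 70L)   # at target: unchanged
  expect_equal(sum(aug$provenance == "original"), nrow(train))
  # duplicates are byte-identical to originals of the same class
  dups <- aug[aug$provenance == "oversample", ]
  for (i in seq_len(nrow(dups))) {
    expect_true(dups$text[i] %in% train$text)
  }
  # deterministic
  expect_identical(oversample(train, plan, seed = 3)$text, aug$text)
})

test_that("EDA operators respect the degenerate-case conventions", {
  # deletion at rate 1 keeps exactly one word
  v <- eda_variants("the sample was small", "UnderpoweredStudy",
                    n_variants = 30, rate = 1, seed = 2)
  del <- v$text[vapply(strsplit(v$text, " "), length, 1L) == 1L]
  expect_gt(length(del), 0L)
  expect_true(all(lengths(strsplit(v$text, " ")) >= 1L))
  # swap on a two-word sentence reverses it
  set.seed(1)
  sw <- replicate(40, {
    x <- eda_variants("sample small", "UnderpoweredStudy", 1, rate = 0.5,
                      seed = sample.int(1e6, 1))$text
    x
  })
  expect_true("small sample" %in% sw)
  # determinism and label preservation
  a <- eda_variants("the sample was small", "UnderpoweredStudy", 5, seed = 7)
  b <- eda_variants("the sample was small", "UnderpoweredStudy", 5, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$intended_label == "UnderpoweredStudy"))
  expect_true(all(a$view == "eda"))
})

test_that("synonym replacement preserves word count", {
  set.seed(8)
  for (i in 1:40) {
    v <- eda_variants("the small sample limited the study power",
                      "UnderpoweredStudy", 1, rate = 0.3,
                      seed = sample.int(1e6, 1))
    n_words <- length(strsplit(v$text, " ")[[1]])
    expect_true(n_words >= 1L && n_words <= 9L)
  }
})

test_that("RAKE scores phrases by summed degree/frequency", {
  kw <- rake_keywords("small sample size limited the statistical power",
                      stopwords = "the")
  expect_identical(kw$phrase, c("small sample size limited",
                                "statistical power"))
  expect_equal(kw$score, c(16, 4))

  one <- rake_keywords("power", stopwords = "the")
  expect_identical(one$phrase, "power")
  expect_equal(one$score, 1)

  expect_equal(nrow(rake_keywords("")), 0L)
  expect_equal(nrow(rake_keywords("the and of", stopwords = c("the", "and", "of"))), 0L)

  # repeated words accumulate degree over phrases
  kw2 <- rake_keywords("sample size, sample quality", stopwords = "the")
  w_sample_score <- 4 / 2   # degree 2+2, freq 2
  expect_equal(kw2$score[kw2$phrase == "sample size"], w_sample_score + 2)
})

test_that("dual-view generation honours the generator contract", {
  seed_sample <- list(text = "the small sample size limited power",
                      label = "UnderpoweredStudy", sentence_id = "s1")
  gen <- template_generator()
  out <- generate_dual_view(seed_sample, gen, n_per_seed = 10,
                            view = "output_view", seed = 3)
  expect_equal(nrow(out), 10L)
  expect_true(all(nzchar(out$text)))
  expect_true(all(out$intended_label == "UnderpoweredStudy"))
  # reproducible under the seed
  out2 <- generate_dual_view(seed_sample, gen, n_per_seed = 10,
                             view = "output_view", seed = 3)
  expect_identical(out, out2)

  # the output-view prompt carries the label name, not the seed text
  seen <- NULL
  probe <- function(prompt, n, seed) {
    seen <<- prompt
    rep("x", n)
  }
  generate_dual_view(seed_sample, probe, 4, "output_view", seed = 1)
  expect_identical(seen$label, "UnderpoweredStudy")
  expect_null(seen$keywords)
  generate_dual_view(seed_sample, probe, 4, "input_view", seed = 1)
  expect_true(length(seen$keywords) > 0)
  expect_false(seed_sample$text %in% seen$keywords)

  # wrong-count generators violate the contract
  bad <- function(prompt, n, seed) rep("x", n - 1)
  expect_error(generate_dual_view(seed_sample, bad, 5, "output_view"),
               "contract")
  multi <- list(text = "t", label = c("A", "B"))
  expect_error(generate_dual_view(multi, gen, 5, "output_view"),
               "exactly one label")
})

test_that("consistency filtering keeps label-consistent candidates exactly", {
  cand <- data.frame(
    text = c("about funding", "about the sample", "about blinding"),
    intended_label = c("Funding", "UnderpoweredStudy", "Blinding"),
    view = "output_view", seed_sentence_id = NA, kept_by_filter = NA,
    stringsAsFactors = FALSE)
  oracle <- function(text) {
    cand$intended_label[match(text, cand$text)]
  }
  expect_equal(nrow(consistency_filter(cand, oracle)), 3L)

  always_pop <- function(text) "Population"
  expect_equal(nrow(consistency_filter(cand, always_pop)), 0L)
  cand2 <- cand
  cand2$intended_label[2] <- "Population"
  kept <- consistency_filter(cand2, always_pop)
  expect_identical(kept$text, "about the sample")

  # keyword filter equals its own brute-force evaluation
  kw_filter <- function(text) {
    if (grepl("funding", text)) "Funding" else "Other"
  }
  kept2 <- consistency_filter(cand, kw_filter, return_all = TRUE)
  brute <- vapply(cand$text, kw_filter, "") == cand$intended_label
  expect_identical(kept2$kept_by_filter, unname(brute))
})

test_that("balancing fills deficits from the pool without fabrication", {
  train <- mk_train(c(Population = 12, Blinding = 75))
  plan <- build_plan(train, target = 70)
  pool <- data.frame(
    text = paste("synthetic population sentence", 1:120),
    intended_label = "Population", view = "output_view",
    seed_sentence_id = NA, kept_by_filter = TRUE, stringsAsFactors = FALSE)
  aug <- balance(train, plan, pool, seed = 5)
  counts <- table(unlist(aug$types_top))
  expect_equal(unname(counts["Population"]), 70L)   # 12 + 58
  expect_equal(sum(aug$provenance != "original"), 58L)
  # originals untouched
  expect_identical(aug$text[seq_len(nrow(train))], train$text)
  # deterministic
  expect_identical(balance(train, plan, pool, seed = 5)$text, aug$text)
  # short pool: everything taken, with a warning, nothing fabricated
  expect_warning(aug2 <- balance(train, plan, pool[1:30, ], seed = 5),
                 "shortfall")
  expect_equal(sum(aug2$provenance != "original"), 30L)
})
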