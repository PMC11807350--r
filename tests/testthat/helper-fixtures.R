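# Shared fixtures, built once per test run and memoized. All corpora are
# generated in code; nothing is read from disk.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixture_env)) {
    assign(key, force(expr), envir = .fixture_env)
  }
  get(key, envir = .fixture_env)
}

# medium corpus with the default (long-tailed) label distribution
fixture_corpus <- function() {
  memo("corpus60", generate_corpus(synth_config(n_articles = 60, seed = 7)))
}

# larger corpus for pipeline-scale checks
fixture_corpus200 <- function() {
  memo("corpus200", generate_corpus(synth_config(n_articles = 200, seed = 7)))
}

# uniform label distribution: every class has ample single-label seeds
fixture_uniform_corpus <- function() {
  memo("uniform200", {
    u <- stats::setNames(rep(1 / 15, 15), load_taxonomy()$top)
    generate_corpus(synth_config(n_articles = 200, seed = 11,
                                 label_distribution = u))
  })
}

fixture_split_sentences <- function() {
  memo("split60", {
    corpus <- fixture_corpus()
    split <- split_corpus(corpus$articles, seed = 1)
    ids <- lapply(split, function(a) sapply(a, function(x) x$article_id))
    s <- corpus$sentences
    list(train = s[s$article_id %in% ids$train, ],
         dev = s[s$article_id %in% ids$dev, ],
         test = s[s$article_id %in% ids$test, ])
  })
}

fixture_models <- function() {
  memo("models60", {
    parts <- fixture_split_sentences()
    cfg <- train_config(seed = 42)
    bm <- train_binary(parts$train, config = cfg)
    train_sal <- parts$train[parts$train$is_sal, ]
    tm <- train_type(train_sal, granularity = "top", config = cfg)
    dev_sal <- parts$dev[parts$dev$is_sal, ]
    thr <- suppressWarnings(
      fit_thresholds(predict_type_probs(tm, dev_sal), dev_sal$types_top))
    list(binary = bm, type = tm, thresholds = thr, parts = parts)
  })
}
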