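#' Run the full SAL pipeline end-to-end on a corpus
#'
#' Executes the two-stage protocol on a corpus with gold labels: split the
#' articles 120/40/40-style at the article level, train the binary SAL
#' sentence classifier on the training split, train the multi-label type
#' classifier on the training split's SAL sentences (optionally after
#' class-balancing augmentation), fit per-label thresholds on the
#' development split, evaluate both stages on the test split, and profile
#' the whole corpus. Deterministic for a fixed config and seed.
#'
#' @param corpus A `sal_corpus` from [generate_corpus()], or any list of
#'   `sal_article`s together with gold labeled sentences in
#'   `corpus$sentences`.
#' @param config A [train_config()].
#' @param granularity Label granularity for the type task.
#' @param augmentation `"none"`, `"oversample"`, `"eda"`,
#'   `"dual-output"` (Output View, unfiltered — the recommended preset),
#'   `"dual-input"`, or `"dual-filtered"` (both views plus consistency
#'   filtering against a classifier trained on the original data).
#' @param ratios Article-level split ratios.
#' @param seed Seed for splitting and augmentation draws.
#' @param target Augmentation target class size.
#' @param n_per_seed Dual-view candidates per seed sentence.
#' @param apply_funding_rule Supplement type predictions with the Funding
#'   rule?
#' @param taxonomy A `sal_taxonomy`.
#' @return List of class `sal_pipeline_result` with the trained models,
#'   thresholds, split sizes, binary and type evaluation on the test
#'   split, and the corpus profile.
#' @export
run_end_to_end <- function(corpus, config = train_config(),
                           granularity = c("top", "fine"),
                           augmentation = c("none", "oversample", "eda",
                                            "dual-output", "dual-input",
                                            "dual-filtered"),
                           ratios = c(0.6, 0.2, 0.2), seed = 1L,
                           target = 70L, n_per_seed = 10L,
                           apply_funding_rule = TRUE,
                           taxonomy = load_taxonomy()) {
  granularity <- match.arg(granularity)
  augmentation <- match.arg(augmentation)
  split <- split_corpus(corpus$articles, ratios = ratios, seed = seed)
  ids <- lapply(split, function(arts) {
    vapply(arts, function(a) a$article_id, character(1))
  })
  sent <- corpus$sentences
  part <- function(which) sent[sent$article_id %in% ids[[which]], , drop = FALSE]
  train_s <- part("train"); dev_s <- part("dev"); test_s <- part("test")

  sentence_model <- train_binary(train_s, config = config)

  train_sal <- train_s[train_s$is_sal, , drop = FALSE]
  train_aug <- augment_training_set(train_sal, augmentation,
                                    granularity = granularity,
                                    config = config, seed = seed,
                                    target = target,
                                    n_per_seed = n_per_seed,
                                    taxonomy = taxonomy)
  type_model <- train_type(train_aug, granularity = granularity,
                           config = config, taxonomy = taxonomy)

  dev_sal <- dev_s[dev_s$is_sal, , drop = FALSE]
  gold_col <- if (granularity == "top") "types_top" else "types_fine"
  dev_probs <- predict_type_probs(type_model, dev_sal)
  thresholds <- fit_thresholds(dev_probs, dev_sal[[gold_col]])

  sal_pred <- predict_sal(sentence_model, test_s)
  binary_eval <- evaluate_binary(test_s$is_sal, sal_pred$is_sal)
  test_sal <- test_s[test_s$is_sal, , drop = FALSE]
  type_pred <- if (apply_funding_rule) {
    predict_with_rules(type_model, thresholds, test_sal)
  } else {
    predict_types(type_model, thresholds, test_sal)
  }
  type_eval <- list(micro = micro_prf(test_sal[[gold_col]], type_pred),
                    macro = macro_prf(test_sal[[gold_col]], type_pred))
  profile <- profile_corpus(corpus$articles, sentence_model, type_model,
                            thresholds,
                            apply_funding_rule = apply_funding_rule)
  structure(list(sentence_model = sentence_model, type_model = type_model,
                 thresholds = thresholds,
                 split_sizes = lengths(split), split_ids = ids,
                 binary_eval = binary_eval, type_eval = type_eval,
                 type_predictions = type_pred, test_gold = test_sal[[gold_col]],
                 profile = profile, granularity = granularity,
                 augmentation = augmentation, seed = seed,
                 taxonomy_version = taxonomy$version),
            class = "sal_pipeline_result")
}

#' Apply one augmentation preset to a SAL training set
#'
#' @param train_sal Labeled SAL sentence data frame.
#' @param method Augmentation preset (see [run_end_to_end()]).
#' @param granularity Label granularity.
#' @param config Training config (used for the filter classifier).
#' @param seed Integer seed.
#' @param target Target class size.
#' @param n_per_seed Dual-view candidates per seed.
#' @param taxonomy A `sal_taxonomy`.
#' @return The (possibly) augmented training set.
#' @export
augment_training_set <- function(train_sal, method = "none",
                                 granularity = "top",
                                 config = train_config(), seed = 1L,
                                 target = 70L, n_per_seed = 10L,
                                 taxonomy = load_taxonomy()) {
  if (method == "none") return(train_sal)
  plan <- build_plan(train_sal, target = target, granularity = granularity,
                     taxonomy = taxonomy)
  if (method == "oversample") return(oversample(train_sal, plan, seed = seed))
  gold_col <- if (granularity == "top") "types_top" else "types_fine"
  if (method == "eda") {
    pool <- list()
    for (r in seq_len(nrow(plan))) {
      if (!plan$eligible[r] || plan$deficit[r] == 0L) next
      idx <- .seed_indices(train_sal, plan, plan$class[r])
      for (i in idx) {
        pool[[length(pool) + 1L]] <- eda_variants(
          train_sal$text[i], plan$class[r],
          n_variants = n_per_seed, seed = seed + i,
          seed_sentence_id = as.character(i))
      }
    }
    pool <- if (length(pool)) do.call(rbind, pool) else
      data.frame(text = character(0), intended_label = character(0),
                 view = character(0), seed_sentence_id = character(0),
                 kept_by_filter = logical(0))
    return(balance(train_sal, plan, pool, seed = seed, taxonomy = taxonomy))
  }
  # dual-view presets
  gen <- template_generator(taxonomy)
  views <- switch(method,
                  "dual-output" = "output_view",
                  "dual-input" = "input_view",
                  "dual-filtered" = c("input_view", "output_view"))
  pool <- list()
  for (r in seq_len(nrow(plan))) {
    if (!plan$eligible[r] || plan$deficit[r] == 0L) next
    idx <- .seed_indices(train_sal, plan, plan$class[r])
    for (i in idx) {
      seed_sample <- list(text = train_sal$text[i], label = plan$class[r],
                          sentence_id = as.character(i))
      for (v in views) {
        pool[[length(pool) + 1L]] <- generate_dual_view(
          seed_sample, gen, n_per_seed = n_per_seed, view = v,
          seed = seed + i)
      }
    }
  }
  pool <- if (length(pool)) do.call(rbind, pool) else
    data.frame(text = character(0), intended_label = character(0),
               view = character(0), seed_sentence_id = character(0),
               kept_by_filter = logical(0))
  if (method == "dual-filtered" && nrow(pool) > 0L) {
    filter_model <- train_type(train_sal, granularity = granularity,
                               config = config, taxonomy = taxonomy)
    pool <- consistency_filter(pool, classifier_filter(filter_model))
  }
  balance(train_sal, plan, pool, seed = seed, taxonomy = taxonomy)
}

#' @export
print.sal_pipeline_result <- function(x, ...) {
  cat("SAL pipeline result (granularity ", x$granularity,
      ", augmentation ", x$augmentation, ")\n", sep = "")
  cat("Split sizes:", paste(x$split_sizes, collapse = "/"), "\n")
  cat(sprintf("Sentence stage  P=%.3f R=%.3f F1=%.3f acc=%.3f\n",
              x$binary_eval$precision, x$binary_eval$recall,
              x$binary_eval$f1, x$binary_eval$accuracy))
  cat(sprintf("Type stage      micro P=%.3f R=%.3f F1=%.3f\n",
              x$type_eval$micro$precision, x$type_eval$micro$recall,
              x$type_eval$micro$f1))
  invisible(x)
}
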