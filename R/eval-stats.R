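#' Micro-averaged multi-label precision, recall and F1
#'
#' Pools true positives, false positives and false negatives over all
#' (sentence, label) decisions; F1 is the harmonic mean of the pooled
#' precision and recall. When no label is predicted at all, precision is
#' reported as 0 with `undefined_precision = TRUE`.
#'
#' @param gold,pred Lists of label sets (character vectors), aligned by
#'   sentence.
#' @return List with `precision`, `recall`, `f1`, the pooled counts, and
#'   `undefined_precision`.
#' @examples
#' micro_prf(list("A", c("A", "B")), list("A", "B"))  # P=1, R=2/3, F1=0.8
#' @export
micro_prf <- function(gold, pred) {
  if (length(gold) != length(pred)) {
    stop("gold and pred are misaligned", call. = FALSE)
  }
  tp <- fp <- fn <- 0L
  for (i in seq_along(gold)) {
    g <- unique(as.character(gold[[i]])); p <- unique(as.character(pred[[i]]))
    tp <- tp + length(intersect(g, p))
    fp <- fp + length(setdiff(p, g))
    fn <- fn + length(setdiff(g, p))
  }
  if (tp + fn == 0L) stop("no gold labels", call. = FALSE)
  undef <- (tp + fp) == 0L
  precision <- if (undef) 0 else tp / (tp + fp)
  recall <- tp / (tp + fn)
  f1 <- if (precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       tp = tp, fp = fp, fn = fn, undefined_precision = undef)
}

#' Macro-averaged multi-label precision, recall and F1
#'
#' Per-label binary scores averaged without weighting. Labels that occur
#' in neither gold nor predictions are excluded and listed in
#' `excluded_labels`. A label with no predictions scores precision 0; a
#' label with no gold occurrences scores recall 0.
#'
#' @param gold,pred Lists of label sets, aligned by sentence.
#' @param labels Label universe; default the union observed in the data.
#' @return List with per-label data frame `per_label`, averaged
#'   `precision`, `recall`, `f1`, and `excluded_labels`.
#' @export
macro_prf <- function(gold, pred, labels = NULL) {
  if (length(gold) != length(pred)) {
    stop("gold and pred are misaligned", call. = FALSE)
  }
  observed <- unique(c(unlist(gold), unlist(pred)))
  labels <- labels %||% sort(observed)
  excluded <- setdiff(labels, observed)
  labels <- intersect(labels, observed)
  per <- lapply(labels, function(lab) {
    g <- vapply(gold, function(s) lab %in% s, logical(1))
    p <- vapply(pred, function(s) lab %in% s, logical(1))
    tp <- sum(g & p); fp <- sum(!g & p); fn <- sum(g & !p)
    precision <- if (tp + fp == 0L) 0 else tp / (tp + fp)
    recall <- if (tp + fn == 0L) 0 else tp / (tp + fn)
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(label = lab, precision = precision, recall = recall, f1 = f1,
               stringsAsFactors = FALSE)
  })
  per <- do.call(rbind, per)
  list(per_label = per, precision = mean(per$precision),
       recall = mean(per$recall), f1 = mean(per$f1),
       excluded_labels = excluded)
}

#' McNemar's test for paired binary outcomes
#'
#' Compares two classifiers on the same items through the discordant
#' counts b (A correct, B wrong) and c (A wrong, B correct). The default
#' statistic is the uncorrected chi-square (b - c)^2 / (b + c) on 1
#' degree of freedom; when b + c < 25 the exact two-sided binomial test
#' on (b, b + c, 1/2) is used instead. With b + c = 0 the statistic is 0
#' and p = 1.
#'
#' @param correct_a,correct_b Logical vectors of per-item correctness, or
#'   `NULL` when `b`/`c` are given directly.
#' @param b,c Discordant counts (alternative input).
#' @param exact_below Use the exact binomial when b + c is below this.
#' @return List with `statistic`, `p_value`, `b`, `c`, `method`.
#' @export
mcnemar_test <- function(correct_a = NULL, correct_b = NULL,
                         b = NULL, c = NULL, exact_below = 25L) {
  if (is.null(b) || is.null(c)) {
    stopifnot(length(correct_a) == length(correct_b))
    b <- sum(correct_a & !correct_b)
    c <- sum(!correct_a & correct_b)
  }
  n_disc <- b + c
  if (n_disc == 0L) {
    return(list(statistic = 0, p_value = 1, b = b, c = c,
                method = "degenerate"))
  }
  if (n_disc < exact_below) {
    lo <- min(b, c)
    p <- min(1, 2 * stats::pbinom(lo, n_disc, 0.5))
    return(list(statistic = NA_real_, p_value = p, b = b, c = c,
                method = "exact-binomial"))
  }
  stat <- (b - c)^2 / n_disc
  list(statistic = stat, p_value = stats::pchisq(stat, df = 1,
                                                 lower.tail = FALSE),
       b = b, c = c, method = "chi-squared")
}

#' Encode a prediction set as a composite Bhapkar class
#'
#' Multi-label predictions become additional classes: the sorted label
#' tuple joined canonically; an empty set maps to the reserved empty
#' class.
#'
#' @param labels Character vector (possibly empty).
#' @return A single class string.
#' @export
composite_class <- function(labels) {
  key <- canonical_set(labels)
  if (identical(key, "")) "<empty>" else key
}

#' Bhapkar's test of marginal homogeneity for paired categorical outcomes
#'
#' The multi-class extension of McNemar's test: with paired outcomes over
#' k categories tabulated as an k-by-k contingency table n, the statistic
#' is d' S^-1 d on the first k - 1 marginal differences
#' d_i = n_{i.} - n_{.i}, with the consistent covariance estimate that
#' does not assume homogeneity: S_ii = n_{i.} + n_{.i} - 2 n_ii -
#' d_i^2 / n and S_ij = -(n_ij + n_ji) - d_i d_j / n. The statistic is
#' chi-square distributed on k - 1 degrees of freedom. On a 2-by-2 table
#' it equals M / (1 - M / n), with M the uncorrected McNemar statistic.
#' A singular S falls back to a generalized inverse with the rank as
#' degrees of freedom, with a warning.
#'
#' @param outcomes_a,outcomes_b Aligned categorical outcome vectors (use
#'   [composite_class()] to encode multi-label sets), or `NULL` when
#'   `table` is given.
#' @param table A k-by-k contingency table of paired counts (rows =
#'   system A, columns = system B), as an alternative input.
#' @return List with `statistic`, `df`, `p_value`, `table`.
#' @export
bhapkar_test <- function(outcomes_a = NULL, outcomes_b = NULL, table = NULL) {
  if (is.null(table)) {
    stopifnot(length(outcomes_a) == length(outcomes_b))
    cats <- sort(union(unique(outcomes_a), unique(outcomes_b)))
    if (length(cats) < 2L) stop("need at least 2 categories", call. = FALSE)
    table <- base::table(factor(outcomes_a, levels = cats),
                         factor(outcomes_b, levels = cats))
  }
  tab <- as.matrix(table)
  k <- nrow(tab)
  stopifnot(k == ncol(tab), k >= 2L)
  n <- sum(tab)
  d <- (rowSums(tab) - colSums(tab))[seq_len(k - 1L)]
  S <- matrix(0, k - 1L, k - 1L)
  for (i in seq_len(k - 1L)) {
    for (j in seq_len(k - 1L)) {
      S[i, j] <- if (i == j) {
        rowSums(tab)[i] + colSums(tab)[i] - 2 * tab[i, i] - d[i]^2 / n
      } else {
        -(tab[i, j] + tab[j, i]) - d[i] * d[j] / n
      }
    }
  }
  if (all(d == 0)) {
    return(list(statistic = 0, df = k - 1L, p_value = 1, table = tab))
  }
  qrS <- qr(S)
  if (qrS$rank < k - 1L) {
    warning("singular covariance; using generalized inverse with df = ",
            qrS$rank, call. = FALSE)
    stat <- drop(t(d) %*% MASS::ginv(S) %*% d)
    df <- qrS$rank
  } else {
    stat <- drop(t(d) %*% solve(S, d))
    df <- k - 1L
  }
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
       table = tab)
}

#' Mean and standard deviation over repeated runs
#'
#' Models are trained and tested over several randomly initialized runs
#' (five in the reference protocol); metrics are summarized as the mean
#' and the sample standard deviation (k - 1 denominator). With a single
#' run the SD is undefined and flagged.
#'
#' @param values Numeric vector of per-run metric values.
#' @return List with `mean`, `sd`, `k`, `sd_defined`.
#' @export
aggregate_runs <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("no runs to aggregate", call. = FALSE)
  k <- length(values)
  list(mean = mean(values),
       sd = if (k >= 2L) stats::sd(values) else NA_real_,
       k = k, sd_defined = k >= 2L)
}

#' Corpus-level SAL profile from the two-stage pipeline
#'
#' Applies the SAL sentence classifier to the abstract and the
#' discussion/limitation-related sections of every article, then the type
#' classifier (with per-label thresholds and the Funding rule) to the
#' predicted SAL sentences, and aggregates: per-type sentence-level
#' counts/percentages, document-level counts/percentages (a type counts
#' once per article), and per-article means with normal-theory 95%
#' confidence intervals based on the t distribution.
#'
#' @param articles List of `sal_article`s.
#' @param sentence_model A `sal_binary_model`.
#' @param type_model A `sal_type_model`.
#' @param thresholds A `sal_thresholds`.
#' @param apply_funding_rule Supplement predictions with the Funding rule?
#' @param keywords Section-selection keywords.
#' @return An object of class `sal_corpus_profile`: list with
#'   `per_article`, `per_type`, `means` (per-article means with CIs),
#'   `n_articles`, `n_sal_sentences`.
#' @export
profile_corpus <- function(articles, sentence_model, type_model, thresholds,
                           apply_funding_rule = TRUE,
                           keywords = .default_section_keywords) {
  if (length(articles) == 0L) stop("empty corpus", call. = FALSE)
  per_article <- list()
  type_doc <- list()     # per type: article ids
  type_sent <- list()    # per type: sentence count
  n_sal_total <- 0L
  for (art in articles) {
    secs <- select_limitation_sections(art, keywords = keywords)
    sents <- extract_sentences(art, secs)
    n_sal <- 0L
    types <- character(0)
    type_count <- 0L
    if (nrow(sents) > 0L) {
      sal <- predict_sal(sentence_model, sents)
      pos <- sents[sal$is_sal, , drop = FALSE]
      n_sal <- nrow(pos)
      if (n_sal > 0L) {
        sets <- if (apply_funding_rule) {
          predict_with_rules(type_model, thresholds, pos)
        } else {
          predict_types(type_model, thresholds, pos)
        }
        for (s in sets) {
          for (ty in s) {
            type_sent[[ty]] <- (type_sent[[ty]] %||% 0L) + 1L
            type_doc[[ty]] <- union(type_doc[[ty]] %||% character(0),
                                    art$article_id)
          }
        }
        types <- sort(unique(unlist(sets)))
        type_count <- sum(lengths(sets))
      }
    }
    n_sal_total <- n_sal_total + n_sal
    per_article[[length(per_article) + 1L]] <- data.frame(
      article_id = art$article_id, n_sal_sentences = n_sal,
      n_type_instances = type_count, n_distinct_types = length(types),
      stringsAsFactors = FALSE)
  }
  per_article <- do.call(rbind, per_article)
  all_types <- sort(union(names(type_sent), names(type_doc)))
  sent_counts <- vapply(all_types, function(t) type_sent[[t]] %||% 0L, 0L)
  doc_counts <- vapply(all_types, function(t) length(type_doc[[t]]), 0L)
  per_type <- data.frame(
    type = all_types,
    sentence_count = as.integer(sent_counts),
    sentence_pct = if (sum(sent_counts) > 0) {
      100 * sent_counts / sum(sent_counts)
    } else rep(0, length(all_types)),
    document_count = as.integer(doc_counts),
    document_pct = 100 * doc_counts / length(articles),
    stringsAsFactors = FALSE)
  rownames(per_type) <- NULL
  ci <- function(x) {
    m <- mean(x)
    if (length(x) < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_))
    half <- stats::qt(0.975, df = length(x) - 1L) *
      stats::sd(x) / sqrt(length(x))
    c(mean = m, lo = m - half, hi = m + half)
  }
  means <- rbind(
    sal_sentences_per_article = ci(per_article$n_sal_sentences),
    type_instances_per_article = ci(per_article$n_type_instances))
  structure(list(per_article = per_article, per_type = per_type,
                 means = means, n_articles = length(articles),
                 n_sal_sentences = n_sal_total),
            class = "sal_corpus_profile")
}

#' @export
print.sal_corpus_profile <- function(x, ...) {
  cat("SAL corpus profile: ", x$n_articles, " articles, ",
      x$n_sal_sentences, " predicted SAL sentences\n", sep = "")
  cat("Per-article means (95% CI):\n")
  print(round(x$means, 3))
  cat("Top types by document count:\n")
  ord <- order(-x$per_type$document_count)
  print(utils::head(x$per_type[ord, ], 10), row.names = FALSE)
  invisible(x)
}
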