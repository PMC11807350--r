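# A compact standard English stopword list used by RAKE and the EDA
# synonym operator.
.default_stopwords <- c(
  "a", "about", "above", "after", "again", "all", "also", "an", "and",
  "any", "are", "as", "at", "be", "because", "been", "before", "being",
  "below", "between", "both", "but", "by", "can", "could", "did", "do",
  "does", "doing", "down", "during", "each", "few", "for", "from",
  "further", "had", "has", "have", "having", "he", "her", "here", "hers",
  "him", "his", "how", "i", "if", "in", "into", "is", "it", "its",
  "itself", "just", "may", "me", "might", "more", "most", "must", "my",
  "no", "nor", "not", "of", "off", "on", "once", "only", "or", "other",
  "our", "out", "over", "own", "same", "she", "should", "so", "some",
  "such", "than", "that", "the", "their", "them", "then", "there",
  "these", "they", "this", "those", "through", "to", "too", "under",
  "until", "up", "very", "was", "we", "were", "what", "when", "where",
  "which", "while", "who", "whom", "why", "will", "with", "would", "you",
  "your")

# Small synonym lexicon for the EDA operators; enough coverage for the
# limitation-sentence vocabulary of the synthetic fixtures.
.default_synonyms <- list(
  small = c("limited", "modest"), limited = c("small", "restricted"),
  sample = c("cohort", "group"), study = c("trial", "investigation"),
  trial = c("study", "experiment"), large = c("substantial", "sizeable"),
  short = c("brief", "limited"), results = c("findings", "outcomes"),
  findings = c("results", "observations"), patients = c("participants", "subjects"),
  participants = c("patients", "subjects"), effect = c("impact", "influence"),
  power = c("sensitivity", "strength"), single = c("one", "sole"),
  may = c("might", "could"), not = c("never", "hardly"),
  measure = c("instrument", "assessment"), outcome = c("endpoint", "measure"),
  duration = c("length", "period"), group = c("arm", "cohort"))

#' Plan class-balancing augmentation for a training set
#'
#' For each class at the chosen granularity, counts its training sentences
#' and computes the deficit `max(0, target - n)` against the minimum class
#' size (default 70). Sentences with multiple labels are excluded from the
#' generation seed pools, because the augmentation method cannot separate
#' the features of each label, and the Funding class is ineligible (all
#' its sentences are multi-label); it is handled by the rule-based
#' detector instead.
#'
#' @param train Labeled sentence data frame (SAL sentences).
#' @param target Minimum class size (default 70).
#' @param granularity `"top"` or `"fine"`.
#' @param taxonomy A `sal_taxonomy`.
#' @return Data frame of class `sal_augment_plan` with one row per class
#'   observed in training: `class`, `n`, `deficit`, `eligible`, `n_seeds`.
#' @export
build_plan <- function(train, target = 70L, granularity = c("top", "fine"),
                       taxonomy = load_taxonomy()) {
  granularity <- match.arg(granularity)
  stopifnot(target >= 1)
  if (nrow(train) == 0L) stop("empty training set", call. = FALSE)
  col <- if (granularity == "top") "types_top" else "types_fine"
  gold <- train[[col]]
  classes <- sort(unique(unlist(gold)))
  single <- lengths(gold) == 1L
  plan <- data.frame(class = classes, stringsAsFactors = FALSE)
  plan$n <- vapply(classes, function(cl) {
    sum(vapply(gold, function(g) cl %in% g, logical(1)))
  }, integer(1))
  plan$deficit <- pmax(0L, as.integer(target) - plan$n)
  plan$eligible <- plan$class != "Funding"
  plan$n_seeds <- vapply(classes, function(cl) {
    sum(single & vapply(gold, function(g) identical(g, cl), logical(1)))
  }, integer(1))
  attr(plan, "target") <- as.integer(target)
  attr(plan, "granularity") <- granularity
  class(plan) <- c("sal_augment_plan", "data.frame")
  plan
}

# seed-pool row indices for one class of a plan
.seed_indices <- function(train, plan, cl) {
  col <- if (attr(plan, "granularity") == "top") "types_top" else "types_fine"
  which(lengths(train[[col]]) == 1L &
          vapply(train[[col]], function(g) identical(g, cl), logical(1)))
}

#' Oversample minority classes to the target size
#'
#' Randomly duplicates single-label sentences of each deficient eligible
#' class, drawn uniformly with replacement, until the class reaches the
#' plan's target. Original records are never altered; duplicates are
#' byte-identical copies marked `provenance = "oversample"`.
#'
#' @param train Labeled sentence data frame the plan was built on.
#' @param plan A [build_plan()] result.
#' @param seed Integer seed.
#' @return The augmented training set with a `provenance` column.
#' @export
oversample <- function(train, plan, seed = 1L) {
  out <- train
  out$provenance <- rep("original", nrow(train))
  extra <- with_seed(seed, {
    added <- list()
    for (r in seq_len(nrow(plan))) {
      if (!plan$eligible[r] || plan$deficit[r] == 0L) next
      idx <- .seed_indices(train, plan, plan$class[r])
      if (length(idx) == 0L) {
        warning("no single-label seeds for class '", plan$class[r],
                "'; skipped", call. = FALSE)
        next
      }
      pick <- idx[sample.int(length(idx), plan$deficit[r], replace = TRUE)]
      dup <- train[pick, , drop = FALSE]
      dup$provenance <- "oversample"
      added[[length(added) + 1L]] <- dup
    }
    added
  })
  if (length(extra) > 0L) out <- .rbind_align(out, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

# One EDA operator application; `rate` is the per-word modification rate.
.eda_once <- function(words, op, rate, lexicon) {
  n <- length(words)
  syn_of <- function(w) {
    s <- lexicon[[tolower(w)]]
    if (is.null(s)) NULL else sample(s, 1L)
  }
  if (op == "swap") {
    if (n < 2L) return(words)
    for (rep in seq_len(max(1L, round(rate * n)))) {
      ij <- sample.int(n, 2L)
      words[ij] <- words[rev(ij)]
    }
    return(words)
  }
  if (op == "delete") {
    if (n < 2L) return(words)
    keep <- stats::runif(n) >= rate
    if (!any(keep)) keep[sample.int(n, 1L)] <- TRUE
    return(words[keep])
  }
  if (op == "insert") {
    for (rep in seq_len(max(1L, round(rate * n)))) {
      cand <- words[vapply(words, function(w) !is.null(lexicon[[tolower(w)]]),
                           logical(1))]
      if (length(cand) == 0L) break
      s <- syn_of(sample(cand, 1L))
      pos <- sample.int(length(words) + 1L, 1L)
      words <- append(words, s, after = pos - 1L)
    }
    return(words)
  }
  # synonym replacement: word count is preserved
  repl <- which(vapply(words, function(w) !is.null(lexicon[[tolower(w)]]),
                       logical(1)))
  if (length(repl) == 0L) return(words)
  k <- min(length(repl), max(1L, round(rate * n)))
  for (i in repl[sample.int(length(repl), k)]) words[i] <- syn_of(words[i])
  words
}

#' Generate EDA variants of a sentence
#'
#' Easy Data Augmentation: each variant applies one operator chosen
#' uniformly at random — synonym replacement, random insertion, random
#' deletion or random swap — at the configured per-word rate. The label is
#' preserved, deletion always retains at least one word, and a one-word
#' sentence passes through deletion/swap unchanged. Deterministic under
#' the seed.
#'
#' @param sentence Non-empty character scalar.
#' @param label The sentence's (single) label.
#' @param n_variants Number of variants.
#' @param rate Per-word modification rate (default 0.1).
#' @param seed Integer seed.
#' @param synonym_lexicon Named list word -> character vector of synonyms.
#' @param seed_sentence_id Provenance id recorded on each variant.
#' @return Data frame of synthetic samples with `view = "eda"`.
#' @export
eda_variants <- function(sentence, label, n_variants = 1L, rate = 0.1,
                         seed = 1L, synonym_lexicon = .default_synonyms,
                         seed_sentence_id = NA_character_) {
  stopifnot(is.character(sentence), nzchar(sentence))
  ops <- c("synonym", "insert", "delete", "swap")
  texts <- with_seed(seed, {
    vapply(seq_len(n_variants), function(v) {
      words <- strsplit(sentence, "[ \t\r\n]+")[[1]]
      words <- words[nzchar(words)]
      op <- sample(ops, 1L)
      paste(.eda_once(words, op, rate, synonym_lexicon), collapse = " ")
    }, character(1))
  })
  data.frame(text = texts, intended_label = label, view = "eda",
             seed_sentence_id = seed_sentence_id, kept_by_filter = NA,
             stringsAsFactors = FALSE)
}

#' RAKE keyword extraction
#'
#' Rapid Automatic Keyword Extraction: candidate phrases are the maximal
#' runs of content words between stopwords and punctuation; each word
#' scores degree/frequency over the co-occurrence graph of the candidates
#' (a word's degree counts all words of every phrase it appears in,
#' itself included); a phrase scores the sum of its word scores. Ties are
#' broken by first occurrence.
#'
#' @param text Character scalar.
#' @param stopwords Character vector of stopwords.
#' @return Data frame `phrase`, `score`, sorted by decreasing score.
#' @examples
#' rake_keywords("small sample size limited the statistical power",
#'               stopwords = "the")
#' @export
rake_keywords <- function(text, stopwords = .default_stopwords) {
  if (!nzchar(trimws(text %||% ""))) {
    return(data.frame(phrase = character(0), score = numeric(0)))
  }
  frags <- strsplit(tolower(text), "[^a-z0-9' -]+")[[1]]
  phrases <- character(0)
  for (frag in frags) {
    words <- strsplit(frag, "[ -]+")[[1]]
    words <- words[nzchar(words)]
    run <- character(0)
    for (w in c(words, "\r")) {   # sentinel flushes the final run
      if (w %in% stopwords || w == "\r") {
        if (length(run) > 0L) phrases <- c(phrases, paste(run, collapse = " "))
        run <- character(0)
      } else {
        run <- c(run, w)
      }
    }
  }
  if (length(phrases) == 0L) {
    return(data.frame(phrase = character(0), score = numeric(0)))
  }
  freq <- list(); degree <- list()
  for (ph in phrases) {
    ws <- strsplit(ph, " ", fixed = TRUE)[[1]]
    for (w in ws) {
      freq[[w]] <- (freq[[w]] %||% 0) + 1
      degree[[w]] <- (degree[[w]] %||% 0) + length(ws)
    }
  }
  score <- vapply(phrases, function(ph) {
    ws <- strsplit(ph, " ", fixed = TRUE)[[1]]
    sum(vapply(ws, function(w) degree[[w]] / freq[[w]], numeric(1)))
  }, numeric(1), USE.NAMES = FALSE)
  out <- data.frame(phrase = phrases, score = score, stringsAsFactors = FALSE)
  out <- out[!duplicated(out$phrase), , drop = FALSE]
  out <- out[order(-out$score, seq_len(nrow(out))), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Dual-view candidate generation for one seed sentence
#'
#' Prompts a pluggable generator either with the seed sentence's RAKE
#' keywords (Input View) or with the class label alone (Output View) and
#' collects exactly `n_per_seed` candidate sentences (default 10 per
#' seed).
#'
#' @param seed_sample A one-row labeled sentence (single-label) or a list
#'   with `text` and a single label in `label`.
#' @param generator A generator function `(prompt, n, seed) -> character`
#'   honouring the contract: exactly `n` non-empty sentences,
#'   deterministic under `seed` (see [template_generator()]).
#' @param n_per_seed Candidates per seed (default 10).
#' @param view `"input_view"` or `"output_view"`.
#' @param seed Integer seed.
#' @param stopwords Stopword list for RAKE.
#' @return Data frame of synthetic samples.
#' @export
generate_dual_view <- function(seed_sample, generator, n_per_seed = 10L,
                               view = c("input_view", "output_view"),
                               seed = 1L, stopwords = .default_stopwords) {
  view <- match.arg(view)
  label <- seed_sample$label %||%
    unlist(seed_sample$types_top %||% seed_sample$types_fine)
  if (length(label) != 1L) {
    stop("seed sample must carry exactly one label", call. = FALSE)
  }
  prompt <- if (view == "input_view") {
    kw <- rake_keywords(as.character(seed_sample$text), stopwords)
    list(view = view, label = label,
         keywords = utils::head(kw$phrase, 3L))
  } else {
    list(view = view, label = label)
  }
  texts <- generator(prompt, n_per_seed, seed)
  if (length(texts) != n_per_seed || any(!nzchar(texts))) {
    stop("generator violated its contract: expected ", n_per_seed,
         " non-empty sentences, got ", length(texts), call. = FALSE)
  }
  data.frame(text = texts, intended_label = label, view = view,
             seed_sentence_id = as.character(seed_sample$sentence_id %||% NA),
             kept_by_filter = NA, stringsAsFactors = FALSE)
}

#' Consistency filtering of synthetic candidates
#'
#' Keeps exactly the candidates whose label under `filter_model` equals
#' their intended label; `kept_by_filter` records the decision. The
#' filter model conventionally is a classifier trained on the original
#' (pre-augmentation) training set, reduced to its argmax label — see
#' [classifier_filter()].
#'
#' @param candidates Data frame of synthetic samples.
#' @param filter_model Function from a sentence to a single label.
#' @param return_all Return all candidates with their flag instead of
#'   only the kept ones?
#' @return Data frame of kept candidates (or all, flagged).
#' @export
consistency_filter <- function(candidates, filter_model, return_all = FALSE) {
  if (nrow(candidates) == 0L) return(candidates)
  pred <- vapply(candidates$text, function(t) as.character(filter_model(t)[1]),
                 character(1), USE.NAMES = FALSE)
  candidates$kept_by_filter <- pred == candidates$intended_label
  if (return_all) candidates else
    candidates[candidates$kept_by_filter, , drop = FALSE]
}

#' Reduce a type classifier to a single-label filter function
#'
#' @param model A `sal_type_model`.
#' @param top_header,innermost_header Header context assumed for bare
#'   candidate sentences.
#' @return Function mapping a sentence to its argmax label.
#' @export
classifier_filter <- function(model, top_header = "Discussion",
                              innermost_header = "Limitations") {
  function(text) {
    rec <- data.frame(text = text, top_header = top_header,
                      innermost_header = innermost_header,
                      stringsAsFactors = FALSE)
    P <- predict_type_probs(model, rec)
    model$label_space[which.max(P[1, ])]
  }
}

# rbind that fills columns present in `base` but absent in `extra` with NA
# (empty sets for list columns), keeping `base`'s column order
.rbind_align <- function(base, extra) {
  for (col in setdiff(names(base), names(extra))) {
    extra[[col]] <- if (is.list(base[[col]])) {
      rep(list(character(0)), nrow(extra))
    } else {
      rep(base[[col]][NA_integer_][1], nrow(extra))
    }
  }
  rbind(base, extra[, names(base), drop = FALSE])
}

# synthetic samples -> labeled sentence rows appendable to a training set
.samples_to_sentences <- function(samples, granularity,
                                  taxonomy = load_taxonomy()) {
  n <- nrow(samples)
  out <- data.frame(
    article_id = rep("synthetic-aug", n),
    section_index = rep(NA_integer_, n),
    char_start = rep(NA_integer_, n),
    char_end = rep(NA_integer_, n),
    text = samples$text,
    top_header = rep("Discussion", n),
    innermost_header = rep("Limitations", n),
    is_sal = rep(TRUE, n),
    stringsAsFactors = FALSE
  )
  if (granularity == "top") {
    out$types_fine <- as.list(samples$intended_label)
    out$types_top <- lapply(samples$intended_label, coarsen,
                            taxonomy = taxonomy)
  } else {
    out$types_fine <- as.list(samples$intended_label)
    out$types_top <- lapply(samples$intended_label, coarsen,
                            taxonomy = taxonomy)
  }
  out$provenance <- samples$view
  out
}

#' Fill minority classes from a pool of synthetic samples
#'
#' For every deficient eligible class the plan names, draws exactly
#' `deficit` samples uniformly without replacement from that class's pool
#' (the whole remaining class pool when it is smaller, with a warning;
#' samples are never fabricated). Deterministic under the seed; original
#' records are untouched.
#'
#' @param train Labeled sentence data frame the plan was built on.
#' @param plan A [build_plan()] result.
#' @param pool Data frame of (filtered) synthetic samples.
#' @param seed Integer seed.
#' @param taxonomy A `sal_taxonomy`.
#' @return The augmented training set with a `provenance` column.
#' @export
balance <- function(train, plan, pool, seed = 1L,
                    taxonomy = load_taxonomy()) {
  out <- train
  out$provenance <- rep("original", nrow(train))
  granularity <- attr(plan, "granularity")
  added <- with_seed(seed, {
    acc <- list()
    for (r in seq_len(nrow(plan))) {
      if (!plan$eligible[r] || plan$deficit[r] == 0L) next
      cl <- plan$class[r]
      cand <- pool[pool$intended_label == cl, , drop = FALSE]
      take <- min(plan$deficit[r], nrow(cand))
      if (take < plan$deficit[r]) {
        warning("pool shortfall for class '", cl, "': wanted ",
                plan$deficit[r], ", pool has ", nrow(cand), call. = FALSE)
      }
      if (take == 0L) next
      pick <- cand[sample.int(nrow(cand), take), , drop = FALSE]
      acc[[length(acc) + 1L]] <- .samples_to_sentences(pick, granularity,
                                                       taxonomy)
    }
    acc
  })
  if (length(added) > 0L) out <- .rbind_align(out, do.call(rbind, added))
  rownames(out) <- NULL
  out
}
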