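# Clause bank: per top-level type, five limitation clauses built around
# type-characteristic cue tokens that occur in no other type's clauses and
# in no filler sentence. The cue separability is what makes generated
# corpora learnable by a bag-of-words model, so pipeline smoke tests have
# a known signal.
.clause_bank <- list(
  StudyDesign = c(
    "the crossover design may have produced carryover effects",
    "the crossover design prevented a parallel comparison",
    "a crossover design complicated the washout interpretation",
    "the factorial crossover design made interactions hard to isolate",
    "the cluster crossover design constrained the analysis"),
  Population = c(
    "the narrow eligibility criteria excluded many typical patients",
    "strict eligibility criteria restricted enrolment to a narrow group",
    "eligibility criteria admitted only a very specific population",
    "the narrow eligibility window limited who could enrol",
    "restrictive eligibility criteria reduced the diversity of the cohort"),
  Setting = c(
    "recruitment occurred at a single academic centre",
    "all participants came from one centre",
    "the unicentric recruitment may not reflect other clinics",
    "conducting the trial at one centre narrowed the context",
    "a single centre provided every enrolled participant"),
  Intervention = c(
    "the multimodal intervention masked each component effect",
    "a multimodal treatment made attribution of benefit difficult",
    "the composite multimodal programme blended several elements",
    "the multimodal delivery varied between therapists",
    "dosage within the multimodal protocol was not standardized"),
  Control = c(
    "no placebo comparator was included",
    "the absence of a placebo arm weakens causal claims",
    "an active placebo was used instead of an inert comparator",
    "lacking a placebo group, expectancy effects remain possible",
    "the placebo condition was not convincingly inert"),
  OutcomeMeasures = c(
    "the outcome instrument was not validated for this population",
    "the chosen instrument may lack validity in this context",
    "instrument precision for the primary outcome was low",
    "the instrument was insensitive to subtle clinical change",
    "relevant outcomes were not captured by the instrument"),
  MissingData = c(
    "attrition before the final visit was considerable",
    "high attrition produced missing outcome data",
    "attrition differed between the arms",
    "missing covariate data arose from attrition",
    "attrition reduced the completeness of follow-up data"),
  UnderpoweredStudy = c(
    "the small sample size limited statistical power",
    "an insufficient sample size precluded subgroup analyses",
    "recruitment difficulties produced a modest sample size",
    "the sample size fell below the planned target",
    "statistical power suffered from the small sample size"),
  Randomization = c(
    "allocation concealment was suboptimal",
    "the randomization sequence allowed allocation prediction",
    "allocation produced unbalanced prognostic factors",
    "stratified allocation was not implemented",
    "the allocation ratio drifted during enrolment"),
  Blinding = c(
    "participants were unblinded to their assignment",
    "masking of participants proved impossible",
    "outcome assessors remained unblinded",
    "the unblinded study team was aware of assignments",
    "unblinded care providers may have introduced bias"),
  StudyDuration = c(
    "only short-term effects were evaluated, leaving long-term benefit unknown",
    "the intervention phase was too brief",
    "long-term durability of the effect was not assessed",
    "the observation period was too short to capture late events",
    "early stopping shortened the experimental phase"),
  StatisticalAnalysis = c(
    "no adjustment for multiplicity was applied",
    "simultaneous testing of several hypotheses inflated error rates",
    "analyses were unadjusted for important confounders",
    "the multiplicity of comparisons raises chance findings",
    "covariate adjustment was omitted from the models"),
  Funding = c(
    "insufficient funding curtailed the planned extension",
    "the study was not financed adequately",
    "limited funding prevented a larger trial",
    "a lack of funding interrupted data collection",
    "funding constraints shortened the project"),
  Generalization = c(
    "generalizability beyond this context is uncertain",
    "findings may not generalize to routine practice",
    "the results may lack generalizability to other populations",
    "external validity of the findings is limited",
    "caution is needed when generalizing these results"),
  Other = c(
    "an idiosyncratic operational constraint affected conduct",
    "unusual circumstances of the trial are hard to classify",
    "an idiosyncratic protocol deviation occurred",
    "a peculiarity of local circumstances resists categorization",
    "miscellaneous constraints limited the work in idiosyncratic ways"))

# one representative fine-grained category per top type (types without
# children keep the top name)
.fine_rep <- c(
  Population = "VerySpecificPopulation", Setting = "Unicentric",
  Intervention = "CompositeIntervention", Control = "NoPlaceboGroup",
  OutcomeMeasures = "ValidityOfMeasurement", MissingData = "HighLossToFollowUp",
  UnderpoweredStudy = "SampleSize", Randomization = "PoorRandomizationMethods",
  Blinding = "Patient", StudyDuration = "FollowUpDuration",
  StatisticalAnalysis = "MultipleTesting")

.sal_frames <- c(
  "We acknowledge that %s.",
  "A further limitation is that %s.",
  "It should be noted that %s.",
  "An important caveat is that %s.",
  "Our findings must be interpreted cautiously because %s.")

.multi_frame <- "We acknowledge that %s, and moreover %s."

.filler_sentences <- c(
  "The mean age of enrolled adults was fifty-two years.",
  "Baseline characteristics are summarized in the table.",
  "Participants completed questionnaires at each visit.",
  "The primary endpoint improved in both arms.",
  "Adverse events were mild and transient.",
  "Recruitment proceeded over eighteen months.",
  "The protocol was approved by the ethics committee.",
  "Data were analysed according to a prespecified plan.",
  "Treatment adherence was high across visits.",
  "Scores were recorded electronically at baseline.")

#' Default top-level label distribution for synthetic corpora
#'
#' Sentence-level label frequencies used by [generate_corpus()], read from
#' the bundled distribution file. The frequencies for Population,
#' OutcomeMeasures, UnderpoweredStudy, Setting and Funding follow the
#' published counts of the annotated corpus; the remaining classes are
#' interpolated to a comparable long tail (the file's `provenance` column
#' records which is which).
#'
#' @return Named numeric vector of probabilities over the 15 top-level
#'   types (sums to 1).
#' @export
default_label_distribution <- function() {
  path <- system.file("extdata", "label_distribution.tsv",
                      package = "salmine")
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$count / sum(tab$count), tab$type)
}

#' Configuration for the synthetic corpus generator
#'
#' The defaults emulate the structure of the annotated corpus: about 4.8
#' SAL sentences per article, about 1.15 labels per SAL sentence, and a
#' long-tailed top-level label distribution in which several classes fall
#' below the augmentation target of 70 in a 120-article training split.
#'
#' @param n_articles Number of articles.
#' @param label_distribution Named probability vector over top types.
#' @param sal_sentences_per_article Mean SAL sentences per article.
#' @param labels_per_sentence Mean labels per SAL sentence (in \[1, 2\]).
#' @param fine_rate Probability that a label is realized at its
#'   representative fine-grained category rather than the bare top level.
#' @param minority_classes Optional classes whose corpus-wide instance
#'   count is capped at `minority_max`.
#' @param minority_max Cap for `minority_classes`.
#' @param seed Integer seed fixing all randomness.
#' @return A list of class `sal_synth_config`.
#' @export
synth_config <- function(n_articles = 200L,
                         label_distribution = default_label_distribution(),
                         sal_sentences_per_article = 4.8,
                         labels_per_sentence = 1.15,
                         fine_rate = 0.5,
                         minority_classes = NULL,
                         minority_max = 20L,
                         seed = 1L) {
  stopifnot(n_articles >= 1, all(label_distribution >= 0),
            sal_sentences_per_article >= 1,
            labels_per_sentence >= 1, labels_per_sentence <= 2,
            fine_rate >= 0, fine_rate <= 1)
  if (labels_per_sentence > length(label_distribution)) {
    stop("labels_per_sentence exceeds the number of types", call. = FALSE)
  }
  structure(list(n_articles = as.integer(n_articles),
                 label_distribution = label_distribution /
                   sum(label_distribution),
                 sal_sentences_per_article = sal_sentences_per_article,
                 labels_per_sentence = labels_per_sentence,
                 fine_rate = fine_rate,
                 minority_classes = minority_classes,
                 minority_max = as.integer(minority_max),
                 seed = as.integer(seed)),
            class = "sal_synth_config")
}

# Build one SAL sentence; returns text plus clause spans (0-based,
# end-exclusive within the sentence) and their fine-or-top categories.
.make_sal_sentence <- function(top_labels, fine_rate) {
  cats <- vapply(top_labels, function(tl) {
    rep_fine <- .fine_rep[tl]
    if (!is.na(rep_fine) && stats::runif(1) < fine_rate) rep_fine else tl
  }, character(1), USE.NAMES = FALSE)
  clauses <- vapply(top_labels, function(tl) {
    sample(.clause_bank[[tl]], 1L)
  }, character(1), USE.NAMES = FALSE)
  if (length(top_labels) == 1L) {
    frame <- sample(.sal_frames, 1L)
    text <- sprintf(frame, clauses[1])
    s <- regexpr(clauses[1], text, fixed = TRUE)[1]
    spans <- data.frame(char_start = s - 1L,
                        char_end = s - 1L + nchar(clauses[1]),
                        category = cats[1], stringsAsFactors = FALSE)
  } else {
    text <- sprintf(.multi_frame, clauses[1], clauses[2])
    s1 <- regexpr(clauses[1], text, fixed = TRUE)[1]
    s2 <- s1 + nchar(clauses[1])
    s2 <- s2 + regexpr(clauses[2], substr(text, s2, nchar(text)),
                       fixed = TRUE)[1] - 1L
    spans <- data.frame(
      char_start = c(s1 - 1L, s2 - 1L),
      char_end = c(s1 - 1L + nchar(clauses[1]), s2 - 1L + nchar(clauses[2])),
      category = cats, stringsAsFactors = FALSE)
  }
  list(text = text, spans = spans)
}

#' Generate a deterministic labeled synthetic corpus
#'
#' Each article has Abstract, Introduction, Methods, Results, Discussion
#' and Study Limitations sections; SAL sentences (template-generated
#' limitation sentences with known labels) are placed only in the
#' abstract and the discussion/limitation sections, interleaved with
#' neutral filler sentences. Gold sentence labels are obtained by
#' projecting the generated clause spans back onto the segmented
#' sentences, so the corpus is self-consistent with the extraction
#' pipeline by construction. Fully reproducible: the same config and seed
#' give byte-identical output.
#'
#' @param config A [synth_config()].
#' @param taxonomy A `sal_taxonomy`.
#' @return An object of class `sal_corpus`: list with `articles` (list of
#'   `sal_article`), `sentences` (gold labeled sentence records over all
#'   sections), `spans` (gold clause spans in document coordinates) and
#'   `config`.
#' @export
generate_corpus <- function(config = synth_config(),
                            taxonomy = load_taxonomy()) {
  types <- names(config$label_distribution)
  bad <- setdiff(types, taxonomy$top)
  if (length(bad) > 0L) {
    stop("label_distribution names unknown types: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  p2 <- config$labels_per_sentence - 1
  counts <- stats::setNames(integer(length(types)), types)
  out <- with_seed(config$seed, {
    articles <- vector("list", config$n_articles)
    spans_all <- list()
    draw_label <- function(exclude = character(0)) {
      w <- config$label_distribution
      capped <- names(counts)[names(counts) %in% config$minority_classes &
                                counts >= config$minority_max]
      w[names(w) %in% c(exclude, capped)] <- 0
      if (sum(w) == 0) w <- config$label_distribution
      sample(types, 1L, prob = w)
    }
    for (a in seq_len(config$n_articles)) {
      aid <- sprintf("SYN%04d", a)
      n_sal <- 2L + stats::rpois(1L, max(0, config$sal_sentences_per_article - 2))
      sal <- vector("list", n_sal)
      for (s in seq_len(n_sal)) {
        l1 <- draw_label()
        labs <- l1
        if (stats::runif(1) < p2) labs <- c(l1, draw_label(exclude = l1))
        for (l in labs) counts[l] <- counts[l] + 1L
        sal[[s]] <- .make_sal_sentence(labs, config$fine_rate)
      }
      # distribute SAL sentences: ~10% to the abstract, a third of the
      # rest to the discussion, the remainder to the limitations section
      place <- vapply(seq_len(n_sal), function(i) {
        u <- stats::runif(1)
        if (u < 0.1) "abstract" else if (u < 0.4) "discussion" else "limitations"
      }, character(1))
      build_body <- function(sal_idx, n_filler) {
        fill <- sample(.filler_sentences, n_filler, replace = n_filler > 10L)
        items <- c(as.list(fill),
                   lapply(sal_idx, function(i) sal[[i]]))
        items <- items[sample.int(length(items))]
        pos <- 0L
        body_parts <- character(length(items))
        sp <- list()
        for (j in seq_along(items)) {
          it <- items[[j]]
          txt <- if (is.list(it)) it$text else it
          if (is.list(it)) {
            sp[[length(sp) + 1L]] <- data.frame(
              char_start = it$spans$char_start + pos,
              char_end = it$spans$char_end + pos,
              category = it$spans$category, stringsAsFactors = FALSE)
          }
          body_parts[j] <- txt
          pos <- pos + nchar(txt) + 1L   # single joining space
        }
        list(body = paste(body_parts, collapse = " "),
             spans = if (length(sp)) do.call(rbind, sp) else NULL)
      }
      ab <- build_body(which(place == "abstract"), 3L)
      di <- build_body(which(place == "discussion"), 3L)
      li <- build_body(which(place == "limitations"), 1L)
      intro <- paste(sample(.filler_sentences, 3L), collapse = " ")
      meth <- paste(sample(.filler_sentences, 4L), collapse = " ")
      res <- paste(sample(.filler_sentences, 3L), collapse = " ")
      sections <- data.frame(
        top_header = c("Abstract", "Introduction", "Methods", "Results",
                       "Discussion", "Discussion"),
        innermost_header = c("", "", "", "", "", "Study limitations"),
        body = c(ab$body, intro, meth, res, di$body, li$body),
        stringsAsFactors = FALSE)
      art <- article(aid, sections)
      flat <- flatten_article(art)
      collect <- function(sp, section_idx) {
        if (is.null(sp)) return(NULL)
        data.frame(article_id = aid, section_index = section_idx,
                   char_start = sp$char_start + flat$section_start[section_idx],
                   char_end = sp$char_end + flat$section_start[section_idx],
                   category = sp$category, stringsAsFactors = FALSE)
      }
      spans_all[[a]] <- do.call(rbind, Filter(Negate(is.null), list(
        collect(ab$spans, 1L), collect(di$spans, 5L), collect(li$spans, 6L))))
      articles[[a]] <- art
    }
    list(articles = articles, spans = spans_all)
  })
  sentences <- list()
  for (a in seq_along(out$articles)) {
    sents <- extract_sentences(out$articles[[a]])
    sp <- out$spans[[a]]
    sp <- if (is.null(sp)) {
      data.frame(article_id = character(0), char_start = integer(0),
                 char_end = integer(0), category = character(0))
    } else sp
    sentences[[a]] <- project_spans_to_sentences(sents, sp, taxonomy)
  }
  spans <- do.call(rbind, Filter(Negate(is.null), out$spans))
  rownames(spans) <- NULL
  structure(list(articles = out$articles,
                 sentences = do.call(rbind, sentences),
                 spans = spans, config = config),
            class = "sal_corpus")
}

#' @export
print.sal_corpus <- function(x, ...) {
  cat("<sal_corpus> ", length(x$articles), " articles, ",
      sum(x$sentences$is_sal), " SAL sentences / ",
      nrow(x$sentences), " total\n", sep = "")
  invisible(x)
}

#' Write a synthetic corpus as BRAT standoff file pairs
#'
#' One `.txt` (the flattened article text) and one `.ann` (text-bound "T"
#' lines with 0-based end-exclusive document offsets) per article, plus a
#' `.sections.tsv` sidecar recording the section headers and offsets so
#' articles can be reconstructed. Round-trips through [parse_brat()] and
#' [project_spans_to_sentences()] to the generator's gold labels.
#'
#' @param corpus A `sal_corpus`.
#' @param directory Output directory (created if needed).
#' @return Invisibly, the article ids written.
#' @export
write_brat <- function(corpus, directory) {
  if (length(corpus$articles) == 0L) return(invisible(character(0)))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create directory: ", directory, call. = FALSE)
  }
  ids <- character(0)
  for (art in corpus$articles) {
    aid <- art$article_id
    flat <- flatten_article(art)
    txt_path <- file.path(directory, paste0(aid, ".txt"))
    con <- file(txt_path, "wb")
    writeBin(charToRaw(flat$text), con)   # no trailing newline: offsets exact
    close(con)
    sp <- corpus$spans[corpus$spans$article_id == aid, , drop = FALSE]
    lines <- character(nrow(sp))
    for (i in seq_len(nrow(sp))) {
      surface <- slice_text(flat$text, sp$char_start[i], sp$char_end[i])
      lines[i] <- sprintf("T%d\t%s %d %d\t%s", i, sp$category[i],
                          sp$char_start[i], sp$char_end[i], surface)
    }
    writeLines(lines, file.path(directory, paste0(aid, ".ann")))
    sec <- art$sections
    sec$doc_start <- flat$section_start
    sec$doc_end <- flat$section_end
    utils::write.table(sec[, c("top_header", "innermost_header",
                               "doc_start", "doc_end")],
                       file.path(directory, paste0(aid, ".sections.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    ids <- c(ids, aid)
  }
  invisible(ids)
}

#' Simulate a multi-annotator label matrix from a corpus
#'
#' Annotator 1 reproduces the gold top-level label set of every SAL
#' sentence; each further annotator independently perturbs each unit's
#' set with probability `noise_rate` by adding, removing or swapping one
#' label. Deterministic under the seed.
#'
#' @param corpus A `sal_corpus`.
#' @param n_annotators Number of annotators (>= 2).
#' @param noise_rate Per-unit perturbation probability in \[0, 1\].
#' @param seed Integer seed.
#' @param mode `"any"` chooses add/remove/swap at random; `"swap"` always
#'   swaps (guaranteeing disagreement when it fires).
#' @return A `sal_unit_matrix`.
#' @export
make_multiannotator <- function(corpus, n_annotators = 3L, noise_rate = 0.2,
                                seed = 1L, mode = c("any", "swap")) {
  mode <- match.arg(mode)
  stopifnot(n_annotators >= 2L, noise_rate >= 0, noise_rate <= 1)
  gold <- corpus$sentences$types_top[corpus$sentences$is_sal]
  tax_top <- load_taxonomy()$top
  cells <- with_seed(seed, {
    m <- matrix(vector("list", length(gold) * n_annotators),
                nrow = length(gold), ncol = n_annotators)
    for (u in seq_along(gold)) {
      m[[u, 1L]] <- gold[[u]]
      for (ann in 2L:n_annotators) {
        labs <- gold[[u]]
        if (stats::runif(1) < noise_rate) {
          op <- if (mode == "swap") "swap" else
            sample(c("add", "remove", "swap"), 1L)
          if (op == "add" || (op == "remove" && length(labs) <= 1L)) {
            labs <- union(labs, sample(setdiff(tax_top, labs), 1L))
          } else if (op == "remove") {
            labs <- setdiff(labs, sample(labs, 1L))
          } else {
            drop_one <- sample(labs, 1L)
            labs <- union(setdiff(labs, drop_one),
                          sample(setdiff(tax_top, labs), 1L))
          }
        }
        m[[u, ann]] <- sort(labs)
      }
    }
    m
  })
  unit_label_matrix(cells,
                    annotators = paste0("A", seq_len(n_annotators)))
}

#' Deterministic template stand-in for the dual-view generator
#'
#' The production dual-view generator is a soft-prompt-tuned
#' encoder-decoder behind the generator contract; this bundled stand-in
#' fills label-specific clause templates (Output View) and additionally
#' splices the prompt keywords into the sentence (Input View), so every
#' downstream augmentation stage is exercisable offline. Deterministic
#' under the seed and always returns exactly `n` non-empty sentences.
#'
#' @param taxonomy A `sal_taxonomy`.
#' @return A generator function `(prompt, n, seed) -> character(n)`
#'   satisfying the contract of [generate_dual_view()].
#' @export
template_generator <- function(taxonomy = load_taxonomy()) {
  function(prompt, n, seed) {
    top <- coarsen(prompt$label, taxonomy)[1]
    clauses <- .clause_bank[[top]]
    if (is.null(clauses)) {
      stop("no templates for label '", prompt$label, "'", call. = FALSE)
    }
    with_seed(seed, {
      vapply(seq_len(n), function(i) {
        cl <- sample(clauses, 1L)
        frame <- sample(.sal_frames, 1L)
        s <- sprintf(frame, cl)
        if (identical(prompt$view, "input_view") &&
            length(prompt$keywords) > 0L) {
          kw <- paste(prompt$keywords, collapse = " and ")
          s <- sub("\\.$", paste0(", with regard to ", kw, "."), s)
        }
        s
      }, character(1))
    })
  }
}
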