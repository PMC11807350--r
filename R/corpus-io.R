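#' Construct an article
#'
#' An article is an ordered list of sections, each with a top-level header
#' (e.g. "Discussion"), an innermost header (e.g. "Study limitations",
#' possibly the same or empty) and a body of running text. Headers may be
#' empty strings but are always present.
#'
#' @param article_id Unique identifier within a corpus.
#' @param sections Data frame with character columns `top_header`,
#'   `innermost_header`, `body`.
#' @param metadata Optional named list (journal type, impact tier, ...).
#' @return An object of class `sal_article`.
#' @export
article <- function(article_id, sections, metadata = list()) {
  stopifnot(is.data.frame(sections),
            all(c("top_header", "innermost_header", "body") %in% names(sections)))
  sections <- sections[, c("top_header", "innermost_header", "body")]
  for (col in names(sections)) {
    if (any(is.na(sections[[col]]))) {
      stop("section field '", col, "' may be empty but not missing",
           call. = FALSE)
    }
  }
  structure(list(article_id = as.character(article_id),
                 sections = sections, metadata = metadata),
            class = "sal_article")
}

#' @export
print.sal_article <- function(x, ...) {
  cat("<sal_article ", x$article_id, "> ", nrow(x$sections), " sections\n",
      sep = "")
  invisible(x)
}

# Document view of an article: section bodies joined by a blank line.
# Returns the flattened text plus 0-based end-exclusive body offsets of
# every section inside it, so section-frame and document-frame coordinates
# interconvert exactly.
flatten_article <- function(art) {
  bodies <- art$sections$body
  sep <- "\n\n"
  starts <- integer(length(bodies))
  pos <- 0L
  for (i in seq_along(bodies)) {
    starts[i] <- pos
    pos <- pos + nchar(bodies[i])
    if (i < length(bodies)) pos <- pos + nchar(sep)
  }
  list(text = paste(bodies, collapse = sep),
       section_start = starts,
       section_end = starts + nchar(bodies))
}

# Common abbreviations that end with a period but do not end a sentence.
.sentence_abbrev <- c("e.g", "i.e", "vs", "al", "fig", "figs", "eq", "ref",
                      "refs", "dr", "mr", "mrs", "ms", "no", "ca", "cf",
                      "approx", "resp", "st")

#' Segment text into sentences
#'
#' Unsupervised punctuation-based sentence segmentation: a sentence ends at
#' a run of `.`, `!` or `?` that is followed by whitespace and an
#' upper-case letter or digit, unless the period terminates a common
#' abbreviation or sits inside a number. Offsets are 0-based,
#' end-exclusive, non-overlapping, ordered, and cover all non-whitespace
#' characters; slicing the input at them reproduces each sentence.
#'
#' @param body Character scalar.
#' @return Data frame with integer columns `char_start`, `char_end`.
#' @examples
#' segment_sentences("First point. Second point.")
#' @export
segment_sentences <- function(body) {
  stopifnot(is.character(body), length(body) == 1L)
  empty <- data.frame(char_start = integer(0), char_end = integer(0))
  if (is.na(body) || !nzchar(trimws(body))) return(empty)

  m <- gregexpr("[.!?]+(?=[ \t\r\n]+[\"'(]?[A-Z0-9])", body, perl = TRUE)[[1]]
  ends <- integer(0)                      # 1-based index of final punctuation
  if (m[1] != -1L) {
    cand <- as.integer(m) + attr(m, "match.length") - 1L
    for (e in cand) {
      st <- as.integer(m)[match(e, cand)]
      prefix <- substr(body, max(1L, st - 12L), st - 1L)
      word <- regmatches(prefix, regexpr("[A-Za-z.]+$", prefix))
      word <- if (length(word)) tolower(sub("\\.$", "", word)) else ""
      if (word %in% .sentence_abbrev) next
      ends <- c(ends, e)
    }
  }
  n <- nchar(body)
  bounds <- c(ends, n)
  starts <- c(1L, ends + 1L)
  out <- data.frame(char_start = integer(0), char_end = integer(0))
  for (i in seq_along(bounds)) {
    seg <- substr(body, starts[i], bounds[i])
    lead <- nchar(seg) - nchar(sub("^[ \t\r\n]+", "", seg))
    trail <- nchar(seg) - nchar(sub("[ \t\r\n]+$", "", seg))
    s0 <- starts[i] + lead
    e0 <- bounds[i] - trail
    if (e0 >= s0) {
      out <- rbind(out, data.frame(char_start = s0 - 1L, char_end = e0))
    }
  }
  out
}

# Slice text by 0-based end-exclusive offsets.
slice_text <- function(text, start, end) {
  substr(rep_len(text, length(start)), start + 1L, end)
}

.default_section_keywords <- c("discussion", "limitation", "weakness",
                               "conclusion", "caveat", "shortcoming",
                               "drawback")

#' Select limitation-relevant sections of an article
#'
#' Returns the abstract plus every section whose top-level or innermost
#' header contains one of the limitation-signalling keywords (`discussion`,
#' `limitation`, `weakness`, `conclusion`, `caveat`, `shortcoming`,
#' `drawback`) as a case-insensitive substring, so "Study Limitations" and
#' "Strengths and weaknesses" both match. The abstract is the section whose
#' top header equals "Abstract" (case-insensitive), or the section named by
#' `metadata$abstract_index`.
#'
#' @param art A `sal_article`.
#' @param keywords Character vector of header keywords.
#' @param include_abstract Include the abstract section?
#' @return Sorted integer vector of section indices (1-based).
#' @export
select_limitation_sections <- function(art,
                                       keywords = .default_section_keywords,
                                       include_abstract = TRUE) {
  heads <- tolower(paste(art$sections$top_header,
                         art$sections$innermost_header, sep = "\n"))
  hit <- rep(FALSE, length(heads))
  for (kw in tolower(keywords)) {
    hit <- hit | grepl(kw, heads, fixed = TRUE)
  }
  idx <- which(hit)
  if (include_abstract) {
    ab <- which(tolower(trimws(art$sections$top_header)) == "abstract")
    if (length(ab) == 0L && !is.null(art$metadata$abstract_index)) {
      ab <- as.integer(art$metadata$abstract_index)
    }
    idx <- union(idx, ab)
  }
  sort(idx)
}

#' Extract sentence records from an article
#'
#' Segments the bodies of the chosen sections into sentences and returns
#' one record per sentence with both section-frame (`char_start`,
#' `char_end` within the section body) and document-frame (`doc_start`,
#' `doc_end` within the flattened article text) offsets, all 0-based
#' end-exclusive.
#'
#' @param art A `sal_article`.
#' @param section_indices Sections to extract; default all.
#' @return Data frame of sentence records.
#' @export
extract_sentences <- function(art, section_indices = seq_len(nrow(art$sections))) {
  flat <- flatten_article(art)
  recs <- list()
  for (si in section_indices) {
    body <- art$sections$body[si]
    seg <- segment_sentences(body)
    if (nrow(seg) == 0L) next
    recs[[length(recs) + 1L]] <- data.frame(
      article_id = art$article_id,
      section_index = si,
      char_start = seg$char_start,
      char_end = seg$char_end,
      doc_start = seg$char_start + flat$section_start[si],
      doc_end = seg$char_end + flat$section_start[si],
      text = slice_text(body, seg$char_start, seg$char_end),
      top_header = art$sections$top_header[si],
      innermost_header = art$sections$innermost_header[si],
      stringsAsFactors = FALSE
    )
  }
  if (length(recs) == 0L) {
    return(data.frame(article_id = character(0), section_index = integer(0),
                      char_start = integer(0), char_end = integer(0),
                      doc_start = integer(0), doc_end = integer(0),
                      text = character(0), top_header = character(0),
                      innermost_header = character(0)))
  }
  do.call(rbind, recs)
}

#' Parse BRAT standoff annotations
#'
#' Reads text-bound ("T") lines of a BRAT `.ann` file against its `.txt`
#' document. Offsets are 0-based and end-exclusive; each line's surface
#' string must reproduce the document slice exactly.
#'
#' @param document_text The full `.txt` content.
#' @param annotation_text The full `.ann` content (may be empty).
#' @param taxonomy Taxonomy used to validate span categories.
#' @param annotator_id Identifier recorded on every span.
#' @return Data frame with columns `id`, `category`, `char_start`,
#'   `char_end`, `surface`, `annotator_id`.
#' @export
parse_brat <- function(document_text, annotation_text,
                       taxonomy = load_taxonomy(), annotator_id = "A1") {
  lines <- strsplit(annotation_text, "\n", fixed = TRUE)[[1]]
  out <- data.frame(id = character(0), category = character(0),
                    char_start = integer(0), char_end = integer(0),
                    surface = character(0), annotator_id = character(0))
  for (i in seq_along(lines)) {
    line <- lines[i]
    if (!nzchar(trimws(line)) || !startsWith(line, "T")) next
    parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3L) {
      stop("malformed BRAT text-bound line ", i, ": ", line, call. = FALSE)
    }
    mid <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
    if (length(mid) != 3L || grepl(";", parts[2], fixed = TRUE)) {
      stop("unsupported BRAT span syntax on line ", i, ": ", parts[2],
           call. = FALSE)
    }
    category <- mid[1]
    s <- suppressWarnings(as.integer(mid[2]))
    e <- suppressWarnings(as.integer(mid[3]))
    if (is.na(s) || is.na(e) || s >= e) {
      stop("invalid offsets on BRAT line ", i, call. = FALSE)
    }
    if (e > nchar(document_text)) {
      stop("span exceeds document bounds on BRAT line ", i, call. = FALSE)
    }
    if (!validate_label(category, "fine", taxonomy)) {
      stop("unknown category '", category, "' on BRAT line ", i, call. = FALSE)
    }
    slice <- slice_text(document_text, s, e)
    if (!identical(slice, parts[3])) {
      stop("surface/offset mismatch on BRAT line ", i, ": expected '",
           parts[3], "', document has '", slice, "'", call. = FALSE)
    }
    out <- rbind(out, data.frame(id = parts[1], category = category,
                                 char_start = s, char_end = e,
                                 surface = parts[3],
                                 annotator_id = annotator_id,
                                 stringsAsFactors = FALSE))
  }
  out
}

#' Project span annotations onto sentences
#'
#' Converts and consolidates span-level type annotations to sentence-level
#' multi-label annotations: a sentence's fine label set is the deduplicated
#' set of categories of all spans overlapping it by at least one character
#' (a span straddling a boundary labels both sentences); the top-level set
#' is obtained by [coarsen()]. Sentences with no overlapping span get empty
#' sets and `is_sal = FALSE`.
#'
#' @param sentences Sentence records sharing a coordinate frame with the
#'   spans (document-frame columns `doc_start`/`doc_end` are used when
#'   present, else `char_start`/`char_end`).
#' @param spans Data frame as returned by [parse_brat()].
#' @param taxonomy A `sal_taxonomy`.
#' @return The sentence records with list-columns `types_fine`,
#'   `types_top` and logical `is_sal` appended.
#' @export
project_spans_to_sentences <- function(sentences, spans,
                                       taxonomy = load_taxonomy()) {
  if (nrow(sentences) == 0L) {
    sentences$types_fine <- list()
    sentences$types_top <- list()
    sentences$is_sal <- logical(0)
    return(sentences)
  }
  use_doc <- all(c("doc_start", "doc_end") %in% names(sentences))
  s0 <- if (use_doc) sentences$doc_start else sentences$char_start
  e0 <- if (use_doc) sentences$doc_end else sentences$char_end
  if (nrow(spans) > 0L && any(spans$char_start < 0L)) {
    stop("span outside document bounds", call. = FALSE)
  }
  fine <- vector("list", nrow(sentences))
  for (i in seq_len(nrow(sentences))) fine[[i]] <- character(0)
  if (nrow(spans) > 0L) {
    for (j in seq_len(nrow(spans))) {
      ov <- which(spans$char_start[j] < e0 & spans$char_end[j] > s0)
      for (i in ov) fine[[i]] <- union(fine[[i]], spans$category[j])
    }
  }
  sentences$types_fine <- lapply(fine, function(x) sort(x))
  sentences$types_top <- lapply(fine, coarsen, taxonomy = taxonomy)
  sentences$is_sal <- lengths(fine) > 0L
  sentences
}

#' Split a corpus into train/development/test sets at the article level
#'
#' Articles (never sentences) are shuffled deterministically under the seed
#' and partitioned by the given ratios; the development and test sizes are
#' the floors of their ratios and every remainder article goes to the
#' training split, so 200 articles at (0.6, 0.2, 0.2) give 120/40/40.
#'
#' @param articles List of `sal_article`s.
#' @param ratios Numeric triple summing to 1 (within 1e-6).
#' @param seed Integer seed.
#' @return List with elements `train`, `dev`, `test`.
#' @export
split_corpus <- function(articles, ratios = c(0.6, 0.2, 0.2), seed = 1L) {
  stopifnot(length(ratios) == 3L, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-6) {
    stop("ratios must sum to 1", call. = FALSE)
  }
  n <- length(articles)
  if (n < 3L) stop("need at least 3 articles to split", call. = FALSE)
  n_dev <- floor(n * ratios[2])
  n_test <- floor(n * ratios[3])
  n_train <- n - n_dev - n_test
  ord <- with_seed(seed, sample.int(n))
  list(train = articles[ord[seq_len(n_train)]],
       dev = articles[ord[n_train + seq_len(n_dev)]],
       test = articles[ord[n_train + n_dev + seq_len(n_test)]])
}

.sentence_fields <- c("article_id", "section_index", "char_start", "char_end",
                      "text", "top_header", "innermost_header")

#' Read and write labeled sentences as JSON Lines
#'
#' One JSON object per line with the sentence record fields, `is_sal` and
#' the two label arrays. `write_sentences()` then `read_sentences()` is a
#' lossless round trip.
#'
#' @param sentences Labeled sentence data frame.
#' @param path File path.
#' @return `read_sentences()` returns the data frame; `write_sentences()`
#'   returns `path` invisibly.
#' @export
write_sentences <- function(sentences, path) {
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  for (i in seq_len(nrow(sentences))) {
    rec <- list(
      article_id = sentences$article_id[i],
      section_index = sentences$section_index[i],
      char_start = sentences$char_start[i],
      char_end = sentences$char_end[i],
      text = sentences$text[i],
      top_header = sentences$top_header[i],
      innermost_header = sentences$innermost_header[i],
      is_sal = isTRUE(sentences$is_sal[i]),
      types_fine = I(as.character(sentences$types_fine[[i]] %||% character(0))),
      types_top = I(as.character(sentences$types_top[[i]] %||% character(0)))
    )
    if ("doc_start" %in% names(sentences)) {
      rec$doc_start <- sentences$doc_start[i]
      rec$doc_end <- sentences$doc_end[i]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE), con)
  }
  invisible(path)
}

#' @rdname write_sentences
#' @export
read_sentences <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  recs <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    obj <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop("malformed JSON on line ", i, ": ",
                           conditionMessage(e), call. = FALSE)
                    })
    missing <- setdiff(c(.sentence_fields, "is_sal"), names(obj))
    if (length(missing) > 0L) {
      stop("record on line ", i, " is missing field(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    recs[[i]] <- obj
  }
  if (length(recs) == 0L) {
    out <- data.frame(article_id = character(0), section_index = integer(0),
                      char_start = integer(0), char_end = integer(0),
                      text = character(0), top_header = character(0),
                      innermost_header = character(0), is_sal = logical(0))
    out$types_fine <- list()
    out$types_top <- list()
    return(out)
  }
  out <- data.frame(
    article_id = vapply(recs, function(r) as.character(r$article_id), ""),
    section_index = vapply(recs, function(r) as.integer(r$section_index), 0L),
    char_start = vapply(recs, function(r) as.integer(r$char_start), 0L),
    char_end = vapply(recs, function(r) as.integer(r$char_end), 0L),
    text = vapply(recs, function(r) as.character(r$text), ""),
    top_header = vapply(recs, function(r) as.character(r$top_header), ""),
    innermost_header = vapply(recs, function(r) as.character(r$innermost_header), ""),
    is_sal = vapply(recs, function(r) isTRUE(r$is_sal), FALSE),
    stringsAsFactors = FALSE
  )
  if (all(vapply(recs, function(r) !is.null(r$doc_start), FALSE))) {
    out$doc_start <- vapply(recs, function(r) as.integer(r$doc_start), 0L)
    out$doc_end <- vapply(recs, function(r) as.integer(r$doc_end), 0L)
  }
  out$types_fine <- lapply(recs, function(r) sort(as.character(r$types_fine %||% character(0))))
  out$types_top <- lapply(recs, function(r) sort(as.character(r$types_top %||% character(0))))
  out
}
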