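make_article <- function(headers, bodies = NULL,
                         inner = rep("", length(headers))) {
  if (is.null(bodies)) {
    bodies <- rep("Filler text one. Filler text two.", length(headers))
  }
  article("A1", data.frame(top_header = headers, innermost_header = inner,
                           body = bodies, stringsAsFactors = FALSE))
}

test_that("BRAT text-bound lines parse with exact surface verification", {
  doc <- "Power low: small sample in one arm."
  spans <- parse_brat(doc, "T1\tSampleSize 11 23\tsmall sample")
  expect_equal(nrow(spans), 1L)
  expect_equal(spans$char_start, 11L)
  expect_equal(spans$char_end, 23L)
  expect_identical(spans$category, "SampleSize")

  expect_equal(nrow(parse_brat(doc, "")), 0L)

  # overlapping spans with different labels are both returned
  ann <- paste("T1\tSampleSize 11 23\tsmall sample",
               "T2\tPopulation 17 30\tsample in one", sep = "\n")
  both <- parse_brat(doc, ann)
  expect_equal(nrow(both), 2L)

  expect_error(parse_brat(doc, "T1\tSampleSize 11 23\twrong text"),
               "mismatch on BRAT line 1")
  expect_error(parse_brat(doc, "T1\tNotALabel 11 23\tsmall sample"),
               "unknown category")
  expect_error(parse_brat(doc, "T1\tSampleSize 11 999\tsmall sample"),
               "bounds")
})

test_that("sentence segmentation covers text and respects offsets", {
  s <- segment_sentences("First point. Second point.")
  expect_equal(nrow(s), 2L)
  expect_equal(nrow(segment_sentences("")), 0L)

  txt <- "The effect (p = 0.03) was small. However, power was low."
  s <- segment_sentences(txt)
  expect_equal(nrow(s), 2L)
  expect_identical(substr(txt, s$char_start[1] + 1, s$char_end[1]),
                   "The effect (p = 0.03) was small.")
  expect_identical(substr(txt, s$char_start[2] + 1, s$char_end[2]),
                   "However, power was low.")

  # offsets ordered, non-overlapping, covering all non-whitespace
  txt2 <- "One here.  Two there!   Three, with 4.5 units? Last one"
  s2 <- segment_sentences(txt2)
  expect_true(all(diff(s2$char_start) > 0))
  expect_true(all(s2$char_end[-nrow(s2)] <= s2$char_start[-1]))
  covered <- unlist(Map(seq, s2$char_start + 1, s2$char_end))
  chars <- strsplit(txt2, "")[[1]]
  expect_true(all(grepl("\\s", chars[setdiff(seq_along(chars), covered)])))
})

test_that("limitation-related sections are selected by header keywords", {
  art <- make_article(c("Introduction", "Methods", "Discussion",
                        "Study Limitations"))
  expect_identical(select_limitation_sections(art), c(3L, 4L))

  art2 <- make_article(c("Abstract", "Strengths and weaknesses", "Results"))
  expect_identical(select_limitation_sections(art2), c(1L, 2L))

  art3 <- make_article(c("Abstract", "Results"))
  expect_identical(select_limitation_sections(art3), 1L)
  expect_identical(select_limitation_sections(art3, include_abstract = FALSE),
                   integer(0))

  # case invariance, and innermost headers count too
  art4 <- make_article(c("Intro", "DISCUSSION", "Body"),
                       inner = c("", "", "Caveats and Drawbacks"))
  expect_identical(select_limitation_sections(art4, include_abstract = FALSE),
                   c(2L, 3L))
})

test_that("span projection consolidates labels and handles straddles", {
  body <- "Intro sentence here. The sample was small. Final remark text."
  art <- make_article("Discussion", body)
  sents <- extract_sentences(art)
  expect_equal(nrow(sents), 3L)

  span_at <- function(pattern, category) {
    s <- regexpr(pattern, body, fixed = TRUE)[1] - 1L
    data.frame(article_id = "A1", category = category, char_start = s,
               char_end = s + nchar(pattern), stringsAsFactors = FALSE)
  }
  lab <- project_spans_to_sentences(sents, span_at("sample was small",
                                                   "SampleSize"))
  expect_identical(lab$types_fine[[2]], "SampleSize")
  expect_identical(lab$types_top[[2]], "UnderpoweredStudy")
  expect_identical(lab$is_sal, c(FALSE, TRUE, FALSE))

  # duplicate category in the same sentence consolidates to one label
  two <- rbind(span_at("The sample", "SampleSize"),
               span_at("was small", "SampleSize"))
  lab2 <- project_spans_to_sentences(sents, two)
  expect_identical(lab2$types_fine[[2]], "SampleSize")

  # straddling span labels both overlapped sentences
  straddle <- span_at("small. Final", "Other")
  lab3 <- project_spans_to_sentences(sents, straddle)
  expect_identical(lab3$types_top[[2]], "Other")
  expect_identical(lab3$types_top[[3]], "Other")

  # label conservation: every span reaches at least one sentence
  n_pairs <- sum(lengths(lab3$types_fine))
  expect_gte(n_pairs, 1L)
})

test_that("article-level splitting is deterministic and exact", {
  arts <- lapply(1:200, function(i) make_article("Discussion"))
  for (i in seq_along(arts)) arts[[i]]$article_id <- paste0("A", i)
  sp <- split_corpus(arts, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(unname(lengths(sp)), c(120L, 40L, 40L))
  sp2 <- split_corpus(arts, c(0.6, 0.2, 0.2), seed = 5)
  expect_identical(sapply(sp$train, function(a) a$article_id),
                   sapply(sp2$train, function(a) a$article_id))
  ids <- unlist(lapply(sp, function(x) sapply(x, function(a) a$article_id)))
  expect_setequal(ids, paste0("A", 1:200))   # disjoint union = input
  expect_equal(length(ids), 200L)

  sp10 <- split_corpus(arts[1:10], c(0.6, 0.2, 0.2), seed = 1)
  expect_identical(unname(lengths(sp10)), c(6L, 2L, 2L))
  expect_error(split_corpus(arts[1:2], seed = 1), "at least 3")
  expect_error(split_corpus(arts, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("JSON Lines sentence records round-trip losslessly", {
  corpus <- fixture_corpus()
  recs <- corpus$sentences[1:100, ]
  path <- tempfile(fileext = ".jsonl")
  write_sentences(recs, path)
  back <- read_sentences(path)
  expect_identical(back$text, recs$text)
  expect_identical(back$is_sal, recs$is_sal)
  expect_identical(back$types_fine, unname(recs$types_fine))
  expect_identical(back$types_top, unname(recs$types_top))
  expect_identical(back$article_id, recs$article_id)

  writeLines('{"article_id":"X","is_sal":false}', path)
  expect_error(read_sentences(path), "line 1")

  file.create(path <- tempfile())
  expect_equal(nrow(read_sentences(path)), 0L)
})
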