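#' @keywords internal
"_PACKAGE"

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's state afterwards. All stochastic operations in the package go
# through this so that a single integer fixes every draw.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Tokenize text into lowercase word tokens
#'
#' Splits on any run of non-alphanumeric characters and lowercases the
#' result. This is the shared tokenizer for the hashing encoder, the
#' Funding rule, EDA and RAKE.
#'
#' @param text Character vector.
#' @return A list of character vectors, one per input element.
#' @export
tokenize_words <- function(text) {
  text <- tolower(as.character(text))
  out <- strsplit(text, "[^a-z0-9]+")
  lapply(out, function(x) x[nzchar(x)])
}

# Deterministic 31-based polynomial string hash over UTF-8 bytes, reduced
# modulo 2^31 - 1. Stable across platforms (pure double arithmetic, all
# intermediates < 2^53).
hash_string <- function(x) {
  vapply(x, function(s) {
    b <- as.integer(charToRaw(s))
    h <- 0
    for (v in b) h <- (h * 31 + v) %% 2147483647
    h
  }, numeric(1), USE.NAMES = FALSE)
}

#' Light suffix-stripping word stemmer
#'
#' A small Porter-family suffix stripper sufficient for cue-word matching:
#' it removes one of the common English suffixes (longest match first) when
#' the remaining stem keeps at least three characters. "funding" and
#' "funds" stem to "fund"; "financed", "financing" and "finance" stem to
#' "financ".
#'
#' @param words Character vector of lowercase tokens.
#' @return Character vector of stems.
#' @export
stem_words <- function(words) {
  suffixes <- c("ational", "fulness", "ization", "ousness", "iveness",
                "tional", "ements", "ations", "ingly", "ement", "ation",
                "ities", "ingly", "edly", "ings", "ness", "ably", "ibly",
                "ies", "ing", "ed", "es", "ly", "s", "e")
  vapply(words, function(w) {
    for (suf in suffixes) {
      if (endsWith(w, suf) && nchar(w) - nchar(suf) >= 3L) {
        return(substr(w, 1L, nchar(w) - nchar(suf)))
      }
    }
    w
  }, character(1), USE.NAMES = FALSE)
}

# Canonical serialization of a label set (sorted, "|"-joined); used to pool
# set-valued annotations and to build composite Bhapkar classes.
canonical_set <- function(labels) {
  if (length(labels) == 0L) return("")
  paste(sort(unique(as.character(labels))), collapse = "|")
}

uncanonical_set <- function(key) {
  if (identical(key, "")) character(0) else strsplit(key, "|", fixed = TRUE)[[1]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
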