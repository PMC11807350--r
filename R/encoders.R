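#' Text encoder contract
#'
#' Classifiers in this package are agnostic to the text representation:
#' an encoder is any object of class `sal_encoder` with fields `name`,
#' `dim` (output width), `sep` (the separator marker used when composing
#' the sentence with its section headers) and a function
#' `encode(texts) -> numeric matrix [n x dim]` that is deterministic for a
#' fixed input. Contextual transformer encoders (e.g. a domain-pretrained
#' biomedical BERT serving its pooled classification token) satisfy the
#' same contract and can be plugged in by wrapping their pooled output;
#' the bundled default is a deterministic feature-hashing bag-of-words
#' encoder that keeps the whole pipeline trainable on a desktop CPU.
#'
#' @param name Encoder name.
#' @param dim Output dimension.
#' @param encode Function from a character vector to an n-by-dim matrix.
#' @param sep Separator marker placed between sentence and headers.
#' @return An object of class `sal_encoder`.
#' @export
text_encoder <- function(name, dim, encode, sep = " [SEP] ") {
  stopifnot(is.function(encode), dim >= 1)
  structure(list(name = name, dim = as.integer(dim), encode = encode,
                 sep = sep), class = "sal_encoder")
}

#' Feature-hashing bag-of-words encoder
#'
#' Tokenizes the input (lowercased word tokens, truncated to `max_length`
#' tokens), hashes every token and every adjacent-token bigram to one of
#' `dim` buckets with a deterministic polynomial string hash, counts
#' bucket hits, and L2-normalizes each row. Fully deterministic and
#' platform-stable.
#'
#' @param dim Number of hash buckets (vector width).
#' @param max_length Token budget per input.
#' @param use_bigrams Also hash adjacent-token bigrams?
#' @return A `sal_encoder`.
#' @export
hash_encoder <- function(dim = 512L, max_length = 128L, use_bigrams = TRUE) {
  dim <- as.integer(dim)
  enc <- function(texts) {
    toks <- tokenize_words(texts)
    out <- matrix(0, nrow = length(texts), ncol = dim)
    for (i in seq_along(toks)) {
      tk <- utils::head(toks[[i]], max_length)
      if (length(tk) == 0L) next
      feats <- tk
      if (use_bigrams && length(tk) > 1L) {
        feats <- c(feats, paste(tk[-length(tk)], tk[-1L], sep = "_"))
      }
      idx <- (hash_string(feats) %% dim) + 1L
      cnt <- tabulate(idx, nbins = dim)
      nrm <- sqrt(sum(cnt^2))
      out[i, ] <- cnt / nrm
    }
    out
  }
  text_encoder(paste0("hash-", dim), dim, enc)
}

#' Resolve an encoder by name
#'
#' `"hash"` (optionally `"hash-<dim>"`) resolves to [hash_encoder()]. Any
#' other name must be supplied as a ready-made `sal_encoder` object by the
#' caller; this keeps heavyweight contextual encoders behind the same
#' contract without making them a dependency.
#'
#' @param name Encoder name or a `sal_encoder` passed through unchanged.
#' @return A `sal_encoder`.
#' @export
resolve_encoder <- function(name = "hash") {
  if (inherits(name, "sal_encoder")) return(name)
  if (identical(name, "hash")) return(hash_encoder())
  m <- regmatches(name, regexec("^hash-([0-9]+)$", name))[[1]]
  if (length(m) == 2L) return(hash_encoder(dim = as.integer(m[2])))
  stop("unknown encoder '", name,
       "'; supply a sal_encoder object for custom encoders", call. = FALSE)
}
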