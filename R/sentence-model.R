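#' Training configuration
#'
#' Hyperparameters shared by the binary sentence classifier and the
#' multi-label type classifier. These are repository defaults chosen for
#' the bundled hashing encoder, not published values.
#'
#' @param epochs Passes over the training data.
#' @param learning_rate SGD step size.
#' @param batch_size Minibatch size.
#' @param seed Integer seed fixing initialization and data order.
#' @param max_length Token budget per input.
#' @param encoder_name Encoder name or `sal_encoder` (see
#'   [resolve_encoder()]).
#' @param hidden Hidden width of the type classifier's MLP head.
#' @param momentum SGD momentum.
#' @return A list of class `sal_train_config`.
#' @export
train_config <- function(epochs = 40L, learning_rate = 0.5, batch_size = 32L,
                         seed = 42L, max_length = 128L, encoder_name = "hash",
                         hidden = 64L, momentum = 0.9) {
  stopifnot(epochs >= 1, learning_rate > 0, batch_size >= 1, max_length >= 1,
            hidden >= 1)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 max_length = as.integer(max_length),
                 encoder_name = encoder_name, hidden = as.integer(hidden),
                 momentum = momentum),
            class = "sal_train_config")
}

#' Compose the classifier input from a sentence and its section headers
#'
#' The classifier input concatenates the target sentence with the
#' top-level section header and the innermost header, joined by the
#' encoder's separator marker. The binary SAL task places the sentence
#' first by default; the type task prepends the headers.
#'
#' @param record A one-row sentence record (or list) with `text`,
#'   `top_header`, `innermost_header`.
#' @param order `"sentence_first"` or `"headers_first"`.
#' @param sep Separator marker.
#' @return A single string; empty headers keep their separator slots.
#' @examples
#' build_input(list(text = "Our sample was small.",
#'                  top_header = "Discussion",
#'                  innermost_header = "Study limitations"))
#' @export
build_input <- function(record, order = c("sentence_first", "headers_first"),
                        sep = " [SEP] ") {
  order <- match.arg(order)
  text <- as.character(record$text)
  top <- as.character(record$top_header %||% "")
  inner <- as.character(record$innermost_header %||% "")
  if (order == "sentence_first") {
    paste(text, top, inner, sep = sep)
  } else {
    paste(top, inner, text, sep = sep)
  }
}

build_inputs <- function(records, order, sep) {
  vapply(seq_len(nrow(records)), function(i) {
    build_input(records[i, ], order = order, sep = sep)
  }, character(1))
}

#' Train the binary SAL sentence classifier
#'
#' Encodes each training sentence together with its headers, then fits a
#' single-logit linear head by minibatch stochastic gradient descent under
#' binary cross-entropy loss (i.e. a sigmoid over one logit, not a
#' two-class softmax). Training is deterministic for a fixed config and
#' seed.
#'
#' @param data Labeled sentence data frame with `text`, `top_header`,
#'   `innermost_header`, `is_sal`; both classes must be present.
#' @param config A [train_config()].
#' @param order Input composition order; the binary task defaults to
#'   sentence first.
#' @param decision_threshold Probability cut-off for the positive class.
#' @return An object of class `sal_binary_model` with a per-epoch loss
#'   history.
#' @export
train_binary <- function(data, config = train_config(),
                         order = "sentence_first", decision_threshold = 0.5) {
  if (nrow(data) == 0L) stop("empty training data", call. = FALSE)
  y <- as.numeric(data$is_sal)
  if (length(unique(y)) < 2L) {
    stop("training data must contain both classes", call. = FALSE)
  }
  encoder <- resolve_encoder(config$encoder_name)
  X <- encoder$encode(build_inputs(data, order, encoder$sep))
  n <- nrow(X); d <- ncol(X)
  lr <- config$learning_rate
  history <- numeric(config$epochs)
  state <- with_seed(config$seed, {
    w <- stats::rnorm(d, sd = 0.01)
    b <- 0
    vw <- numeric(d); vb <- 0
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        z <- drop(Xb %*% w) + b
        p <- 1 / (1 + exp(-z))
        g <- p - y[idx]
        gw <- drop(crossprod(Xb, g)) / length(idx)
        gb <- mean(g)
        vw <- config$momentum * vw - lr * gw
        vb <- config$momentum * vb - lr * gb
        w <- w + vw
        b <- b + vb
      }
      z <- drop(X %*% w) + b
      p <- pmin(pmax(1 / (1 + exp(-z)), 1e-12), 1 - 1e-12)
      history[ep] <- -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    list(w = w, b = b)
  })
  structure(list(encoder = encoder, w = state$w, b = state$b,
                 decision_threshold = decision_threshold, order = order,
                 config = config, history = history),
            class = "sal_binary_model")
}

#' Predict SAL probabilities for sentence records
#'
#' @param model A `sal_binary_model`.
#' @param records Sentence record data frame.
#' @return Data frame with `probability` and `is_sal` (probability at or
#'   above the model's decision threshold counts as positive).
#' @export
predict_sal <- function(model, records) {
  if (nrow(records) == 0L) {
    return(data.frame(probability = numeric(0), is_sal = logical(0)))
  }
  X <- model$encoder$encode(build_inputs(records, model$order,
                                         model$encoder$sep))
  p <- 1 / (1 + exp(-(drop(X %*% model$w) + model$b)))
  data.frame(probability = p, is_sal = p >= model$decision_threshold)
}

#' Binary evaluation for the positive class
#'
#' Precision, recall and F1 for the positive class plus overall accuracy.
#' When nothing is predicted positive, precision (and hence F1) is
#' reported as 0 with `undefined_precision = TRUE`.
#'
#' @param gold,pred Logical vectors of equal length.
#' @return List with `precision`, `recall`, `f1`, `accuracy`,
#'   `undefined_precision`.
#' @export
evaluate_binary <- function(gold, pred) {
  gold <- as.logical(gold); pred <- as.logical(pred)
  if (length(gold) != length(pred)) {
    stop("gold and pred must have equal length", call. = FALSE)
  }
  tp <- sum(gold & pred); fp <- sum(!gold & pred); fn <- sum(gold & !pred)
  undef <- (tp + fp) == 0L
  precision <- if (undef) 0 else tp / (tp + fp)
  recall <- if ((tp + fn) == 0L) NA_real_ else tp / (tp + fn)
  f1 <- if (!is.na(recall) && (precision + recall) > 0) {
    2 * precision * recall / (precision + recall)
  } else 0
  list(precision = precision, recall = recall, f1 = f1,
       accuracy = mean(gold == pred), undefined_precision = undef)
}
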