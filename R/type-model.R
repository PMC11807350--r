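#' Train the multi-label SAL type classifier
#'
#' Encodes each SAL sentence (headers prepended by default), feeds the
#' representation through a one-hidden-layer perceptron and a softmax that
#' yields a probability distribution over the label space, and minimizes
#' cross-entropy against a target distribution that spreads the mass
#' uniformly over the sentence's gold labels. At `top` granularity the
#' label space is the 15 top-level categories; at `fine` granularity it is
#' the 24 fine-grained plus the 15 top-level categories, because sentences
#' may carry only a top-level label. A sigmoid head with per-label binary
#' cross-entropy is available behind `head = "sigmoid"`.
#'
#' @param data Labeled sentence data frame; every row must be a SAL
#'   sentence with at least one gold label at the granularity.
#' @param granularity `"top"` or `"fine"`.
#' @param config A [train_config()].
#' @param taxonomy A `sal_taxonomy`.
#' @param order Input composition order (headers first by default).
#' @param head `"softmax"` (probabilities sum to 1) or `"sigmoid"`.
#' @return An object of class `sal_type_model`.
#' @export
train_type <- function(data, granularity = c("top", "fine"),
                       config = train_config(), taxonomy = load_taxonomy(),
                       order = "headers_first",
                       head = c("softmax", "sigmoid")) {
  granularity <- match.arg(granularity)
  head <- match.arg(head)
  if (nrow(data) == 0L) stop("empty training data", call. = FALSE)
  label_space <- if (granularity == "top") taxonomy$top
                 else c(taxonomy$top, taxonomy$fine)
  gold_col <- if (granularity == "top") "types_top" else "types_fine"
  gold <- data[[gold_col]]
  if (any(lengths(gold) == 0L)) {
    stop("every training sentence needs at least one gold label",
         call. = FALSE)
  }
  unknown <- setdiff(unique(unlist(gold)), label_space)
  if (length(unknown) > 0L) {
    stop("unknown label(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  k <- length(label_space)
  Tmat <- matrix(0, nrow(data), k, dimnames = list(NULL, label_space))
  for (i in seq_len(nrow(data))) {
    Tmat[i, gold[[i]]] <- 1 / length(gold[[i]])
  }
  encoder <- resolve_encoder(config$encoder_name)
  X <- encoder$encode(build_inputs(data, order, encoder$sep))
  n <- nrow(X); d <- ncol(X); h <- config$hidden
  lr <- config$learning_rate
  history <- numeric(config$epochs)
  state <- with_seed(config$seed, {
    W1 <- matrix(stats::rnorm(d * h, sd = sqrt(2 / d)), d, h)
    b1 <- numeric(h)
    W2 <- matrix(stats::rnorm(h * k, sd = sqrt(2 / h)), h, k)
    b2 <- numeric(k)
    vW1 <- matrix(0, d, h); vb1 <- numeric(h)
    vW2 <- matrix(0, h, k); vb2 <- numeric(k)
    forward <- function(Xb) {
      H <- tanh(sweep(Xb %*% W1, 2, b1, "+"))
      Z <- sweep(H %*% W2, 2, b2, "+")
      if (head == "softmax") {
        Z <- Z - apply(Z, 1, max)
        E <- exp(Z)
        P <- E / rowSums(E)
      } else {
        P <- 1 / (1 + exp(-Z))
      }
      list(H = H, P = P)
    }
    for (ep in seq_len(config$epochs)) {
      ord <- sample.int(n)
      for (start in seq(1L, n, by = config$batch_size)) {
        idx <- ord[start:min(start + config$batch_size - 1L, n)]
        Xb <- X[idx, , drop = FALSE]
        Tb <- Tmat[idx, , drop = FALSE]
        fw <- forward(Xb)
        if (head == "sigmoid") Tb <- (Tb > 0) + 0   # per-label binary targets
        dZ <- (fw$P - Tb) / length(idx)
        gW2 <- crossprod(fw$H, dZ); gb2 <- colSums(dZ)
        dH <- (dZ %*% t(W2)) * (1 - fw$H^2)
        gW1 <- crossprod(Xb, dH); gb1 <- colSums(dH)
        vW2 <- config$momentum * vW2 - lr * gW2
        vb2 <- config$momentum * vb2 - lr * gb2
        vW1 <- config$momentum * vW1 - lr * gW1
        vb1 <- config$momentum * vb1 - lr * gb1
        W2 <- W2 + vW2; b2 <- b2 + vb2
        W1 <- W1 + vW1; b1 <- b1 + vb1
      }
      P <- forward(X)$P
      P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
      history[ep] <- if (head == "softmax") {
        -mean(rowSums(Tmat * log(P)))
      } else {
        -mean(rowSums((Tmat > 0) * log(P) + (1 - (Tmat > 0)) * log(1 - P)))
      }
    }
    list(W1 = W1, b1 = b1, W2 = W2, b2 = b2)
  })
  structure(list(encoder = encoder, weights = state, head = head,
                 label_space = label_space, granularity = granularity,
                 order = order, config = config, history = history,
                 taxonomy_version = taxonomy$version),
            class = "sal_type_model")
}

#' Per-label probabilities for sentence records
#'
#' @param model A `sal_type_model`.
#' @param records Sentence record data frame.
#' @return Numeric matrix `[n x labels]`; with the softmax head every row
#'   sums to 1.
#' @export
predict_type_probs <- function(model, records) {
  if (nrow(records) == 0L) {
    return(matrix(0, 0, length(model$label_space),
                  dimnames = list(NULL, model$label_space)))
  }
  X <- model$encoder$encode(build_inputs(records, model$order,
                                         model$encoder$sep))
  w <- model$weights
  H <- tanh(sweep(X %*% w$W1, 2, w$b1, "+"))
  Z <- sweep(H %*% w$W2, 2, w$b2, "+")
  P <- if (model$head == "softmax") {
    Z <- Z - apply(Z, 1, max)
    E <- exp(Z)
    E / rowSums(E)
  } else {
    1 / (1 + exp(-Z))
  }
  dimnames(P) <- list(NULL, model$label_space)
  P
}

#' Fit per-label decision thresholds on a development set
#'
#' Dynamic thresholding: for every label independently, sweep the
#' candidate grid and keep the threshold maximizing that label's binary F1
#' on the development set; ties go to the smallest such threshold. A label
#' absent from the development gold gets the grid maximum with a warning.
#'
#' @param probabilities Matrix `[n x labels]` of per-sentence label
#'   probabilities (columns named).
#' @param gold List of gold label sets, one per development sentence.
#' @param grid Strictly increasing candidate thresholds in (0, 1);
#'   default 0.01 to 0.99 in steps of 0.01.
#' @return Named numeric vector of class `sal_thresholds` with the grid as
#'   an attribute.
#' @export
fit_thresholds <- function(probabilities, gold,
                           grid = seq(0.01, 0.99, by = 0.01)) {
  stopifnot(is.matrix(probabilities), !is.null(colnames(probabilities)))
  if (nrow(probabilities) == 0L) stop("empty development set", call. = FALSE)
  if (length(grid) == 0L || any(diff(grid) <= 0) ||
      any(grid <= 0) || any(grid >= 1)) {
    stop("grid must be strictly increasing within (0, 1)", call. = FALSE)
  }
  if (length(gold) != nrow(probabilities)) {
    stop("gold and probabilities are misaligned", call. = FALSE)
  }
  labels <- colnames(probabilities)
  thr <- stats::setNames(numeric(length(labels)), labels)
  for (lab in labels) {
    y <- vapply(gold, function(g) lab %in% g, logical(1))
    if (!any(y)) {
      warning("label '", lab, "' absent from development gold; ",
              "threshold set to grid maximum", call. = FALSE)
      thr[lab] <- max(grid)
      next
    }
    p <- probabilities[, lab]
    best_f1 <- -1; best_t <- grid[1]
    for (t in grid) {
      pred <- p >= t
      tp <- sum(pred & y); fp <- sum(pred & !y); fn <- sum(!pred & y)
      f1 <- if (tp == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
      if (f1 > best_f1 + 1e-12) {
        best_f1 <- f1
        best_t <- t
      }
    }
    thr[lab] <- best_t
  }
  structure(thr, grid = grid, class = "sal_thresholds")
}

#' Predict label sets with per-label thresholds
#'
#' A label is predicted when its probability reaches its threshold. When
#' no label passes and `fallback = "argmax"` (the default: every input is
#' assumed to be a SAL sentence, so an empty type set is implausible), the
#' single highest-probability label is emitted.
#'
#' @param model A `sal_type_model`.
#' @param thresholds A `sal_thresholds` over the model's label space.
#' @param records Sentence record data frame.
#' @param fallback `"argmax"` or `"empty"`.
#' @return List of character label sets, one per record.
#' @export
predict_types <- function(model, thresholds, records,
                          fallback = c("argmax", "empty")) {
  fallback <- match.arg(fallback)
  if (!setequal(names(thresholds), model$label_space)) {
    stop("thresholds and model label spaces differ", call. = FALSE)
  }
  P <- predict_type_probs(model, records)
  thr <- as.numeric(thresholds[model$label_space])
  lapply(seq_len(nrow(P)), function(i) {
    sel <- model$label_space[P[i, ] >= thr]
    if (length(sel) == 0L && fallback == "argmax") {
      sel <- model$label_space[which.max(P[i, ])]
    }
    sort(sel)
  })
}

#' Rule-based Funding detector
#'
#' Labels a sentence as Funding when any stemmed token equals one of the
#' configured stems. Under the default suffix-stripping stemmer the stems
#' are `"financ"` and `"fund"` ("funding", "funds", "financed",
#' "financing" all match); the literal pair `c("finance", "fund")` can be
#' supplied instead.
#'
#' @param sentence Character scalar.
#' @param stems Stems to match.
#' @param stemmer Function mapping a token vector to stems.
#' @return `TRUE` or `FALSE`.
#' @export
funding_rule <- function(sentence, stems = c("financ", "fund"),
                         stemmer = stem_words) {
  toks <- tokenize_words(sentence)[[1]]
  if (length(toks) == 0L) return(FALSE)
  any(stemmer(toks) %in% stems)
}

#' Predict types with the Funding rule applied
#'
#' The Funding class is rare and excluded from augmentation, so the
#' classifier output is supplemented by [funding_rule()]: sentences where
#' the rule fires gain the Funding label (set union, so an existing
#' Funding prediction is unchanged).
#'
#' @inheritParams predict_types
#' @param stems,stemmer Passed to [funding_rule()].
#' @return List of character label sets.
#' @export
predict_with_rules <- function(model, thresholds, records,
                               fallback = c("argmax", "empty"),
                               stems = c("financ", "fund"),
                               stemmer = stem_words) {
  out <- predict_types(model, thresholds, records, fallback)
  for (i in seq_len(nrow(records))) {
    if (funding_rule(records$text[i], stems = stems, stemmer = stemmer)) {
      out[[i]] <- sort(union(out[[i]], "Funding"))
    }
  }
  out
}
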