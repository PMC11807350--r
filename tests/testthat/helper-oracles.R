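# Independent brute-force oracles used to cross-check the package's
# vectorized/coincidence-matrix implementations. These deliberately use
# naive direct-definition loops.

# Krippendorff's alpha by raw pairwise enumeration (no coincidence matrix)
oracle_alpha <- function(cells, distance) {
  vals <- list()
  unit_of <- integer(0)
  for (u in seq_len(nrow(cells))) {
    row <- Filter(Negate(is.null), cells[u, ])
    if (length(row) < 2L) next
    for (v in row) {
      vals[[length(vals) + 1L]] <- v
      unit_of <- c(unit_of, u)
    }
  }
  n <- length(vals)
  do_sum <- 0
  for (u in unique(unit_of)) {
    idx <- which(unit_of == u)
    m_u <- length(idx)
    for (i in idx) for (j in idx) {
      if (i != j) do_sum <- do_sum + distance(vals[[i]], vals[[j]]) / (m_u - 1)
    }
  }
  Do <- do_sum / n
  de_sum <- 0
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) de_sum <- de_sum + distance(vals[[i]], vals[[j]])
  }
  De <- de_sum / (n * (n - 1))
  1 - Do / De
}

# micro/macro P-R-F1 by per-decision enumeration over an explicit label
# universe
oracle_micro <- function(gold, pred) {
  universe <- unique(c(unlist(gold), unlist(pred)))
  tp <- fp <- fn <- 0
  for (i in seq_along(gold)) {
    for (lab in universe) {
      g <- lab %in% gold[[i]]; p <- lab %in% pred[[i]]
      if (g && p) tp <- tp + 1
      if (!g && p) fp <- fp + 1
      if (g && !p) fn <- fn + 1
    }
  }
  P <- if (tp + fp == 0) 0 else tp / (tp + fp)
  R <- tp / (tp + fn)
  list(precision = P, recall = R,
       f1 = if (P + R > 0) 2 * P * R / (P + R) else 0)
}

oracle_macro <- function(gold, pred) {
  universe <- sort(unique(c(unlist(gold), unlist(pred))))
  scores <- sapply(universe, function(lab) {
    tp <- fp <- fn <- 0
    for (i in seq_along(gold)) {
      g <- lab %in% gold[[i]]; p <- lab %in% pred[[i]]
      if (g && p) tp <- tp + 1
      if (!g && p) fp <- fp + 1
      if (g && !p) fn <- fn + 1
    }
    P <- if (tp + fp == 0) 0 else tp / (tp + fp)
    R <- if (tp + fn == 0) 0 else tp / (tp + fn)
    c(P = P, R = R, F = if (P + R > 0) 2 * P * R / (P + R) else 0)
  })
  list(precision = mean(scores["P", ]), recall = mean(scores["R", ]),
       f1 = mean(scores["F", ]))
}

# Bhapkar statistic via the multinomial delta method: d = A m with m the
# vectorized cell counts, Cov(m) = n (diag(p) - p p'), V = A Cov A'.
oracle_bhapkar <- function(tab) {
  k <- nrow(tab)
  n <- sum(tab)
  m <- as.vector(tab)              # column-major: cell (i, j) at (j-1)k + i
  p <- m / n
  A <- matrix(0, k - 1, k * k)
  for (r in seq_len(k - 1)) {
    for (i in seq_len(k)) for (j in seq_len(k)) {
      pos <- (j - 1) * k + i
      if (i == r) A[r, pos] <- A[r, pos] + 1   # row-r marginal
      if (j == r) A[r, pos] <- A[r, pos] - 1   # col-r marginal
    }
  }
  d <- drop(A %*% m)
  Cov <- n * (diag(p) - outer(p, p))
  V <- A %*% Cov %*% t(A)
  drop(t(d) %*% solve(V, d))
}

# exhaustive per-label threshold search, direct definition
oracle_best_threshold <- function(p, y, grid) {
  f1_at <- sapply(grid, function(t) {
    pred <- p >= t
    tp <- sum(pred & y)
    if (tp == 0) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(y)
    2 * prec * rec / (prec + rec)
  })
  list(threshold = grid[which.max(f1_at)], f1 = max(f1_at))
}

# random label-set fixtures
random_label_sets <- function(n, labels, max_size = 3L, allow_empty = TRUE) {
  lapply(seq_len(n), function(i) {
    k <- sample(0:max_size, 1L)
    if (!allow_empty) k <- max(1L, k)
    sort(sample(labels, min(k, length(labels))))
  })
}
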