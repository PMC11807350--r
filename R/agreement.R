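#' MASI distance between two label sets
#'
#' MASI (Measuring Agreement on Set-valued Items) scores the similarity of
#' two sets as the product of their Jaccard overlap J and a monotonicity
#' weight M: M = 1 for identical sets, 2/3 when one set strictly contains
#' the other, 1/3 when they overlap but neither contains the other, and 0
#' for disjoint sets. The distance is 1 - J*M. Two empty sets are
#' identical (distance 0); an empty versus a non-empty set is disjoint
#' (distance 1).
#'
#' @param a,b Character vectors (label sets; empty allowed).
#' @return A number in \[0, 1\].
#' @examples
#' masi_distance(c("A"), c("A", "B"))  # 2/3
#' @export
masi_distance <- function(a, b) {
  a <- unique(as.character(a)); b <- unique(as.character(b))
  if (length(a) == 0L && length(b) == 0L) return(0)
  inter <- length(intersect(a, b))
  uni <- length(union(a, b))
  if (inter == 0L) return(1)
  J <- inter / uni
  M <- if (setequal(a, b)) 1
       else if (all(a %in% b) || all(b %in% a)) 2 / 3
       else 1 / 3
  1 - J * M
}

#' Nominal (identity) distance between label sets
#'
#' 0 when the two sets are equal, 1 otherwise. With singleton sets this is
#' the classical nominal metric for Krippendorff's alpha.
#'
#' @param a,b Character vectors.
#' @return 0 or 1.
#' @export
nominal_distance <- function(a, b) {
  as.numeric(!setequal(unique(as.character(a)), unique(as.character(b))))
}

#' Construct a unit-by-annotator label matrix
#'
#' The reliability data for Krippendorff's alpha: one row per unit
#' (sentence), one column per annotator, each cell a label set or `NULL`
#' for a missing annotation. At least two annotators are required and every
#' unit must carry at least one annotation; units with fewer than two
#' annotations are retained here but skipped when coincidences are
#' computed.
#'
#' @param cells A list-matrix (`matrix(list(...))`) of label sets / `NULL`.
#' @param units,annotators Optional dimension names.
#' @return An object of class `sal_unit_matrix`.
#' @export
unit_label_matrix <- function(cells, units = NULL, annotators = NULL) {
  stopifnot(is.matrix(cells), is.list(cells))
  if (ncol(cells) < 2L) stop("need at least 2 annotators", call. = FALSE)
  n_coded <- apply(cells, 1L, function(row) sum(!vapply(row, is.null, TRUE)))
  if (any(n_coded == 0L)) {
    stop("every unit needs at least one annotation", call. = FALSE)
  }
  rownames(cells) <- units %||% rownames(cells)
  colnames(cells) <- annotators %||% colnames(cells)
  structure(list(cells = cells), class = "sal_unit_matrix")
}

#' Krippendorff's alpha with a pluggable set distance
#'
#' Computes alpha = 1 - Do/De in the coincidence-matrix formulation for
#' any number of annotators with missing annotations: units with fewer
#' than two annotations are dropped; within each pairable unit every
#' ordered pair of values contributes its distance weighted by
#' 1/(m_u - 1); expected disagreement pools all pairable values. The
#' supplied `distance` plays the role of the squared difference term, so a
#' set-valued metric such as [masi_distance()] plugs in directly.
#'
#' @param m A `sal_unit_matrix` (or a bare list-matrix).
#' @param distance Function of two label sets returning a number in
#'   \[0, 1\]; default [masi_distance()].
#' @return Alpha (a number \eqn{\le 1}).
#' @export
krippendorff_alpha <- function(m, distance = masi_distance) {
  cells <- if (inherits(m, "sal_unit_matrix")) m$cells else m
  stopifnot(is.matrix(cells), is.list(cells))
  # canonical keys so identical sets pool together
  keys <- apply(cells, c(1, 2), function(cell) {
    v <- cell[[1]]
    if (is.null(v)) NA_character_ else canonical_set(v)
  })
  m_u <- rowSums(!is.na(keys))
  pairable <- which(m_u >= 2L)
  if (length(pairable) == 0L) {
    stop("alpha undefined: no unit has two or more annotations", call. = FALSE)
  }
  pooled <- table(keys[pairable, , drop = FALSE][!is.na(keys[pairable, , drop = FALSE])])
  vals <- names(pooled)
  nv <- length(vals)
  dmat <- matrix(0, nv, nv, dimnames = list(vals, vals))
  for (i in seq_len(nv)) {
    for (j in seq_len(nv)) {
      if (i < j) {
        d <- distance(uncanonical_set(vals[i]), uncanonical_set(vals[j]))
        dmat[i, j] <- d
        dmat[j, i] <- d
      }
    }
  }
  n_total <- sum(pooled)
  do_sum <- 0
  for (u in pairable) {
    row <- keys[u, ]
    row <- row[!is.na(row)]
    cnt <- table(row)
    idx <- match(names(cnt), vals)
    cvec <- as.numeric(cnt)
    # ordered within-unit coincidences: c_k * c_l for k != l
    pair_d <- (cvec %o% cvec) * dmat[idx, idx, drop = FALSE]
    do_sum <- do_sum + sum(pair_d) / (length(row) - 1L)
  }
  Do <- do_sum / n_total
  nvec <- as.numeric(pooled)
  De <- sum((nvec %o% nvec) * dmat) / (n_total * (n_total - 1L))
  if (De == 0) {
    if (Do == 0) return(1)
    stop("alpha undefined: zero expected but nonzero observed disagreement",
         call. = FALSE)
  }
  1 - Do / De
}

#' Cohen's kappa for two aligned categorical sequences
#'
#' Pairwise token-level chance-corrected agreement: kappa =
#' (po - pe) / (1 - pe), with pe the sum of products of the two
#' annotators' marginal proportions. When both annotators assign one and
#' the same label everywhere (pe = 1), kappa is defined as 1.
#'
#' @param a,b Character vectors of identical length (token labels,
#'   including an outside label such as `"O"`).
#' @return Kappa (a number \eqn{\le 1}).
#' @export
cohens_kappa <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  if (length(a) != length(b)) {
    stop("sequences must have identical length", call. = FALSE)
  }
  if (length(a) == 0L) stop("empty sequences", call. = FALSE)
  po <- mean(a == b)
  cats <- union(a, b)
  pa <- table(factor(a, levels = cats)) / length(a)
  pb <- table(factor(b, levels = cats)) / length(b)
  pe <- sum(as.numeric(pa) * as.numeric(pb))
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Pairwise Cohen's kappa matrix
#'
#' @param sequences Named list of aligned categorical label vectors, one
#'   per annotator.
#' @return Symmetric matrix of pairwise kappa values (diagonal 1).
#' @export
kappa_matrix <- function(sequences) {
  k <- length(sequences)
  nms <- names(sequences) %||% paste0("A", seq_len(k))
  out <- matrix(1, k, k, dimnames = list(nms, nms))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      if (i < j) {
        v <- cohens_kappa(sequences[[i]], sequences[[j]])
        out[i, j] <- v
        out[j, i] <- v
      }
    }
  }
  out
}
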