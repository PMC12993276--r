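# External and internal clustering evaluation: adjusted Rand index,
# normalised mutual information, and silhouette.

#' @noRd
.check_labels <- function(u, v) {
  u <- as.vector(u); v <- as.vector(v)
  if (length(u) != length(v)) stop("label vectors must have equal length")
  if (length(u) == 0L) stop("label vectors must be non-empty")
  list(u = u, v = v)
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, adjusted for chance:
#' \code{(RI - E[RI]) / (max RI - E[RI])}, computed from the contingency
#' table via the combinatorial formula. Equals 1 for identical partitions
#' (up to label permutation) and is near 0 for random labelings.
#'
#' @param u,v label vectors of equal length
#' @return scalar in (-1, 1]
#' @export
adjustedRandIndex <- function(u, v) {
  l <- .check_labels(u, v)
  tab <- table(l$u, l$v)
  sum_nij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  n2 <- choose(length(l$u), 2)
  expected <- a * b / n2
  maxi <- (a + b) / 2
  if (maxi == expected) return(1)          # both partitions trivial
  unname((sum_nij - expected) / (maxi - expected))
}

#' Normalised mutual information
#'
#' \code{2 MI(U, V) / (H(U) + H(V))} with the mutual information and
#' entropies taken from the empirical joint distribution (natural log;
#' the base cancels in the ratio). Two constant labelings are identical
#' partitions and score 1.
#'
#' @param u,v label vectors of equal length
#' @return scalar in [0, 1]
#' @export
normalizedMutualInfo <- function(u, v) {
  l <- .check_labels(u, v)
  n <- length(l$u)
  tab <- table(l$u, l$v) / n
  pu <- rowSums(tab)
  pv <- colSums(tab)
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu + hv == 0) return(1)
  mi <- 0
  for (i in seq_along(pu)) for (j in seq_along(pv)) {
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pu[i] * pv[j]))
  }
  unname(2 * mi / (hu + hv))
}

#' Mean silhouette width
#'
#' For each cell, \code{(b - a) / max(a, b)} where a is its mean distance
#' to its own cluster and b the smallest mean distance to another cluster;
#' the score is the mean over cells. Cells in singleton clusters contribute
#' 0. Distances are Euclidean in the embedding by default, or cosine.
#'
#' @param Z cells x features matrix (typically the embedding)
#' @param labels cluster assignment per cell; at least 2 clusters required
#' @param metric \code{"euclidean"} or \code{"cosine"}
#' @return scalar in [-1, 1]
#' @export
silhouetteScore <- function(Z, labels, metric = c("euclidean", "cosine")) {
  metric <- match.arg(metric)
  Z <- as.matrix(Z)
  labels <- as.vector(labels)
  if (nrow(Z) != length(labels)) stop("one label per row of Z required")
  ul <- unique(labels)
  if (length(ul) < 2L) stop("silhouette requires at least 2 clusters")
  d <- if (metric == "euclidean") {
    as.matrix(stats::dist(Z))
  } else {
    nrm <- sqrt(rowSums(Z^2))
    if (any(nrm == 0)) stop("cosine silhouette requires nonzero rows")
    1 - tcrossprod(Z / nrm)
  }
  n <- nrow(Z)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1L) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1L)
    b <- min(vapply(ul[ul != labels[i]],
                    function(k) mean(d[i, labels == k]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Evaluate a clustering against ground truth
#'
#' @param pred predicted label vector
#' @param truth true label vector
#' @param embedding optional cells x latent matrix; when given the
#'   silhouette of the prediction is included
#' @return one-row data.frame with columns \code{ari}, \code{nmi} and,
#'   when an embedding is given, \code{silhouette}
#' @export
evaluateClustering <- function(pred, truth, embedding = NULL) {
  out <- data.frame(ari = adjustedRandIndex(truth, pred),
                    nmi = normalizedMutualInfo(truth, pred))
  if (!is.null(embedding))
    out$silhouette <- silhouetteScore(embedding, pred)
  out
}
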