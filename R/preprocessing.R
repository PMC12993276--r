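# Preprocessing: library-size normalisation, log1p, highly-variable-gene
# selection, cosine KNN graph, and the three stochastic augmentations.

#' @noRd
.as_count_matrix <- function(X) {
  if (is(X, "Matrix")) X <- as.matrix(X)
  if (!is.matrix(X)) X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (any(X < 0)) stop("count matrix must be non-negative")
  if (is.null(rownames(X))) rownames(X) <- paste0("cell_", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("gene_", seq_len(ncol(X)))
  if (anyDuplicated(rownames(X))) stop("cell identifiers must be unique")
  if (anyDuplicated(colnames(X))) stop("gene identifiers must be unique")
  X
}

#' Library-size normalisation
#'
#' Rescales every cell so its total expression equals a common target
#' \code{s0}: \code{Xnorm_ij = X_ij / sum_j(X_ij) * s0}. Cells whose counts
#' are all zero have no defined scaling and are dropped with a warning.
#' The per-cell size factors (library size over the median library size)
#' are recorded for the ZINB mean head.
#'
#' @param X non-negative cells x genes count matrix
#' @param s0 common library target (default 10,000)
#' @return a \code{\link{NormalizedCounts}}
#' @examples
#' nc <- normalizeLibrarySize(matrix(c(1, 1, 2, 5, 0, 5), 2, byrow = TRUE))
#' rowSums(normValues(nc))
#' @export
normalizeLibrarySize <- function(X, s0 = 1e4) {
  X <- .as_count_matrix(X)
  lib <- rowSums(X)
  zero <- lib == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero cell(s) dropped: ",
            paste(utils::head(rownames(X)[zero], 5), collapse = ", "))
    X <- X[!zero, , drop = FALSE]
    lib <- lib[!zero]
  }
  if (nrow(X) == 0L) stop("no cells left after dropping all-zero rows")
  vals <- X / lib * s0
  new("NormalizedCounts", values = vals, scale = s0,
      sizeFactors = lib / stats::median(lib))
}

#' Elementwise log1p transform
#'
#' \code{ln(x + 1)}, applied to the denoised matrix that feeds the masked
#' representation learner (the ZINB likelihood itself always sees raw
#' counts).
#'
#' @param x non-negative matrix or \code{\link{NormalizedCounts}}
#' @return numeric matrix
#' @export
log1pTransform <- function(x) {
  if (is(x, "NormalizedCounts")) x <- normValues(x)
  if (any(x < 0)) stop("log1p transform requires non-negative input")
  log1p(x)
}

#' Highly variable gene selection
#'
#' Ranks genes by dispersion (variance over mean of the library-normalised
#' expression), z-scored within 20 mean-occupancy bins so that highly
#' expressed genes do not dominate, and returns the indices of the top
#' \code{nTop} genes in their original (stable) order. Genes with zero
#' variance rank below every gene with positive variance.
#'
#' @param X cells x genes count matrix
#' @param nTop number of genes to retain
#' @param nBins number of mean bins for dispersion normalisation
#' @return increasing integer vector of retained gene indices
#' @export
selectHVG <- function(X, nTop = 2000, nBins = 20) {
  X <- .as_count_matrix(X)
  g <- ncol(X)
  if (nTop <= 0) stop("nTop must be positive")
  if (nTop >= g) return(seq_len(g))
  lib <- rowSums(X)
  lib[lib == 0] <- 1
  Xn <- X / lib * mean(lib)
  mu <- colMeans(Xn)
  v <- apply(Xn, 2L, stats::var)
  disp <- ifelse(mu > 0, v / mu, 0)
  # standardise dispersion within quantile bins of the mean; median/MAD
  # is used so that a bin dominated by genuinely variable genes does not
  # normalise its own signal away
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = nBins + 1)))
  bin <- cut(mu, breaks = br, include.lowest = TRUE)
  nd <- disp
  for (b in levels(bin)) {
    i <- which(bin == b)
    if (length(i) < 2L) { nd[i] <- 0; next }
    s <- stats::mad(disp[i])
    if (s == 0) s <- stats::sd(disp[i])
    if (s == 0) { nd[i] <- 0; next }
    nd[i] <- (disp[i] - stats::median(disp[i])) / s
  }
  nd[v == 0] <- -Inf
  sort(order(nd, decreasing = TRUE)[seq_len(nTop)])
}

#' Cosine k-nearest-neighbour graph
#'
#' For each cell, the \code{k} nearest other cells under cosine distance
#' \code{1 - x.y / (|x||y|)}. Ties are broken towards the lower cell index.
#'
#' @param X numeric cells x features matrix with no zero-norm rows
#' @param k neighbours per cell (must be < number of cells)
#' @return a \code{\link{KNNGraph}}
#' @export
buildKnnGraph <- function(X, k = 15) {
  X <- as.matrix(X)
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L || k >= n) stop("k must satisfy 1 <= k < n_cells")
  nrm <- sqrt(rowSums(X^2))
  if (any(nrm == 0)) stop("zero-norm rows must be removed before building ",
                          "the KNN graph")
  Xunit <- X / nrm
  d <- 1 - tcrossprod(Xunit)
  nb <- matrix(0L, n, k)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nb[i, ] <- order(di)[seq_len(k)]     # stable order: ties to lower index
  }
  new("KNNGraph", k = k, neighbors = nb, metric = "cosine")
}

#' Stochastic augmentation of an expression matrix
#'
#' Produces a training-time view of \code{X} by applying, in order: zeroing
#' a random fraction of gene entries per cell, adding i.i.d. Gaussian noise,
#' and exchanging a random fraction of each cell's entries with one
#' uniformly chosen KNN neighbour. The input matrix is never modified. With
#' all three dials at zero the output equals the input exactly.
#'
#' @param X numeric cells x genes matrix
#' @param graph a \code{\link{KNNGraph}} over the same cells (required only
#'   when \code{swapRatio > 0})
#' @param config an \code{\link{augmentationConfig}}
#' @param seed optional integer seed; identical seeds give bit-identical
#'   output
#' @return augmented copy of \code{X}
#' @export
augmentCells <- function(X, graph = NULL, config = augmentationConfig(),
                         seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  g <- ncol(X)
  out <- X
  with_seed(seed, {
    if (config$maskFraction > 0) {
      m <- round(config$maskFraction * g)
      for (i in seq_len(n)) out[i, sample.int(g, m)] <- 0
    }
    if (config$noiseVariance > 0) {
      out <- out + matrix(stats::rnorm(n * g, 0,
                                       sqrt(config$noiseVariance)), n, g)
    }
    if (config$swapRatio > 0) {
      if (is.null(graph)) stop("swap augmentation requires a KNN graph")
      nb <- knnNeighbors(graph)
      m <- round(config$swapRatio * g)
      for (i in seq_len(n)) {
        j <- nb[i, sample.int(ncol(nb), 1L)]
        idx <- sample.int(g, m)
        tmp <- out[i, idx]
        out[i, idx] <- out[j, idx]
        out[j, idx] <- tmp
      }
    }
  })
  out
}
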