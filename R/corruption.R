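# Self-supervised corruption of the denoised matrix: within-gene shuffling,
# Bernoulli mask sampling, and elementwise composition
# X_M = X' * M + X_z * (1 - M).

#' Shuffle expression values within genes
#'
#' Permutes each gene column independently across cells, preserving every
#' gene's value multiset (and hence its marginal distribution) while
#' destroying cell identity. This is the substitution source for the
#' masking corruption.
#'
#' @param X numeric cells x genes matrix
#' @param seed optional integer seed
#' @return matrix of the same shape with each column permuted
#' @export
shuffleWithinGenes <- function(X, seed = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  with_seed(seed, {
    out <- X
    for (j in seq_len(ncol(X))) out[, j] <- X[sample.int(n), j]
    out
  })
}

#' Sample a Bernoulli mask matrix
#'
#' Independent draws \code{M_ij ~ Bernoulli(p_j)} with a per-gene (or
#' common) probability.
#'
#' @param n number of cells (rows)
#' @param g number of genes (columns)
#' @param p masking probability: scalar or one value per gene, in [0, 1]
#' @param seed optional integer seed
#' @return binary n x g matrix
#' @export
sampleMask <- function(n, g, p, seed = NULL) {
  if (any(p < 0 | p > 1)) stop("mask probabilities must lie in [0, 1]")
  if (length(p) == 1L) p <- rep(p, g)
  if (length(p) != g) stop("p must be scalar or one probability per gene")
  with_seed(seed,
    matrix(stats::rbinom(n * g, 1L, rep(p, each = n)), n, g))
}

#' Compose the corrupted matrix
#'
#' \code{X_M = X' * M + X_z * (1 - M)} elementwise: masked entries come
#' from the shuffled matrix, unmasked entries are the denoised values,
#' untouched.
#'
#' @param shuffled the within-gene shuffled matrix X'
#' @param denoised the denoised matrix X_z
#' @param mask binary matrix M
#' @return corrupted matrix of the same shape
#' @export
composeMasked <- function(shuffled, denoised, mask) {
  shuffled <- as.matrix(shuffled); denoised <- as.matrix(denoised)
  mask <- as.matrix(mask)
  if (!identical(dim(shuffled), dim(denoised)) ||
      !identical(dim(shuffled), dim(mask)))
    stop("shuffled, denoised and mask must have identical shape")
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  shuffled * mask + denoised * (1 - mask)
}

#' Draw a full corrupted view of a denoised matrix
#'
#' Convenience wrapper drawing a fresh within-gene shuffle and Bernoulli
#' mask and composing them; one such view is drawn per training epoch.
#'
#' @param denoised the denoised (log1p-transformed) matrix X_z
#' @param config a \code{\link{corruptionConfig}}
#' @param seed optional integer seed
#' @return a \code{\link{MaskedBatch}}
#' @export
makeMaskedBatch <- function(denoised, config = corruptionConfig(),
                            seed = NULL) {
  denoised <- as.matrix(denoised)
  n <- nrow(denoised); g <- ncol(denoised)
  p <- config$maskRatio
  if (length(p) == 1L) p <- rep(p, g)
  with_seed(seed, {
    shuf <- shuffleWithinGenes(denoised)
    M <- sampleMask(n, g, p)
    new("MaskedBatch", corrupted = composeMasked(shuf, denoised, M),
        mask = M + 0, shuffled = shuf, maskProbs = p)
  })
}
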