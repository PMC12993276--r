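#' @import methods
NULL

#' Per-entry zero-inflated negative binomial parameters
#'
#' Container for the three parameter matrices of a ZINB model over a
#' cells-by-genes count matrix: the conditional mean, the (gene/entry-wise)
#' dispersion, and the zero-inflation (dropout) probability. The three
#' matrices must be congruent and respect the support of each parameter.
#'
#' @slot mean non-negative numeric matrix of conditional means
#' @slot dispersion strictly positive numeric matrix of NB dispersions
#' @slot dropout numeric matrix of dropout probabilities in [0, 1]
#'
#' @export
setClass("ZINBParams",
  representation(mean = "matrix", dispersion = "matrix", dropout = "matrix"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@mean)
    if (!identical(d, dim(object@dispersion)) ||
        !identical(d, dim(object@dropout)))
      msg <- c(msg, "mean, dispersion and dropout must have identical shape")
    if (any(object@mean < 0)) msg <- c(msg, "mean must be non-negative")
    if (any(object@dispersion <= 0))
      msg <- c(msg, "dispersion must be strictly positive")
    if (any(object@dropout < 0 | object@dropout > 1))
      msg <- c(msg, "dropout must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn ZINBParams constructor
#' @param mean,dispersion,dropout parameter matrices (see slots)
#' @export
ZINBParams <- function(mean, dispersion, dropout) {
  new("ZINBParams", mean = as.matrix(mean),
      dispersion = as.matrix(dispersion), dropout = as.matrix(dropout))
}

#' @describeIn ZINBParams mean matrix accessor
#' @param object a \code{ZINBParams}
#' @export
zinbMean <- function(object) object@mean
#' @describeIn ZINBParams dispersion matrix accessor
#' @export
zinbDispersion <- function(object) object@dispersion
#' @describeIn ZINBParams dropout matrix accessor
#' @export
zinbDropout <- function(object) object@dropout

setMethod("show", "ZINBParams", function(object) {
  d <- dim(object@mean)
  cat("ZINBParams:", d[1], "cells x", d[2], "genes\n")
  cat("  mean range      [", format(min(object@mean), digits = 4), ",",
      format(max(object@mean), digits = 4), "]\n")
  cat("  dispersion range[", format(min(object@dispersion), digits = 4), ",",
      format(max(object@dispersion), digits = 4), "]\n")
  cat("  mean dropout    ", format(mean(object@dropout), digits = 4), "\n")
})

#' Library-size-normalised expression matrix
#'
#' Counts rescaled so every cell (row) sums to a common target \code{scale}
#' (10,000 by default in the pipeline), with the per-cell size factors
#' (library size over median library size) retained for the ZINB mean head.
#'
#' @slot values non-negative matrix, rows summing to \code{scale}
#' @slot scale the common row target s0
#' @slot sizeFactors strictly positive per-cell scalars
#' @export
setClass("NormalizedCounts",
  representation(values = "matrix", scale = "numeric",
                 sizeFactors = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@scale) != 1L || object@scale <= 0)
      msg <- c(msg, "scale must be a single positive number")
    if (any(object@values < 0)) msg <- c(msg, "values must be non-negative")
    if (length(object@sizeFactors) != nrow(object@values))
      msg <- c(msg, "one size factor per cell required")
    if (any(object@sizeFactors <= 0))
      msg <- c(msg, "size factors must be strictly positive")
    rs <- rowSums(object@values)
    if (any(abs(rs - object@scale) > 1e-6 * object@scale))
      msg <- c(msg, "every row must sum to `scale`")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn NormalizedCounts normalised value matrix accessor
#' @param object a \code{NormalizedCounts}
#' @export
normValues <- function(object) object@values
#' @describeIn NormalizedCounts per-cell size factor accessor
#' @export
cellSizeFactors <- function(object) object@sizeFactors

setMethod("show", "NormalizedCounts", function(object) {
  cat("NormalizedCounts:", nrow(object@values), "cells x",
      ncol(object@values), "genes; row target", object@scale, "\n")
})

#' Cosine k-nearest-neighbour graph over cells
#'
#' @slot k number of neighbours per cell
#' @slot neighbors integer matrix (cells x k) of neighbour indices; a cell is
#'   never its own neighbour, ties broken towards the lower index
#' @slot metric the distance used (always \code{"cosine"})
#' @export
setClass("KNNGraph",
  representation(k = "integer", neighbors = "matrix", metric = "character"),
  validity = function(object) {
    msg <- character()
    n <- nrow(object@neighbors)
    if (ncol(object@neighbors) != object@k)
      msg <- c(msg, "neighbor matrix must have k columns")
    if (object@k >= n) msg <- c(msg, "k must be smaller than the cell count")
    if (any(object@neighbors == seq_len(n)))
      msg <- c(msg, "a cell must not be its own neighbor")
    if (any(object@neighbors < 1L) || any(object@neighbors > n))
      msg <- c(msg, "neighbor indices out of range")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn KNNGraph neighbour index matrix accessor
#' @param object a \code{KNNGraph}
#' @export
knnNeighbors <- function(object) object@neighbors

setMethod("show", "KNNGraph", function(object) {
  cat("KNNGraph (cosine):", nrow(object@neighbors), "cells, k =",
      object@k, "\n")
})

#' A corrupted view of the denoised matrix for masked self-supervision
#'
#' Holds the corrupted matrix together with the ground-truth Bernoulli mask
#' (1 = entry replaced by its within-gene shuffled counterpart) and the
#' shuffled source matrix, so that the mask-prediction and weighted
#' reconstruction losses can be computed exactly.
#'
#' @slot corrupted the composed matrix X_M
#' @slot mask binary matrix, 1 where the entry was replaced
#' @slot shuffled the within-gene shuffled source matrix
#' @slot maskProbs per-gene Bernoulli probabilities used to draw the mask
#' @export
setClass("MaskedBatch",
  representation(corrupted = "matrix", mask = "matrix",
                 shuffled = "matrix", maskProbs = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@corrupted)
    if (!identical(d, dim(object@mask)) || !identical(d, dim(object@shuffled)))
      msg <- c(msg, "corrupted, mask and shuffled must share a shape")
    if (!all(object@mask %in% c(0, 1)))
      msg <- c(msg, "mask entries must be 0 or 1")
    if (length(object@maskProbs) != d[2])
      msg <- c(msg, "one mask probability per gene required")
    if (any(object@maskProbs < 0 | object@maskProbs > 1))
      msg <- c(msg, "mask probabilities must lie in [0, 1]")
    if (length(msg)) msg else TRUE
  }
)

setMethod("show", "MaskedBatch", function(object) {
  cat("MaskedBatch:", nrow(object@corrupted), "x", ncol(object@corrupted),
      "; empirical mask rate", format(mean(object@mask), digits = 4), "\n")
})

#' Fitted ZINB denoising autoencoder
#'
#' @slot nets internal network weights (encoder, decoder trunk, three heads)
#' @slot config the \code{\link{denoiserConfig}} used
#' @slot sizeFactors per-cell size factors seen during training
#' @slot input the encoder input matrix retained for refitting/denoising
#' @slot counts the raw count matrix the likelihood was evaluated on
#' @slot history per-epoch training loss
#' @slot trained whether training completed
#' @export
setClass("ZINBDenoiser",
  representation(nets = "list", config = "list", sizeFactors = "numeric",
                 input = "matrix", counts = "matrix",
                 history = "data.frame", trained = "logical"))

setMethod("show", "ZINBDenoiser", function(object) {
  cat("ZINBDenoiser:", ncol(object@counts), "genes, latent",
      object@config$latentDim, if (object@trained) "(trained)" else
        "(untrained)", "\n")
  if (nrow(object@history))
    cat("  final NLL:", format(utils::tail(object@history$loss, 1),
        digits = 6), "after", nrow(object@history), "epochs\n")
})

#' Fitted masked autoencoder (encoder, mask predictor, decoder)
#'
#' @slot nets internal network weights
#' @slot config the \code{\link{maskedAEConfig}} used
#' @slot history per-epoch training losses
#' @slot trained whether training completed
#' @export
setClass("MaskedAutoencoder",
  representation(nets = "list", config = "list", history = "data.frame",
                 trained = "logical"))

setMethod("show", "MaskedAutoencoder", function(object) {
  cat("MaskedAutoencoder: latent", object@config$latentDim,
      if (object@trained) "(trained)" else "(untrained)", "\n")
})

#' Result of the full clustering pipeline
#'
#' @slot labels integer cluster assignment per cell (argmax of q)
#' @slot embedding cells x latent_dim embedding Z
#' @slot centers cluster centres in embedding space
#' @slot q Student-t soft assignments (rows sum to 1)
#' @slot p self-training target distribution at the last refresh
#' @slot history per-epoch loss terms for every training stage
#' @slot config the resolved \code{\link{scmcConfig}}
#' @slot geneIndex indices of the retained (highly variable) genes
#' @slot cellIds cell identifiers, in the order of \code{labels}
#' @export
setClass("ScmcFit",
  representation(labels = "integer", embedding = "matrix",
                 centers = "matrix", q = "matrix", p = "matrix",
                 history = "data.frame", config = "list",
                 geneIndex = "integer", cellIds = "character"),
  validity = function(object) {
    msg <- character()
    n <- length(object@labels)
    if (nrow(object@embedding) != n)
      msg <- c(msg, "embedding rows must match label count")
    if (nrow(object@q) != n) msg <- c(msg, "q rows must match label count")
    if (nrow(object@q) && any(abs(rowSums(object@q) - 1) > 1e-6))
      msg <- c(msg, "rows of q must sum to 1")
    if (length(msg)) msg else TRUE
  }
)

#' @describeIn ScmcFit cluster label accessor
#' @param object a \code{ScmcFit}
#' @export
clusterLabels <- function(object) {
  stats::setNames(object@labels, object@cellIds)
}
#' @describeIn ScmcFit embedding (Z) accessor
#' @export
cellEmbedding <- function(object) object@embedding
#' @describeIn ScmcFit cluster centre accessor
#' @export
clusterCenters <- function(object) object@centers
#' @describeIn ScmcFit soft assignment (q) accessor
#' @export
softAssignments <- function(object) object@q
#' @describeIn ScmcFit per-epoch loss history accessor
#' @export
lossHistory <- function(object) object@history

setMethod("show", "ScmcFit", function(object) {
  k <- length(unique(object@labels))
  cat("ScmcFit:", length(object@labels), "cells,", k, "clusters, latent dim",
      ncol(object@embedding), "\n")
  cat("  cluster sizes:", paste(table(object@labels), collapse = ", "), "\n")
  cat("  epochs logged:", nrow(object@history), "\n")
})
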