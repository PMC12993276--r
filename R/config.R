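# Validated configuration constructors. Plain named lists keep the configs
# serialisable (YAML round trip in the CLI) while the constructors enforce
# the invariants once, up front.

#' @noRd
.check_frac <- function(x, nm) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stop(nm, " must be a single number in [0, 1]", call. = FALSE)
  x
}

#' @noRd
.check_pos <- function(x, nm, int = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    stop(nm, " must be a single positive number", call. = FALSE)
  if (int) as.integer(x) else x
}

#' Augmentation configuration for the representation learner
#'
#' Three stochastic views applied to the masked autoencoder's training
#' input: zeroing a random fraction of gene entries per cell (mimicking
#' dropout), adding i.i.d. Gaussian noise, and swapping a fraction of a
#' cell's entries with one of its cosine-KNN neighbours.
#'
#' @param maskFraction fraction of gene entries zeroed per cell (default 0.10)
#' @param noiseVariance variance of the additive Gaussian noise (default 0.6)
#' @param swapRatio fraction of a cell's genes exchanged with a random
#'   neighbour (default 0.2)
#' @return a named list of class \code{augmentation_config}
#' @export
augmentationConfig <- function(maskFraction = 0.10, noiseVariance = 0.6,
                               swapRatio = 0.2) {
  if (!is.numeric(noiseVariance) || noiseVariance < 0)
    stop("noiseVariance must be >= 0")
  structure(list(
    maskFraction = .check_frac(maskFraction, "maskFraction"),
    noiseVariance = noiseVariance,
    swapRatio = .check_frac(swapRatio, "swapRatio")
  ), class = c("augmentation_config", "list"))
}

#' Configuration of the ZINB denoising autoencoder
#'
#' @param hiddenSizes encoder hidden layer widths (decoder is mirrored)
#' @param latentDim bottleneck dimension
#' @param learningRate Adam learning rate
#' @param epochs maximum training epochs
#' @param batchSize minibatch size
#' @param patience epochs without improvement before early stopping
#' @return a named list of class \code{denoiser_config}
#' @export
denoiserConfig <- function(hiddenSizes = c(64, 32), latentDim = 16,
                           learningRate = 1e-3, epochs = 100,
                           batchSize = 256, patience = 20) {
  stopifnot(all(hiddenSizes > 0))
  structure(list(
    hiddenSizes = as.integer(hiddenSizes),
    latentDim = .check_pos(latentDim, "latentDim", int = TRUE),
    learningRate = .check_pos(learningRate, "learningRate"),
    epochs = .check_pos(epochs, "epochs", int = TRUE),
    batchSize = .check_pos(batchSize, "batchSize", int = TRUE),
    patience = .check_pos(patience, "patience", int = TRUE)
  ), class = c("denoiser_config", "list"))
}

#' Configuration of the masked autoencoder
#'
#' \code{lambda} weights the reconstruction error on corrupted entries
#' against uncorrupted ones; \code{gamma} mixes the mask-prediction
#' cross-entropy with the weighted reconstruction loss. The defaults
#' (0.7 / 0.65) sit at the optimum plateau reported for both dials.
#'
#' @param hiddenSizes encoder hidden widths (decoder mirrored)
#' @param latentDim embedding dimension
#' @param learningRate Adam learning rate
#' @param epochs pretraining epochs
#' @param batchSize minibatch size
#' @param lambda weight on masked entries in the reconstruction loss, in
#'   [0, 1] (default 0.7)
#' @param gamma mix between mask-prediction and reconstruction losses, in
#'   [0, 1] (default 0.65)
#' @param usePredictor include the mask predictor and its loss; switching it
#'   off gives the no-prediction ablation
#' @param positiveOnly use the positive-term-only mask cross-entropy (debug
#'   flag; the default full binary cross-entropy is the non-degenerate form)
#' @return a named list of class \code{masked_ae_config}
#' @export
maskedAEConfig <- function(hiddenSizes = c(256, 64), latentDim = 32,
                           learningRate = 1e-3, epochs = 100,
                           batchSize = 256, lambda = 0.7, gamma = 0.65,
                           usePredictor = TRUE, positiveOnly = FALSE) {
  stopifnot(all(hiddenSizes > 0), is.logical(usePredictor),
            is.logical(positiveOnly))
  structure(list(
    hiddenSizes = as.integer(hiddenSizes),
    latentDim = .check_pos(latentDim, "latentDim", int = TRUE),
    learningRate = .check_pos(learningRate, "learningRate"),
    epochs = .check_pos(epochs, "epochs", int = TRUE),
    batchSize = .check_pos(batchSize, "batchSize", int = TRUE),
    lambda = .check_frac(lambda, "lambda"),
    gamma = .check_frac(gamma, "gamma"),
    usePredictor = usePredictor,
    positiveOnly = positiveOnly
  ), class = c("masked_ae_config", "list"))
}

#' Configuration of the shuffle/Bernoulli corruption
#'
#' @param maskRatio Bernoulli probability that an entry is replaced by its
#'   within-gene shuffled counterpart; scalar applied to all genes or one
#'   probability per gene. Default 0.3, the upper edge of the reported
#'   optimal 0.2--0.3 band.
#' @return a named list of class \code{corruption_config}
#' @export
corruptionConfig <- function(maskRatio = 0.3) {
  if (any(maskRatio < 0 | maskRatio > 1))
    stop("maskRatio must lie in [0, 1]")
  structure(list(maskRatio = maskRatio),
            class = c("corruption_config", "list"))
}

#' Configuration of the weighted soft clustering head
#'
#' @param inflation exponent of the Markov-like sharpening of the soft
#'   K-means weights (default 1 = no sharpening)
#' @param tDof degrees of freedom of the Student-t assignment kernel
#'   (default 1)
#' @param refreshEvery epochs between refreshes of the self-training target
#'   distribution p
#' @param maxEpochs maximum joint-training epochs
#' @param labelTol stop when fewer than this fraction of labels change
#'   between consecutive refreshes (default 0.001)
#' @param learningRate Adam learning rate for joint training
#' @return a named list of class \code{cluster_config}
#' @export
clusterConfig <- function(inflation = 1, tDof = 1, refreshEvery = 20,
                          maxEpochs = 200, labelTol = 0.001,
                          learningRate = 1e-3) {
  structure(list(
    inflation = .check_pos(inflation, "inflation"),
    tDof = .check_pos(tDof, "tDof"),
    refreshEvery = .check_pos(refreshEvery, "refreshEvery", int = TRUE),
    maxEpochs = .check_pos(maxEpochs, "maxEpochs", int = TRUE),
    labelTol = .check_frac(labelTol, "labelTol"),
    learningRate = .check_pos(learningRate, "learningRate")
  ), class = c("cluster_config", "list"))
}

#' Mixing weights of the total training objective
#'
#' The overall objective is
#' \code{alpha * L_zinb + beta * L_mask + phi * L_kmeans + theta * L_cluster}.
#' By default the denoiser is pretrained and then frozen (\code{alpha = 0});
#' setting \code{alpha > 0} re-enables joint fine-tuning of the ZINB term.
#'
#' @param alpha weight on the ZINB negative log-likelihood
#' @param beta weight on the masked-autoencoder loss
#' @param phi weight on the weighted K-means loss
#' @param theta weight on the KL self-training loss
#' @return a named list of class \code{loss_weights}
#' @export
lossWeights <- function(alpha = 0, beta = 1, phi = 0.1, theta = 1) {
  w <- c(alpha = alpha, beta = beta, phi = phi, theta = theta)
  if (any(w < 0)) stop("loss weights must be non-negative")
  if (all(w == 0)) stop("at least one loss weight must be positive")
  structure(as.list(w), class = c("loss_weights", "list"))
}

#' Full pipeline configuration
#'
#' Bundles the per-stage configurations plus the preprocessing options and a
#' single global seed. The global seed fans out to per-stage derived seeds
#' (stable hash of the stage name) so stages are individually reproducible.
#'
#' @param s0 library-size target each cell is scaled to (default 10,000)
#' @param nHVG number of highly variable genes retained (default 2000;
#'   capped at the gene count)
#' @param knnK neighbours in the cosine KNN graph (default 15)
#' @param useDenoiser run the ZINB denoising stage; switching it off gives
#'   the no-denoiser ablation
#' @param useAugmentation apply the three augmentations to the masked
#'   autoencoder's training input stream
#' @param augmentation an \code{\link{augmentationConfig}}
#' @param denoiser a \code{\link{denoiserConfig}}
#' @param corruption a \code{\link{corruptionConfig}}
#' @param maskedAE a \code{\link{maskedAEConfig}}
#' @param clustering a \code{\link{clusterConfig}}
#' @param weights a \code{\link{lossWeights}}
#' @param seed global integer seed
#' @param verbose print per-stage progress
#' @return a named list of class \code{scmc_config}
#' @export
scmcConfig <- function(s0 = 1e4, nHVG = 2000, knnK = 15,
                       useDenoiser = TRUE, useAugmentation = TRUE,
                       augmentation = augmentationConfig(),
                       denoiser = denoiserConfig(),
                       corruption = corruptionConfig(),
                       maskedAE = maskedAEConfig(),
                       clustering = clusterConfig(),
                       weights = lossWeights(),
                       seed = 1L, verbose = FALSE) {
  structure(list(
    s0 = .check_pos(s0, "s0"),
    nHVG = .check_pos(nHVG, "nHVG", int = TRUE),
    knnK = .check_pos(knnK, "knnK", int = TRUE),
    useDenoiser = isTRUE(useDenoiser),
    useAugmentation = isTRUE(useAugmentation),
    augmentation = augmentation,
    denoiser = denoiser,
    corruption = corruption,
    maskedAE = maskedAE,
    clustering = clustering,
    weights = weights,
    seed = as.integer(seed),
    verbose = isTRUE(verbose)
  ), class = c("scmc_config", "list"))
}

# apply `key=value` overrides with dotted paths onto a nested config list,
# rejecting keys that do not already exist
#' @noRd
config_override <- function(config, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("override must be key=value: ", ov)
    path <- strsplit(kv[1L], ".", fixed = TRUE)[[1L]]
    val <- utils::type.convert(kv[2L], as.is = TRUE)
    node <- config
    for (i in seq_along(path)[-length(path)]) {
      if (is.null(node[[path[i]]])) stop("unknown config key: ", kv[1L])
      node <- node[[path[i]]]
    }
    leaf <- path[length(path)]
    if (is.null(node[[leaf]])) stop("unknown config key: ", kv[1L])
    config <- .config_assign(config, path, val)
  }
  config
}

#' @noRd
.config_assign <- function(config, path, val) {
  if (length(path) == 1L) {
    config[[path]] <- val
    return(config)
  }
  config[[path[1L]]] <- .config_assign(config[[path[1L]]], path[-1L], val)
  config
}

# merge a (possibly partial) plain list read from YAML into a full default
# config, rejecting unknown keys at any level
#' @noRd
config_merge <- function(defaults, user) {
  if (is.null(user)) return(defaults)
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(defaults[[nm]]))) {
      defaults[[nm]] <- config_merge(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}
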