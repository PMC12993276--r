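# Weighted soft K-means in embedding space plus Student-t soft assignment
# with KL self-training, and the staged pipeline tying the stages together:
# (1) pretrain the ZINB denoiser, (2) denoise, log1p, corrupt, pretrain the
# masked autoencoder, (3) initialise centres by hard K-means on Z and
# alternate target refreshes with gradient steps on the total objective.

#' @noRd
.sqdist <- function(Z, centers) {
  # squared Euclidean distances, cells x centers
  zz <- rowSums(Z^2)
  cc <- rowSums(centers^2)
  d2 <- outer(zz, cc, "+") - 2 * tcrossprod(Z, centers)
  pmax(d2, 0)
}

#' Soft K-means weights with Markov-like inflation
#'
#' \code{wbar_ik = exp(-|z_i - c_k|^2) / sum_k' exp(-|z_i - c_k'|^2)},
#' sharpened by \code{w_ik = wbar_ik^inflation / sum_k' wbar_ik'^inflation}.
#' Rows sum to one; \code{inflation = 1} leaves the weights untouched and
#' the limit of large inflation is one-hot at the nearest centre.
#'
#' @param Z cells x latent embedding
#' @param centers clusters x latent centre matrix
#' @param inflation sharpening exponent (default 1)
#' @return cells x clusters weight matrix
#' @export
softClusterWeights <- function(Z, centers, inflation = 1) {
  d2 <- .sqdist(as.matrix(Z), as.matrix(centers))
  lw <- -d2
  lw <- lw - apply(lw, 1L, max)
  if (inflation != 1) lw <- lw * inflation
  w <- exp(lw)
  w / rowSums(w)
}

#' Weighted centre update
#'
#' \code{c_k = sum_i w_ik z_i / sum_i w_ik}, the minimiser of the weighted
#' K-means loss in the centres. A cluster whose total weight underflows is
#' re-seeded from the cell farthest from every current centre (logged via
#' \code{message}).
#'
#' @param Z cells x latent embedding
#' @param weights cells x clusters weight matrix
#' @return clusters x latent centre matrix
#' @export
updateCenters <- function(Z, weights) {
  Z <- as.matrix(Z); weights <- as.matrix(weights)
  tot <- colSums(weights)
  centers <- crossprod(weights, Z) / pmax(tot, 1e-300)
  dead <- which(tot < 1e-12)
  if (length(dead)) {
    live <- setdiff(seq_along(tot), dead)
    for (k in dead) {
      d2 <- .sqdist(Z, centers[live, , drop = FALSE])
      far <- which.max(apply(d2, 1L, min))
      message("re-seeding empty cluster ", k, " from cell ", far)
      centers[k, ] <- Z[far, ]
    }
  }
  centers
}

#' Weighted K-means loss
#'
#' \code{sum_i sum_k w_ik |z_i - c_k|^2}.
#'
#' @param Z cells x latent embedding
#' @param centers clusters x latent centres
#' @param weights cells x clusters weights
#' @return non-negative scalar
#' @export
kmeansLoss <- function(Z, centers, weights) {
  sum(as.matrix(weights) * .sqdist(as.matrix(Z), as.matrix(centers)))
}

#' Student-t soft assignment
#'
#' \code{q_ik} proportional to \code{(1 + |z_i - c_k|^2 / t)^(-(t+1)/2)},
#' row-normalised: the probability that cell i belongs to cluster k under a
#' Student-t kernel on embedding-to-centre distance.
#'
#' @param Z cells x latent embedding
#' @param centers clusters x latent centres
#' @param tDof degrees of freedom t (default 1)
#' @return cells x clusters soft assignment matrix, rows summing to 1
#' @export
softAssign <- function(Z, centers, tDof = 1) {
  if (tDof <= 0) stop("tDof must be positive")
  d2 <- .sqdist(as.matrix(Z), as.matrix(centers))
  num <- (1 + d2 / tDof)^(-(tDof + 1) / 2)
  num / rowSums(num)
}

#' Self-training target distribution
#'
#' \code{p_ik = (q_ik^2 / f_k) / sum_k' (q_ik'^2 / f_k')} with soft cluster
#' frequencies \code{f_k = sum_i q_ik}: squaring strengthens confident
#' assignments while the frequency normalisation guards against degenerate
#' large clusters.
#'
#' @param q soft assignment matrix (rows sum to 1)
#' @return target matrix of the same shape, rows summing to 1
#' @export
targetDistribution <- function(q) {
  q <- as.matrix(q)
  f <- colSums(q)
  p <- sweep(q^2, 2L, pmax(f, 1e-300), "/")
  p / rowSums(p)
}

#' KL self-training clustering loss
#'
#' \code{KL(p || q) = sum_i sum_k p_ik log(p_ik / q_ik)}; non-negative and
#' zero iff p equals q. Vanishing q under positive p is clipped at 1e-12
#' with a warning.
#'
#' @param p target distribution
#' @param q soft assignments
#' @return non-negative scalar
#' @export
clusterKLLoss <- function(p, q) {
  p <- as.matrix(p); q <- as.matrix(q)
  if (!identical(dim(p), dim(q))) stop("p and q must have identical shape")
  if (any(q < 1e-12 & p > 0)) {
    warning("q underflow clipped at 1e-12")
    q <- pmax(q, 1e-12)
  }
  pos <- p > 0
  sum(p[pos] * (log(p[pos]) - log(q[pos])))
}

#' Total training objective
#'
#' \code{alpha L_zinb + beta L_mask + phi L_kmeans + theta L_cluster}.
#'
#' @param lzinb,lmask,lkmeans,lcluster the four loss terms
#' @param weights a \code{\link{lossWeights}}
#' @return scalar
#' @export
totalLoss <- function(lzinb, lmask, lkmeans, lcluster,
                      weights = lossWeights()) {
  weights$alpha * lzinb + weights$beta * lmask +
    weights$phi * lkmeans + weights$theta * lcluster
}

# gradients of KL(p || q) under the Student-t kernel w.r.t. the embedding
# and the centres (both are free parameters of the joint objective)
#' @noRd
.kl_grad_Z <- function(Z, centers, p, q, tDof) {
  d2 <- .sqdist(Z, centers)
  U <- (p - q) / (1 + d2 / tDof)
  ((tDof + 1) / tDof) * (rowSums(U) * Z - U %*% centers)
}

#' @noRd
.kl_grad_C <- function(Z, centers, p, q, tDof) {
  d2 <- .sqdist(Z, centers)
  U <- (p - q) / (1 + d2 / tDof)
  ((tDof + 1) / tDof) * (colSums(U) * centers - crossprod(U, Z))
}

#' Cluster a count matrix with the full denoise--mask--cluster pipeline
#'
#' Staged training: (1) the ZINB denoising autoencoder is pretrained on raw
#' counts; (2) the denoised matrix is depth-normalised, log1p-transformed,
#' corrupted by within-gene shuffling under a Bernoulli mask and used to
#' pretrain the masked autoencoder; (3) cluster centres are initialised by
#' hard K-means on the embedding, then target refreshes alternate with
#' gradient steps on the combined objective until labels stabilise. Final
#' labels are the argmax of the Student-t soft assignment.
#'
#' @param counts non-negative cells x genes count matrix, or a
#'   \code{SingleCellExperiment} with a \code{counts} assay
#' @param nClusters number of clusters (>= 2)
#' @param config a \code{\link{scmcConfig}}
#' @return a \code{\link{ScmcFit}}
#' @examples
#' sim <- simulateCounts(simulationConfig(nCells = 120, nGenes = 60,
#'                                        seed = 7))
#' cfg <- scmcConfig(seed = 7,
#'                   denoiser = denoiserConfig(epochs = 30),
#'                   maskedAE = maskedAEConfig(epochs = 20),
#'                   clustering = clusterConfig(maxEpochs = 20))
#' fit <- scMaskClust(sim$counts, nClusters = 3, config = cfg)
#' table(clusterLabels(fit), sim$labels)
#' @export
scMaskClust <- function(counts, nClusters, config = scmcConfig()) {
  if (is(counts, "SummarizedExperiment")) {
    counts <- SummarizedExperiment::assay(counts, "counts")
    counts <- t(as.matrix(counts))          # Bioconductor stores genes x cells
  }
  X <- .as_count_matrix(counts)
  nClusters <- as.integer(nClusters)
  if (nClusters < 2L) stop("nClusters must be at least 2")
  seed <- config$seed
  say <- function(...) if (config$verbose) message(...)

  # ---- preprocessing -----------------------------------------------------
  norm <- normalizeLibrarySize(X, s0 = config$s0)
  X <- X[rownames(normValues(norm)), , drop = FALSE]
  sf <- cellSizeFactors(norm)
  hvg <- selectHVG(X, nTop = min(config$nHVG, ncol(X)))
  X <- X[, hvg, drop = FALSE]
  n <- nrow(X)

  history <- data.frame()

  # ---- stage 1: ZINB denoising ------------------------------------------
  if (config$useDenoiser) {
    say("pretraining ZINB denoiser")
    den <- trainDenoiser(X, sizeFactors = sf, config = config$denoiser,
                         seed = derive_seed(seed, "denoiser"))
    history <- rbind(history,
      data.frame(phase = "denoiser", epoch = den@history$epoch,
                 lzinb = den@history$loss, lm = NA, lrec = NA, lmask = NA,
                 lkmeans = NA, lcluster = NA, total = den@history$loss))
    Xz <- denoiseCounts(den)
  } else {
    den <- NULL
    Xz <- X
  }
  # depth-normalise the denoised matrix, move to log scale, and
  # standardise genes: unit-variance features keep the fixed-variance
  # noise augmentation proportionate across genes of very different scale
  Xlog <- log1p(Xz / rowSums(Xz) * config$s0)
  gmu <- colMeans(Xlog)
  gsd <- pmax(apply(Xlog, 2L, stats::sd), 1e-8)
  Xlog <- sweep(sweep(Xlog, 2L, gmu), 2L, gsd, "/")

  graph <- NULL
  if (config$useAugmentation && config$augmentation$swapRatio > 0)
    graph <- buildKnnGraph(Xlog, k = min(config$knnK, n - 1L))
  aug <- if (config$useAugmentation) config$augmentation else NULL

  # ---- stage 2: masked-autoencoder pretraining ---------------------------
  say("pretraining masked autoencoder")
  mae <- trainMaskedAE(Xlog, config = config$maskedAE,
                       corruption = config$corruption, graph = graph,
                       augmentation = aug,
                       seed = derive_seed(seed, "masked-ae"))
  h <- mae@history
  history <- rbind(history,
    data.frame(phase = "masked-ae", epoch = h$epoch, lzinb = NA,
               lm = h$lm, lrec = h$lrec, lmask = h$loss, lkmeans = NA,
               lcluster = NA, total = h$loss))

  # ---- stage 3: joint clustering ----------------------------------------
  say("joint clustering")
  ccfg <- config$clustering
  mcfg <- config$maskedAE
  wts <- config$weights
  nets <- mae@nets
  params <- .mae_params(nets, mcfg$usePredictor)
  state <- adam_init(params)

  Zev <- encodeCells(mae, Xlog)
  km_seed <- derive_seed(seed, "kmeans-init")
  centers <- with_seed(km_seed, {
    km <- tryCatch(
      stats::kmeans(Zev, centers = nClusters, nstart = 20, iter.max = 50),
      error = function(e)
        stats::kmeans(Zev, centers = Zev[sample.int(n, nClusters), ],
                      iter.max = 50))
    km$centers
  })
  qev <- softAssign(Zev, centers, ccfg$tDof)
  p <- targetDistribution(qev)
  labels <- max.col(qev, ties.method = "first")

  # centres are free parameters of the joint objective, moved by the same
  # optimiser as the network (small steps avoid the degenerate jump of a
  # closed-form re-estimate when the soft weights are near-uniform)
  cparams <- list(centers = centers)
  cstate <- adam_init(cparams)

  joint_seed <- derive_seed(seed, "joint")
  with_seed(joint_seed, {
    for (epoch in seq_len(ccfg$maxEpochs)) {
      # refresh the self-training target and test for convergence
      if (epoch > 1L && (epoch - 1L) %% ccfg$refreshEvery == 0L) {
        Zev <- .encode_with_nets(nets, Xlog)
        qev <- softAssign(Zev, cparams$centers, ccfg$tDof)
        p <- targetDistribution(qev)
        new_labels <- max.col(qev, ties.method = "first")
        changed <- mean(new_labels != labels)
        labels <- new_labels
        if (changed < ccfg$labelTol) break
      }
      # corrupted (and augmented) pass drives the representation objective
      batch <- makeMaskedBatch(Xlog, config$corruption)
      Xc <- batch@corrupted
      if (!is.null(aug)) Xc <- augmentCells(Xc, graph = graph, config = aug)
      fw <- .mae_forward(nets, Xc, mcfg$usePredictor)
      bw <- .mae_backward(nets, fw, Xlog, batch@mask, mcfg,
                          beta = wts$beta)
      # the clustering losses see the clean embedding of the data itself;
      # their gradient flows through a separate encoder pass
      Henc <- nn_forward(nets$enc, Xlog)
      Z <- Henc[[length(Henc)]]
      centers <- cparams$centers
      w <- softClusterWeights(Z, centers, ccfg$inflation)
      d2 <- .sqdist(Z, centers)
      lkm <- sum(w * d2)
      q <- softAssign(Z, centers, ccfg$tDof)
      lkl <- clusterKLLoss(p, q)
      dZ <- wts$phi * 2 * (Z - w %*% centers) +
        wts$theta * .kl_grad_Z(Z, centers, p, q, ccfg$tDof)
      dC <- wts$phi * 2 * (colSums(w) * centers - crossprod(w, Z)) +
        wts$theta * .kl_grad_C(Z, centers, p, q, ccfg$tDof)
      bw_enc <- nn_backward(nets$enc, Henc, dZ)
      gcl <- nn_grads(bw_enc, "enc")
      for (nm in names(gcl)) bw$grads[[nm]] <- bw$grads[[nm]] + gcl[[nm]]
      state <- adam_step(params, bw$grads, state, lr = ccfg$learningRate)
      cstate <- adam_step(cparams, list(centers = dC), cstate,
                          lr = ccfg$learningRate)
      lz <- NA_real_
      if (wts$alpha > 0 && !is.null(den)) {
        # joint fine-tuning of the frozen-by-default denoiser
        dfw <- .denoiser_forward(den@nets, den@input,
                                 matrix(den@sizeFactors, n, ncol(X)))
        dbw <- .denoiser_backward(den@nets, dfw, den@counts,
                                  matrix(1, n, ncol(X)))
        lz <- dbw$loss
        dgr <- lapply(dbw$grads, function(g) wts$alpha * g)
        dparams <- .denoiser_params(den@nets)
        if (is.null(nets$.den_state)) nets$.den_state <- adam_init(dparams)
        nets$.den_state <- adam_step(dparams, dgr, nets$.den_state,
                                     lr = config$denoiser$learningRate)
      }
      history <- rbind(history,
        data.frame(phase = "joint", epoch = epoch, lzinb = lz, lm = bw$lm,
                   lrec = bw$lrec, lmask = bw$loss, lkmeans = lkm,
                   lcluster = lkl,
                   total = totalLoss(ifelse(is.na(lz), 0, lz), bw$loss,
                                     lkm, lkl, wts)))
    }
  })

  # final state from the clean forward pass
  mae@nets <- nets
  centers <- cparams$centers
  Zev <- encodeCells(mae, Xlog)
  qev <- softAssign(Zev, centers, ccfg$tDof)
  p <- targetDistribution(qev)
  labels <- max.col(qev, ties.method = "first")

  new("ScmcFit", labels = as.integer(labels), embedding = Zev,
      centers = centers, q = qev, p = p, history = history,
      config = unclass(config), geneIndex = as.integer(hvg),
      cellIds = rownames(X))
}

# encoder forward on raw nets (avoids rebuilding the S4 object every epoch)
#' @noRd
.encode_with_nets <- function(nets, X) {
  H <- nn_forward(nets$enc, as.matrix(X))
  H[[length(H)]]
}
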