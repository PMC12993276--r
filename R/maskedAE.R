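# Masked autoencoder: encoder producing the embedding Z, a linear mask
# predictor trained with cross-entropy, and a decoder reconstructing the
# uncorrupted matrix from [Z, M'] under a mask-weighted MSE.

.MP_MIN <- 1e-7   # mask-probability clipping

#' Mask-prediction cross-entropy loss
#'
#' Full binary cross-entropy between the true mask and the predicted mask
#' probabilities, averaged over entries. The positive-term-only form (which
#' is degenerate: it is minimised by predicting 1 everywhere) is available
#' behind \code{positiveOnly} for inspection.
#'
#' @param mask binary matrix of true mask indicators
#' @param pred predicted probabilities in (0, 1)
#' @param positiveOnly use only the \code{-M log M'} term
#' @return non-negative scalar
#' @export
maskLoss <- function(mask, pred, positiveOnly = FALSE) {
  mask <- as.matrix(mask); pred <- as.matrix(pred)
  if (!identical(dim(mask), dim(pred))) stop("mask/prediction shape mismatch")
  pred <- pmin(pmax(pred, .MP_MIN), 1 - .MP_MIN)
  if (positiveOnly) return(-mean(mask * log(pred)))
  -mean(mask * log(pred) + (1 - mask) * log1p(-pred))
}

#' Mask-weighted mean squared error
#'
#' \code{(1/N) sum_ij W_ij (X_ij - Xhat_ij)^2} with
#' \code{W_ij = lambda M_ij + (1 - lambda)(1 - M_ij)} and N the total
#' number of entries, so masked entries carry weight \code{lambda} and
#' unmasked entries \code{1 - lambda}.
#'
#' @param X target matrix (the uncorrupted denoised matrix)
#' @param Xhat reconstruction
#' @param mask binary mask matrix
#' @param lambda weight on masked entries, in [0, 1] (default 0.7)
#' @return non-negative scalar
#' @export
weightedMSE <- function(X, Xhat, mask, lambda = 0.7) {
  X <- as.matrix(X); Xhat <- as.matrix(Xhat); mask <- as.matrix(mask)
  if (!identical(dim(X), dim(Xhat)) || !identical(dim(X), dim(mask)))
    stop("shape mismatch")
  lambda <- .check_frac(lambda, "lambda")
  W <- lambda * mask + (1 - lambda) * (1 - mask)
  mean(W * (X - Xhat)^2)
}

#' Combined masked-autoencoder loss
#'
#' \code{gamma * L_m + (1 - gamma) * L_rec}.
#'
#' @param lm mask-prediction loss
#' @param lrec weighted reconstruction loss
#' @param gamma mixing weight in [0, 1] (default 0.65)
#' @return scalar
#' @export
totalMaskLoss <- function(lm, lrec, gamma = 0.65) {
  gamma <- .check_frac(gamma, "gamma")
  gamma * lm + (1 - gamma) * lrec
}

# ---- model ---------------------------------------------------------------

#' @noRd
.mae_init <- function(g, config) {
  nets <- list(
    enc = nn_init(c(g, config$hiddenSizes, config$latentDim),
                  hidden_act = "relu", out_act = "linear"))
  if (config$usePredictor) {
    nets$W_m <- .glorot(config$latentDim, g)
    nets$b_m <- numeric(g)
    dec_in <- config$latentDim + g
  } else {
    dec_in <- config$latentDim
  }
  nets$dec <- nn_init(c(dec_in, rev(config$hiddenSizes), g),
                      hidden_act = "relu", out_act = "linear")
  nets
}

#' @noRd
.mae_params <- function(nets, usePredictor) {
  p <- c(nn_params(nets$enc, "enc"), nn_params(nets$dec, "dec"))
  if (usePredictor) p <- c(p, nets[c("W_m", "b_m")])
  p
}

#' @noRd
.mae_forward <- function(nets, Xin, usePredictor) {
  Henc <- nn_forward(nets$enc, Xin)
  Z <- Henc[[length(Henc)]]
  if (usePredictor) {
    a_m <- sweep(Z %*% nets$W_m, 2L, nets$b_m, "+")
    Mp <- pmin(pmax(sigmoid(a_m), .MP_MIN), 1 - .MP_MIN)
    dec_in <- cbind(Z, Mp)
  } else {
    Mp <- NULL
    dec_in <- Z
  }
  Hdec <- nn_forward(nets$dec, dec_in)
  list(Henc = Henc, Z = Z, Mp = Mp, Hdec = Hdec,
       Xhat = Hdec[[length(Hdec)]])
}

# backward pass; dZ_extra lets the clustering losses inject their gradient
# at the embedding. `beta` scales the masked-AE loss terms.
#' @noRd
.mae_backward <- function(nets, fw, target, M, config, beta = 1,
                          dZ_extra = NULL) {
  N <- length(target)
  lam <- config$lambda
  W <- lam * M + (1 - lam) * (1 - M)
  err <- fw$Xhat - target
  lrec <- mean(W * err^2)
  dXhat <- beta * (1 - config$gamma) * 2 * W * err / N
  bw_dec <- nn_backward(nets$dec, fw$Hdec, dXhat)
  if (config$usePredictor) {
    Mp <- fw$Mp
    lm <- if (config$positiveOnly) -mean(M * log(Mp)) else
      -mean(M * log(Mp) + (1 - M) * log1p(-Mp))
    d <- ncol(fw$Z)
    dZ <- bw_dec$dX[, seq_len(d), drop = FALSE]
    dMp_dec <- bw_dec$dX[, -seq_len(d), drop = FALSE]
    dMp_ce <- if (config$positiveOnly) beta * config$gamma * (-M / Mp) / N
      else beta * config$gamma * (Mp - M) / (Mp * (1 - Mp)) / N
    live <- (Mp > .MP_MIN) & (Mp < 1 - .MP_MIN)
    dA_m <- (dMp_ce * live + dMp_dec) * Mp * (1 - Mp)
    dW_m <- crossprod(fw$Z, dA_m)
    db_m <- colSums(dA_m)
    dZ <- dZ + dA_m %*% t(nets$W_m)
  } else {
    lm <- 0
    dZ <- bw_dec$dX
    dW_m <- db_m <- NULL
  }
  if (!is.null(dZ_extra)) dZ <- dZ + dZ_extra
  bw_enc <- nn_backward(nets$enc, fw$Henc, dZ)
  grads <- c(nn_grads(bw_enc, "enc"), nn_grads(bw_dec, "dec"))
  if (config$usePredictor) grads <- c(grads, list(W_m = dW_m, b_m = db_m))
  list(lm = lm, lrec = lrec,
       loss = totalMaskLoss(lm, lrec, config$gamma), grads = grads)
}

#' Pretrain the masked autoencoder
#'
#' Each epoch draws a fresh within-gene shuffle and Bernoulli mask of the
#' (log1p-transformed, denoised) input, optionally passes the corrupted
#' matrix through the stochastic augmentations, and minimises
#' \code{gamma * L_m + (1 - gamma) * L_rec} against the uncorrupted target
#' with Adam.
#'
#' @param X the uncorrupted target matrix (cells x genes, log scale)
#' @param config a \code{\link{maskedAEConfig}}
#' @param corruption a \code{\link{corruptionConfig}}
#' @param graph optional \code{\link{KNNGraph}} for the swap augmentation
#' @param augmentation optional \code{\link{augmentationConfig}}; when
#'   \code{NULL} no augmentation is applied
#' @param batch optional \code{\link{MaskedBatch}}: train against this one
#'   fixed corruption every epoch instead of drawing a fresh one (useful
#'   for studying what the mask predictor can learn from a single
#'   corruption)
#' @param seed integer seed
#' @return a trained \code{\link{MaskedAutoencoder}}
#' @export
trainMaskedAE <- function(X, config = maskedAEConfig(),
                          corruption = corruptionConfig(), graph = NULL,
                          augmentation = NULL, batch = NULL, seed = 1L) {
  X <- as.matrix(X)
  n <- nrow(X); g <- ncol(X)
  fixed <- batch
  with_seed(seed, {
    nets <- .mae_init(g, config)
    params <- .mae_params(nets, config$usePredictor)
    state <- adam_init(params)
    hist <- data.frame()
    for (epoch in seq_len(config$epochs)) {
      batch <- if (is.null(fixed)) makeMaskedBatch(X, corruption) else fixed
      Xc <- batch@corrupted
      if (!is.null(augmentation))
        Xc <- augmentCells(Xc, graph = graph, config = augmentation)
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      ep <- c(lm = 0, lrec = 0, loss = 0)
      for (s in starts) {
        b <- idx[s:min(s + config$batchSize - 1L, n)]
        fw <- .mae_forward(nets, Xc[b, , drop = FALSE], config$usePredictor)
        bw <- .mae_backward(nets, fw, X[b, , drop = FALSE],
                            batch@mask[b, , drop = FALSE], config)
        state <- adam_step(params, bw$grads, state,
                           lr = config$learningRate)
        ep <- ep + c(bw$lm, bw$lrec, bw$loss) * length(b)
      }
      hist <- rbind(hist, data.frame(epoch = epoch, t(ep / n)))
    }
  })
  new("MaskedAutoencoder", nets = nets, config = unclass(config),
      history = hist,
      trained = TRUE)
}

#' Embed cells with a trained masked autoencoder
#'
#' @param model a \code{\link{MaskedAutoencoder}}
#' @param X cells x genes matrix on the training scale
#' @return cells x latent_dim embedding Z
#' @export
encodeCells <- function(model, X) {
  H <- nn_forward(model@nets$enc, as.matrix(X))
  H[[length(H)]]
}

#' Predict which entries were corrupted
#'
#' Sigmoid of a linear map from the embedding to the gene dimension,
#' clipped away from 0 and 1.
#'
#' @param model a \code{\link{MaskedAutoencoder}} trained with its mask
#'   predictor enabled
#' @param Z cells x latent_dim embedding
#' @return matrix of probabilities in (0, 1), cells x genes
#' @export
predictMask <- function(model, Z) {
  if (!model@config$usePredictor)
    stop("model was trained without a mask predictor")
  a <- sweep(as.matrix(Z) %*% model@nets$W_m, 2L, model@nets$b_m, "+")
  pmin(pmax(sigmoid(a), .MP_MIN), 1 - .MP_MIN)
}

#' Reconstruct expression from embedding and predicted mask
#'
#' @param model a \code{\link{MaskedAutoencoder}}
#' @param Z embedding matrix
#' @param Mp predicted mask probabilities (required when the model was
#'   trained with its predictor; recomputed from \code{Z} when omitted)
#' @return reconstructed cells x genes matrix
#' @export
decodeCells <- function(model, Z, Mp = NULL) {
  Z <- as.matrix(Z)
  if (model@config$usePredictor) {
    if (is.null(Mp)) Mp <- predictMask(model, Z)
    dec_in <- cbind(Z, as.matrix(Mp))
  } else {
    dec_in <- Z
  }
  H <- nn_forward(model@nets$dec, dec_in)
  H[[length(H)]]
}
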