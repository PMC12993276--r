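# Zero-inflated negative binomial likelihood and the denoising autoencoder
# trained on raw counts. The log-pmf, its analytic gradients, and the
# backpropagation through the three parameter heads are all implemented
# here; the dense-layer plumbing lives in nn-engine.R.

# numerical floors applied before any log
.MU_MIN <- 1e-6; .MU_MAX <- 1e6
.TH_MIN <- 1e-6; .TH_MAX <- 1e6
.PI_MIN <- 1e-6

#' Negative binomial log-pmf (mean/dispersion form)
#'
#' \code{log P(x | mu, theta)} for the NB parameterised by mean \code{mu}
#' and dispersion \code{theta}:
#' \deqn{\Gamma(x+\theta) / (x!\,\Gamma(\theta)) \cdot
#'       (\theta/(\theta+\mu))^\theta (\mu/(\mu+\theta))^x}
#' evaluated through log-gamma for stability. As \code{theta} grows the
#' distribution approaches Poisson(\code{mu}).
#'
#' @param x non-negative counts (vector or matrix)
#' @param mu positive means
#' @param theta positive dispersions
#' @return log-probabilities, same shape as the broadcast arguments
#' @export
nbLogPmf <- function(x, mu, theta) {
  if (!all(is.finite(mu)) || !all(is.finite(theta)))
    stop("mu and theta must be finite")
  if (any(mu <= 0) || any(theta <= 0))
    stop("mu and theta must be strictly positive")
  if (any(x < 0)) stop("x must be non-negative")
  lgamma(x + theta) - lgamma(x + 1) - lgamma(theta) +
    theta * (log(theta) - log(theta + mu)) +
    x * (log(mu) - log(theta + mu))
}

#' Zero-inflated negative binomial log-pmf
#'
#' \code{ZINB(x | pi, mu, theta) = pi * [x = 0] + (1 - pi) * NB(x | mu,
#' theta)}; the two branches at \code{x = 0} are combined on the log scale.
#'
#' @param x non-negative counts
#' @param pi dropout probabilities in [0, 1]
#' @param mu positive means
#' @param theta positive dispersions
#' @return log-probabilities
#' @export
zinbLogPmf <- function(x, pi, mu, theta) {
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  nb <- nbLogPmf(x, mu, theta)
  out <- log1p(-pi) + nb                     # -Inf when pi = 1, correctly
  if (any(x == 0)) {
    i <- which(x == 0)
    pii <- if (length(pi) == 1L) rep(pi, length(i)) else pi[i]
    a <- log(pii)                            # point-mass branch
    b <- log1p(-pii) + nb[i]                 # NB branch
    hi <- pmax(a, b)
    lo <- pmin(a, b)
    v <- ifelse(is.infinite(hi) & hi < 0, -Inf, hi + log1p(exp(lo - hi)))
    out[i] <- v
  }
  out
}

# gradients of the ZINB log-likelihood w.r.t. (mu, theta, pi), vectorised.
# Used both by backprop and by the finite-difference gradient test. The two
# branches (x > 0 / x = 0) are blended arithmetically to avoid indexing on
# large matrices; parameters are assumed clipped away from the boundaries.
#' @noRd
.zinb_grad <- function(x, pi, mu, theta) {
  tm <- theta + mu
  A <- log(theta / tm)
  pos <- (x > 0) * 1
  # x > 0 branch: log(1 - pi) + NB terms
  dmu_p <- x / mu - (x + theta) / tm
  dth_p <- digamma(x + theta) - digamma(theta) + A + (mu - x) / tm
  dpi_p <- -1 / (1 - pi)
  # x = 0 branch: log(pi + (1 - pi) * NB0)
  nb0 <- exp(theta * A)
  den <- pi + (1 - pi) * nb0
  dmu_z <- -(1 - pi) * nb0 * theta / tm / den
  dth_z <- (1 - pi) * nb0 * (A + mu / tm) / den
  dpi_z <- (1 - nb0) / den
  list(dmu = pos * dmu_p + (1 - pos) * dmu_z,
       dtheta = pos * dth_p + (1 - pos) * dth_z,
       dpi = pos * dpi_p + (1 - pos) * dpi_z)
}

# fast ZINB negative mean log-likelihood for training (parameters already
# clipped inside (0, Inf) / (0, 1), so every log is finite)
#' @noRd
.zinb_nll <- function(x, pi, mu, theta, w) {
  tm <- theta + mu
  nb <- lgamma(x + theta) - lgamma(x + 1) - lgamma(theta) +
    theta * (log(theta) - log(tm)) + x * (log(mu) - log(tm))
  pos <- (x > 0) * 1
  ll <- pos * (log1p(-pi) + nb) +
    (1 - pos) * log(pi + (1 - pi) * exp((1 - pos) * nb))
  -sum(w * ll) / sum(w)
}

#' Mean ZINB negative log-likelihood of a count matrix
#'
#' Mean over all (unmasked) entries of \code{-zinbLogPmf}. When an exclusion
#' mask is supplied, masked entries (mask = 1) contribute nothing to the
#' likelihood.
#'
#' @param X non-negative count matrix
#' @param params a \code{\link{ZINBParams}} of matching shape
#' @param exclude optional binary matrix; entries with 1 are excluded
#' @return scalar loss (non-negative)
#' @export
zinbLoss <- function(X, params, exclude = NULL) {
  X <- as.matrix(X)
  if (!identical(dim(X), dim(zinbMean(params))))
    stop("count matrix and ZINB parameters must have identical shape")
  ll <- zinbLogPmf(X, zinbDropout(params), pmax(zinbMean(params), .MU_MIN),
                   zinbDispersion(params))
  if (is.null(exclude)) return(-mean(ll))
  if (!identical(dim(exclude), dim(X))) stop("exclusion mask shape mismatch")
  keep <- exclude == 0
  if (!any(keep)) return(0)
  -sum(ll[keep]) / sum(keep)
}

# ---- denoiser ------------------------------------------------------------

# forward through encoder, decoder trunk and the three heads.
# Returns everything needed by the backward pass.
#' @noRd
.denoiser_forward <- function(nets, Xin, sf) {
  Henc <- nn_forward(nets$enc, Xin)
  Hdec <- nn_forward(nets$dec, Henc[[length(Henc)]])
  D <- Hdec[[length(Hdec)]]
  a_mu <- sweep(D %*% nets$W_mu, 2L, nets$b_mu, "+")
  a_th <- sweep(D %*% nets$W_th, 2L, nets$b_th, "+")
  a_pi <- sweep(D %*% nets$W_pi, 2L, nets$b_pi, "+")
  mu0 <- pmin(pmax(exp(a_mu), .MU_MIN), .MU_MAX)    # before size factors
  mu <- sf * mu0
  th <- pmin(pmax(exp(a_th), .TH_MIN), .TH_MAX)
  pii <- pmin(pmax(sigmoid(a_pi), .PI_MIN), 1 - .PI_MIN)
  list(Henc = Henc, Hdec = Hdec, D = D, mu0 = mu0, mu = mu, th = th,
       pi = pii, a_mu = a_mu, a_th = a_th, a_pi = a_pi)
}

# one training step on a batch: returns loss, parameter grads
#' @noRd
.denoiser_backward <- function(nets, fw, Xb, w) {
  N <- sum(w)
  loss <- .zinb_nll_cpp(c(Xb), c(fw$pi), c(fw$mu), c(fw$th), c(w))
  gr <- .zinb_grad_cpp(c(Xb), c(fw$pi), c(fw$mu), c(fw$th))
  gr <- lapply(gr, function(v) matrix(v, nrow(Xb), ncol(Xb)))
  scale <- -w / N
  # chain through the clipped heads; gradient is zero where clipped
  live_mu <- (exp(fw$a_mu) > .MU_MIN) & (exp(fw$a_mu) < .MU_MAX)
  live_th <- (fw$th > .TH_MIN) & (fw$th < .TH_MAX)
  live_pi <- (fw$pi > .PI_MIN) & (fw$pi < 1 - .PI_MIN)
  dA_mu <- scale * gr$dmu * fw$mu * live_mu      # d mu / d a = mu
  dA_th <- scale * gr$dtheta * fw$th * live_th
  dA_pi <- scale * gr$dpi * fw$pi * (1 - fw$pi) * live_pi
  dW_mu <- crossprod(fw$D, dA_mu); db_mu <- colSums(dA_mu)
  dW_th <- crossprod(fw$D, dA_th); db_th <- colSums(dA_th)
  dW_pi <- crossprod(fw$D, dA_pi); db_pi <- colSums(dA_pi)
  dD <- dA_mu %*% t(nets$W_mu) + dA_th %*% t(nets$W_th) +
    dA_pi %*% t(nets$W_pi)
  bw_dec <- nn_backward(nets$dec, fw$Hdec, dD)
  bw_enc <- nn_backward(nets$enc, fw$Henc, bw_dec$dX)
  grads <- c(nn_grads(bw_enc, "enc"), nn_grads(bw_dec, "dec"),
             list(W_mu = dW_mu, b_mu = db_mu, W_th = dW_th, b_th = db_th,
                  W_pi = dW_pi, b_pi = db_pi))
  list(loss = loss, grads = grads)
}

#' @noRd
.denoiser_params <- function(nets) {
  c(nn_params(nets$enc, "enc"), nn_params(nets$dec, "dec"),
    nets[c("W_mu", "b_mu", "W_th", "b_th", "W_pi", "b_pi")])
}

#' Train the ZINB denoising autoencoder
#'
#' Fits an encoder--decoder network whose decoder feeds three parameter
#' heads (\code{exp} for dispersion, size-factor-scaled \code{exp} for the
#' mean, \code{sigmoid} for dropout) by minimising the mean ZINB negative
#' log-likelihood of the raw counts with Adam. The encoder consumes the
#' log1p of depth-normalised counts while the likelihood always sees the
#' raw counts. Training stops early when the loss has not improved for
#' \code{patience} epochs.
#'
#' @param counts non-negative cells x genes count matrix (HVG-filtered)
#' @param sizeFactors per-cell positive size factors; computed from library
#'   sizes when \code{NULL}
#' @param config a \code{\link{denoiserConfig}}
#' @param exclude optional binary matrix of entries to exclude from the
#'   likelihood
#' @param seed integer seed controlling initialisation and batching
#' @return a trained \code{\link{ZINBDenoiser}}
#' @export
trainDenoiser <- function(counts, sizeFactors = NULL,
                          config = denoiserConfig(), exclude = NULL,
                          seed = 1L) {
  X <- .as_count_matrix(counts)
  n <- nrow(X); g <- ncol(X)
  if (is.null(sizeFactors)) {
    lib <- rowSums(X)
    if (any(lib == 0)) stop("all-zero cells must be removed before training")
    sizeFactors <- lib / stats::median(lib)
  }
  if (any(sizeFactors <= 0)) stop("size factors must be strictly positive")
  sfm <- matrix(sizeFactors, n, g)
  # encoder features: log of depth-adjusted counts, standardised per gene
  # (the likelihood below always sees the raw counts)
  Xraw_in <- log1p(X / sizeFactors)
  in_center <- colMeans(Xraw_in)
  in_scale <- pmax(apply(Xraw_in, 2L, stats::sd), 1e-8)
  Xin <- sweep(sweep(Xraw_in, 2L, in_center), 2L, in_scale, "/")
  w <- if (is.null(exclude)) matrix(1, n, g) else 1 - exclude

  with_seed(seed, {
    hlast <- config$hiddenSizes[1L]          # decoder mirrors the encoder
    nets <- list(
      enc = nn_init(c(g, config$hiddenSizes, config$latentDim),
                    hidden_act = "elu", out_act = "linear"),
      dec = nn_init(c(config$latentDim, rev(config$hiddenSizes)),
                    hidden_act = "elu", out_act = "elu"),
      # small head weights; the mean bias starts each gene at its
      # depth-adjusted average so optimisation begins near the data
      W_mu = .glorot(hlast, g) * 0.05,
      b_mu = log(colMeans(X / sizeFactors) + 1e-4),
      W_th = .glorot(hlast, g) * 0.05, b_th = numeric(g),
      W_pi = .glorot(hlast, g) * 0.05, b_pi = numeric(g))
    nets$in_center <- in_center
    nets$in_scale <- in_scale
    params <- .denoiser_params(nets)
    state <- adam_init(params)
    hist <- numeric(0)
    best <- Inf; since_best <- 0L
    for (epoch in seq_len(config$epochs)) {
      idx <- sample.int(n)
      starts <- seq(1L, n, by = config$batchSize)
      ep_loss <- 0; ep_n <- 0
      for (s in starts) {
        b <- idx[s:min(s + config$batchSize - 1L, n)]
        fw <- .denoiser_forward(nets, Xin[b, , drop = FALSE],
                                sfm[b, , drop = FALSE])
        bw <- .denoiser_backward(nets, fw, X[b, , drop = FALSE],
                                 w[b, , drop = FALSE])
        if (!is.finite(bw$loss))
          stop("ZINB training loss became non-finite at epoch ", epoch,
               "; lower the learning rate")
        state <- adam_step(params, bw$grads, state,
                           lr = config$learningRate)
        ep_loss <- ep_loss + bw$loss * length(b); ep_n <- ep_n + length(b)
      }
      hist <- c(hist, ep_loss / ep_n)
      if (hist[epoch] < best - 1e-5) {
        best <- hist[epoch]; since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
  })
  new("ZINBDenoiser", nets = nets, config = unclass(config),
      sizeFactors = sizeFactors, input = Xin, counts = X,
      history = data.frame(epoch = seq_along(hist), loss = hist),
      trained = TRUE)
}

#' Fitted ZINB parameters of a trained denoiser
#'
#' @param model a trained \code{\link{ZINBDenoiser}}
#' @param counts optional count matrix to evaluate on (defaults to the
#'   training data); size factors are recomputed from its library sizes
#'   unless supplied
#' @param sizeFactors optional per-cell size factors for \code{counts}
#' @return a \code{\link{ZINBParams}}
#' @export
zinbFitted <- function(model, counts = NULL, sizeFactors = NULL) {
  if (!model@trained) stop("model has not been trained")
  if (is.null(counts)) {
    Xin <- model@input
    sf <- model@sizeFactors
  } else {
    X <- .as_count_matrix(counts)
    if (is.null(sizeFactors)) {
      lib <- rowSums(X)
      sizeFactors <- lib / stats::median(lib)
    }
    sf <- sizeFactors
    Xin <- log1p(X / sf)
    Xin <- sweep(sweep(Xin, 2L, model@nets$in_center), 2L,
                 model@nets$in_scale, "/")
  }
  fw <- .denoiser_forward(model@nets, Xin, matrix(sf, nrow(Xin), ncol(Xin)))
  ZINBParams(mean = fw$mu, dispersion = fw$th, dropout = fw$pi)
}

#' Denoised expression matrix
#'
#' Returns the fitted conditional mean matrix M (size-factor scaled), the
#' deterministic denoised reconstruction of the counts. With
#' \code{dropoutAdjust = TRUE} the mean is attenuated by the fitted
#' non-dropout probability, \code{(1 - Pi) * M}.
#'
#' @param model a trained \code{\link{ZINBDenoiser}}
#' @param counts optional matrix to denoise (defaults to training data)
#' @param dropoutAdjust multiply by (1 - dropout probability)
#' @return non-negative matrix of the same shape as the input counts
#' @export
denoiseCounts <- function(model, counts = NULL, dropoutAdjust = FALSE) {
  p <- zinbFitted(model, counts)
  out <- zinbMean(p)
  if (dropoutAdjust) out <- (1 - zinbDropout(p)) * out
  dimnames(out) <- dimnames(if (is.null(counts)) model@counts else counts)
  out
}
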