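# Minimal dense feed-forward engine used by the denoising and masking
# autoencoders: Glorot-uniform initialisation, ELU/ReLU hidden activations,
# analytic backpropagation, Adam updates. All state is plain R lists so that
# models serialise with saveRDS and training is fully deterministic under
# set.seed().

#' @noRd
.act_fun <- function(a, act) {
  switch(act,
    linear = a,
    relu   = pmax(a, 0),
    elu    = { p <- (a > 0) * 1; p * a + (1 - p) * expm1(pmin(a, 0)) },
    sigmoid = 1 / (1 + exp(-a)),
    stop("unknown activation: ", act)
  )
}

# derivative expressed through the activation OUTPUT h (valid for these four)
#' @noRd
.act_deriv <- function(h, act) {
  switch(act,
    linear = 1,
    relu   = (h > 0) * 1,
    elu    = { p <- (h > 0) * 1; p + (1 - p) * (h + 1) },
    sigmoid = h * (1 - h),
    stop("unknown activation: ", act)
  )
}

#' @noRd
.glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

# dims: c(n_in, hidden..., n_out); hidden_act on all but last layer,
# out_act on the last ("linear" for embeddings/heads, "elu" for decoder
# trunks whose output is itself a hidden representation).
#' @noRd
nn_init <- function(dims, hidden_act = "relu", out_act = "linear") {
  L <- length(dims) - 1L
  stopifnot(L >= 1L)
  W <- vector("list", L)
  b <- vector("list", L)
  for (l in seq_len(L)) {
    W[[l]] <- .glorot(dims[l], dims[l + 1L])
    b[[l]] <- numeric(dims[l + 1L])
  }
  acts <- c(rep(hidden_act, L - 1L), out_act)
  list(W = W, b = b, acts = acts, dims = dims)
}

# forward pass keeping every layer output for backprop;
# H[[1]] is the input, H[[L+1]] the network output
#' @noRd
nn_forward <- function(net, X) {
  L <- length(net$W)
  H <- vector("list", L + 1L)
  H[[1L]] <- X
  for (l in seq_len(L)) {
    A <- H[[l]] %*% net$W[[l]]
    A <- sweep(A, 2L, net$b[[l]], "+")
    H[[l + 1L]] <- .act_fun(A, net$acts[l])
  }
  H
}

# dOut: gradient of the scalar loss w.r.t. the network output.
# Returns parameter gradients and the gradient w.r.t. the input.
#' @noRd
nn_backward <- function(net, H, dOut) {
  L <- length(net$W)
  dW <- vector("list", L)
  db <- vector("list", L)
  delta <- dOut * .act_deriv(H[[L + 1L]], net$acts[L])
  for (l in rev(seq_len(L))) {
    dW[[l]] <- crossprod(H[[l]], delta)
    db[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$W[[l]])) * .act_deriv(H[[l]], net$acts[l - 1L])
    } else {
      delta <- delta %*% t(net$W[[l]])
    }
  }
  list(dW = dW, db = db, dX = delta)
}

# ---- Adam over an arbitrary flat named list of numeric arrays -------------
# The update runs in place (C++ kernel): the parameter arrays are mutated
# directly, and because the network lists hold references to the same
# arrays the networks advance with every step without copying.

#' @noRd
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

#' @noRd
adam_step <- function(params, grads, state, lr = 1e-3,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  .adam_step_cpp(params, grads[names(params)], state$m, state$v, state$t,
                 lr, beta1, beta2, eps)
  state
}

# flatten a network's parameters into the named-list form Adam consumes
#' @noRd
nn_params <- function(net, prefix) {
  out <- list()
  for (l in seq_along(net$W)) {
    out[[paste0(prefix, "_W", l)]] <- net$W[[l]]
    out[[paste0(prefix, "_b", l)]] <- net$b[[l]]
  }
  out
}

#' @noRd
nn_grads <- function(bw, prefix) {
  out <- list()
  for (l in seq_along(bw$dW)) {
    out[[paste0(prefix, "_W", l)]] <- bw$dW[[l]]
    out[[paste0(prefix, "_b", l)]] <- bw$db[[l]]
  }
  out
}

# evaluate expr with a temporary RNG seed, restoring the caller's stream
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# derive a stage-specific 31-bit seed from one global seed, so stages can be
# rerun independently yet reproducibly
#' @noRd
derive_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' @noRd
sigmoid <- function(x) 1 / (1 + exp(-x))
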