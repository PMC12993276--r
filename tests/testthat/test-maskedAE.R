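test_that("mask cross-entropy matches hand arithmetic", {
  M <- matrix(c(1, 0, 0, 0), 2, 2, byrow = TRUE)
  Mp <- matrix(c(0.9, 0.1, 0.2, 0.4), 2, 2, byrow = TRUE)
  expect_equal(maskLoss(M, Mp),
               -(log(0.9) + log(0.9) + log(0.8) + log(0.6)) / 4,
               tolerance = 1e-10)
  # perfect prediction costs ~ 0; the maximal-entropy predictor costs log 2
  expect_lt(maskLoss(M, pmin(pmax(M, 1e-7), 1 - 1e-7)), 1e-5)
  expect_equal(maskLoss(M, matrix(0.5, 2, 2)), log(2), tolerance = 1e-12)
  # the printed positive-only form keeps only the -M log M' term
  expect_equal(maskLoss(M, Mp, positiveOnly = TRUE), -log(0.9) / 4,
               tolerance = 1e-10)
  expect_error(maskLoss(M, matrix(0.5, 3, 2)), "mismatch")
})

test_that("weighted MSE follows its definition and lambda monotonicity", {
  X <- matrix(c(1, 0), 1, 2)
  Xh <- matrix(0, 1, 2)
  M <- matrix(c(1, 0), 1, 2)
  expect_equal(weightedMSE(X, Xh, M, lambda = 0.7), 0.35)
  # lambda = 0.5 is exactly half the plain MSE
  set.seed(1)
  A <- matrix(rnorm(60), 6, 10)
  B <- matrix(rnorm(60), 6, 10)
  Mm <- matrix(rbinom(60, 1, 0.3), 6, 10)
  expect_equal(weightedMSE(A, B, Mm, 0.5), 0.5 * mean((A - B)^2),
               tolerance = 1e-12)
  expect_equal(weightedMSE(A, A, Mm, 0.8), 0)
  # errors concentrated on masked entries: non-decreasing in lambda
  Bm <- A
  Bm[Mm == 1] <- Bm[Mm == 1] + 1
  lams <- seq(0, 1, by = 0.25)
  vals <- sapply(lams, function(l) weightedMSE(A, Bm, Mm, l))
  expect_true(all(diff(vals) >= 0))
  # concentrated on unmasked entries: non-increasing
  Bu <- A
  Bu[Mm == 0] <- Bu[Mm == 0] + 1
  valsu <- sapply(lams, function(l) weightedMSE(A, Bu, Mm, l))
  expect_true(all(diff(valsu) <= 0))
})

test_that("the combined masked loss is linear in gamma", {
  expect_equal(totalMaskLoss(0.2, 0.4, 0), 0.4)
  expect_equal(totalMaskLoss(0.2, 0.4, 1), 0.2)
  expect_equal(totalMaskLoss(0.2, 0.4, 0.65), 0.27, tolerance = 1e-12)
  g <- seq(0, 1, by = 0.1)
  v <- sapply(g, function(x) totalMaskLoss(3, 7, x))
  expect_equal(v, 7 - 4 * g, tolerance = 1e-12)
})

test_that("encoder, predictor and decoder have the right shapes and determinism", {
  set.seed(3)
  X <- matrix(rexp(120 * 50), 120, 50)
  cfg <- maskedAEConfig(epochs = 3, latentDim = 8, hiddenSizes = c(32, 16))
  mae <- trainMaskedAE(X, config = cfg, seed = 4)
  Z <- encodeCells(mae, X)
  expect_identical(dim(Z), c(120L, 8L))
  expect_true(all(is.finite(Z)))
  Mp <- predictMask(mae, Z)
  expect_identical(dim(Mp), c(120L, 50L))
  expect_true(all(Mp > 0 & Mp < 1))
  Xh <- decodeCells(mae, Z, Mp)
  expect_identical(dim(Xh), dim(X))
  expect_identical(encodeCells(mae, X), Z)
  # without its predictor the model refuses to predict masks
  mae2 <- trainMaskedAE(X, config = maskedAEConfig(epochs = 2,
    latentDim = 8, hiddenSizes = c(32, 16), usePredictor = FALSE), seed = 4)
  expect_error(predictMask(mae2, encodeCells(mae2, X)), "without a mask")
  expect_identical(dim(decodeCells(mae2, encodeCells(mae2, X))), dim(X))
})

test_that("a single-layer identity encoder passes input through", {
  net <- scMaskClust:::nn_init(c(4, 4), hidden_act = "relu",
                               out_act = "linear")
  net$W[[1]] <- diag(4)
  net$b[[1]] <- rep(0, 4)
  X <- matrix(rnorm(20), 5, 4)
  H <- scMaskClust:::nn_forward(net, X)
  expect_equal(H[[2]], X)
})

test_that("training separates masked from unmasked entries and reduces error", {
  set.seed(5)
  sim <- tiny_sim(seed = 5, nCells = 200, nGenes = 60)
  Xl <- scale(log1p(normValues(normalizeLibrarySize(sim$counts))))
  # trained against one fixed corruption, the predictor assigns higher
  # probability to the entries that really were replaced
  b <- makeMaskedBatch(Xl, corruptionConfig(0.3), seed = 99)
  mae <- trainMaskedAE(Xl, config = maskedAEConfig(epochs = 100),
                       batch = b, seed = 5)
  Mp <- predictMask(mae, encodeCells(mae, b@corrupted))
  expect_gt(mean(Mp[b@mask == 1]), mean(Mp[b@mask == 0]) + 0.1)
  # under fresh per-epoch corruption the reconstruction error still falls
  mae2 <- trainMaskedAE(Xl, config = maskedAEConfig(epochs = 60), seed = 5)
  h <- mae2@history
  expect_lt(mean(tail(h$lrec, 5)), mean(head(h$lrec, 5)))
  # gradient flow: encoder weights move under training
  mae1 <- trainMaskedAE(Xl, config = maskedAEConfig(epochs = 1), seed = 5)
  expect_false(isTRUE(all.equal(mae1@nets$enc$W[[1]], mae2@nets$enc$W[[1]])))
})
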