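test_that("soft K-means weights: symmetry, inflation identity and hard limit", {
  Z <- matrix(c(0, 0,
                2, 0), 2, 2, byrow = TRUE)
  C <- matrix(c(1, 1,
                1, -1), 2, 2, byrow = TRUE)
  # both cells are equidistant from the two centres
  w <- softClusterWeights(Z, C)
  expect_equal(unname(w), matrix(0.5, 2, 2), tolerance = 1e-12)
  set.seed(2)
  Z2 <- matrix(rnorm(40), 20, 2)
  C2 <- matrix(rnorm(6), 3, 2)
  w1 <- softClusterWeights(Z2, C2, inflation = 1)
  expect_equal(unname(rowSums(w1)), rep(1, 20), tolerance = 1e-12)
  # inflation = 1 is the identity on the softmax weights
  d2 <- scMaskClust:::.sqdist(Z2, C2)
  wbar <- exp(-d2) / rowSums(exp(-d2))
  expect_equal(w1, wbar, tolerance = 1e-9)
  # large inflation approaches one-hot at the nearest centre
  whard <- softClusterWeights(Z2, C2, inflation = 500)
  expect_equal(unname(max.col(whard)), unname(apply(d2, 1, which.min)))
  expect_gt(min(apply(whard, 1, max)), 0.999)
})

test_that("centre update is the weighted mean and re-seeds dead clusters", {
  Z <- matrix(c(0, 0, 1, 0, 10, 0, 11, 0), 4, 2, byrow = TRUE)
  w <- matrix(c(1, 0,
                1, 0,
                0, 1,
                0, 1), 4, 2, byrow = TRUE)
  C <- updateCenters(Z, w)
  expect_equal(unname(C), matrix(c(0.5, 0, 10.5, 0), 2, 2, byrow = TRUE))
  # uniform weights put every centre at the global mean
  wu <- matrix(0.5, 4, 2)
  Cu <- updateCenters(Z, wu)
  expect_equal(unname(Cu[1, ]), unname(colMeans(Z)))
  expect_equal(unname(Cu[2, ]), unname(colMeans(Z)))
  # 4-point hand case with fractional weights
  wf <- matrix(c(0.9, 0.1,
                 0.8, 0.2,
                 0.1, 0.9,
                 0.2, 0.8), 4, 2, byrow = TRUE)
  Cf <- updateCenters(Z, wf)
  expect_equal(unname(Cf[1, 1]),
               sum(wf[, 1] * Z[, 1]) / sum(wf[, 1]), tolerance = 1e-12)
  # a cluster with no weight is re-seeded from the farthest cell
  wz <- cbind(rep(1, 4), 0)
  expect_message(Cz <- updateCenters(Z, wz), "re-seeding")
  expect_false(any(!is.finite(Cz)))
})

test_that("weighted K-means loss is non-negative and decreases at the centre optimum", {
  set.seed(4)
  Z <- matrix(rnorm(60), 30, 2)
  C <- matrix(rnorm(4), 2, 2)
  w <- softClusterWeights(Z, C)
  expect_gte(kmeansLoss(Z, C, w), 0)
  # cells exactly at their one-hot centres: zero loss
  Ch <- matrix(c(0, 0, 5, 5), 2, 2, byrow = TRUE)
  Zh <- Ch[c(1, 1, 2, 2), ]
  wh <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2, byrow = TRUE)
  expect_equal(kmeansLoss(Zh, Ch, wh), 0)
  # Eq-17 update cannot increase the loss at fixed weights
  expect_lte(kmeansLoss(Z, updateCenters(Z, w), w), kmeansLoss(Z, C, w))
})

test_that("Student-t soft assignment normalises and matches hand values", {
  Z <- matrix(c(0, 0), 1, 2)
  C1 <- matrix(c(1, 0), 1, 2)
  expect_equal(unname(softAssign(Z, C1)), matrix(1, 1, 1))
  # equidistant centres split evenly
  C2 <- matrix(c(1, 0, -1, 0), 2, 2, byrow = TRUE)
  expect_equal(unname(softAssign(Z, C2)), matrix(0.5, 1, 2))
  # t = 1, squared distances (0, 1): q = (1, 1/2) / 1.5
  C3 <- matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)
  expect_equal(unname(softAssign(Z, C3, tDof = 1)),
               matrix(c(2 / 3, 1 / 3), 1, 2), tolerance = 1e-12)
  expect_error(softAssign(Z, C3, tDof = 0), "positive")
  set.seed(1)
  q <- softAssign(matrix(rnorm(40), 20, 2), C2)
  expect_equal(unname(rowSums(q)), rep(1, 20), tolerance = 1e-12)
})

test_that("target distribution sharpens q and keeps rows normalised", {
  # one-hot q is a fixed point
  q1 <- diag(2)
  expect_equal(targetDistribution(q1), q1)
  # uniform q stays uniform
  qu <- matrix(1 / 3, 4, 3)
  expect_equal(targetDistribution(qu), qu, tolerance = 1e-12)
  # 2x2 hand case: p_ik = (q_ik^2 / f_k) / row sum
  q <- matrix(c(0.9, 0.1, 0.4, 0.6), 2, 2, byrow = TRUE)
  f <- colSums(q)
  raw <- q^2 / matrix(f, 2, 2, byrow = TRUE)
  p_hand <- raw / rowSums(raw)
  expect_equal(targetDistribution(q), p_hand, tolerance = 1e-12)
  expect_equal(rowSums(targetDistribution(q)), c(1, 1), tolerance = 1e-12)
  # confidence grows for the dominant entry
  expect_gt(targetDistribution(q)[1, 1], q[1, 1])
})

test_that("KL clustering loss: Gibbs inequality and hand value", {
  p <- matrix(c(1, 0), 1, 2)
  q <- matrix(c(0.5, 0.5), 1, 2)
  expect_equal(clusterKLLoss(p, q), log(2), tolerance = 1e-12)
  expect_equal(clusterKLLoss(q, q), 0)
  set.seed(3)
  for (i in 1:20) {
    a <- matrix(rexp(8), 2, 4)
    a <- a / rowSums(a)
    b <- matrix(rexp(8), 2, 4)
    b <- b / rowSums(b)
    expect_gte(clusterKLLoss(a, b), 0)
  }
  expect_warning(clusterKLLoss(p, matrix(c(1e-15, 1), 1, 2)), "underflow")
  expect_error(clusterKLLoss(p, matrix(0.5, 2, 2)), "identical shape")
})

test_that("the total objective is linear in its weights", {
  expect_equal(totalLoss(1, 2, 3, 4, lossWeights(1, 1, 1, 1)), 10)
  expect_equal(totalLoss(5, 2, 3, 4, lossWeights(0, 1, 0, 0)), 2)
  base <- totalLoss(1, 2, 3, 4, lossWeights(0.1, 0.2, 0.3, 0.4))
  up <- totalLoss(1, 2, 3, 4, lossWeights(0.1, 0.2, 0.3 + 1, 0.4))
  expect_equal(up - base, 3, tolerance = 1e-12)
  expect_error(lossWeights(0, 0, 0, 0), "positive")
  expect_error(lossWeights(-1, 1, 1, 1), "non-negative")
})

test_that("two well-separated blobs are recovered perfectly and deterministically", {
  # two far-apart Poisson populations in expression space
  set.seed(10)
  n <- 60
  g <- 40
  mu1 <- rexp(g, 1 / 2)
  mu2 <- mu1 * exp(sample(c(-2, 2), g, replace = TRUE))
  X <- rbind(matrix(rpois(n * g, rep(mu1 * 20, each = n)), n, g),
             matrix(rpois(n * g, rep(mu2 * 20, each = n)), n, g))
  truth <- rep(1:2, each = n)
  cfg <- tiny_scmc_config(seed = 1)
  fit <- scMaskClust(X, 2, cfg)
  expect_equal(adjustedRandIndex(truth, clusterLabels(fit)), 1)
  fit2 <- scMaskClust(X, 2, cfg)
  expect_identical(clusterLabels(fit), clusterLabels(fit2))
  # result object invariants
  expect_equal(unname(rowSums(softAssignments(fit))), rep(1, 2 * n),
               tolerance = 1e-6)
  expect_equal(unname(rowSums(fit@p)), rep(1, 2 * n), tolerance = 1e-6)
  expect_identical(length(clusterLabels(fit)), nrow(X))
  expect_s4_class(fit, "ScmcFit")
  h <- lossHistory(fit)
  expect_true(all(c("denoiser", "masked-ae", "joint") %in% h$phase))
  expect_true(all(h$lcluster[h$phase == "joint"] > -1e-8))
})

test_that("joint fine-tuning of the denoiser (alpha > 0) runs and logs its loss", {
  sim <- tiny_sim(seed = 17)
  cfg <- tiny_scmc_config(seed = 17, weights = lossWeights(alpha = 0.1))
  fit <- scMaskClust(sim$counts, 3, cfg)
  h <- subset(lossHistory(fit), phase == "joint")
  expect_true(all(is.finite(h$lzinb)))
  expect_identical(length(clusterLabels(fit)), nrow(sim$counts))
})
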