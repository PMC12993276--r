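test_that("NB log-pmf matches closed forms and the Poisson limit", {
  # x = 0 collapses to theta * log(theta / (theta + mu))
  expect_equal(nbLogPmf(0, mu = 2, theta = 1), log(1 / 3),
               tolerance = 1e-12)
  # independent scalar oracle via stats::dnbinom
  expect_equal(nbLogPmf(4, mu = 2.5, theta = 0.7),
               dnbinom(4, size = 0.7, mu = 2.5, log = TRUE),
               tolerance = 1e-8)
  # NB -> Poisson as dispersion grows
  expect_equal(nbLogPmf(0:10, mu = 3, theta = 1e8),
               dpois(0:10, 3, log = TRUE), tolerance = 1e-5)
  expect_error(nbLogPmf(1, mu = -1, theta = 1), "positive")
  expect_error(nbLogPmf(1, mu = 1, theta = Inf), "finite")
})

test_that("ZINB log-pmf handles the zero-inflation mixture correctly", {
  # certain zero
  expect_equal(zinbLogPmf(0, pi = 1, mu = 2, theta = 1), 0)
  # no inflation reduces to NB for all x
  x <- 0:15
  expect_equal(zinbLogPmf(x, pi = 0, mu = 4, theta = 2),
               nbLogPmf(x, mu = 4, theta = 2), tolerance = 1e-12)
  # hand value: log(0.5 + 0.5/3) = log(2/3)
  expect_equal(zinbLogPmf(0, pi = 0.5, mu = 2, theta = 1), log(2 / 3),
               tolerance = 1e-12)
  expect_error(zinbLogPmf(0, pi = 1.2, mu = 1, theta = 1), "0, 1")
})

test_that("ZINB pmf sums to one and is monotone in pi at zero", {
  for (mu in c(0.5, 2, 20)) {
    for (theta in c(0.3, 2)) {
      for (pi in c(0, 0.4, 1)) {
        xmax <- qnbinom(1 - 1e-13, size = theta, mu = mu) + 10
        s <- sum(exp(zinbLogPmf(0:xmax, pi, mu, theta)))
        expect_equal(s, 1, tolerance = 1e-6)
      }
    }
  }
  # continuity in pi at 0 and monotone increase of P(0) in pi
  p0 <- sapply(seq(0, 1, by = 0.1),
               function(p) zinbLogPmf(0, p, mu = 3, theta = 1))
  expect_true(all(diff(p0) > 0))
  expect_equal(p0[1], nbLogPmf(0, 3, 1), tolerance = 1e-10)
})

test_that("matrix ZINB loss decomposes into scalar calls and respects masks", {
  X <- matrix(c(0, 3, 1, 0, 2, 5), 3, 2)
  set.seed(1)
  par <- ZINBParams(mean = matrix(runif(6, 1, 4), 3, 2),
                    dispersion = matrix(runif(6, 0.5, 2), 3, 2),
                    dropout = matrix(runif(6, 0.1, 0.6), 3, 2))
  manual <- -mean(sapply(seq_along(X), function(i)
    zinbLogPmf(X[i], zinbDropout(par)[i], zinbMean(par)[i],
               zinbDispersion(par)[i])))
  expect_equal(zinbLoss(X, par), manual, tolerance = 1e-10)
  expect_gte(zinbLoss(X, par), 0)
  # excluded entries contribute nothing
  excl <- matrix(c(1, 0, 0, 0, 0, 0), 3, 2)
  keep <- which(excl == 0)
  manual2 <- -mean(sapply(keep, function(i)
    zinbLogPmf(X[i], zinbDropout(par)[i], zinbMean(par)[i],
               zinbDispersion(par)[i])))
  expect_equal(zinbLoss(X, par, exclude = excl), manual2, tolerance = 1e-10)
  expect_error(zinbLoss(matrix(0, 2, 2), par), "identical shape")
  # certain zeros under full inflation cost nothing
  z <- matrix(0, 3, 2)
  parz <- ZINBParams(mean = zinbMean(par), dispersion = zinbDispersion(par),
                     dropout = matrix(1 - 1e-12, 3, 2))
  expect_lt(zinbLoss(z, parz), 1e-10)
})

test_that("analytic ZINB gradients match finite differences", {
  eps <- 1e-6
  for (x in c(0, 1, 7)) {
    for (pars in list(c(pi = 0.3, mu = 2, th = 1.5),
                      c(pi = 0.7, mu = 0.4, th = 0.2))) {
      g <- scMaskClust:::.zinb_grad(x, pars["pi"], pars["mu"], pars["th"])
      f <- function(pi, mu, th) zinbLogPmf(x, pi, mu, th)
      fd_mu <- (f(pars["pi"], pars["mu"] + eps, pars["th"]) -
                f(pars["pi"], pars["mu"] - eps, pars["th"])) / (2 * eps)
      fd_th <- (f(pars["pi"], pars["mu"], pars["th"] + eps) -
                f(pars["pi"], pars["mu"], pars["th"] - eps)) / (2 * eps)
      fd_pi <- (f(pars["pi"] + eps, pars["mu"], pars["th"]) -
                f(pars["pi"] - eps, pars["mu"], pars["th"])) / (2 * eps)
      expect_equal(unname(g$dmu), unname(fd_mu), tolerance = 1e-4)
      expect_equal(unname(g$dtheta), unname(fd_th), tolerance = 1e-4)
      expect_equal(unname(g$dpi), unname(fd_pi), tolerance = 1e-4)
    }
  }
})

test_that("compiled ZINB kernels agree with the reference R implementation", {
  set.seed(5)
  n <- 500
  x <- as.double(rpois(n, 4))
  pi <- runif(n, 1e-4, 1 - 1e-4)
  mu <- runif(n, 0.1, 50)
  th <- runif(n, 0.1, 20)
  w <- runif(n)
  expect_equal(scMaskClust:::.zinb_nll_cpp(x, pi, mu, th, w),
               scMaskClust:::.zinb_nll(x, pi, mu, th, w),
               tolerance = 1e-10)
  gc_ <- scMaskClust:::.zinb_grad_cpp(x, pi, mu, th)
  gr_ <- scMaskClust:::.zinb_grad(x, pi, mu, th)
  expect_equal(gc_$dmu, gr_$dmu, tolerance = 1e-10)
  expect_equal(gc_$dtheta, gr_$dtheta, tolerance = 1e-10)
  expect_equal(gc_$dpi, gr_$dpi, tolerance = 1e-10)
})

test_that("ZINBParams enforces its invariants", {
  m <- matrix(1, 2, 2)
  expect_error(ZINBParams(m, m, matrix(2, 2, 2)), "0, 1")
  expect_error(ZINBParams(m, matrix(0, 2, 2), m * 0.5), "positive")
  expect_error(ZINBParams(-m, m, m * 0.5), "non-negative")
  expect_error(ZINBParams(m, m, matrix(0.5, 3, 2)), "identical shape")
  p <- ZINBParams(m, m, m * 0.5)
  expect_s4_class(p, "ZINBParams")
})
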