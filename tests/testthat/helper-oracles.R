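# Independent oracles used across the suite. These are deliberately written
# by a different route than the package implementations: pair enumeration
# instead of contingency-table combinatorics, stats::dnbinom instead of the
# hand-coded log-gamma form, explicit per-point loops instead of matrix
# algebra.

# Rand/adjusted-Rand by brute-force enumeration of all cell pairs
oracle_ari <- function(u, v) {
  n <- length(u)
  tp <- tn <- fp <- fn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      su <- u[i] == u[j]
      sv <- v[i] == v[j]
      if (su && sv) tp <- tp + 1
      else if (!su && !sv) tn <- tn + 1
      else if (!su && sv) fp <- fp + 1
      else fn <- fn + 1
    }
  }
  total <- tp + tn + fp + fn
  # expected index under permutation null, from pair counts
  a <- tp + fn   # same-in-u pairs
  b <- tp + fp   # same-in-v pairs
  expected <- a * b / total
  maxi <- (a + b) / 2
  if (maxi == expected) return(1)
  (tp - expected) / (maxi - expected)
}

# NMI from the empirical joint distribution, explicit double loop
oracle_nmi <- function(u, v) {
  n <- length(u)
  uu <- unique(u)
  vv <- unique(v)
  pj <- outer(uu, vv, Vectorize(function(a, b) sum(u == a & v == b))) / n
  pu <- rowSums(pj)
  pv <- colSums(pj)
  hu <- -sum(pu[pu > 0] * log(pu[pu > 0]))
  hv <- -sum(pv[pv > 0] * log(pv[pv > 0]))
  if (hu + hv == 0) return(1)
  mi <- 0
  for (i in seq_along(pu)) for (j in seq_along(pv))
    if (pj[i, j] > 0) mi <- mi + pj[i, j] * log(pj[i, j] / (pu[i] * pv[j]))
  2 * mi / (hu + hv)
}

# scalar ZINB log-pmf through stats::dnbinom (independent of the package's
# log-gamma implementation)
oracle_zinb_logpmf <- function(x, pi, mu, theta) {
  nb <- stats::dnbinom(x, size = theta, mu = mu)
  log(pi * (x == 0) + (1 - pi) * nb)
}

# small training configurations for fast unit tests (full-size defaults are
# exercised in the acceptance tests)
tiny_scmc_config <- function(seed = 1L, ...) {
  scmcConfig(seed = seed,
             denoiser = denoiserConfig(epochs = 40),
             maskedAE = maskedAEConfig(epochs = 40),
             clustering = clusterConfig(maxEpochs = 40),
             ...)
}

tiny_sim <- function(seed = 1L, nCells = 150, nGenes = 60, ...) {
  simulateCounts(simulationConfig(nCells = nCells, nGenes = nGenes,
                                  seed = seed, ...))
}
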