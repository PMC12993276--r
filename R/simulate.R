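# Seeded generator of clustered ZINB count matrices with full ground truth,
# plus the ablation and hyperparameter-sweep drivers that run the pipeline
# on simulated data.

#' Simulation configuration
#'
#' Defines clustered zero-inflated negative binomial counts: baseline gene
#' means drawn log-uniformly, cluster-specific up/down regulation of a
#' random differential-expression gene set, log-normal cell library
#' factors, NB sampling, and mean-dependent logistic dropout
#' \code{pi_ij = sigmoid(-steepness * (log mu_ij - midpoint))}. The
#' defaults produce three clusters of 600 cells x 200 genes with roughly
#' 40--60\% zeros and a mean dropout probability near 0.4.
#'
#' @param nCells,nGenes,nClusters dimensions of the simulation
#' @param deGeneFraction fraction of genes differentially expressed per
#'   cluster (default 0.2)
#' @param logFC absolute log-fold-change of DE genes (natural log,
#'   default 1.0)
#' @param baseMeanRange interval for the log-uniform baseline gene means
#' @param dispersion NB dispersion theta (scalar, default 2)
#' @param dropoutMidpoint log-mean at which dropout probability is 0.5
#' @param dropoutSteepness slope of the logistic dropout curve; larger
#'   means sharper mean-dependence, very negative midpoints disable
#'   dropout
#' @param libsizeSigma sd of the log-normal cell library factor
#' @param clusterProportions simplex vector of cluster sizes (default
#'   equal)
#' @param seed integer seed
#' @return a named list of class \code{simulation_config}
#' @export
simulationConfig <- function(nCells = 600, nGenes = 200, nClusters = 3,
                             deGeneFraction = 0.2, logFC = 1.0,
                             baseMeanRange = c(0.5, 50), dispersion = 2,
                             dropoutMidpoint = log(2), dropoutSteepness = 1,
                             libsizeSigma = 0.35,
                             clusterProportions = NULL, seed = 1L) {
  nCells <- .check_pos(nCells, "nCells", int = TRUE)
  nGenes <- .check_pos(nGenes, "nGenes", int = TRUE)
  nClusters <- .check_pos(nClusters, "nClusters", int = TRUE)
  if (is.null(clusterProportions))
    clusterProportions <- rep(1 / nClusters, nClusters)
  if (length(clusterProportions) != nClusters ||
      abs(sum(clusterProportions) - 1) > 1e-8 ||
      any(clusterProportions <= 0))
    stop("clusterProportions must be a positive vector summing to 1")
  if (length(baseMeanRange) != 2L || any(baseMeanRange <= 0) ||
      baseMeanRange[1] > baseMeanRange[2])
    stop("baseMeanRange must be a positive increasing interval")
  if (dispersion <= 0) stop("dispersion must be positive")
  if (dropoutSteepness < 0) stop("dropoutSteepness must be >= 0")
  structure(list(
    nCells = nCells, nGenes = nGenes, nClusters = nClusters,
    deGeneFraction = .check_frac(deGeneFraction, "deGeneFraction"),
    logFC = logFC, baseMeanRange = baseMeanRange, dispersion = dispersion,
    dropoutMidpoint = dropoutMidpoint,
    dropoutSteepness = dropoutSteepness,
    libsizeSigma = libsizeSigma,
    clusterProportions = clusterProportions,
    seed = as.integer(seed)
  ), class = c("simulation_config", "list"))
}

#' Simulate clustered ZINB counts with ground truth
#'
#' @param config a \code{\link{simulationConfig}}
#' @return a list with \code{counts} (cells x genes integer matrix),
#'   \code{labels} (true cluster per cell), \code{trueMeans} (per-entry
#'   NB mean including the library factor), \code{trueDropout} (per-entry
#'   dropout probability) and the echoed \code{config}
#' @export
simulateCounts <- function(config = simulationConfig()) {
  n <- config$nCells; g <- config$nGenes; K <- config$nClusters
  with_seed(config$seed, {
    base <- exp(stats::runif(g, log(config$baseMeanRange[1]),
                             log(config$baseMeanRange[2])))
    # cluster-level fold-change matrix (K x g)
    fc <- matrix(1, K, g)
    nde <- round(config$deGeneFraction * g)
    for (k in seq_len(K)) {
      if (nde > 0 && config$logFC != 0) {
        idx <- sample.int(g, nde)
        sgn <- sample(c(-1, 1), nde, replace = TRUE)
        fc[k, idx] <- exp(sgn * config$logFC)
      }
    }
    # cluster labels at the configured proportions, in random order
    sizes <- floor(config$clusterProportions * n)
    while (sum(sizes) < n) {
      i <- which.max(config$clusterProportions * n - sizes)
      sizes[i] <- sizes[i] + 1L
    }
    labels <- sample(rep(seq_len(K), times = sizes))
    lib <- stats::rlnorm(n, 0, config$libsizeSigma)
    mu <- (lib * fc[labels, , drop = FALSE]) *
      matrix(base, n, g, byrow = TRUE)
    counts <- matrix(stats::rnbinom(n * g, size = config$dispersion,
                                    mu = mu), n, g)
    pi <- stats::plogis(-config$dropoutSteepness *
                          (log(mu) - config$dropoutMidpoint))
    drop <- matrix(stats::runif(n * g) < pi, n, g)
    counts[drop] <- 0L
    dimnames(counts) <- list(paste0("cell_", seq_len(n)),
                             paste0("gene_", seq_len(g)))
    dimnames(mu) <- dimnames(pi) <- dimnames(counts)
    list(counts = counts, labels = labels, trueMeans = mu,
         trueDropout = pi, config = config)
  })
}

#' @noRd
.fit_and_score <- function(sim, nClusters, config) {
  fit <- scMaskClust(sim$counts, nClusters = nClusters, config = config)
  ev <- evaluateClustering(clusterLabels(fit), sim$labels)
  cbind(ev, data.frame(seed = config$seed))
}

#' Run the full model and its three ablations on simulated data
#'
#' For each seed the same simulated data set is clustered by the full
#' pipeline and by three ablated variants: no denoiser (the masked
#' autoencoder sees normalised counts), no reconstruction weighting
#' (lambda forced to 0.5), and no mask predictor (the prediction head and
#' its cross-entropy term removed).
#'
#' @param simConfig a \code{\link{simulationConfig}}
#' @param config a \code{\link{scmcConfig}} used for every variant
#' @param nSeeds number of replicate seeds
#' @return a list with \code{results} (long data.frame: method, seed, ari,
#'   nmi) and \code{summary} (method x metric mean table shaped 4 methods
#'   x 2 metrics)
#' @export
ablationSuite <- function(simConfig = simulationConfig(),
                          config = scmcConfig(), nSeeds = 5) {
  variants <- list(
    full = identity,
    noDenoise = function(cfg) { cfg$useDenoiser <- FALSE; cfg },
    noWeighting = function(cfg) { cfg$maskedAE$lambda <- 0.5; cfg },
    noPredictor = function(cfg) { cfg$maskedAE$usePredictor <- FALSE; cfg })
  res <- list()
  for (s in seq_len(nSeeds)) {
    sc <- simConfig
    sc$seed <- derive_seed(simConfig$seed + s - 1L, "ablation-sim")
    sim <- simulateCounts(sc)
    for (v in names(variants)) {
      cfg <- variants[[v]](config)
      # paired design: every variant runs on the same data with the same
      # training seed, so differences are structural, not sampling noise
      cfg$seed <- derive_seed(config$seed + s - 1L, "ablation-fit")
      fit <- scMaskClust(sim$counts, nClusters = simConfig$nClusters,
                         config = cfg)
      ev <- evaluateClustering(clusterLabels(fit), sim$labels)
      res[[length(res) + 1L]] <- data.frame(method = v, seed = s,
                                            ari = ev$ari, nmi = ev$nmi)
    }
  }
  results <- do.call(rbind, res)
  summary <- do.call(rbind, lapply(split(results, results$method),
    function(d) data.frame(method = d$method[1],
                           ari = mean(d$ari), nmi = mean(d$nmi))))
  summary <- summary[c("full", "noDenoise", "noWeighting", "noPredictor"), ]
  rownames(summary) <- NULL
  list(results = results, summary = summary)
}

#' Sweep a corruption/loss hyperparameter over simulated data
#'
#' Runs the full pipeline for every value of one tunable dial --
#' \code{"maskRatio"} (Bernoulli corruption probability), \code{"lambda"}
#' (weight on masked entries in the reconstruction loss) or \code{"gamma"}
#' (mask-prediction vs reconstruction mix) -- over several seeds.
#'
#' @param parameter one of \code{"maskRatio"}, \code{"lambda"},
#'   \code{"gamma"}
#' @param values numeric values to sweep
#' @param simConfig a \code{\link{simulationConfig}}
#' @param config a \code{\link{scmcConfig}}
#' @param nSeeds replicate seeds per value
#' @return long data.frame with columns parameter, value, seed, ari, nmi
#' @export
sweepParameter <- function(parameter = c("maskRatio", "lambda", "gamma"),
                           values, simConfig = simulationConfig(),
                           config = scmcConfig(), nSeeds = 5) {
  parameter <- match.arg(parameter)
  res <- list()
  for (s in seq_len(nSeeds)) {
    sc <- simConfig
    sc$seed <- derive_seed(simConfig$seed + s - 1L, "sweep-sim")
    sim <- simulateCounts(sc)
    for (v in values) {
      cfg <- config
      if (parameter == "maskRatio") cfg$corruption$maskRatio <- v
      if (parameter == "lambda") cfg$maskedAE$lambda <- v
      if (parameter == "gamma") cfg$maskedAE$gamma <- v
      # paired across values: one training seed per replicate
      cfg$seed <- derive_seed(config$seed + s - 1L, "sweep-fit")
      fit <- scMaskClust(sim$counts, nClusters = simConfig$nClusters,
                         config = cfg)
      ev <- evaluateClustering(clusterLabels(fit), sim$labels)
      res[[length(res) + 1L]] <- data.frame(parameter = parameter,
                                            value = v, seed = s,
                                            ari = ev$ari, nmi = ev$nmi)
    }
  }
  do.call(rbind, res)
}
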