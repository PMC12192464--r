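#' Build a fuzzy-fusion configuration
#'
#' @param theta membership thresholds in [0, 1], one per measure (scalar
#'   recycled), named by measure or in the order BCorrU, BCorrD, COH1, PDC.
#' @param slope membership slopes (> 0), recycled likewise.
#' @param weight nonnegative fusion weights; normalized to sum to 1.
#' @param decisionThreshold optional binarization cutoff in [0, 1].
#' @return a \linkS4class{FusionConfig}.
#' @export
fusionConfig <- function(theta = 0.5, slope = 10, weight = 1,
                         decisionThreshold = 0.5) {
  expand <- function(v) {
    if (is.null(names(v))) v <- stats::setNames(rep_len(v, 4L), .MEASURES)
    v[.MEASURES]
  }
  w <- expand(weight)
  new("FusionConfig", theta = expand(theta), slope = expand(slope),
      weight = w / sum(w), decisionThreshold = decisionThreshold)
}

#' Default fusion configuration
#'
#' Equal weights, midpoint thresholds and moderate slopes; a neutral
#' starting point before GA tuning.
#' @return a \linkS4class{FusionConfig}.
#' @export
defaultFusionConfig <- function() fusionConfig()

#' Fuse the four measure matrices into one directed FC matrix
#'
#' Fuzzy synthesis: each measure value passes through a logistic
#' membership sigma(k_m (value - theta_m)) and the memberships are
#' combined by the convex weights, fused(i, j) =
#' sum_m alpha_m sigma(k_m (m(i, j) - theta_m)). Undirected measures
#' (BCorrU, COH1) contribute the same value to both directions. Entries
#' are clipped to [0, 1] and the diagonal zeroed.
#'
#' @param measures named list with elements BCorrU, BCorrD, COH1, PDC
#'   (\linkS4class{MeasureMatrix} or plain matrices), same dimensions.
#' @param config a \linkS4class{FusionConfig}.
#' @return a \linkS4class{FusedFC}.
#' @export
fuseMeasures <- function(measures, config = defaultFusionConfig()) {
  miss <- setdiff(.MEASURES, names(measures))
  if (length(miss)) stop("missing measure(s): ", paste(miss, collapse = ", "))
  vals <- lapply(measures[.MEASURES], function(m)
    if (is(m, "MeasureMatrix")) m@values else m)
  dims <- vapply(vals, dim, integer(2))
  if (any(dims != dims[, 1L])) stop("measure matrices differ in shape")
  fused <- 0
  for (m in .MEASURES)
    fused <- fused + config@weight[[m]] *
      logistic(config@slope[[m]] * (vals[[m]] - config@theta[[m]]))
  fused <- zero_diag(pmin(pmax(fused, 0), 1))
  dimnames(fused) <- dimnames(vals[[1L]])
  new("FusedFC", values = fused, config = config)
}

# Decode a real genome of length 12 into a FusionConfig.
decode_genome <- function(g) {
  theta <- pmin(pmax(g[1:4], 0), 1)
  slope <- pmin(pmax(g[5:8], 0.5), 30)
  w <- pmin(pmax(g[9:12], 0), 1)
  if (sum(w) < 1e-12) w <- rep(1, 4)
  fusionConfig(theta = stats::setNames(theta, .MEASURES),
               slope = stats::setNames(slope, .MEASURES),
               weight = stats::setNames(w, .MEASURES))
}

# Mean edge-detection AUC of a genome across training networks.
fitness_of <- function(genome, measuresList, truths) {
  cfg <- decode_genome(genome)
  mean(vapply(seq_along(measuresList), function(i)
    edgeAUC(fuseMeasures(measuresList[[i]], cfg), truths[[i]]), 0))
}

#' Genetic-algorithm tuning of fusion parameters
#'
#' Evolves the membership thresholds, slopes and fusion weights to
#' maximize the mean edge-recovery AUC of the fused matrix against the
#' ground-truth adjacencies of a set of training networks whose measure
#' matrices were computed beforehand. Tournament selection, uniform
#' crossover, Gaussian mutation, one elite (so the running best fitness
#' is non-decreasing). If the population degenerates to identical
#' genomes the run stops early with a warning.
#'
#' @param measuresList list (one element per training network) of
#'   four-measure lists as returned by \code{\link{measureSuite}}.
#' @param truths list of \linkS4class{GroundTruthNetwork} (or adjacency
#'   matrices), parallel to \code{measuresList}.
#' @param popSize population size (>= 10).
#' @param generations number of generations.
#' @param mutationRate per-gene mutation probability.
#' @param mutationSd Gaussian mutation standard deviation.
#' @param crossoverRate probability a child is produced by uniform
#'   crossover of two parents (otherwise cloned).
#' @param tournamentSize tournament size for parent selection.
#' @param seed integer seed; the run is deterministic given the seed.
#' @return list with \code{config} (best \linkS4class{FusionConfig}),
#'   \code{fitness} (its training AUC) and \code{trace} (per-generation
#'   best/mean fitness).
#' @export
gaOptimize <- function(measuresList, truths, popSize = 50L, generations = 40L,
                       mutationRate = 0.2, mutationSd = 0.1,
                       crossoverRate = 0.7, tournamentSize = 3L, seed = 1L) {
  stopifnot(popSize >= 10, length(measuresList) == length(truths),
            length(measuresList) >= 1)
  nGenes <- 12L
  with_seed(seed, {
    pop <- lapply(seq_len(popSize), function(i)
      c(stats::runif(4), stats::runif(4, 1, 20), stats::runif(4)))
    fit <- vapply(pop, fitness_of, 0, measuresList, truths)
    trace <- data.frame(generation = integer(0), best = numeric(0),
                        mean = numeric(0))
    for (gen in seq_len(generations)) {
      elite_i <- which.max(fit)
      newpop <- list(pop[[elite_i]])
      while (length(newpop) < popSize) {
        pick <- function() {
          cand <- sample.int(popSize, tournamentSize)
          pop[[cand[which.max(fit[cand])]]]
        }
        child <- pick()
        if (stats::runif(1) < crossoverRate) {
          other <- pick()
          mask <- stats::runif(nGenes) < 0.5
          child[mask] <- other[mask]
        }
        mut <- stats::runif(nGenes) < mutationRate
        child[mut] <- child[mut] + stats::rnorm(sum(mut), sd = mutationSd)
        newpop[[length(newpop) + 1L]] <- child
      }
      pop <- newpop
      fit <- vapply(pop, fitness_of, 0, measuresList, truths)
      trace <- rbind(trace, data.frame(generation = gen, best = max(fit),
                                       mean = mean(fit)))
      if (all(vapply(pop, identical, TRUE, pop[[1L]]))) {
        warning("population degenerated to identical genomes; stopping early")
        break
      }
    }
    best <- which.max(fit)
    list(config = decode_genome(pop[[best]]), fitness = fit[best],
         trace = trace)
  })
}

#' End-to-end fusion tuning on simulated networks
#'
#' Draws training (and optionally held-out) ground-truth networks,
#' simulates a stationary recording from each, computes the four measure
#' matrices, and runs the genetic algorithm. Held-out networks are used
#' only for evaluation, never for tuning.
#'
#' @param nTrain,nHeldout numbers of training / held-out networks.
#' @param nNodes,density,weightRange network parameters
#'   (see \code{\link{makeNetwork}}).
#' @param duration_s simulated duration per network in seconds.
#' @param fs sampling rate in Hz.
#' @param order generator MVAR order.
#' @param band,nFreqs,fitOrder,maxOrder,maxLag measure parameters
#'   (see \code{\link{measureSuite}}).
#' @param seed master seed; network, simulation and GA seeds are derived
#'   from it.
#' @param ... GA hyperparameters passed to \code{\link{gaOptimize}}.
#' @return list: \code{config}, \code{trace}, \code{trainAUC},
#'   \code{heldoutAUC} (NA if no held-out networks), and
#'   \code{singleMeasureAUC} (held-out mean AUC per individual measure).
#' @export
tuneFusionGA <- function(nTrain = 5L, nHeldout = 0L, nNodes = 30L,
                         density = 0.2, weightRange = c(0.3, 0.8),
                         duration_s = 10, fs = 1000, order = 1L,
                         band = c(1, 45), nFreqs = 64, fitOrder = "auto",
                         maxOrder = 5L, maxLag = NULL, seed = 1L, ...) {
  total <- nTrain + nHeldout
  nets <- lapply(seq_len(total), function(i)
    makeNetwork(nNodes, density, weightRange, seed = seed + 17L * i))
  suites <- lapply(seq_len(total), function(i) {
    rec <- simulateFromNetwork(nets[[i]], duration_s, fs = fs, order = order,
                               seed = seed + 31L * i)
    measureSuite(rec, band = band, nFreqs = nFreqs, order = fitOrder,
                 maxOrder = maxOrder, maxLag = maxLag)
  })
  ga <- gaOptimize(suites[seq_len(nTrain)], nets[seq_len(nTrain)],
                   seed = seed, ...)
  heldout <- if (nHeldout > 0) (nTrain + 1):total else integer(0)
  heldAUC <- NA_real_
  singles <- stats::setNames(rep(NA_real_, 4L), .MEASURES)
  if (length(heldout)) {
    heldAUC <- mean(vapply(heldout, function(i)
      edgeAUC(fuseMeasures(suites[[i]], ga$config), nets[[i]]), 0))
    for (m in .MEASURES)
      singles[m] <- mean(vapply(heldout, function(i)
        edgeAUC(suites[[i]][[m]], nets[[i]]), 0))
  }
  list(config = ga$config, trace = ga$trace, trainAUC = ga$fitness,
       heldoutAUC = heldAUC, singleMeasureAUC = singles)
}
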