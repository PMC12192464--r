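#' Construct a ground-truth network from an explicit adjacency
#'
#' Direct constructor for \linkS4class{GroundTruthNetwork}, including the
#' degenerate zero-coupling network used for null checks. For random
#' networks use \code{\link{makeNetwork}}.
#'
#' @param adjacency square nonnegative matrix with zero diagonal; entry
#'   (i, j) is the coupling i -> j.
#' @param seed integer recorded for provenance (NA if not applicable).
#' @return a \linkS4class{GroundTruthNetwork}.
#' @export
groundTruthNetwork <- function(adjacency, seed = NA_integer_) {
  n <- nrow(adjacency)
  new("GroundTruthNetwork", adjacency = adjacency,
      density = sum(adjacency > 0) / (n * (n - 1)), seed = as.integer(seed))
}

#' Draw a random directed weighted ground-truth network
#'
#' Samples exactly \code{round(density * n * (n - 1))} directed off-diagonal
#' edges uniformly at random and assigns each a weight drawn uniformly from
#' \code{weightRange}. Reproducible under a fixed seed.
#'
#' @param nNodes number of nodes (>= 2). Default 30, the scale the fusion
#'   parameters are tuned at.
#' @param density fraction of possible off-diagonal directed edges present,
#'   in (0, 1].
#' @param weightRange interval the edge couplings are drawn from.
#' @param seed integer seed.
#' @return a \linkS4class{GroundTruthNetwork}.
#' @examples
#' net <- makeNetwork(30, density = 0.2, seed = 1)
#' sum(adjacencyMatrix(net) > 0)  # 174 edges
#' @export
makeNetwork <- function(nNodes = 30, density = 0.2, weightRange = c(0.3, 0.8),
                        seed = 1L) {
  stopifnot(nNodes >= 2, density > 0, density <= 1)
  nEdges <- round(density * nNodes * (nNodes - 1))
  if (nEdges < 1)
    stop("density ", density, " yields zero edges on ", nNodes, " nodes")
  with_seed(seed, {
    off <- which(row(diag(nNodes)) != col(diag(nNodes)))
    pick <- sample(off, nEdges)
    a <- matrix(0, nNodes, nNodes)
    a[pick] <- stats::runif(nEdges, weightRange[1], weightRange[2])
    new("GroundTruthNetwork", adjacency = a, density = density,
        seed = as.integer(seed))
  })
}

#' MVAR coefficients implied by a ground-truth network
#'
#' Maps the adjacency onto autoregressive coefficient matrices: the edge
#' weight of i -> j enters the regression matrices as coefficient
#' (target j, source i), split evenly across the requested lags, plus a
#' self-decay of 0.5 on the diagonal at lag 1. Coefficient (k, i, j) is
#' nonzero only where the adjacency has an edge or i = j.
#'
#' @param net a \linkS4class{GroundTruthNetwork}.
#' @param order number of lags p.
#' @param selfDecay lag-1 diagonal autoregression coefficient.
#' @return list of p coefficient matrices (regression convention:
#'   entry (i, j) is the influence of channel j on channel i).
#' @export
mvarCoefficients <- function(net, order = 1L, selfDecay = 0.5) {
  stopifnot(order >= 1)
  cross <- t(net@adjacency) / order
  coeffs <- lapply(seq_len(order), function(k) cross)
  diag(coeffs[[1L]]) <- diag(coeffs[[1L]]) + selfDecay
  coeffs
}

# Uniformly shrink a coefficient list until the companion spectral radius
# is at or below `target`.
stabilize_coeffs <- function(coeffs, target = 0.95, maxIter = 200L) {
  for (iter in seq_len(maxIter)) {
    r <- companion_radius(coeffs)
    if (r <= target) return(coeffs)
    coeffs <- lapply(coeffs, function(A) A * min(0.95, target / r))
  }
  stop("coefficients could not be stabilized within ", maxIter, " shrink steps")
}

# 1/f-shaped observation noise (per channel, unit variance before scaling).
pink_noise <- function(nChannels, nSamples) {
  out <- matrix(0, nChannels, nSamples)
  f <- c(1, seq_len(nSamples - 1))
  scale <- 1 / sqrt(pmin(f, nSamples - f + 1))
  for (i in seq_len(nChannels)) {
    spec <- stats::fft(stats::rnorm(nSamples)) * scale
    x <- Re(stats::fft(spec, inverse = TRUE)) / nSamples
    out[i, ] <- x / stats::sd(x)
  }
  out
}

#' Simulate a stationary recording from one ground-truth network
#'
#' Generates a stable MVAR time series whose coefficient structure follows
#' the network (see \code{\link{mvarCoefficients}}), with unit-diagonal
#' innovation covariance scaled by \code{noiseScale^2} and a burn-in
#' discarded so only the stationary regime is returned.
#'
#' @param net a \linkS4class{GroundTruthNetwork}.
#' @param duration_s recording length in seconds.
#' @param fs sampling rate in Hz (default 1000, SEEG-like).
#' @param order MVAR order of the generator.
#' @param noiseScale innovation standard deviation.
#' @param seed integer seed (bitwise-reproducible output).
#' @param burnIn samples discarded to remove transients.
#' @param obsNoise1f standard deviation of optional additive 1/f-shaped
#'   observation noise (0 = off, the default).
#' @return a \linkS4class{Recording}.
#' @export
simulateFromNetwork <- function(net, duration_s, fs = 1000, order = 1L,
                                noiseScale = 1, seed = 1L, burnIn = 1000L,
                                obsNoise1f = 0) {
  n <- nrow(net@adjacency)
  nKeep <- round(duration_s * fs)
  coeffs <- stabilize_coeffs(mvarCoefficients(net, order))
  with_seed(seed, {
    innov <- matrix(stats::rnorm(n * (burnIn + nKeep), sd = noiseScale),
                    nrow = n)
    x <- var_recurse(coeffs, innov, as.integer(burnIn))
    if (obsNoise1f > 0) x <- x + obsNoise1f * pink_noise(n, nKeep)
    new("Recording", data = x, fs = fs,
        channelLabels = sprintf("ch%02d", seq_len(n)))
  })
}

#' Simulate a multi-task session from known networks
#'
#' Concatenates task blocks, each generated by the stable MVAR dynamics of
#' that task's ground-truth network, and records the block plan as task
#' annotations (half-open intervals in seconds, 0-based). Per-block seeds
#' are derived deterministically from \code{seed}.
#'
#' @param truthNetworks named list of \linkS4class{GroundTruthNetwork},
#'   one per task label; all must share the node count.
#' @param blockPlan data.frame with columns \code{task} and
#'   \code{duration_s}, in presentation order.
#' @param fs sampling rate in Hz.
#' @param order MVAR order of the generators.
#' @param noiseScale innovation standard deviation.
#' @param seed integer master seed.
#' @param burnIn per-block burn-in samples (discarded).
#' @param obsNoise1f optional 1/f observation-noise sd (0 = off).
#' @return a \linkS4class{TaskSession}.
#' @examples
#' nets <- list(A = makeNetwork(5, 0.3, seed = 1),
#'              B = makeNetwork(5, 0.3, seed = 2))
#' plan <- data.frame(task = c("A", "B"), duration_s = c(20, 20))
#' ses <- simulateSession(nets, plan, fs = 250, seed = 7)
#' @export
simulateSession <- function(truthNetworks, blockPlan, fs = 1000, order = 1L,
                            noiseScale = 1, seed = 1L, burnIn = 1000L,
                            obsNoise1f = 0) {
  stopifnot(is.data.frame(blockPlan),
            all(c("task", "duration_s") %in% names(blockPlan)),
            all(blockPlan$duration_s >= 1))
  if (!all(blockPlan$task %in% names(truthNetworks)))
    stop("every task in the block plan needs a truth network")
  sizes <- vapply(truthNetworks, function(x) nrow(x@adjacency), 0L)
  if (length(unique(sizes)) != 1L)
    stop("all truth networks must share the node count")
  blocks <- vector("list", nrow(blockPlan))
  for (b in seq_len(nrow(blockPlan))) {
    net <- truthNetworks[[blockPlan$task[b]]]
    rec <- tryCatch(
      simulateFromNetwork(net, blockPlan$duration_s[b], fs = fs, order = order,
                          noiseScale = noiseScale, seed = seed + 1000L * b,
                          burnIn = burnIn, obsNoise1f = obsNoise1f),
      error = function(e) stop("block ", b, " (task ", blockPlan$task[b],
                               "): ", conditionMessage(e)))
    blocks[[b]] <- rec@data
  }
  ends <- cumsum(blockPlan$duration_s)
  ann <- data.frame(start_s = c(0, ends[-length(ends)]), end_s = ends,
                    task = blockPlan$task, stringsAsFactors = FALSE)
  rec <- new("Recording", data = do.call(cbind, blocks), fs = fs,
             channelLabels = sprintf("ch%02d", seq_len(sizes[1L])))
  new("TaskSession", recording = rec, annotations = ann,
      truthNetworks = truthNetworks)
}
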