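#' Window-by-feature matrix of vectorized FC
#'
#' One row per window, columns the off-diagonal FC entries in fixed
#' (column-major) order; the representation used by clustering,
#' embedding and classification.
#'
#' @param wfc a \linkS4class{WindowedFC}.
#' @param includeMixed keep windows labelled "mixed"?
#' @return numeric matrix with attributes \code{task} (labels) and
#'   \code{windows} (the retained window metadata).
#' @export
fcFeatureMatrix <- function(wfc, includeMixed = FALSE) {
  keep <- if (includeMixed) rep(TRUE, nrow(wfc@windows)) else wfc@windows$task != "mixed"
  mats <- wfc@matrices[keep]
  X <- t(vapply(mats, offdiag, numeric(length(offdiag(mats[[1L]])))))
  attr(X, "task") <- wfc@windows$task[keep]
  attr(X, "windows") <- wfc@windows[keep, , drop = FALSE]
  X
}

# Spectral clustering: Gaussian affinity (median-distance kernel width),
# symmetric normalized Laplacian, k-means on the leading eigenvectors.
spectral_cluster <- function(X, k, seed) {
  D <- as.matrix(stats::dist(X))
  sigma <- stats::median(D[upper.tri(D)][D[upper.tri(D)] > 0])
  if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  A <- exp(-D^2 / (2 * sigma^2))
  diag(A) <- 0
  d <- pmax(rowSums(A), 1e-12)
  L <- diag(nrow(A)) - t(A / sqrt(d)) / sqrt(d)  # I - D^-1/2 A D^-1/2
  ev <- eigen((L + t(L)) / 2, symmetric = TRUE)
  U <- ev$vectors[, (ncol(ev$vectors) - k + 1):ncol(ev$vectors), drop = FALSE]
  rn <- sqrt(rowSums(U^2)); rn[rn < 1e-12] <- 1
  U <- U / rn
  with_seed(seed, stats::kmeans(U, centers = k, nstart = 10)$cluster)
}

# BIRCH-style clustering: sequential clustering-feature (CF) absorption
# under a radius threshold, then Ward agglomeration of CF centroids to k
# clusters. The threshold is relaxed from a distance quantile until at
# least k subclusters survive.
birch_cluster <- function(X, k, seed) {
  D <- stats::dist(X)
  for (q in c(0.25, 0.1, 0.05, 0.01, 0)) {
    thr <- if (q > 0) stats::quantile(D, q) else -1
    nCF <- 0L
    cfN <- integer(0); cfLS <- list(); cfSS <- numeric(0)
    assign_cf <- integer(nrow(X))
    for (i in seq_len(nrow(X))) {
      xi <- X[i, ]
      best <- 0L; bestd <- Inf
      if (nCF > 0L) {
        for (c in seq_len(nCF)) {
          d <- sqrt(sum((cfLS[[c]] / cfN[c] - xi)^2))
          if (d < bestd) { bestd <- d; best <- c }
        }
      }
      absorbed <- FALSE
      if (best > 0L) {
        n1 <- cfN[best] + 1L
        ls1 <- cfLS[[best]] + xi
        ss1 <- cfSS[best] + sum(xi^2)
        rad <- sqrt(max(ss1 / n1 - sum((ls1 / n1)^2), 0))
        if (rad <= thr) {
          cfN[best] <- n1; cfLS[[best]] <- ls1; cfSS[best] <- ss1
          assign_cf[i] <- best
          absorbed <- TRUE
        }
      }
      if (!absorbed) {
        nCF <- nCF + 1L
        cfN[nCF] <- 1L; cfLS[[nCF]] <- xi; cfSS[nCF] <- sum(xi^2)
        assign_cf[i] <- nCF
      }
    }
    if (nCF >= k) {
      centroids <- t(vapply(seq_len(nCF), function(c) cfLS[[c]] / cfN[c],
                            numeric(ncol(X))))
      if (nCF == k) return(assign_cf)
      hc <- stats::hclust(stats::dist(centroids), method = "ward.D2")
      sub2cl <- stats::cutree(hc, k = k)
      return(sub2cl[assign_cf])
    }
  }
  stop("could not form ", k, " subclusters")
}

#' Cluster sliding-window FC into task states
#'
#' Unsupervised grouping of the window-wise FC patterns by spectral
#' clustering or BIRCH. Mixed-label windows are excluded by default so
#' cluster labels can be compared against the true task labels.
#'
#' @param wfc a \linkS4class{WindowedFC}.
#' @param k number of clusters (>= 2, <= number of windows).
#' @param algorithm "spectral" or "birch".
#' @param seed integer seed (k-means restarts).
#' @param includeMixed keep "mixed" windows?
#' @return data.frame with start_s, end_s, task (truth) and cluster.
#' @export
clusterWindows <- function(wfc, k, algorithm = c("spectral", "birch"),
                           seed = 1L, includeMixed = FALSE) {
  algorithm <- match.arg(algorithm)
  X <- fcFeatureMatrix(wfc, includeMixed = includeMixed)
  stopifnot(k >= 2)
  if (k > nrow(X)) stop("k exceeds the number of windows")
  cl <- switch(algorithm,
               spectral = spectral_cluster(X, k, seed),
               birch = birch_cluster(X, k, seed))
  out <- attr(X, "windows")
  out$cluster <- as.integer(cl)
  out
}

#' 2-D t-SNE embedding of window-wise FC
#'
#' Exact t-distributed stochastic neighbor embedding of the vectorized FC
#' patterns: per-point Gaussian bandwidths calibrated to the target
#' perplexity by bisection, symmetrized affinities, early exaggeration,
#' and momentum gradient descent. Deterministic under a fixed seed.
#'
#' @param wfc a \linkS4class{WindowedFC} (or plain feature matrix).
#' @param perplexity target perplexity; requires
#'   \code{windows > 3 * perplexity}.
#' @param seed integer seed for the initial layout.
#' @param maxIter gradient-descent iterations.
#' @param includeMixed keep "mixed" windows (WindowedFC input)?
#' @return data.frame with columns dim1, dim2 and (when available) task.
#' @export
embedTSNE <- function(wfc, perplexity = 10, seed = 1L, maxIter = 400L,
                      includeMixed = FALSE) {
  X <- if (is(wfc, "WindowedFC")) fcFeatureMatrix(wfc, includeMixed) else as.matrix(wfc)
  W <- nrow(X)
  if (W <= 3 * perplexity)
    stop("perplexity too large: need windows > 3 * perplexity")
  D2 <- as.matrix(stats::dist(X))^2
  P <- matrix(0, W, W)
  logU <- log(perplexity)
  for (i in seq_len(W)) {
    di <- D2[i, -i]
    beta <- 1
    lo <- -Inf; hi <- Inf
    for (iter in 1:50) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp < 1e-300) { H <- 0; p <- rep(1 / length(di), length(di)) }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * W)
  P <- pmax(P, 1e-12)
  with_seed(seed, {
    Y <- matrix(stats::rnorm(W * 2, sd = 1e-4), W, 2)
    dY <- matrix(0, W, 2)
    gains <- matrix(1, W, 2)
    for (iter in seq_len(maxIter)) {
      mult <- if (iter <= 100) 4 else 1   # early exaggeration
      momentum <- if (iter <= 250) 0.5 else 0.8
      num <- 1 / (1 + as.matrix(stats::dist(Y))^2)
      diag(num) <- 0
      Q <- pmax(num / sum(num), 1e-12)
      PQ <- (mult * P - Q) * num
      grad <- 4 * (diag(rowSums(PQ)) - PQ) %*% Y
      gains <- ifelse(sign(grad) != sign(dY), gains + 0.2, gains * 0.8)
      gains[gains < 0.01] <- 0.01
      dY <- momentum * dY - 25 * gains * grad   # learning rate sized for small W
      Y <- Y + dY
      Y <- sweep(Y, 2L, colMeans(Y))
    }
    out <- data.frame(dim1 = Y[, 1L], dim2 = Y[, 2L])
    tk <- attr(X, "task")
    if (!is.null(tk)) out$task <- tk
    out
  })
}
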