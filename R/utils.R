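# Internal helpers shared across modules.

# Evaluate code under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

logistic <- function(x) 1 / (1 + exp(-x))

# Off-diagonal entries in fixed (column-major) order.
offdiag <- function(m) m[row(m) != col(m)]

zero_diag <- function(m) { diag(m) <- 0; m }

# Rank-based AUC of scores for a binary ground truth (ties -> mid-ranks).
auc_score <- function(scores, truth) {
  truth <- as.logical(truth)
  npos <- sum(truth); nneg <- sum(!truth)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores)
  (sum(r[truth]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Edge-recovery AUC of a connectivity estimate
#'
#' Threshold-free recovery score: AUC of the off-diagonal connectivity
#' scores against the presence/absence of the corresponding directed
#' edges in a ground-truth network.
#'
#' @param fc a \linkS4class{FusedFC}, \linkS4class{MeasureMatrix} or
#'   numeric matrix (source row -> target column).
#' @param truth a \linkS4class{GroundTruthNetwork} or adjacency matrix.
#' @return AUC in [0, 1] (NA if the truth has no edges or no non-edges).
#' @export
edgeAUC <- function(fc, truth) {
  v <- if (is(fc, "FusedFC") || is(fc, "MeasureMatrix")) fc@values else fc
  a <- if (is(truth, "GroundTruthNetwork")) truth@adjacency else truth
  stopifnot(all(dim(v) == dim(a)))
  auc_score(offdiag(v), offdiag(a) > 0)
}

# Per-channel linear detrend + z-score; zero-variance channels are left
# as all-zero rows (callers warn where the spec requires it).
detrend_zscore <- function(x) {
  n <- ncol(x)
  tt <- seq_len(n) - (n + 1) / 2
  stt <- sum(tt^2)
  out <- x - rowMeans(x)
  slope <- (out %*% tt) / stt
  out <- out - tcrossprod(slope, tt)
  sds <- sqrt(rowSums(out^2) / (n - 1))
  flat <- sds < 1e-12
  sds[flat] <- 1
  out <- out / sds
  out[flat, ] <- 0
  attr(out, "flat") <- which(flat)
  attr(out, "scales") <- sds
  out
}

# Spectral radius of the companion matrix of MVAR coefficient list.
companion_radius <- function(coeffs) {
  p <- length(coeffs)
  n <- nrow(coeffs[[1L]])
  comp <- matrix(0, n * p, n * p)
  for (k in seq_len(p)) comp[1:n, ((k - 1) * n + 1):(k * n)] <- coeffs[[k]]
  if (p > 1L)
    comp[(n + 1):(n * p), 1:(n * (p - 1))] <- diag(n * (p - 1))
  max(Mod(eigen(comp, only.values = TRUE)$values))
}
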