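#' Pair-counting confusion over all window pairs
#'
#' For every unordered pair of windows, counts: TP pairs co-clustered in
#' both labelings; FP pairs co-clustered in the reference T but not in
#' the prediction Y; FN pairs co-clustered in Y but not in T; TN pairs
#' separated in both. TP + FP + FN + TN = W(W-1)/2.
#'
#' @param Y predicted labels.
#' @param T_ true labels (same length).
#' @return list with TP, FP, FN, TN.
#' @export
pairCounts <- function(Y, T_) {
  if (length(Y) != length(T_)) stop("label vectors differ in length")
  sameY <- outer(Y, Y, "==")
  sameT <- outer(T_, T_, "==")
  ut <- upper.tri(sameY)
  list(TP = sum(sameY[ut] & sameT[ut]),
       FP = sum(!sameY[ut] & sameT[ut]),
       FN = sum(sameY[ut] & !sameT[ut]),
       TN = sum(!sameY[ut] & !sameT[ut]))
}

entropy_of <- function(x) {
  p <- table(x) / length(x)
  -sum(p[p > 0] * log(p[p > 0]))
}

# Normalized mutual information, 2 I(Y,T) / (H(Y) + H(T)). When both
# partitions are single-class the labelings are identical partitions ->
# 1; a single-class partition against a multi-class one -> 0.
nmi_of <- function(Y, T_) {
  hy <- entropy_of(Y); ht <- entropy_of(T_)
  if (hy + ht == 0) return(1)
  if (hy == 0 || ht == 0) return(0)
  tab <- table(Y, T_)
  n <- length(Y)
  mi <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
    nij <- tab[i, j]
    if (nij > 0)
      mi <- mi + nij / n * log(nij * n / (sum(tab[i, ]) * sum(tab[, j])))
  }
  2 * mi / (hy + ht)
}

# Adjusted Rand index from the contingency table (expected-index
# correction of the Rand index).
ari_of <- function(Y, T_) {
  tab <- table(Y, T_)
  n <- length(Y)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  sa <- sum(ch2(rowSums(tab)))
  sb <- sum(ch2(colSums(tab)))
  expected <- sa * sb / ch2(n)
  maxidx <- (sa + sb) / 2
  if (abs(maxidx - expected) < 1e-300) return(1)
  (sij - expected) / (maxidx - expected)
}

# Optimal one-to-one matching of predicted clusters to reference classes
# (maximizes matched count); exhaustive over permutations, fine for the
# handful of task states considered (k <= 8).
match_clusters <- function(Y, T_) {
  uy <- sort(unique(Y)); ut <- sort(unique(T_))
  k <- max(length(uy), length(ut))
  if (k > 8L) stop("cluster matching supports up to 8 classes")
  tab <- matrix(0, k, k)   # rows: T classes, cols: Y clusters (padded)
  for (i in seq_along(T_)) {
    r <- match(T_[i], ut); c <- match(Y[i], uy)
    tab[r, c] <- tab[r, c] + 1
  }
  perms <- perms_of(k)
  best <- perms[[which.max(vapply(perms, function(p)
    sum(tab[cbind(seq_len(k), p)]), 0))]]
  # rows: true classes; columns: all Y clusters, reordered so column i is
  # the cluster matched to class i (row sums = class counts).
  conf <- tab[seq_along(ut), best, drop = FALSE]
  list(confusion = conf, classes = ut)
}

perms_of <- function(k) {
  if (k == 1L) return(list(1L))
  sub <- perms_of(k - 1L)
  out <- list()
  for (p in sub) for (pos in seq_len(k)) out[[length(out) + 1L]] <- append(p, k, after = pos - 1L)
  out
}

#' Clustering / labeling agreement metrics
#'
#' The pair-counting and information-theoretic agreement metrics between
#' a predicted and a true labeling: normalized mutual information
#' (2 I / (H(Y) + H(T))), Fowlkes-Mallows (TP / sqrt((TP+FP)(TP+FN))),
#' Rand index ((TP+TN) / all pairs), adjusted Rand, plus confusion-based
#' metrics after optimal one-to-one cluster-to-class matching: matched
#' accuracy, balanced accuracy (macro-averaged recall) and per-class
#' precision. Pair-counting metrics are invariant to label permutation.
#'
#' @param Y predicted labels.
#' @param T_ true labels.
#' @return list with MI, FM, RI, AR, accuracy, BAS, precision (named per
#'   class) and the matched confusion matrix (rows: true classes).
#' @export
clusteringMetrics <- function(Y, T_) {
  pc <- pairCounts(Y, T_)
  denom <- sqrt((pc$TP + pc$FP) * (pc$TP + pc$FN))
  fm <- if (denom == 0) 0 else pc$TP / denom
  total <- pc$TP + pc$FP + pc$FN + pc$TN
  ri <- (pc$TP + pc$TN) / total
  m <- match_clusters(Y, T_)
  conf <- m$confusion
  nc <- nrow(conf)
  matched <- conf[cbind(seq_len(nc), seq_len(nc))]
  acc <- sum(matched) / length(Y)
  recalls <- matched / pmax(rowSums(conf), 1)
  prec <- matched / pmax(colSums(conf)[seq_len(nc)], 1)
  names(prec) <- m$classes
  list(MI = nmi_of(Y, T_), FM = fm, RI = ri, AR = ari_of(Y, T_),
       accuracy = acc, BAS = mean(recalls), precision = prec,
       confusion = conf)
}
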