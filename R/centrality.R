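#' Map channel-level FC to a region-level network
#'
#' For each ordered pair of regions, keeps the maximum FC weight among
#' all directed channel links between them; within-region links are
#' discarded (zero diagonal). Adding a duplicate of a channel to its
#' region never changes the result (max aggregation is idempotent).
#'
#' @param fc a \linkS4class{FusedFC}, \linkS4class{MeasureMatrix} or
#'   labelled numeric matrix (source row -> target column).
#' @param atlas data.frame mapping channels to regions: columns
#'   \code{channel}, \code{region} (optional \code{hemisphere} is kept as
#'   annotation only). Every FC channel must be mapped.
#' @return a \linkS4class{RegionGraph} (regions in first-appearance
#'   order of the atlas).
#' @export
toRegionGraph <- function(fc, atlas) {
  v <- if (is(fc, "FusedFC") || is(fc, "MeasureMatrix")) fc@values else fc
  labels <- rownames(v)
  if (is.null(labels)) stop("FC matrix must carry channel labels")
  unmapped <- setdiff(labels, atlas$channel)
  if (length(unmapped))
    stop("unmapped channel(s): ", paste(unmapped, collapse = ", "))
  regions <- unique(atlas$region[match(labels, atlas$channel)])
  regOf <- atlas$region[match(labels, atlas$channel)]
  R <- length(regions)
  out <- matrix(0, R, R, dimnames = list(regions, regions))
  for (a in seq_len(R)) for (b in seq_len(R)) {
    if (a == b) next
    out[a, b] <- max(v[regOf == regions[a], regOf == regions[b]])
  }
  new("RegionGraph", values = out, regions = regions)
}

as_region_matrix <- function(g) {
  if (is(g, "RegionGraph")) g@values else as.matrix(g)
}

# Directed shortest-path distance matrix with lengths = 1 / weight
# (stronger link = shorter path); D[u, v] = distance u -> v.
sp_distances <- function(m) {
  ig <- igraph::graph_from_adjacency_matrix(m, mode = "directed",
                                            weighted = TRUE, diag = FALSE)
  w <- 1 / igraph::E(ig)$weight
  igraph::distances(ig, mode = "out", weights = w)
}

#' Weighted degree centrality
#'
#' Weighted in- and out-strength normalized by the maximum possible
#' (R - 1 links of weight 1): in_degree(v) = sum_u g(u, v) / (R - 1),
#' out_degree(v) = sum_u g(v, u) / (R - 1).
#'
#' @param g a \linkS4class{RegionGraph} or weighted adjacency matrix
#'   with entries in [0, 1].
#' @return data.frame with region, in_degree, out_degree.
#' @export
degreeCentrality <- function(g) {
  m <- as_region_matrix(g)
  R <- nrow(m)
  stopifnot(R >= 2)
  data.frame(region = if (is.null(rownames(m))) as.character(seq_len(R)) else rownames(m),
             in_degree = colSums(m) / (R - 1),
             out_degree = rowSums(m) / (R - 1),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Closeness centrality (directed, weighted)
#'
#' Shortest-path closeness with link lengths 1 / weight. For node v with
#' r reachable counterparts at total distance sum_d, closeness =
#' r / sum_d (the (n-1)/sum_d form scaled by the reachable fraction
#' r/(n-1), so disconnected graphs stay in [0, 1]); a node with no
#' reachable counterpart gets 0. Direction "in" uses paths into v,
#' "out" paths out of v.
#'
#' @param g a \linkS4class{RegionGraph} or weighted adjacency matrix.
#' @param direction "in" or "out".
#' @return named numeric vector of closeness values.
#' @export
closenessCentrality <- function(g, direction = c("in", "out")) {
  direction <- match.arg(direction)
  m <- as_region_matrix(g)
  D <- sp_distances(m)          # D[u, v] = u -> v
  if (direction == "out") D <- t(D)   # now D[u, v] = distance relevant to v = column
  cc <- vapply(seq_len(ncol(D)), function(v) {
    d <- D[-v, v]
    d <- d[is.finite(d)]
    if (!length(d)) 0 else length(d) / sum(d)
  }, 0)
  stats::setNames(cc, rownames(m))
}

#' Betweenness centrality (directed, weighted)
#'
#' Sum over source-target pairs of the fraction of shortest paths (link
#' lengths 1 / weight) passing through the node, normalized by
#' (n - 1)(n - 2).
#'
#' @param g a \linkS4class{RegionGraph} or weighted adjacency matrix.
#' @param normalized divide by (n - 1)(n - 2)?
#' @return named numeric vector.
#' @export
betweennessCentrality <- function(g, normalized = TRUE) {
  m <- as_region_matrix(g)
  n <- nrow(m)
  ig <- igraph::graph_from_adjacency_matrix(m, mode = "directed",
                                            weighted = TRUE, diag = FALSE)
  b <- igraph::betweenness(ig, directed = TRUE,
                           weights = 1 / igraph::E(ig)$weight)
  if (normalized && n > 2) b <- b / ((n - 1) * (n - 2))
  stats::setNames(as.numeric(b), rownames(m))
}

#' Katz centrality (directed, weighted)
#'
#' Solves x = alpha A' x + beta 1 (A' oriented by direction: incoming
#' edges for "in", outgoing for "out") with alpha = alphaFrac / lambda_max
#' for convergence, then rescales the vector to maximum 1. An empty graph
#' gives all-equal values (pure beta).
#'
#' @param g a \linkS4class{RegionGraph} or weighted adjacency matrix.
#' @param direction "in" or "out".
#' @param alphaFrac attenuation as a fraction of 1 / lambda_max (< 1).
#' @param beta baseline centrality.
#' @param alpha explicit attenuation factor overriding alphaFrac.
#' @param rescale divide by the maximum so values lie in (0, 1]?
#' @return named numeric vector.
#' @export
katzCentrality <- function(g, direction = c("in", "out"), alphaFrac = 0.9,
                           beta = 1, alpha = NULL, rescale = TRUE) {
  direction <- match.arg(direction)
  m <- as_region_matrix(g)
  n <- nrow(m)
  A <- if (direction == "in") t(m) else m   # x = alpha A x + beta
  lmax <- max(Mod(eigen(m, only.values = TRUE)$values))
  if (is.null(alpha)) {
    stopifnot(alphaFrac < 1)
    alpha <- if (lmax > 0) alphaFrac / lmax else 0
  }
  x <- solve(diag(n) - alpha * A, rep(beta, n))
  if (rescale) x <- x / max(x)
  stats::setNames(as.numeric(x), rownames(m))
}

# The canonical seven-metric profile of one region graph.
seven_metrics <- function(g) {
  m <- as_region_matrix(g)
  deg <- degreeCentrality(m)
  data.frame(region = deg$region,
             in_d = deg$in_degree, out_d = deg$out_degree,
             in_cl = as.numeric(closenessCentrality(m, "in")),
             out_cl = as.numeric(closenessCentrality(m, "out")),
             btn = as.numeric(betweennessCentrality(m)),
             in_K = as.numeric(katzCentrality(m, "in")),
             out_K = as.numeric(katzCentrality(m, "out")),
             stringsAsFactors = FALSE)
}

#' Region connectivity profiles across windows and tasks
#'
#' For every sliding window, maps the FC matrix to a region graph and
#' computes the seven centrality metrics (in/out degree, in/out
#' closeness, betweenness, in/out Katz); the per-(region, task)
#' distributions over windows are summarized by median and quartiles.
#' All metrics are constructed to lie in [0, 1], so the profile axes are
#' directly comparable.
#'
#' @param wfc a channel-level \linkS4class{WindowedFC}.
#' @param atlas channel-to-region map (see \code{\link{toRegionGraph}}).
#' @param includeMixed keep "mixed" windows?
#' @return a \linkS4class{ConnectivityProfile}.
#' @export
buildProfiles <- function(wfc, atlas, includeMixed = FALSE) {
  keep <- if (includeMixed) seq_len(nrow(wfc@windows)) else which(wfc@windows$task != "mixed")
  if (!length(keep)) stop("no windows to profile")
  samples <- do.call(rbind, lapply(keep, function(k) {
    m <- wfc@matrices[[k]]
    dimnames(m) <- list(wfc@nodeLabels, wfc@nodeLabels)
    rg <- if (wfc@level == "region") m else toRegionGraph(m, atlas)@values
    met <- seven_metrics(rg)
    long <- stats::reshape(met, direction = "long",
                           varying = setdiff(names(met), "region"),
                           v.names = "value", timevar = "metric",
                           times = setdiff(names(met), "region"))
    data.frame(window = k, task = wfc@windows$task[k],
               region = long$region, metric = long$metric,
               value = long$value, row.names = NULL,
               stringsAsFactors = FALSE)
  }))
  agg <- stats::aggregate(value ~ region + task + metric, data = samples,
                          FUN = function(v) c(median = stats::median(v),
                                              q25 = unname(stats::quantile(v, 0.25)),
                                              q75 = unname(stats::quantile(v, 0.75)),
                                              n = length(v)))
  summary <- data.frame(region = agg$region, task = agg$task,
                        metric = agg$metric,
                        median = agg$value[, "median"],
                        q25 = agg$value[, "q25"], q75 = agg$value[, "q75"],
                        n = agg$value[, "n"], stringsAsFactors = FALSE)
  new("ConnectivityProfile", summary = summary, samples = samples)
}

#' Region-level windowed FC
#'
#' Applies the max-weight channel-to-region mapping to every window of a
#' channel-level \linkS4class{WindowedFC}.
#'
#' @inheritParams buildProfiles
#' @return a region-level \linkS4class{WindowedFC}.
#' @export
regionWFC <- function(wfc, atlas) {
  stopifnot(wfc@level == "channel")
  mats <- lapply(wfc@matrices, function(m) {
    dimnames(m) <- list(wfc@nodeLabels, wfc@nodeLabels)
    toRegionGraph(m, atlas)@values
  })
  regions <- rownames(mats[[1L]])
  new("WindowedFC", windows = wfc@windows, matrices = mats,
      nodeLabels = regions, level = "region")
}

#' Subset a WindowedFC by task label
#'
#' @param wfc a \linkS4class{WindowedFC}.
#' @param task task label to keep.
#' @return a \linkS4class{WindowedFC} with only that task's windows.
#' @export
subsetTask <- function(wfc, task) {
  keep <- which(wfc@windows$task == task)
  if (!length(keep)) stop("no windows with task ", task)
  new("WindowedFC", windows = wfc@windows[keep, , drop = FALSE],
      matrices = wfc@matrices[keep], nodeLabels = wfc@nodeLabels,
      level = wfc@level)
}
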