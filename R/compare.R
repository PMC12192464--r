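#' First-order Wasserstein distance between two sample vectors
#'
#' Area between the two empirical CDFs (the 1-D earth-mover distance).
#' For equal-size samples this reduces to the mean absolute difference of
#' the sorted samples.
#'
#' @param a,b non-empty numeric sample vectors.
#' @return nonnegative distance.
#' @export
wasserstein1d <- function(a, b) {
  if (!length(a) || !length(b)) stop("empty sample vector")
  knots <- sort(unique(c(a, b)))
  if (length(knots) == 1L) return(0)
  Fa <- stats::ecdf(a)(knots)
  Fb <- stats::ecdf(b)(knots)
  gaps <- diff(knots)
  sum(abs(Fa[-length(Fa)] - Fb[-length(Fb)]) * gaps)
}

#' One-sided Mann-Whitney U test
#'
#' Rank-sum test that sample \code{a} is stochastically greater (or less)
#' than sample \code{b}: exact enumeration when m + n <= 12 and there are
#' no ties, normal approximation with tie correction otherwise. If every
#' value is tied across both samples, p = 1 with a warning.
#'
#' @param a,b numeric samples (>= 3 values each).
#' @param alternative "greater" (a > b) or "less".
#' @return list with U (statistic for a) and p.
#' @export
mannWhitneyOneSided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(length(a) >= 3, length(b) >= 3)
  if (length(unique(c(a, b))) == 1L) {
    warning("all values tied across both samples; p = 1")
    return(list(U = length(a) * length(b) / 2, p = 1))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b) <= 12L) && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = alternative,
                                            exact = exact, correct = TRUE))
  list(U = unname(wt$statistic), p = wt$p.value)
}

#' Classify a directed region link by its two task distributions
#'
#' Compares the per-window weight distributions of every directed region
#' link between two tasks: strong in both (both medians at or above
#' \code{strongThresh} and Wasserstein distance below \code{distThresh}),
#' stronger in one task (distance at or above \code{distThresh}, that
#' task's median larger and at or above \code{strongThresh}), or weak.
#'
#' @param wfcA,wfcB region-level \linkS4class{WindowedFC} for tasks A
#'   and B (same region set, >= 3 windows each).
#' @param strongThresh median threshold for a "strong" link.
#' @param distThresh Wasserstein decision boundary.
#' @return data.frame: source, target, median_A, median_B, wasserstein,
#'   class (strong_in_both / stronger_in_A / stronger_in_B / weak).
#' @export
classifyLinks <- function(wfcA, wfcB, strongThresh = 0.5, distThresh = 0.2) {
  if (!identical(wfcA@nodeLabels, wfcB@nodeLabels))
    stop("region sets differ between tasks")
  stopifnot(length(wfcA@matrices) >= 3, length(wfcB@matrices) >= 3)
  regions <- wfcA@nodeLabels
  R <- length(regions)
  res <- list()
  for (a in seq_len(R)) for (b in seq_len(R)) {
    if (a == b) next
    sa <- vapply(wfcA@matrices, function(m) m[a, b], 0)
    sb <- vapply(wfcB@matrices, function(m) m[a, b], 0)
    ma <- stats::median(sa); mb <- stats::median(sb)
    w <- wasserstein1d(sa, sb)
    cls <- if (ma >= strongThresh && mb >= strongThresh && w < distThresh)
      "strong_in_both"
    else if (w >= distThresh && ma > mb && ma >= strongThresh)
      "stronger_in_A"
    else if (w >= distThresh && mb > ma && mb >= strongThresh)
      "stronger_in_B"
    else "weak"
    res[[length(res) + 1L]] <- data.frame(
      source = regions[a], target = regions[b], median_A = ma,
      median_B = mb, wasserstein = w, class = cls,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}

#' Highlight regions by median degree and one-sided task contrast
#'
#' Reproduces the median-threshold highlighting rule: a region is
#' excluded when both task medians fall below \code{medLo}; otherwise it
#' is flagged significant for the task whose one-sided Mann-Whitney test
#' passes at \code{alpha}; otherwise shared_veryhigh when both medians
#' exceed \code{medHi}, else shared_high. A pure function of the medians
#' and p-values.
#'
#' @param samplesA,samplesB long data.frames with columns \code{region}
#'   and \code{value}: per-window degree samples per region for tasks A
#'   and B.
#' @param alpha one-sided significance level.
#' @param medLo inclusion threshold on the median (>=).
#' @param medHi "very high" threshold on the median (>).
#' @param bonferroni apply Bonferroni correction over regions?
#' @return data.frame: region, median_A, median_B, U, p_A_greater,
#'   p_B_greater, highlight (excluded / sig_A / sig_B / shared_veryhigh /
#'   shared_high).
#' @export
highlightRegions <- function(samplesA, samplesB, alpha = 0.001,
                             medLo = 0.5, medHi = 0.8, bonferroni = FALSE) {
  regions <- union(unique(samplesA$region), unique(samplesB$region))
  rows <- lapply(regions, function(r) {
    va <- samplesA$value[samplesA$region == r]
    vb <- samplesB$value[samplesB$region == r]
    if (length(va) < 3 || length(vb) < 3)
      return(data.frame(region = r, median_A = NA_real_, median_B = NA_real_,
                        U = NA_real_, p_A_greater = NA_real_,
                        p_B_greater = NA_real_, highlight = "excluded",
                        stringsAsFactors = FALSE))
    tg <- mannWhitneyOneSided(va, vb, "greater")
    tl <- mannWhitneyOneSided(vb, va, "greater")
    data.frame(region = r, median_A = stats::median(va),
               median_B = stats::median(vb), U = tg$U,
               p_A_greater = tg$p, p_B_greater = tl$p,
               highlight = NA_character_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  mult <- if (bonferroni) sum(!is.na(out$p_A_greater)) else 1
  for (i in seq_len(nrow(out))) {
    if (!is.na(out$highlight[i])) next
    pa <- min(out$p_A_greater[i] * mult, 1)
    pb <- min(out$p_B_greater[i] * mult, 1)
    out$highlight[i] <-
      if (out$median_A[i] < medLo && out$median_B[i] < medLo) "excluded"
      else if (pa < alpha) "sig_A"
      else if (pb < alpha) "sig_B"
      else if (out$median_A[i] > medHi && out$median_B[i] > medHi) "shared_veryhigh"
      else "shared_high"
  }
  out
}

#' Per-window region degree samples by task
#'
#' Long-format in- or out-degree samples per (window, region, task) from
#' a region-level \linkS4class{WindowedFC}; the input the degree
#' contrasts and highlights consume.
#'
#' @param wfc a region-level \linkS4class{WindowedFC}.
#' @param metric "in_degree" or "out_degree".
#' @param includeMixed keep "mixed" windows?
#' @return data.frame: window, task, region, value.
#' @export
degreeDistributions <- function(wfc, metric = c("in_degree", "out_degree"),
                                includeMixed = FALSE) {
  metric <- match.arg(metric)
  stopifnot(wfc@level == "region")
  keep <- if (includeMixed) seq_len(nrow(wfc@windows)) else which(wfc@windows$task != "mixed")
  do.call(rbind, lapply(keep, function(k) {
    deg <- degreeCentrality(wfc@matrices[[k]])
    data.frame(window = k, task = wfc@windows$task[k],
               region = wfc@nodeLabels, value = deg[[metric]],
               stringsAsFactors = FALSE)
  }))
}
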