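#' Bipolar derivation
#'
#' Subtracts adjacent-contact pairs (anode minus cathode), the standard
#' montage for suppressing the common reference in depth recordings.
#'
#' @param rec a \linkS4class{Recording}.
#' @param pairs data.frame or 2-column matrix of (anode, cathode) labels.
#' @return a \linkS4class{Recording} with one channel per pair, labelled
#'   "anode-cathode".
#' @export
bipolarDerivation <- function(rec, pairs) {
  pairs <- as.matrix(pairs)
  miss <- setdiff(as.vector(pairs), rec@channelLabels)
  if (length(miss)) stop("unknown channels in bipolar pairs: ",
                         paste(miss, collapse = ", "))
  ia <- match(pairs[, 1L], rec@channelLabels)
  ic <- match(pairs[, 2L], rec@channelLabels)
  new("Recording", data = rec@data[ia, , drop = FALSE] - rec@data[ic, , drop = FALSE],
      fs = rec@fs, channelLabels = paste(pairs[, 1L], pairs[, 2L], sep = "-"))
}

# Shared per-window preprocessing: linear detrend + z-score each channel.
# Returns the matrix with a "flat" attribute listing zero-variance channels.
prep_window <- function(window) {
  x <- if (is(window, "Recording")) window@data else window
  detrend_zscore(x)
}

new_measure <- function(values, name, band = numeric(0), labels = NULL) {
  values <- zero_diag(pmin(pmax(values, 0), 1))
  if (!is.null(labels)) dimnames(values) <- list(labels, labels)
  new("MeasureMatrix", values = values, measureName = name, band = band)
}

#' Undirected correlation connectivity (BCorrU)
#'
#' Absolute pairwise Pearson correlation between channels within one
#' window. Undirected and symmetric; the diagonal is zeroed. Channels are
#' linearly detrended and z-scored first. Zero-variance channels get all
#' entries 0 with a warning.
#'
#' @param window a \linkS4class{Recording} (or channels x samples matrix)
#'   with >= 2 channels and >= 100 samples.
#' @return a \linkS4class{MeasureMatrix} ("BCorrU").
#' @export
bcorrU <- function(window) {
  x <- prep_window(window)
  stopifnot(nrow(x) >= 2, ncol(x) >= 100)
  flat <- attr(x, "flat")
  if (length(flat)) {
    warning("zero-variance channel(s): ", paste(flat, collapse = ", "),
            "; their connectivity set to 0")
    x[flat, 1L] <- 1e-30  # avoid cor() NaN; rows are otherwise zero
  }
  r <- abs(stats::cor(t(x)))
  if (length(flat)) { r[flat, ] <- 0; r[, flat] <- 0 }
  labels <- if (is(window, "Recording")) window@channelLabels else rownames(x)
  new_measure(r, "BCorrU", labels = labels)
}

# Max over lags tau in 1..maxLag of |cor(x_i(t - tau), x_j(t))|:
# cmax[i, j] = best prediction of j's present from i's past.
lagged_cormax <- function(x, maxLag) {
  n <- nrow(x); N <- ncol(x)
  cmax <- matrix(0, n, n)
  for (tau in seq_len(maxLag)) {
    past <- x[, 1:(N - tau), drop = FALSE]
    pres <- x[, (tau + 1):N, drop = FALSE]
    r <- abs(suppressWarnings(stats::cor(t(past), t(pres))))
    r[!is.finite(r)] <- 0
    cmax <- pmax(cmax, r)
  }
  cmax
}

#' Directed lagged-correlation connectivity (BCorrD)
#'
#' Compares the predictive power of node i's past on node j's present
#' against the reverse: c+(i, j) is the maximum absolute lagged
#' correlation over lags 1..maxLag, and the direction i -> j is retained
#' (with value c+(i, j)) only when c+(i, j) > c+(j, i); the losing
#' direction is zeroed.
#'
#' @param window a \linkS4class{Recording} or channels x samples matrix.
#' @param maxLag maximum lag in samples (default 100 ms worth, i.e.
#'   0.1 * fs for a Recording); must be >= 1 and < n_samples / 10.
#' @return a \linkS4class{MeasureMatrix} ("BCorrD").
#' @export
bcorrD <- function(window, maxLag = NULL) {
  x <- prep_window(window)
  if (is.null(maxLag)) {
    if (!is(window, "Recording"))
      stop("maxLag required when the input has no sampling rate")
    maxLag <- max(1L, round(0.1 * window@fs))
  }
  if (maxLag < 1 || maxLag >= ncol(x) / 10)
    stop("maxLag must be >= 1 and < n_samples / 10")
  cmax <- lagged_cormax(x, maxLag)
  win <- cmax > t(cmax)
  out <- ifelse(win, cmax, 0)
  labels <- if (is(window, "Recording")) window@channelLabels else rownames(x)
  new_measure(out, "BCorrD", labels = labels)
}

#' Compute the four-measure suite on one window
#'
#' Convenience wrapper computing BCorrU, BCorrD, COH1 and PDC on a single
#' window (one MVAR fit shared by the two spectral measures).
#'
#' @param window a \linkS4class{Recording}.
#' @param band frequency band in Hz for the spectral measures.
#' @param nFreqs number of equispaced evaluation frequencies in the band.
#' @param order MVAR order, or "auto" for BIC selection.
#' @param maxOrder maximum candidate order for "auto".
#' @param maxLag BCorrD maximum lag (default 0.1 * fs samples).
#' @return named list of four \linkS4class{MeasureMatrix} objects.
#' @export
measureSuite <- function(window, band = c(1, 45), nFreqs = 64,
                         order = "auto", maxOrder = 10L, maxLag = NULL) {
  model <- fitMVAR(window, order = order, maxOrder = maxOrder)
  list(BCorrU = bcorrU(window),
       BCorrD = bcorrD(window, maxLag = maxLag),
       COH1 = coh1(model, band = band, nFreqs = nFreqs),
       PDC = pdc(model, band = band, nFreqs = nFreqs))
}
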