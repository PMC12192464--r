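#' Sliding-window functional connectivity
#'
#' Slides a window (default 5 s, 50% overlap) over the session, computes
#' the four connectivity measures per window, and fuses them into one
#' directed FC matrix per window. Window k covers
#' [k * hop, k * hop + window_s) with hop = window_s * (1 - overlap),
#' anchored at the session start (0-based, half-open, seconds). A window
#' fully inside one task annotation gets that task's label; windows
#' straddling a boundary (or outside all annotations) are labelled
#' "mixed".
#'
#' @param session a \linkS4class{TaskSession}, or a
#'   \linkS4class{Recording} with \code{annotations} supplied.
#' @param windowS window length in seconds.
#' @param overlap fractional overlap in [0, 1).
#' @param config a \linkS4class{FusionConfig} for the fusion step.
#' @param annotations data.frame (start_s, end_s, task) when
#'   \code{session} is a bare Recording; ignored otherwise.
#' @param band,nFreqs,order,maxOrder,maxLag measure parameters
#'   (see \code{\link{measureSuite}}).
#' @return a \linkS4class{WindowedFC} (channel level).
#' @export
slidingFC <- function(session, windowS = 5, overlap = 0.5,
                      config = defaultFusionConfig(), annotations = NULL,
                      band = c(1, 45), nFreqs = 64, order = "auto",
                      maxOrder = 10L, maxLag = NULL) {
  if (is(session, "TaskSession")) {
    rec <- session@recording
    annotations <- session@annotations
  } else {
    rec <- session
    if (is.null(annotations))
      annotations <- data.frame(start_s = numeric(0), end_s = numeric(0),
                                task = character(0))
  }
  stopifnot(overlap >= 0, overlap < 1, windowS > 0)
  dur <- ncol(rec@data) / rec@fs
  if (dur < windowS) stop("session shorter than one window")
  hop <- windowS * (1 - overlap)
  starts <- seq(0, dur - windowS + 1e-9, by = hop)
  label_of <- function(s, e) {
    hit <- which(annotations$start_s <= s + 1e-9 & annotations$end_s >= e - 1e-9)
    if (length(hit) == 1L) annotations$task[hit] else "mixed"
  }
  mats <- vector("list", length(starts))
  tasks <- character(length(starts))
  for (k in seq_along(starts)) {
    i0 <- round(starts[k] * rec@fs) + 1L
    i1 <- round((starts[k] + windowS) * rec@fs)
    win <- new("Recording", data = rec@data[, i0:i1, drop = FALSE],
               fs = rec@fs, channelLabels = rec@channelLabels)
    suite <- measureSuite(win, band = band, nFreqs = nFreqs, order = order,
                          maxOrder = maxOrder, maxLag = maxLag)
    mats[[k]] <- fuseMeasures(suite, config)@values
    tasks[k] <- label_of(starts[k], starts[k] + windowS)
  }
  new("WindowedFC",
      windows = data.frame(start_s = starts, end_s = starts + windowS,
                           task = tasks, stringsAsFactors = FALSE),
      matrices = mats, nodeLabels = rec@channelLabels, level = "channel")
}

#' Functional-connectivity dynamics (FCD) matrix
#'
#' Pearson correlation between the vectorized off-diagonal FC entries of
#' every pair of sliding windows. The diagonal is 1; a window with
#' zero-variance FC gets zero off-diagonal similarity (with a warning).
#'
#' @param wfc a \linkS4class{WindowedFC} with >= 2 windows.
#' @return an \linkS4class{FCDMatrix}.
#' @export
computeFCD <- function(wfc) {
  W <- length(wfc@matrices)
  if (W < 2) stop("need at least 2 windows")
  V <- vapply(wfc@matrices, offdiag, numeric(length(offdiag(wfc@matrices[[1L]]))))
  sds <- apply(V, 2L, stats::sd)
  flat <- sds < 1e-12
  if (any(flat)) {
    warning("constant FC in window(s) ", paste(which(flat), collapse = ", "),
            "; their FCD similarities set to 0")
    V[1L, flat] <- V[1L, flat] + 1e-30
  }
  fcd <- suppressWarnings(stats::cor(V))
  fcd[!is.finite(fcd)] <- 0
  if (any(flat)) { fcd[flat, ] <- 0; fcd[, flat] <- 0 }
  diag(fcd) <- 1
  fcd <- (fcd + t(fcd)) / 2
  new("FCDMatrix", values = fcd, windows = wfc@windows)
}

#' Within- vs between-task FCD contrast
#'
#' Mean FCD similarity among window pairs sharing a task label versus
#' pairs from different tasks ("mixed" windows excluded). A clearly
#' positive difference is the quantitative counterpart of the visually
#' distinct task blocks in the FCD matrix.
#'
#' @param fcd an \linkS4class{FCDMatrix}.
#' @return list with \code{within}, \code{between}, \code{difference},
#'   and the two groups of similarities (\code{withinValues},
#'   \code{betweenValues}).
#' @export
fcdTaskSeparation <- function(fcd) {
  keep <- fcd@windows$task != "mixed"
  v <- fcd@values[keep, keep, drop = FALSE]
  tk <- fcd@windows$task[keep]
  same <- outer(tk, tk, "==")
  ut <- upper.tri(v)
  within <- v[ut & same]
  between <- v[ut & !same]
  list(within = mean(within), between = mean(between),
       difference = mean(within) - mean(between),
       withinValues = within, betweenValues = between)
}
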