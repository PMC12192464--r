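#' @import methods
NULL

#' Multichannel recording
#'
#' Container for a multichannel electrophysiology recording: a channels x
#' samples numeric matrix plus sampling rate and unique channel labels.
#' Signals are stored as acquired; windowing, detrending and z-scoring
#' happen inside the connectivity measures.
#'
#' @slot data numeric matrix, channels x samples, all finite.
#' @slot fs sampling rate in Hz.
#' @slot channelLabels character vector, one unique label per channel.
#' @exportClass Recording
setClass("Recording",
  representation(data = "matrix", fs = "numeric", channelLabels = "character"))

setValidity("Recording", function(object) {
  msg <- character()
  if (!is.numeric(object@data)) msg <- c(msg, "data must be numeric")
  if (any(!is.finite(object@data))) msg <- c(msg, "data contains non-finite values")
  if (length(object@fs) != 1L || object@fs <= 0) msg <- c(msg, "fs must be a single positive number")
  if (ncol(object@data) <= object@fs)
    msg <- c(msg, "recording must be longer than 1 s (n_samples > fs)")
  if (nrow(object@data) != length(object@channelLabels))
    msg <- c(msg, "one label per channel required")
  if (anyDuplicated(object@channelLabels)) msg <- c(msg, "channel labels must be unique")
  if (length(msg)) msg else TRUE
})

#' Ground-truth directed network
#'
#' Directed weighted adjacency used by the signal simulator and as the
#' recovery oracle for connectivity estimation. Entry (i, j) is the
#' coupling strength of the directed edge i -> j; the diagonal is zero.
#'
#' @slot adjacency nonnegative numeric matrix, zero diagonal.
#' @slot density fraction of possible off-diagonal edges present.
#' @slot seed integer seed the network was drawn with (NA if constructed
#'   directly from an adjacency matrix).
#' @exportClass GroundTruthNetwork
setClass("GroundTruthNetwork",
  representation(adjacency = "matrix", density = "numeric", seed = "integer"))

setValidity("GroundTruthNetwork", function(object) {
  a <- object@adjacency
  msg <- character()
  if (nrow(a) != ncol(a)) msg <- c(msg, "adjacency must be square")
  if (nrow(a) < 2L) msg <- c(msg, "at least 2 nodes required")
  if (any(a < 0)) msg <- c(msg, "couplings must be nonnegative")
  if (any(diag(a) != 0)) msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})

#' Simulated task session
#'
#' A recording concatenated from task blocks, the task annotations
#' (non-overlapping half-open intervals in seconds), and the ground-truth
#' network underlying each task block.
#'
#' @slot recording a \linkS4class{Recording}.
#' @slot annotations data.frame with columns start_s, end_s, task.
#' @slot truthNetworks named list of \linkS4class{GroundTruthNetwork},
#'   one per task label.
#' @exportClass TaskSession
setClass("TaskSession",
  representation(recording = "Recording", annotations = "data.frame",
                 truthNetworks = "list"))

setValidity("TaskSession", function(object) {
  ann <- object@annotations
  msg <- character()
  if (!all(c("start_s", "end_s", "task") %in% names(ann)))
    msg <- c(msg, "annotations need columns start_s, end_s, task")
  else {
    if (any(ann$end_s <= ann$start_s)) msg <- c(msg, "empty annotation interval")
    o <- order(ann$start_s)
    if (nrow(ann) > 1L && any(ann$start_s[o][-1L] < ann$end_s[o][-nrow(ann)] - 1e-9))
      msg <- c(msg, "annotation intervals overlap")
    dur <- ncol(object@recording@data) / object@recording@fs
    if (any(ann$end_s > dur + 1e-9)) msg <- c(msg, "annotation beyond recording duration")
    if (length(object@truthNetworks) &&
        !all(unique(ann$task) %in% names(object@truthNetworks)))
      msg <- c(msg, "every task label needs a truth network")
  }
  if (length(msg)) msg else TRUE
})

#' Fitted MVAR spectral model
#'
#' Multivariate autoregressive model of order p. Coefficient matrices
#' follow the regression convention A_k[i, j] = influence of channel j at
#' lag k on channel i now; the spectral matrix is
#' Abar(f) = I - sum_k A_k exp(-i 2 pi f k / fs).
#'
#' @slot order model order p.
#' @slot coeffs list of p coefficient matrices (n x n).
#' @slot residCov residual (innovation) covariance, n x n.
#' @slot fs sampling rate in Hz.
#' @slot bic BIC values per candidate order when order selection was run
#'   (named numeric; empty otherwise).
#' @slot scales per-channel standard deviations removed by the
#'   within-window z-scoring (1 when the model was built from known
#'   coefficients); used to express coefficients in original units.
#' @exportClass SpectralModel
setClass("SpectralModel",
  representation(order = "integer", coeffs = "list", residCov = "matrix",
                 fs = "numeric", bic = "numeric", scales = "numeric"))

setValidity("SpectralModel", function(object) {
  msg <- character()
  if (length(object@coeffs) != object@order) msg <- c(msg, "need one coefficient matrix per lag")
  n <- nrow(object@residCov)
  if (ncol(object@residCov) != n) msg <- c(msg, "residCov must be square")
  if (max(abs(object@residCov - t(object@residCov))) > 1e-8)
    msg <- c(msg, "residCov must be symmetric")
  for (A in object@coeffs)
    if (!all(dim(A) == c(n, n))) msg <- c(msg, "coefficient dimension mismatch")
  if (length(msg)) msg else TRUE
})

#' Single-measure connectivity matrix
#'
#' One connectivity measure evaluated on one signal window. Entries are in
#' [0, 1] with zero diagonal; orientation is source row -> target column
#' throughout the package. BCorrU and COH1 are symmetric, BCorrD and PDC
#' may be asymmetric.
#'
#' @slot values numeric matrix in [0, 1], zero diagonal.
#' @slot measureName one of "BCorrU", "BCorrD", "COH1", "PDC".
#' @slot band frequency band (f_lo, f_hi) in Hz for spectral measures,
#'   numeric(0) for time-domain measures.
#' @exportClass MeasureMatrix
setClass("MeasureMatrix",
  representation(values = "matrix", measureName = "character", band = "numeric"))

setValidity("MeasureMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (!object@measureName %in% c("BCorrU", "BCorrD", "COH1", "PDC"))
    msg <- c(msg, "unknown measure name")
  if (any(v < -1e-9) || any(v > 1 + 1e-9)) msg <- c(msg, "entries must lie in [0, 1]")
  if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
  if (object@measureName %in% c("BCorrU", "COH1") &&
      max(abs(v - t(v))) > 1e-8)
    msg <- c(msg, "undirected measure must be symmetric")
  if (length(msg)) msg else TRUE
})

#' Fuzzy-fusion configuration
#'
#' Per-measure logistic membership parameters (threshold theta in [0, 1],
#' slope k > 0) and convex fusion weights, plus an optional binarization
#' threshold. These are the parameters the genetic algorithm tunes.
#'
#' @slot theta named numeric(4), membership thresholds.
#' @slot slope named numeric(4), membership slopes (> 0).
#' @slot weight named numeric(4), nonnegative, summing to 1.
#' @slot decisionThreshold scalar in [0, 1] for optional binarization.
#' @exportClass FusionConfig
setClass("FusionConfig",
  representation(theta = "numeric", slope = "numeric", weight = "numeric",
                 decisionThreshold = "numeric"))

.MEASURES <- c("BCorrU", "BCorrD", "COH1", "PDC")

setValidity("FusionConfig", function(object) {
  msg <- character()
  for (s in c("theta", "slope", "weight"))
    if (!identical(sort(names(slot(object, s))), sort(.MEASURES)))
      msg <- c(msg, sprintf("%s must be named by the four measures", s))
  if (any(object@slope <= 0)) msg <- c(msg, "slopes must be positive")
  if (any(object@theta < 0 | object@theta > 1)) msg <- c(msg, "thresholds must lie in [0, 1]")
  if (any(object@weight < 0) || abs(sum(object@weight) - 1) > 1e-8)
    msg <- c(msg, "weights must be nonnegative and sum to 1")
  if (length(msg)) msg else TRUE
})

#' Fused functional-connectivity matrix
#'
#' Directed weighted FC matrix produced by fuzzy fusion of the four
#' measures, with the configuration that produced it.
#'
#' @slot values numeric matrix in [0, 1], zero diagonal, source row ->
#'   target column.
#' @slot config the \linkS4class{FusionConfig} used.
#' @exportClass FusedFC
setClass("FusedFC",
  representation(values = "matrix", config = "FusionConfig"))

setValidity("FusedFC", function(object) {
  v <- object@values
  msg <- character()
  if (any(v < -1e-9) || any(v > 1 + 1e-9)) msg <- c(msg, "entries must lie in [0, 1]")
  if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})

#' Sliding-window functional connectivity
#'
#' Ordered stack of directed weighted FC matrices, one per sliding window,
#' with window time bounds and the task label covering each window
#' ("mixed" for windows straddling a task boundary).
#'
#' @slot windows data.frame with columns start_s, end_s, task.
#' @slot matrices list of numeric FC matrices, one per window.
#' @slot nodeLabels node (channel or region) labels shared by all matrices.
#' @slot level "channel" or "region".
#' @exportClass WindowedFC
setClass("WindowedFC",
  representation(windows = "data.frame", matrices = "list",
                 nodeLabels = "character", level = "character"))

setValidity("WindowedFC", function(object) {
  msg <- character()
  if (nrow(object@windows) != length(object@matrices))
    msg <- c(msg, "one matrix per window required")
  if (!object@level %in% c("channel", "region")) msg <- c(msg, "level must be channel or region")
  n <- length(object@nodeLabels)
  for (m in object@matrices)
    if (!all(dim(m) == c(n, n))) { msg <- c(msg, "matrix dimension mismatch"); break }
  if (nrow(object@windows) > 1L && is.unsorted(object@windows$start_s))
    msg <- c(msg, "windows must be time-ordered")
  if (length(msg)) msg else TRUE
})

#' Functional-connectivity dynamics (FCD) matrix
#'
#' Window-by-window similarity matrix: entry (a, b) is the Pearson
#' correlation between the vectorized off-diagonal FC of windows a and b.
#' Symmetric with unit diagonal.
#'
#' @slot values W x W numeric matrix in [-1, 1].
#' @slot windows window metadata shared with the source
#'   \linkS4class{WindowedFC}.
#' @exportClass FCDMatrix
setClass("FCDMatrix",
  representation(values = "matrix", windows = "data.frame"))

setValidity("FCDMatrix", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != ncol(v) || nrow(v) != nrow(object@windows))
    msg <- c(msg, "FCD must be W x W with matching window metadata")
  if (max(abs(v - t(v))) > 1e-8) msg <- c(msg, "FCD must be symmetric")
  if (any(abs(diag(v) - 1) > 1e-8)) msg <- c(msg, "FCD diagonal must be 1")
  if (any(v < -1 - 1e-8 | v > 1 + 1e-8)) msg <- c(msg, "FCD entries must lie in [-1, 1]")
  if (length(msg)) msg else TRUE
})

#' Region-level directed network
#'
#' Directed weighted network over brain regions obtained by taking, for
#' each ordered region pair, the maximum FC weight among all channel
#' pairs connecting the two regions. Within-region links are discarded.
#'
#' @slot values R x R numeric matrix in [0, 1], zero diagonal.
#' @slot regions region names.
#' @exportClass RegionGraph
setClass("RegionGraph",
  representation(values = "matrix", regions = "character"))

setValidity("RegionGraph", function(object) {
  v <- object@values
  msg <- character()
  if (nrow(v) != length(object@regions) || ncol(v) != length(object@regions))
    msg <- c(msg, "matrix must match region list")
  if (any(v < -1e-9) || any(v > 1 + 1e-9)) msg <- c(msg, "entries must lie in [0, 1]")
  if (any(diag(v) != 0)) msg <- c(msg, "diagonal must be zero")
  if (length(msg)) msg else TRUE
})

#' Region connectivity profiles
#'
#' Per (region, task) distributions of the seven centrality metrics
#' (in/out degree, in/out closeness, betweenness, in/out Katz) over
#' sliding windows, with median and quartile summaries. All metrics are
#' standardized to [0, 1].
#'
#' @slot summary data.frame: region, task, metric, median, q25, q75, n.
#' @slot samples data.frame: window, task, region, metric, value.
#' @exportClass ConnectivityProfile
setClass("ConnectivityProfile",
  representation(summary = "data.frame", samples = "data.frame"))
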