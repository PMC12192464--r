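#' Accessor generics
#'
#' Small accessor family for the package's containers: raw signal matrix,
#' sampling rate, labels, connectivity values, window metadata.
#'
#' @param x a package object.
#' @return the corresponding slot content.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("recordingData", function(x) standardGeneric("recordingData"))
#' @rdname accessors
#' @export
setGeneric("samplingRate", function(x) standardGeneric("samplingRate"))
#' @rdname accessors
#' @export
setGeneric("channelLabels", function(x) standardGeneric("channelLabels"))
#' @rdname accessors
#' @export
setGeneric("adjacencyMatrix", function(x) standardGeneric("adjacencyMatrix"))
#' @rdname accessors
#' @export
setGeneric("connValues", function(x) standardGeneric("connValues"))
#' @rdname accessors
#' @export
setGeneric("measureName", function(x) standardGeneric("measureName"))
#' @rdname accessors
#' @export
setGeneric("windowInfo", function(x) standardGeneric("windowInfo"))
#' @rdname accessors
#' @export
setGeneric("fcMatrices", function(x) standardGeneric("fcMatrices"))
#' @rdname accessors
#' @export
setGeneric("nodeLabels", function(x) standardGeneric("nodeLabels"))
#' @rdname accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))
#' @rdname accessors
#' @export
setGeneric("annotations", function(x) standardGeneric("annotations"))
#' @rdname accessors
#' @export
setGeneric("truthNetworks", function(x) standardGeneric("truthNetworks"))

#' @rdname accessors
setMethod("recordingData", "Recording", function(x) x@data)
#' @rdname accessors
setMethod("recordingData", "TaskSession", function(x) x@recording@data)
#' @rdname accessors
setMethod("samplingRate", "Recording", function(x) x@fs)
#' @rdname accessors
setMethod("samplingRate", "TaskSession", function(x) x@recording@fs)
#' @rdname accessors
setMethod("samplingRate", "SpectralModel", function(x) x@fs)
#' @rdname accessors
setMethod("channelLabels", "Recording", function(x) x@channelLabels)
#' @rdname accessors
setMethod("channelLabels", "TaskSession", function(x) x@recording@channelLabels)
#' @rdname accessors
setMethod("adjacencyMatrix", "GroundTruthNetwork", function(x) x@adjacency)
#' @rdname accessors
setMethod("connValues", "MeasureMatrix", function(x) x@values)
#' @rdname accessors
setMethod("connValues", "FusedFC", function(x) x@values)
#' @rdname accessors
setMethod("connValues", "FCDMatrix", function(x) x@values)
#' @rdname accessors
setMethod("connValues", "RegionGraph", function(x) x@values)
#' @rdname accessors
setMethod("measureName", "MeasureMatrix", function(x) x@measureName)
#' @rdname accessors
setMethod("windowInfo", "WindowedFC", function(x) x@windows)
#' @rdname accessors
setMethod("windowInfo", "FCDMatrix", function(x) x@windows)
#' @rdname accessors
setMethod("fcMatrices", "WindowedFC", function(x) x@matrices)
#' @rdname accessors
setMethod("nodeLabels", "WindowedFC", function(x) x@nodeLabels)
#' @rdname accessors
setMethod("regionNames", "RegionGraph", function(x) x@regions)
#' @rdname accessors
setMethod("annotations", "TaskSession", function(x) x@annotations)
#' @rdname accessors
setMethod("truthNetworks", "TaskSession", function(x) x@truthNetworks)

setMethod("show", "Recording", function(object) {
  cat(sprintf("Recording: %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(object@data), ncol(object@data), object@fs,
              ncol(object@data) / object@fs))
})

setMethod("show", "GroundTruthNetwork", function(object) {
  a <- object@adjacency
  cat(sprintf("GroundTruthNetwork: %d nodes, %d directed edges (density %.3f)\n",
              nrow(a), sum(a > 0), sum(a > 0) / (nrow(a) * (nrow(a) - 1))))
})

setMethod("show", "TaskSession", function(object) {
  cat(sprintf("TaskSession: %d channels, %.1f s @ %g Hz\n",
              nrow(object@recording@data),
              ncol(object@recording@data) / object@recording@fs,
              object@recording@fs))
  ann <- object@annotations
  for (i in seq_len(nrow(ann)))
    cat(sprintf("  [%6.1f, %6.1f) %s\n", ann$start_s[i], ann$end_s[i], ann$task[i]))
})

setMethod("show", "SpectralModel", function(object) {
  cat(sprintf("SpectralModel: order %d, %d channels, fs %g Hz\n",
              object@order, nrow(object@residCov), object@fs))
})

setMethod("show", "MeasureMatrix", function(object) {
  band <- if (length(object@band)) sprintf(", band %g-%g Hz", object@band[1], object@band[2]) else ""
  cat(sprintf("MeasureMatrix [%s]: %d x %d%s\n", object@measureName,
              nrow(object@values), ncol(object@values), band))
})

setMethod("show", "FusionConfig", function(object) {
  cat("FusionConfig (measure: theta / slope / weight)\n")
  for (m in .MEASURES)
    cat(sprintf("  %-6s %.3f / %6.2f / %.3f\n", m,
                object@theta[m], object@slope[m], object@weight[m]))
})

setMethod("show", "FusedFC", function(object) {
  cat(sprintf("FusedFC: %d x %d directed weighted matrix\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "WindowedFC", function(object) {
  cat(sprintf("WindowedFC (%s level): %d windows of %d x %d FC, tasks: %s\n",
              object@level, nrow(object@windows), length(object@nodeLabels),
              length(object@nodeLabels),
              paste(unique(object@windows$task), collapse = ", ")))
})

setMethod("show", "FCDMatrix", function(object) {
  cat(sprintf("FCDMatrix: %d x %d window similarities\n",
              nrow(object@values), ncol(object@values)))
})

setMethod("show", "RegionGraph", function(object) {
  cat(sprintf("RegionGraph: %d regions, %d directed links\n",
              length(object@regions), sum(object@values > 0)))
})

setMethod("show", "ConnectivityProfile", function(object) {
  cat(sprintf("ConnectivityProfile: %d regions x %d tasks x %d metrics\n",
              length(unique(object@summary$region)),
              length(unique(object@summary$task)),
              length(unique(object@summary$metric))))
})
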