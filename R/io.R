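#' Read a recording from a matrix file with a JSON sidecar
#'
#' Plain-text recording format: a tab-separated channels x samples
#' matrix, plus a JSON sidecar holding \code{fs} (Hz), the
#' \code{channel_labels}, and optionally \code{bipolar_pairs} (list of
#' [anode, cathode]); when pairs are present the bipolar derivation is
#' applied on read.
#'
#' @param path path to the matrix TSV.
#' @param sidecar path to the JSON sidecar (default \code{path + ".json"}).
#' @return a \linkS4class{Recording}.
#' @export
readRecording <- function(path, sidecar = paste0(path, ".json")) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  if (is.null(meta$fs)) stop("sidecar lacks fs (sampling rate)")
  x <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(x) <- NULL
  labels <- meta$channel_labels
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(nrow(x)))
  if (length(labels) != nrow(x))
    stop("label count (", length(labels), ") does not match channel count (",
         nrow(x), ")")
  bad <- which(apply(x, 1L, function(r) any(!is.finite(r))))
  if (length(bad))
    stop("non-finite samples in channel(s): ",
         paste(labels[bad], collapse = ", "))
  rec <- new("Recording", data = x, fs = meta$fs, channelLabels = labels)
  if (!is.null(meta$bipolar_pairs))
    rec <- bipolarDerivation(rec, do.call(rbind, meta$bipolar_pairs))
  rec
}

#' Write a recording as matrix TSV + JSON sidecar
#'
#' @param rec a \linkS4class{Recording}.
#' @param path output TSV path; the sidecar goes to \code{path + ".json"}.
#' @return \code{path}, invisibly.
#' @export
writeRecording <- function(rec, path) {
  utils::write.table(format(rec@data, digits = 8, trim = TRUE, scientific = TRUE),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(fs = rec@fs, channel_labels = rec@channelLabels),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write task annotations (3-column TSV)
#'
#' Annotations are half-open intervals in seconds: columns start_s,
#' end_s, task (with header).
#'
#' @param path TSV path.
#' @return data.frame with start_s, end_s, task.
#' @export
readAnnotations <- function(path) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  if (!all(c("start_s", "end_s", "task") %in% names(ann)))
    stop("annotations need columns start_s, end_s, task")
  ann
}

#' @rdname readAnnotations
#' @param ann annotations data.frame to write.
#' @export
writeAnnotations <- function(ann, path) {
  utils::write.table(ann[, c("start_s", "end_s", "task")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a channel-to-region atlas map (TSV)
#'
#' @param path TSV with columns channel, region and optionally
#'   hemisphere (header required).
#' @return data.frame.
#' @export
readAtlas <- function(path) {
  atlas <- utils::read.table(path, sep = "\t", header = TRUE,
                             stringsAsFactors = FALSE)
  if (!all(c("channel", "region") %in% names(atlas)))
    stop("atlas needs columns channel, region")
  atlas
}

#' Write a network / region graph as an edge-list CSV
#'
#' @param g \linkS4class{GroundTruthNetwork}, \linkS4class{RegionGraph}
#'   or weighted adjacency matrix.
#' @param path output CSV (columns source, target, weight).
#' @export
writeEdgeList <- function(g, path) {
  m <- if (is(g, "GroundTruthNetwork")) g@adjacency else as_region_matrix(g)
  labels <- rownames(m)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  idx <- which(m > 0, arr.ind = TRUE)
  utils::write.csv(data.frame(source = labels[idx[, 1L]],
                              target = labels[idx[, 2L]],
                              weight = m[idx]),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a fusion configuration as JSON
#'
#' @param config a \linkS4class{FusionConfig}.
#' @param path JSON path.
#' @export
writeFusionConfig <- function(config, path) {
  jsonlite::write_json(list(theta = as.list(config@theta),
                            slope = as.list(config@slope),
                            weight = as.list(config@weight),
                            decision_threshold = config@decisionThreshold),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeFusionConfig
#' @export
readFusionConfig <- function(path) {
  j <- jsonlite::fromJSON(path)
  fusionConfig(theta = unlist(j$theta), slope = unlist(j$slope),
               weight = unlist(j$weight),
               decisionThreshold = j$decision_threshold)
}

#' Pipeline configuration
#'
#' Bundles the analysis parameters with their defaults: 5 s windows with
#' 50% overlap, 1-45 Hz band, BIC order selection, 5-fold stratified
#' time-separated cross-validation, alpha 0.001 and median thresholds
#' 0.5 / 0.8 for the degree highlights, strong/distance link thresholds
#' 0.5 / 0.2. One master seed fans out to fixed per-stage offsets.
#'
#' @param window_s sliding-window length (s).
#' @param overlap fractional window overlap.
#' @param band spectral band (Hz).
#' @param mvar_order MVAR order or "auto".
#' @param max_order BIC candidate ceiling for "auto".
#' @param cluster_k number of clusters (NULL = number of tasks).
#' @param classifier "rfc" or "svm".
#' @param folds cross-validation folds K.
#' @param strong_thresh,dist_thresh link-classification thresholds.
#' @param med_lo,med_hi,alpha degree-highlight thresholds.
#' @param seed master seed.
#' @param fusion a \linkS4class{FusionConfig} (default configuration if
#'   NULL).
#' @return list of class "fcdynConfig".
#' @export
pipelineConfig <- function(window_s = 5, overlap = 0.5, band = c(1, 45),
                           mvar_order = "auto", max_order = 10L,
                           cluster_k = NULL, classifier = "rfc", folds = 5L,
                           strong_thresh = 0.5, dist_thresh = 0.2,
                           med_lo = 0.5, med_hi = 0.8, alpha = 0.001,
                           seed = 1L, fusion = NULL) {
  cfg <- list(window_s = window_s, overlap = overlap, band = band,
              mvar_order = mvar_order, max_order = max_order,
              cluster_k = cluster_k, classifier = classifier, folds = folds,
              strong_thresh = strong_thresh, dist_thresh = dist_thresh,
              med_lo = med_lo, med_hi = med_hi, alpha = alpha, seed = seed,
              fusion = if (is.null(fusion)) defaultFusionConfig() else fusion)
  class(cfg) <- "fcdynConfig"
  cfg
}

config_json <- function(config) {
  ser <- unclass(config)
  ser$fusion <- list(theta = as.list(config$fusion@theta),
                     slope = as.list(config$fusion@slope),
                     weight = as.list(config$fusion@weight),
                     decision_threshold = config$fusion@decisionThreshold)
  jsonlite::toJSON(ser, auto_unbox = TRUE, digits = NA, null = "null")
}

write_matrix_csv <- function(m, path) {
  utils::write.csv(as.data.frame(m), path, row.names = TRUE)
  invisible(path)
}

#' Run the full analysis pipeline on one session
#'
#' Chains the stages end to end: sliding-window FC, FCD matrix, task
#' clustering, task classification, region profiles and between-task
#' degree comparisons (the last two require an atlas). Each stage's
#' outputs are written under \code{outDir} as CSV/JSON; a manifest
#' records the package version, the seed, the resolved configuration and
#' its hash, per-stage wall time and input shapes. A stage failure halts
#' the run with the stage name; earlier outputs are retained.
#'
#' @param session a \linkS4class{TaskSession}, or a
#'   \linkS4class{Recording} with \code{annotations}.
#' @param outDir output directory (created if needed).
#' @param config a \code{\link{pipelineConfig}}.
#' @param atlas optional channel-to-region map (data.frame or TSV path).
#' @param annotations annotations when \code{session} is a Recording;
#'   NULL skips clustering/classification (connectivity stages still run).
#' @return (invisibly) list with the in-memory stage results and the
#'   manifest.
#' @export
runPipeline <- function(session, outDir, config = pipelineConfig(),
                        atlas = NULL, annotations = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  if (is.character(atlas)) atlas <- readAtlas(atlas)
  if (is(session, "TaskSession")) {
    annotations <- session@annotations
    rec <- session@recording
  } else rec <- session
  cfgPath <- file.path(outDir, "config.json")
  writeLines(config_json(config), cfgPath)
  cfgHash <- unname(tools::md5sum(cfgPath))
  manifest <- list(package = "fcdyn",
                   version = as.character(utils::packageVersion("fcdyn")),
                   seed = config$seed, config_hash = cfgHash,
                   input = list(channels = nrow(rec@data),
                                samples = ncol(rec@data), fs = rec@fs),
                   stages = list())
  results <- list()
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    manifest$stages[[name]] <<- list(seconds = round(proc.time()[["elapsed"]] - t0, 3))
    message(sprintf("[fcdyn] stage %-14s %7.2f s", name,
                    manifest$stages[[name]]$seconds))
    out
  }
  hasAnn <- !is.null(annotations) && nrow(annotations) > 0

  results$wfc <- stage("windowed_fc", slidingFC(
    rec, windowS = config$window_s, overlap = config$overlap,
    config = config$fusion, annotations = annotations, band = config$band,
    order = config$mvar_order, maxOrder = config$max_order))
  wfcCsv <- do.call(rbind, lapply(seq_along(results$wfc@matrices), function(k)
    cbind(window = k, as.data.frame(results$wfc@matrices[[k]]))))
  utils::write.csv(wfcCsv, file.path(outDir, "windowed_fc.csv"), row.names = TRUE)
  jsonlite::write_json(list(orientation = "rows = source, columns = target",
                            config_hash = cfgHash,
                            windows = results$wfc@windows),
                       file.path(outDir, "windowed_fc.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")

  results$fcd <- stage("fcd", computeFCD(results$wfc))
  write_matrix_csv(results$fcd@values, file.path(outDir, "fcd.csv"))

  if (hasAnn) {
    k <- if (is.null(config$cluster_k)) length(unique(annotations$task)) else config$cluster_k
    results$clustering <- stage("clustering", {
      cl <- lapply(c("spectral", "birch"), function(alg)
        clusterWindows(results$wfc, k = k, algorithm = alg,
                       seed = config$seed + 101L))
      names(cl) <- c("spectral", "birch")
      rep <- lapply(cl, function(d) clusteringMetrics(d$cluster, d$task))
      list(assignments = cl, metrics = rep)
    })
    jsonlite::write_json(
      lapply(results$clustering$metrics, function(m)
        m[c("MI", "FM", "RI", "AR", "accuracy", "BAS")]),
      file.path(outDir, "clustering.json"), auto_unbox = TRUE, digits = NA)

    results$classification <- stage("classification", classifyTasks(
      results$wfc, model = config$classifier, K = config$folds,
      seed = config$seed + 202L))
    utils::write.csv(as.data.frame.matrix(results$classification$confusion),
                     file.path(outDir, "confusion.csv"))
    jsonlite::write_json(
      results$classification[c("accuracy", "BAS", "hamming_loss", "mae")],
      file.path(outDir, "classification.json"), auto_unbox = TRUE, digits = NA)
  } else {
    message("[fcdyn] no annotations: clustering and classification skipped")
  }

  if (!is.null(atlas)) {
    results$profiles <- stage("profiles", buildProfiles(results$wfc, atlas))
    utils::write.csv(results$profiles@summary,
                     file.path(outDir, "profiles.csv"), row.names = FALSE)
    if (hasAnn && length(unique(annotations$task)) >= 2) {
      results$comparison <- stage("comparison", {
        rwfc <- regionWFC(results$wfc, atlas)
        tasks <- unique(annotations$task)[1:2]
        wa <- subsetTask(rwfc, tasks[1L]); wb <- subsetTask(rwfc, tasks[2L])
        links <- classifyLinks(wa, wb, strongThresh = config$strong_thresh,
                               distThresh = config$dist_thresh)
        degA <- degreeDistributions(rwfc)
        hl <- highlightRegions(degA[degA$task == tasks[1L], ],
                               degA[degA$task == tasks[2L], ],
                               alpha = config$alpha, medLo = config$med_lo,
                               medHi = config$med_hi)
        list(tasks = tasks, links = links, highlights = hl)
      })
      utils::write.csv(results$comparison$links,
                       file.path(outDir, "links.csv"), row.names = FALSE)
      utils::write.csv(results$comparison$highlights,
                       file.path(outDir, "highlights.csv"), row.names = FALSE)
    }
  }
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(results = results, manifest = manifest))
}
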