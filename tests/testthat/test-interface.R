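test_that("recordings round-trip through the TSV + sidecar format", {
  net <- makeNetwork(4, 0.4, seed = 1)
  rec <- simulateFromNetwork(net, duration_s = 2, fs = 200, seed = 2)
  path <- file.path(tempdir(), "rec.tsv")
  writeRecording(rec, path)
  back <- readRecording(path)
  expect_equal(recordingData(back), recordingData(rec), tolerance = 1e-6)
  expect_equal(samplingRate(back), 200)
  expect_equal(channelLabels(back), channelLabels(rec))
  # label-count mismatch and non-finite samples are rejected
  jsonlite::write_json(list(fs = 200, channel_labels = c("a", "b")),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(readRecording(path), "label count")
  jsonlite::write_json(list(channel_labels = letters[1:4]),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(readRecording(path), "fs")
  x <- recordingData(rec); x[2, 5] <- NA
  writeLines(apply(format(x), 1, paste, collapse = "\t"), path)
  jsonlite::write_json(list(fs = 200, channel_labels = channelLabels(rec)),
                       paste0(path, ".json"), auto_unbox = TRUE)
  expect_error(readRecording(path), "ch02")
})

test_that("annotations, atlases and edge lists round-trip", {
  ann <- data.frame(start_s = c(0, 30), end_s = c(30, 60),
                    task = c("a", "b"), stringsAsFactors = FALSE)
  p <- file.path(tempdir(), "ann.tsv")
  writeAnnotations(ann, p)
  expect_equal(readAnnotations(p), ann)
  net <- makeNetwork(5, 0.3, seed = 3)
  ep <- file.path(tempdir(), "edges.csv")
  writeEdgeList(net, ep)
  ed <- read.csv(ep)
  expect_equal(nrow(ed), sum(adjacencyMatrix(net) > 0))
  cfg <- fusionConfig(theta = c(0.1, 0.2, 0.3, 0.4), slope = 5,
                      weight = c(1, 2, 3, 4))
  cp <- file.path(tempdir(), "cfg.json")
  writeFusionConfig(cfg, cp)
  cfg2 <- readFusionConfig(cp)
  expect_equal(cfg2@theta, cfg@theta)
  expect_equal(cfg2@weight, cfg@weight)
})

test_that("the pipeline produces all artifacts, deterministically", {
  nets <- list(A = makeNetwork(5, 0.3, seed = 1),
               B = makeNetwork(5, 0.3, seed = 2),
               C = makeNetwork(5, 0.3, seed = 3))
  plan <- data.frame(task = c("A", "B", "C"), duration_s = c(25, 25, 25))
  ses <- simulateSession(nets, plan, fs = 250, seed = 4)
  atlas <- data.frame(channel = sprintf("ch%02d", 1:5),
                      region = c("R1", "R1", "R2", "R2", "R3"))
  cfg <- pipelineConfig(mvar_order = "auto", max_order = 5, seed = 9)
  out1 <- file.path(tempdir(), "run1")
  out2 <- file.path(tempdir(), "run2")
  res <- suppressMessages(runPipeline(ses, out1, config = cfg, atlas = atlas))
  for (f in c("config.json", "windowed_fc.csv", "fcd.csv", "clustering.json",
              "classification.json", "confusion.csv", "profiles.csv",
              "links.csv", "highlights.csv", "manifest.json"))
    expect_true(file.exists(file.path(out1, f)), info = f)
  man <- jsonlite::fromJSON(file.path(out1, "manifest.json"))
  expect_equal(man$seed, 9)
  expect_equal(man$input$channels, 5)
  expect_true(all(c("windowed_fc", "fcd", "clustering", "classification",
                    "profiles", "comparison") %in% names(man$stages)))
  suppressMessages(runPipeline(ses, out2, config = cfg, atlas = atlas))
  for (f in c("windowed_fc.csv", "fcd.csv", "confusion.csv", "profiles.csv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
})

test_that("without annotations the connectivity stages still run", {
  net <- makeNetwork(4, 0.4, seed = 5)
  rec <- simulateFromNetwork(net, duration_s = 15, fs = 250, seed = 6)
  out <- file.path(tempdir(), "run_noann")
  res <- suppressMessages(runPipeline(rec, out, config = pipelineConfig(max_order = 4)))
  expect_true(file.exists(file.path(out, "fcd.csv")))
  expect_false(file.exists(file.path(out, "classification.json")))
  expect_null(res$results$classification)
})
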