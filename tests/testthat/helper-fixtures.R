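# Shared fixtures, all generated in code.

# A Recording from an explicit matrix (fs low so short fixtures satisfy
# the >1 s invariant).
toy_recording <- function(data, fs = 100) {
  new("Recording", data = data, fs = fs,
      channelLabels = sprintf("ch%02d", seq_len(nrow(data))))
}

# WindowedFC built directly from a list of FC matrices (zero-diagonal),
# tiled in time without overlap so classification folds have no
# adjacency drops unless asked for.
toy_wfc <- function(mats, tasks, windowS = 5, level = "channel") {
  n <- nrow(mats[[1L]])
  starts <- (seq_along(mats) - 1L) * windowS
  new("WindowedFC",
      windows = data.frame(start_s = starts, end_s = starts + windowS,
                           task = tasks, stringsAsFactors = FALSE),
      matrices = mats, nodeLabels = sprintf("ch%02d", seq_len(n)),
      level = level)
}

random_fc <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  diag(m) <- 0
  m
}

# Independent detrend + z-score oracle built on lm().
oracle_standardize <- function(x) {
  t(apply(x, 1L, function(r) {
    res <- stats::residuals(stats::lm(r ~ seq_along(r)))
    s <- stats::sd(res)
    if (s < 1e-12) rep(0, length(r)) else res / s
  }))
}

# Three-task 10-node session at the study's sampling rate, with its
# windowed FC; memoized because two acceptance properties share it.
.acc_env <- new.env(parent = emptyenv())
acc_sessions <- function(nSeeds = 5) {
  key <- paste0("s", nSeeds)
  if (is.null(.acc_env[[key]])) {
    plan <- data.frame(task = c("A", "B", "C"), duration_s = c(60, 60, 60))
    .acc_env[[key]] <- lapply(seq_len(nSeeds), function(s) {
      nets <- list(A = makeNetwork(10, 0.2, seed = 100 + s),
                   B = makeNetwork(10, 0.2, seed = 200 + s),
                   C = makeNetwork(10, 0.2, seed = 300 + s))
      ses <- simulateSession(nets, plan, fs = 1000, seed = 500 + s)
      wfc <- slidingFC(ses)
      list(session = ses, wfc = wfc)
    })
  }
  .acc_env[[key]]
}
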