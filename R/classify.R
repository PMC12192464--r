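#' Task identification by stratified, time-separated cross-validation
#'
#' Learns to identify the cognitive task from a window's FC pattern.
#' Folds are stratified by task AND formed from contiguous time segments
#' per class: each class's time-ordered windows are cut into K contiguous
#' segments and segment f goes to fold f, so train and test windows never
#' interleave in time; training windows whose time span overlaps any test
#' window (sliding-window adjacency across the split boundary) are
#' dropped. Predictions are concatenated across folds into one confusion
#' matrix (metrics are also reported per fold).
#'
#' @param wfc a \linkS4class{WindowedFC}; "mixed" windows are excluded.
#' @param model "rfc" (random forest, 500 trees) or "svm" (RBF kernel,
#'   C = 1, features z-scored on the training fold only).
#' @param K number of folds (every class needs >= K windows).
#' @param seed integer seed (forest bootstrap).
#' @param ntree forest size for "rfc".
#' @return list with accuracy, BAS (macro recall), hamming_loss
#'   (= 1 - accuracy for single-label prediction), mae (on integer-encoded
#'   labels in annotation order; encoding-dependent, see \code{encoding}),
#'   per-class precision, aggregated confusion matrix (rows: true),
#'   per-fold metrics, fold assignment and the label encoding.
#' @export
classifyTasks <- function(wfc, model = c("rfc", "svm"), K = 5L, seed = 1L,
                          ntree = 500L) {
  model <- match.arg(model)
  X <- fcFeatureMatrix(wfc, includeMixed = FALSE)
  task <- attr(X, "task")
  win <- attr(X, "windows")
  classes <- unique(task)  # annotation (first-appearance) order
  counts <- table(factor(task, levels = classes))
  if (any(counts < K))
    stop("class(es) with fewer than K windows: ",
         paste(names(counts)[counts < K], collapse = ", "))
  # contiguous, stratified fold assignment
  fold <- integer(length(task))
  for (cl in classes) {
    idx <- which(task == cl)            # already time-ordered
    cuts <- floor(seq(0, length(idx), length.out = K + 1L))
    for (f in seq_len(K)) fold[idx[(cuts[f] + 1L):cuts[f + 1L]]] <- f
  }
  yTrue <- factor(task, levels = classes)
  yPred <- factor(rep(NA_character_, length(task)), levels = classes)
  perFold <- data.frame()
  for (f in seq_len(K)) {
    test <- which(fold == f)
    train <- which(fold != f)
    # drop training windows time-overlapping any test window
    overlaps <- vapply(train, function(i)
      any(win$start_s[i] < win$end_s[test] - 1e-9 &
          win$end_s[i] > win$start_s[test] + 1e-9), TRUE)
    train <- train[!overlaps]
    if (length(unique(task[train])) < 2L)
      stop("fold ", f, ": fewer than 2 classes left for training")
    if (model == "rfc") {
      fitted <- with_seed(seed + f, randomForest::randomForest(
        x = X[train, , drop = FALSE], y = yTrue[train], ntree = ntree))
      pred <- stats::predict(fitted, X[test, , drop = FALSE])
    } else {
      mu <- colMeans(X[train, , drop = FALSE])
      sdv <- apply(X[train, , drop = FALSE], 2L, stats::sd)
      sdv[sdv < 1e-12] <- 1
      Ztr <- scale(X[train, , drop = FALSE], center = mu, scale = sdv)
      Zte <- scale(X[test, , drop = FALSE], center = mu, scale = sdv)
      fitted <- e1071::svm(x = Ztr, y = yTrue[train], kernel = "radial",
                           cost = 1, scale = FALSE)
      pred <- stats::predict(fitted, Zte)
    }
    yPred[test] <- pred
    perFold <- rbind(perFold, data.frame(
      fold = f, n_test = length(test), n_train = length(train),
      accuracy = mean(pred == yTrue[test]),
      BAS = mean(vapply(intersect(classes, task[test]), function(cl)
        mean(pred[yTrue[test] == cl] == cl), 0))))
  }
  conf <- table(true = yTrue, predicted = yPred)
  acc <- mean(yPred == yTrue)
  recalls <- diag(conf) / pmax(rowSums(conf), 1)
  prec <- diag(conf) / pmax(colSums(conf), 1)
  enc <- stats::setNames(seq_along(classes), classes)
  list(accuracy = acc, BAS = mean(recalls),
       hamming_loss = mean(yPred != yTrue),
       mae = mean(abs(enc[as.character(yPred)] - enc[as.character(yTrue)])),
       precision = stats::setNames(as.numeric(prec), classes),
       confusion = conf, perFold = perFold, fold = fold,
       encoding = enc, windows = win, predicted = yPred, true = yTrue)
}
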