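test_that("pair counts follow the pairwise definitions", {
  pc <- pairCounts(c(0, 0, 1, 1), c(0, 0, 1, 1))
  expect_equal(pc, list(TP = 2, FP = 0, FN = 0, TN = 4))
  # hand enumeration of all 6 pairs for T=[0,0,1,1], Y=[0,1,1,1]
  pc2 <- pairCounts(c(0, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(pc2, list(TP = 1, FP = 1, FN = 2, TN = 2))
  set.seed(1)
  for (i in 1:5) {
    pc3 <- pairCounts(sample(2, 4, TRUE), sample(3, 4, TRUE))
    expect_equal(pc3$TP + pc3$FP + pc3$FN + pc3$TN, 6)
  }
  expect_error(pairCounts(1:3, 1:4), "length")
})

test_that("agreement metrics hit their closed-form values", {
  ident <- clusteringMetrics(c(1, 1, 2, 2, 3), c(1, 1, 2, 2, 3))
  expect_equal(ident$MI, 1)
  expect_equal(ident$FM, 1)
  expect_equal(ident$RI, 1)
  expect_equal(ident$AR, 1)
  expect_equal(ident$accuracy, 1)
  m <- clusteringMetrics(c(0, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(m$FM, 1 / sqrt(6))
  expect_equal(m$RI, 0.5)
  # permuting cluster ids changes nothing pairwise
  m2 <- clusteringMetrics(c(5, 9, 9, 9), c(0, 0, 1, 1))
  expect_equal(m2[c("MI", "FM", "RI", "AR", "accuracy", "BAS")],
               m[c("MI", "FM", "RI", "AR", "accuracy", "BAS")])
  # MI symmetric in its arguments
  set.seed(2)
  a <- sample(3, 30, TRUE); b <- sample(3, 30, TRUE)
  expect_equal(clusteringMetrics(a, b)$MI, clusteringMetrics(b, a)$MI)
})

test_that("adjusted Rand is centred on zero for random labelings", {
  set.seed(3)
  ars <- replicate(100, {
    clusteringMetrics(sample(3, 200, TRUE), sample(3, 200, TRUE))$AR
  })
  expect_lt(abs(mean(ars)), 0.05)
})

test_that("well-separated FC populations are clustered perfectly by both algorithms", {
  set.seed(4)
  A <- random_fc(5, 10); B <- random_fc(5, 20)  # far apart vs sd 0.01 noise
  mats <- lapply(1:20, function(i) {
    base <- if (i <= 10) A else B
    m <- pmin(pmax(base + matrix(rnorm(25, sd = 0.01), 5), 0), 1)
    diag(m) <- 0; m
  })
  wfc <- toy_wfc(mats, tasks = rep(c("a", "b"), each = 10))
  for (alg in c("spectral", "birch")) {
    cl <- clusterWindows(wfc, k = 2, algorithm = alg, seed = 1)
    expect_equal(clusteringMetrics(cl$cluster, cl$task)$RI, 1)
  }
  expect_error(clusterWindows(wfc, k = 30), "exceeds")
})

test_that("t-SNE embeds duplicates together, deterministically", {
  set.seed(5)
  X <- matrix(rnorm(40 * 6), 40)
  X[40, ] <- X[1, ]          # exact duplicate pair
  e1 <- embedTSNE(X, perplexity = 5, seed = 3)
  e2 <- embedTSNE(X, perplexity = 5, seed = 3)
  expect_equal(nrow(e1), 40)
  expect_identical(e1, e2)
  D <- as.matrix(dist(cbind(e1$dim1, e1$dim2)))
  expect_lte(D[1, 40], quantile(D[upper.tri(D)], 0.05))
  expect_error(embedTSNE(X, perplexity = 20), "perplexity")
})

test_that("separable tasks are classified perfectly; hamming = 1 - accuracy", {
  set.seed(6)
  A <- random_fc(5, 30); B <- random_fc(5, 40)
  mats <- lapply(1:30, function(i) {
    base <- if (i <= 15) A else B
    m <- pmin(pmax(base + matrix(rnorm(25, sd = 0.01), 5), 0), 1)
    diag(m) <- 0; m
  })
  wfc <- toy_wfc(mats, tasks = rep(c("a", "b"), each = 15))
  for (model in c("rfc", "svm")) {
    res <- classifyTasks(wfc, model = model, K = 5, seed = 1)
    expect_equal(res$accuracy, 1)
    expect_equal(res$hamming_loss, 0)
    expect_equal(res$mae, 0)
    expect_equal(res$hamming_loss, 1 - res$accuracy)
    # stratification: each fold's class counts within 1 of balance
    tab <- table(res$fold, attr(fcFeatureMatrix(wfc), "task"))
    expect_true(all(abs(tab - 3) <= 1))
  }
  expect_error(classifyTasks(toy_wfc(mats[1:16], rep(c("a", "b"), c(15, 1))),
                             K = 5), "fewer than K")
})

test_that("aggregated metrics track mean per-fold metrics on balanced data", {
  set.seed(7)
  A <- random_fc(4, 50); B <- random_fc(4, 60)
  mats <- lapply(1:40, function(i) {
    base <- if (i <= 20) A else B
    m <- pmin(pmax(base + matrix(rnorm(16, sd = 0.15), 4), 0), 1)
    diag(m) <- 0; m
  })
  wfc <- toy_wfc(mats, tasks = rep(c("a", "b"), each = 20))
  res <- classifyTasks(wfc, model = "rfc", K = 5, seed = 2)
  expect_lt(abs(res$accuracy - mean(res$perFold$accuracy)), 0.05)
  expect_lt(abs(res$BAS - mean(res$perFold$BAS)), 0.05)
})

test_that("hamming loss for mismatched labels counts disagreements", {
  set.seed(8)
  mats <- lapply(1:20, function(i) random_fc(4, 70 + i))
  wfc <- toy_wfc(mats, tasks = rep(c("a", "b"), 10))
  res <- classifyTasks(wfc, model = "rfc", K = 5, seed = 3)
  expect_equal(res$hamming_loss, 1 - res$accuracy)
  expect_equal(sum(res$confusion), 20)
  expect_equal(rowSums(res$confusion), c(a = 10, b = 10))
})
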