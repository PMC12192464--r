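test_that("BCorrU captures perfect correlation regardless of sign and matches the direct formula", {
  set.seed(1)
  x1 <- rnorm(600)
  rec <- toy_recording(rbind(x1, x1, -x1, rnorm(600)))
  m <- connValues(bcorrU(rec))
  expect_equal(m[1, 2], 1)
  expect_equal(m[1, 3], 1)       # absolute value: sign-invariant
  expect_true(all(diag(m) == 0))
  expect_equal(m, t(m))
  # independent white noise stays near zero and equals the direct
  # Pearson formula on independently standardized signals
  set.seed(7)
  y <- matrix(rnorm(2 * 5000), 2)
  mi <- connValues(bcorrU(toy_recording(y)))
  expect_lt(mi[1, 2], 0.05)
  oracle <- abs(cor(t(oracle_standardize(y))))
  expect_equal(mi[1, 2], oracle[1, 2], tolerance = 1e-10)
})

test_that("a zero-variance channel is zeroed with a warning", {
  set.seed(2)
  rec <- toy_recording(rbind(rnorm(300), rep(1, 300), rnorm(300)))
  expect_warning(m <- connValues(bcorrU(rec)), "zero-variance")
  expect_true(all(m[2, ] == 0) && all(m[, 2] == 0))
})

test_that("BCorrD assigns the direction of a lagged coupling and zeroes the loser", {
  set.seed(3)
  x1 <- rnorm(5000)
  x2 <- 0.9 * c(rep(0, 3), x1[1:4997]) + 0.1 * rnorm(5000)
  rec <- toy_recording(rbind(x1, x2))
  m <- connValues(bcorrD(rec, maxLag = 10))
  expect_gt(m[1, 2], 0.5)
  expect_equal(m[2, 1], 0)
  # oracle: exhaustive lagged-correlation scan on independently
  # standardized signals
  z <- oracle_standardize(rbind(x1, x2))
  best <- max(sapply(1:10, function(tau)
    abs(cor(z[1, 1:(5000 - tau)], z[2, (tau + 1):5000]))))
  expect_equal(m[1, 2], best, tolerance = 1e-10)
})

test_that("BCorrD stays small for independent channels", {
  for (seed in 1:5) {
    set.seed(seed)
    rec <- toy_recording(matrix(rnorm(2 * 5000), 2))
    m <- connValues(bcorrD(rec, maxLag = 100))
    expect_lt(max(m), 0.08)
  }
})

test_that("correlation measures are permutation-equivariant and scale-invariant", {
  set.seed(4)
  x <- matrix(rnorm(4 * 1000), 4)
  x[2, ] <- x[2, ] + 0.5 * c(0, x[1, -1000])
  rec <- toy_recording(x)
  perm <- c(3, 1, 4, 2)
  recP <- toy_recording(x[perm, ])
  for (fn in list(function(r) connValues(bcorrU(r)),
                  function(r) connValues(bcorrD(r, maxLag = 5)))) {
    expect_equal(unname(fn(recP)), unname(fn(rec)[perm, perm]), tolerance = 1e-12)
  }
  scaled <- x; scaled[1, ] <- 100 * scaled[1, ]
  recS <- toy_recording(scaled)
  expect_equal(connValues(bcorrU(recS)), connValues(bcorrU(rec)), tolerance = 1e-10)
  expect_equal(connValues(bcorrD(recS, maxLag = 5)),
               connValues(bcorrD(rec, maxLag = 5)), tolerance = 1e-10)
  # PDC after refitting the model on the scaled data
  p1 <- connValues(pdc(fitMVAR(rec, order = 2), band = c(1, 40)))
  p2 <- connValues(pdc(fitMVAR(recS, order = 2), band = c(1, 40)))
  expect_equal(p1, p2, tolerance = 1e-8)
})

test_that("MVAR fit of white noise has near-zero coefficients", {
  set.seed(5)
  rec <- toy_recording(matrix(rnorm(3 * 20000), 3), fs = 1000)
  A <- mvarCoeffs(fitMVAR(rec, order = 1))[[1]]
  expect_lt(max(abs(A)), 0.03)
})

test_that("COH1 vanishes for uncoupled channels and is bounded", {
  model <- spectralModel(diag(0.5, 3), fs = 1000)
  m <- connValues(coh1(model, band = c(1, 45)))
  expect_lt(max(m), 1e-8)
  set.seed(6)
  a <- matrix(c(0.5, 0.3, 0, 0.5), 2, 2)
  m2 <- connValues(coh1(spectralModel(a, fs = 1000)))
  expect_true(all(m2 >= 0 & m2 <= 1))
  expect_equal(m2, t(m2))
})

test_that("model-based coherence agrees with a nonparametric Welch estimate", {
  a <- matrix(c(0.5, 0.3, 0, 0.5), 2, 2)       # edge 1 -> 2 in signal space
  net <- groundTruthNetwork(matrix(c(0, 0.3, 0, 0), 2, 2, byrow = TRUE))
  rec <- simulateFromNetwork(net, duration_s = 50, fs = 1000, seed = 9)
  model <- fitMVAR(rec, order = 1)
  est <- connValues(coh1(model, band = c(1, 45), nFreqs = 64))[1, 2]
  sp <- stats::spec.pgram(stats::ts(t(recordingData(rec)), frequency = 1000),
                          spans = c(101, 101), taper = 0.1, plot = FALSE,
                          detrend = TRUE)
  inband <- sp$freq >= 1 & sp$freq <= 45
  welch <- mean(sqrt(sp$coh[inband, 1]))       # $coh is squared coherency
  expect_lt(abs(est - welch), 0.05)
})

test_that("PDC is zero without coupling and directed with it", {
  m0 <- connValues(pdc(spectralModel(diag(0.5, 3), fs = 1000)))
  expect_lt(max(m0), 1e-10)
  a <- matrix(c(0.5, 0.3, 0, 0.5), 2, 2)
  m <- connValues(pdc(spectralModel(a, fs = 1000)))
  expect_gt(m[1, 2], 0.1)   # source row 1 -> target column 2
  expect_equal(m[2, 1], 0)
})

test_that("directed measures rank true edges above absent edges (AUC >= 0.85)", {
  aucs <- sapply(1:10, function(seed) {
    net <- makeNetwork(10, density = 0.2, weightRange = c(0.4, 0.4),
                       seed = 400 + seed)
    rec <- simulateFromNetwork(net, duration_s = 20, fs = 1000,
                               seed = 600 + seed)
    model <- fitMVAR(rec, order = "auto", maxOrder = 5)
    c(bcorrd = edgeAUC(bcorrD(rec), net),
      pdc = edgeAUC(pdc(model), net))
  })
  expect_gte(mean(aucs["bcorrd", ]), 0.85)
  expect_gte(mean(aucs["pdc", ]), 0.85)
})
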