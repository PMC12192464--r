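test_that("region mapping takes the maximum link and is idempotent under duplication", {
  fc <- matrix(c(0, 0.3, 0.2,
                 0.1, 0, 0.7,
                 0.4, 0.5, 0), 3, 3, byrow = TRUE,
               dimnames = list(c("c1", "c2", "c3"), c("c1", "c2", "c3")))
  atlas <- data.frame(channel = c("c1", "c2", "c3"),
                      region = c("A", "A", "B"))
  rg <- toRegionGraph(fc, atlas)
  expect_equal(regionNames(rg), c("A", "B"))
  expect_equal(connValues(rg)[["A", "B"]], 0.7)  # max(0.2, 0.7)
  expect_equal(connValues(rg)[["B", "A"]], 0.5)  # max(0.4, 0.5)
  # one channel per region: region matrix equals channel matrix
  atlas1 <- data.frame(channel = c("c1", "c2", "c3"),
                       region = c("R1", "R2", "R3"))
  expect_equal(unname(connValues(toRegionGraph(fc, atlas1))), unname(fc))
  # duplicating a channel inside its region changes nothing
  fc4 <- rbind(cbind(fc, fc[, 2]), c(fc[2, ], 0))
  dimnames(fc4) <- list(c("c1", "c2", "c3", "c2b"), c("c1", "c2", "c3", "c2b"))
  atlas4 <- rbind(atlas, data.frame(channel = "c2b", region = "A"))
  expect_equal(connValues(toRegionGraph(fc4, atlas4)), connValues(rg))
  # symmetric in -> symmetric out
  sym <- (fc + t(fc)) / 2; diag(sym) <- 0
  rgs <- connValues(toRegionGraph(sym, atlas))
  expect_equal(rgs, t(rgs))
  expect_error(toRegionGraph(fc, atlas[1:2, ]), "unmapped")
})

test_that("degree centrality is weighted strength over the possible maximum", {
  m <- matrix(0, 3, 3); m[1, 2] <- 0.6; m[3, 2] <- 0.4
  deg <- degreeCentrality(m)
  expect_equal(deg$in_degree[2], 0.5)      # (0.6 + 0.4) / 2
  expect_equal(deg$out_degree[2], 0)
  sat <- matrix(1, 4, 4); diag(sat) <- 0
  expect_equal(degreeCentrality(sat)$in_degree, rep(1, 4))
  expect_equal(degreeCentrality(diag(0, 3))$in_degree, rep(0, 3))
})

test_that("closeness matches hand-computed chains, stars and empty graphs", {
  chain <- matrix(0, 3, 3); chain[1, 2] <- 1; chain[2, 3] <- 1   # a->b->c
  expect_equal(unname(closenessCentrality(chain, "in")[3]), 2 / 3)
  star <- matrix(0, 4, 4); star[1, 2:4] <- 1
  expect_equal(unname(closenessCentrality(star, "out")[1]), 1)
  expect_equal(unname(closenessCentrality(matrix(0, 3, 3), "in")), rep(0, 3))
})

test_that("betweenness matches hand cases", {
  chain <- matrix(0, 3, 3); chain[1, 2] <- 1; chain[2, 3] <- 1
  expect_equal(unname(betweennessCentrality(chain, normalized = FALSE)[2]), 1)
  expect_equal(unname(betweennessCentrality(chain)[2]), 1 / 2)
  full <- matrix(0.5, 4, 4); diag(full) <- 0
  expect_equal(unname(betweennessCentrality(full)), rep(0, 4))
})

test_that("path centralities equal brute-force enumeration on random digraphs", {
  for (seed in 1:3) {
    set.seed(seed)
    for (g in 1:7) {
      m <- matrix(0, 5, 5)
      edges <- sample(20, 8)
      off <- which(row(m) != col(m))
      m[off[edges]] <- runif(8, 0.2, 1)
      expect_equal(unname(betweennessCentrality(m, normalized = FALSE)),
                   brute_betweenness(m), tolerance = 1e-9)
      expect_equal(unname(closenessCentrality(m, "in")),
                   brute_closeness(m, "in"), tolerance = 1e-9)
      expect_equal(unname(closenessCentrality(m, "out")),
                   brute_closeness(m, "out"), tolerance = 1e-9)
    }
  }
})

test_that("Katz centrality solves the linear system and handles the empty graph", {
  m <- matrix(0, 2, 2); m[1, 2] <- 1
  x <- katzCentrality(m, "in", alpha = 0.1, rescale = FALSE)
  expect_equal(unname(x), c(1, 1.1))
  expect_equal(unname(katzCentrality(matrix(0, 4, 4), "in")), rep(1, 4))
  # Neumann-series oracle on random graphs
  for (seed in 4:6) {
    set.seed(seed)
    m <- matrix(runif(36, 0, 0.8), 6); diag(m) <- 0
    lmax <- max(Mod(eigen(m, only.values = TRUE)$values))
    alpha <- 0.9 / lmax
    series <- rep(1, 6)
    term <- rep(1, 6)
    for (k in 1:500) { term <- alpha * t(m) %*% term; series <- series + term }
    expect_equal(unname(katzCentrality(m, "in", rescale = FALSE)),
                 as.numeric(series), tolerance = 1e-10)
  }
})

test_that("centralities are invariant under node relabeling", {
  set.seed(9)
  m <- matrix(runif(25) * (runif(25) < 0.5), 5); diag(m) <- 0
  perm <- sample(5)
  mp <- m[perm, perm]
  expect_equal(unname(betweennessCentrality(mp)),
               unname(betweennessCentrality(m))[perm])
  expect_equal(unname(closenessCentrality(mp, "in")),
               unname(closenessCentrality(m, "in"))[perm])
  expect_equal(unname(katzCentrality(mp, "out")),
               unname(katzCentrality(m, "out"))[perm])
})

test_that("profiles summarize the seven metrics per region and task in [0, 1]", {
  set.seed(10)
  mats <- lapply(1:6, function(i) random_fc(4, 900 + i))
  wfc <- toy_wfc(mats, tasks = rep(c("a", "b"), each = 3))
  atlas <- data.frame(channel = sprintf("ch%02d", 1:4),
                      region = c("R1", "R1", "R2", "R3"))
  prof <- buildProfiles(wfc, atlas)
  s <- prof@summary
  expect_setequal(unique(s$metric),
                  c("in_d", "out_d", "in_cl", "out_cl", "btn", "in_K", "out_K"))
  expect_setequal(unique(s$region), c("R1", "R2", "R3"))
  expect_true(all(s$median >= 0 & s$median <= 1))
  expect_true(all(s$q25 <= s$median & s$median <= s$q75))
  # independent recomputation of one cell's median
  vals <- sapply(1:3, function(k) {
    m <- mats[[k]]; dimnames(m) <- list(wfc@nodeLabels, wfc@nodeLabels)
    rg <- toRegionGraph(m, atlas)
    degreeCentrality(connValues(rg))$in_degree[2]   # region R2, task a
  })
  cell <- s[s$region == "R2" & s$task == "a" & s$metric == "in_d", ]
  expect_equal(cell$median, median(vals))
  # single-window task -> median equals the value, zero IQR width
  w1 <- toy_wfc(mats[1], tasks = "solo")
  p1 <- buildProfiles(w1, atlas)@summary
  expect_true(all(p1$q25 == p1$median & p1$q75 == p1$median))
})
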