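# Region-level WindowedFC whose single link (A -> B) has prescribed
# per-window weights.
link_wfc <- function(weights, task = "t") {
  mats <- lapply(weights, function(w) {
    m <- matrix(0, 2, 2, dimnames = list(c("A", "B"), c("A", "B")))
    m[1, 2] <- w
    m
  })
  wfc <- toy_wfc(mats, tasks = rep(task, length(weights)), level = "region")
  wfc@nodeLabels <- c("A", "B")
  wfc
}

test_that("wasserstein distance has its closed forms and metric axioms", {
  expect_equal(wasserstein1d(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(wasserstein1d(rep(0, 5), rep(1, 5)), 1)
  expect_error(wasserstein1d(numeric(0), 1), "empty")
  set.seed(1)
  for (i in 1:20) {
    a <- runif(8); b <- runif(8)
    # equal-size closed form: mean |difference of sorted samples|
    expect_equal(wasserstein1d(a, b), mean(abs(sort(a) - sort(b))),
                 tolerance = 1e-12)
    # quantile-integration oracle
    qs <- seq(0.0005, 0.9995, by = 0.001)
    expect_equal(wasserstein1d(a, b),
                 mean(abs(quantile(a, qs, type = 1) - quantile(b, qs, type = 1))),
                 tolerance = 1e-3)
    cvec <- runif(sample(3:9, 1))
    expect_equal(wasserstein1d(a, b), wasserstein1d(b, a))
    expect_lte(wasserstein1d(a, b),
               wasserstein1d(a, cvec) + wasserstein1d(cvec, b) + 1e-12)
  }
})

test_that("links are classified by medians, strength and distance", {
  set.seed(2)
  strongA <- link_wfc(rnorm(20, 0.9, 0.01))
  strongA2 <- link_wfc(rnorm(20, 0.9, 0.01))
  weakB <- link_wfc(rnorm(20, 0.1, 0.01))
  expect_equal(classifyLinks(strongA, strongA2)$class[1], "strong_in_both")
  expect_equal(classifyLinks(strongA, weakB)$class[1], "stronger_in_A")
  expect_equal(classifyLinks(weakB, strongA)$class[1], "stronger_in_B")
  expect_equal(classifyLinks(weakB, link_wfc(rnorm(20, 0.12, 0.01)))$class[1],
               "weak")
  # swapping tasks relabels the classes symmetrically
  ab <- classifyLinks(strongA, weakB)
  ba <- classifyLinks(weakB, strongA)
  expect_equal(ab$wasserstein, ba$wasserstein)
  expect_equal(ab$median_A, ba$median_B)
  # a known shift is always detected
  hits <- sapply(1:100, function(s) {
    set.seed(1000 + s)
    wa <- link_wfc(pmin(rnorm(15, 0.85, 0.05), 1))
    wb <- link_wfc(pmax(rnorm(15, 0.45, 0.05), 0))
    classifyLinks(wa, wb)$class[1] == "stronger_in_A"
  })
  expect_true(all(hits))
})

test_that("one-sided Mann-Whitney matches exact enumeration and simulation", {
  # b entirely above a: exact one-sided p = 1 / choose(6, 3) = 0.05
  r <- mannWhitneyOneSided(c(4, 5, 6), c(1, 2, 3), "greater")
  expect_equal(r$p, 0.05)
  expect_equal(r$U, 9)
  same <- mannWhitneyOneSided(c(1, 2, 3), c(1.1, 2.1, 2.9), "greater")
  expect_gt(same$p, 0.4)
  set.seed(3)
  big <- mannWhitneyOneSided(rnorm(50, 0.9, 0.05), rnorm(50, 0.3, 0.05),
                             "greater")
  expect_lt(big$p, 0.001)
  expect_warning(tied <- mannWhitneyOneSided(rep(1, 5), rep(1, 5)), "tied")
  expect_equal(tied$p, 1)
})

test_that("region highlighting follows the median/p-value rule table", {
  set.seed(4)
  tight <- function(mu, n = 30) pmin(pmax(rnorm(n, mu, 0.005), 0), 1)
  mk <- function(vals) data.frame(region = "R", value = vals)
  hl <- function(a, b, ...) highlightRegions(mk(a), mk(b), ...)$highlight[1]
  # both medians below 0.5 -> excluded (even with a significant shift)
  expect_equal(hl(tight(0.40), tight(0.45)), "excluded")
  expect_equal(hl(tight(0.45), tight(0.20)), "excluded")
  # significant one-sided difference wins over shared levels
  expect_equal(hl(tight(0.90), tight(0.50)), "sig_A")
  expect_equal(hl(tight(0.50), tight(0.90)), "sig_B")
  # no significant difference: very high if both medians > 0.8
  expect_equal(hl(tight(0.90), tight(0.90)), "shared_veryhigh")
  expect_equal(hl(tight(0.85), tight(0.85)), "shared_veryhigh")
  # boundary: median exactly 0.8 is not "> 0.8" (symmetric samples, no
  # significant difference)
  expect_equal(hl(0.8 + seq(-0.001, 0.001, length.out = 31),
                  0.8 + seq(-0.001, 0.001, length.out = 31)), "shared_high")
  # one median high, the other between medLo and medHi, no signif at 0.001
  sameish <- tight(0.55)
  expect_equal(hl(sameish, sameish + rnorm(30, 0, 1e-6)), "shared_high")
  # median exactly 0.5 is included (>= rule); complete separation is
  # significant
  expect_equal(hl(0.5 + seq(0, 0.001, length.out = 31),
                  0.3 + seq(0, 0.001, length.out = 31)), "sig_A")
  # bonferroni flag weakens borderline significance
  a <- tight(0.9); b <- tight(0.6)
  many <- rbind(mk(a), data.frame(region = paste0("R", 1:50),
                                  value = rep(0.1, 50)))
  expect_true(all(c("excluded", "sig_A") %in%
                  highlightRegions(rbind(mk(a),
                                         data.frame(region = "S", value = tight(0.2))),
                                   rbind(mk(b),
                                         data.frame(region = "S", value = tight(0.1))))$highlight))
})

test_that("degree distributions reshape region-level windows per task", {
  set.seed(5)
  wa <- link_wfc(rnorm(5, 0.7, 0.01), task = "a")
  dd <- degreeDistributions(wa, "in_degree")
  expect_equal(nrow(dd), 10)     # 5 windows x 2 regions
  expect_equal(unique(dd$task), "a")
  expect_equal(dd$value[dd$region == "B"],
               sapply(wa@matrices, function(m) m[1, 2]))
})
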