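# Rank-based ROC/AUC, threshold estimation, bootstrap, rank-sum test.

test_that("AUC matches brute-force pair counting", {
  # brute force over all positive-negative pairs
  bruteAuc <- function(s, l) {
    l <- as.logical(l)
    pos <- s[l]; neg <- s[!l]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  expect_equal(aucRank(c(0.2, 0.8, 0.4, 0.6), c(0, 1, 1, 0)), 0.75)
  expect_equal(bruteAuc(c(0.2, 0.8, 0.4, 0.6), c(0, 1, 1, 0)), 0.75)
  set.seed(31)
  for (i in 1:10) {
    s <- round(rnorm(30), 1)     # rounding forces ties
    l <- rbinom(30, 1, 0.4)
    if (sum(l) == 0 || sum(l) == 30) next
    expect_equal(aucRank(s, l), bruteAuc(s, l))
  }
})

test_that("AUC equals the normalized Mann-Whitney U statistic", {
  set.seed(5)
  for (i in 1:8) {
    s <- rnorm(40); l <- rbinom(40, 1, 0.5)
    if (sum(l) %in% c(0, 40)) next
    U <- rankSumTest(s[l == 1], s[l == 0])$statistic
    expect_equal(aucRank(s, l), U / (sum(l) * sum(1 - l)), tolerance = 1e-12)
  }
})

test_that("AUC edge cases behave", {
  expect_identical(aucRank(c(1, 2, 3, 10, 11), c(0, 0, 0, 1, 1)), 1)
  s <- rnorm(20); l <- rbinom(20, 1, 0.5); l[1] <- 0L; l[2] <- 1L
  expect_equal(aucRank(s, l) + aucRank(s, 1 - l), 1)
  expect_error(aucRank(1:5, rep(1, 5)), "both classes")
})

test_that("ROC points are monotone and integrate to the AUC", {
  set.seed(9)
  for (i in 1:6) {
    s <- round(rnorm(50), 1); l <- rbinom(50, 1, 0.4)
    if (sum(l) %in% c(0, 50)) next
    pts <- rocPoints(s, l)
    expect_true(all(diff(pts$fpr) >= 0))
    expect_true(all(diff(pts$tpr) >= 0))
    expect_equal(pts$fpr[1], 0); expect_equal(pts$tpr[1], 0)
    expect_equal(pts$fpr[nrow(pts)], 1); expect_equal(pts$tpr[nrow(pts)], 1)
    expect_equal(somiteCPM:::trapezoidArea(pts), aucRank(s, l),
                 tolerance = 1e-12)
    # rank invariance under a strictly increasing transform
    pts2 <- rocPoints(exp(s), l)
    expect_equal(pts2[c("fpr", "tpr")], pts[c("fpr", "tpr")])
  }
})

test_that("one observation per class gives the three corner points", {
  pts <- rocPoints(c(1, 2), c(0, 1))
  expect_equal(pts$fpr, c(0, 0, 1))
  expect_equal(pts$tpr, c(0, 1, 1))
})

test_that("cross-check against an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  s <- rnorm(60); l <- rbinom(60, 1, 0.5); l[1:2] <- c(0L, 1L)
  ref <- as.numeric(suppressMessages(pROC::auc(l, s, direction = "<")))
  expect_equal(aucRank(s, l), ref, tolerance = 1e-12)
})

test_that("threshold estimate is the gap midpoint for separated classes", {
  s <- c(1.4, 1.8, 2.0, 3.0, 3.4, 4.0)
  l <- c(0, 0, 0, 1, 1, 1)
  expect_equal(thresholdEstimate(s, l), 2.5)
})

test_that("the estimated threshold maximizes Youden's J (scan oracle)", {
  set.seed(21)
  for (i in 1:6) {
    s <- rnorm(40, mean = ifelse(rbinom(40, 1, 0.5) == 1, 1, 0))
    l <- as.integer(s + rnorm(40, sd = 0.6) > 0.5)
    if (sum(l) %in% c(0, 40)) next
    th <- thresholdEstimate(s, l)
    J <- function(c) mean(s[l == 1] > c) - mean(s[l == 0] > c)
    # exhaustive scan: one cut inside every interval between order stats
    ss <- sort(unique(s))
    cuts <- c(ss[1] - 1, (ss[-length(ss)] + ss[-1]) / 2, ss[length(ss)] + 1)
    expect_equal(J(th), max(vapply(cuts, J, numeric(1))), tolerance = 1e-12)
  }
})

test_that("bootstrap CI brackets the point estimate and tightens with n", {
  gen <- function(n, seed) {
    withr::with_seed(seed, {
      s <- c(rnorm(n, 1.5), rnorm(n, 0))
      list(s = s, l = rep(c(1, 0), each = n))
    })
  }
  small <- gen(10, 1); big <- gen(100, 1)
  ciS <- bootstrapCI(small$s, small$l, n = 400L, seed = 2L)
  ciB <- bootstrapCI(big$s, big$l, n = 400L, seed = 2L)
  expect_lt(diff(ciB), diff(ciS))
  expect_gte(aucRank(big$s, big$l), ciB[1])
  expect_lte(aucRank(big$s, big$l), ciB[2])
  # perfectly separated large sample: upper bound is 1
  sep <- c(rnorm(50, 10), rnorm(50, 0))
  lab <- rep(c(1, 0), each = 50)
  expect_identical(bootstrapCI(sep, lab, n = 200L, seed = 1L)[2], 1)
  # reproducibility from the seed
  expect_identical(bootstrapCI(small$s, small$l, n = 200L, seed = 7L),
                   bootstrapCI(small$s, small$l, n = 200L, seed = 7L))
})

test_that("rank-sum test matches exhaustive enumeration and intuition", {
  expect_equal(rankSumTest(1:8, 1:8)$p, 1)
  bruteU <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  set.seed(3)
  for (i in 1:6) {
    a <- sample(1:20, 6, replace = TRUE)
    b <- sample(1:20, 7, replace = TRUE)
    expect_equal(rankSumTest(a, b)$statistic, bruteU(a, b))
  }
  withr::with_seed(4, {
    a <- rnorm(20, 10); b <- rnorm(20, 0)
    expect_lt(rankSumTest(a, b)$p, 0.001)
  })
  expect_error(rankSumTest(numeric(0), 1:3), "non-empty")
})

test_that("Gaussian two-sample AUC approaches the closed form", {
  n <- 2000L
  withr::with_seed(11, {
    pos <- rnorm(n, mean = 1, sd = 1)
    neg <- rnorm(n, mean = 0, sd = 1)
  })
  a <- aucRank(c(pos, neg), rep(c(1, 0), each = n))
  target <- pnorm(1 / sqrt(2))
  se <- sqrt(target * (1 - target) * (1 / n + 1 / n))  # conservative
  expect_lt(abs(a - target), 3 * se)
})

test_that("rocAnalysis bundles a coherent result object", {
  d <- genARDataset(shapePopulationSpec(noiseRate = 0.05), seed = 3L)
  r <- rocAnalysis(d$scores, d$labels, nBoot = 300L, seed = 1L)
  expect_s4_class(r, "RocResult")
  expect_gte(r@auc, r@ci[1] - 1e-12)
  expect_lte(r@auc, r@ci[2] + 1e-12)
  expect_identical(sum(r@n), length(d$scores))
})
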