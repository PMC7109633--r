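# Generators: labelled somite images, division trajectories, score datasets.

test_that("somite images round-trip their aspect ratio", {
  for (ar in c(1, 2, 3)) {
    img <- genSomiteImage(aspectRatio = ar, seed = ar + 1L)
    somitic <- rep(TRUE, nrow(img$comp))
    lab <- labelSomiteClusters(img$grid, somitic)
    expect_identical(length(lab$sizes), 1L)
    sites <- which(lab$clusters == 1L, arr.ind = TRUE)
    measured <- aspectRatio(cbind(x = sites[, 2], y = sites[, 1]))
    expect_lt(abs(measured - ar) / ar, 0.05)
  }
})

test_that("image ground truth matches the morphometric operations exactly", {
  img <- genSomiteImage(aspectRatio = 2, ringCells = 20L, coreCells = 10L,
                        seed = 4L)
  cls <- somiteCPM:::decodeClass(img$cells$class)
  expect_equal(epithelialFraction(cls), img$truth$epiFraction,
               tolerance = 1e-12)
  expect_identical(somitocoelSize(cls)$cells, 10L)
})

test_that("generators are seed-deterministic", {
  a <- genSomiteImage(aspectRatio = 1.5, seed = 9L)
  b <- genSomiteImage(aspectRatio = 1.5, seed = 9L)
  c <- genSomiteImage(aspectRatio = 1.5, seed = 10L)
  expect_identical(a$grid, b$grid)
  expect_false(identical(a$grid, c$grid))

  d1 <- genARDataset(seed = 5L); d2 <- genARDataset(seed = 5L)
  expect_identical(d1, d2)

  t1 <- genDivisionTrajectory(seed = 2L); t2 <- genDivisionTrajectory(seed = 2L)
  expect_identical(t1$trajectory@snapshots[[1]]$grid,
                   t2$trajectory@snapshots[[1]]$grid)
})

test_that("zero-noise datasets are perfectly separable at the true cut", {
  d <- genARDataset(shapePopulationSpec(noiseRate = 0), seed = 1L)
  expect_identical(aucRank(d$scores, d$labels), 1)
  th <- thresholdEstimate(d$scores, d$labels)
  expect_lt(abs(th - d$truth$threshold) / d$truth$threshold, 0.1)
})

test_that("threshold recovery holds across generative cuts", {
  for (tau in c(2.0, 2.5, 3.0)) {
    spec <- shapePopulationSpec(threshold = tau, noiseRate = 0)
    d <- genARDataset(spec, seed = 11L)
    th <- thresholdEstimate(d$scores, d$labels)
    expect_lt(abs(th - tau) / tau, 0.1)
  }
})

test_that("label noise lowers the AUC as expected", {
  d0 <- genARDataset(shapePopulationSpec(noiseRate = 0), seed = 2L)
  d2 <- genARDataset(shapePopulationSpec(noiseRate = 0.2), seed = 2L)
  expect_gt(aucRank(d0$scores, d0$labels), aucRank(d2$scores, d2$labels))
})

test_that("population spec validity is enforced", {
  expect_error(shapePopulationSpec(nControl = 0L), "counts")
  expect_error(shapePopulationSpec(noiseRate = 0.7), "noiseRate")
})
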