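# Shape metrics, cluster labelling and division detection.

test_that("aspect ratio matches continuum values for simple shapes", {
  # solid axis-aligned rectangle: population moments give ~ a/b
  rect <- expand.grid(x = 1:40, y = 1:10)
  expect_lt(abs(aspectRatio(rect) - 4), 0.02)

  # rotation invariance (continuous rotation of the same site set)
  th <- 30 * pi / 180
  rot <- cbind(x = rect$x * cos(th) - rect$y * sin(th),
               y = rect$x * sin(th) + rect$y * cos(th))
  expect_lt(abs(aspectRatio(rot) - 4), 0.05)

  # solid disk is isotropic
  disk <- expand.grid(x = -20:20, y = -20:20)
  disk <- disk[disk$x^2 + disk$y^2 <= 400, ]
  expect_lt(abs(aspectRatio(disk) - 1), 0.05)
})

test_that("aspect ratio is invariant under translation, permutation, scale", {
  set.seed(7)
  pts <- cbind(x = rnorm(200, sd = 3), y = rnorm(200, sd = 1.3))
  a0 <- aspectRatio(pts)
  expect_equal(aspectRatio(sweep(pts, 2, c(100, -50), "+")), a0)
  expect_equal(aspectRatio(pts[sample(nrow(pts)), ]), a0)
  expect_equal(aspectRatio(pts * 7.3), a0, tolerance = 1e-12)
  expect_gte(a0, 1)
})

test_that("degenerate site sets raise errors", {
  expect_error(aspectRatio(cbind(1, 1)), "degenerate")
  expect_error(aspectRatio(cbind(1:10, 2 * (1:10) + 5)), "collinear")
})

test_that("cluster labelling separates blobs and filters specks", {
  g <- matrix(0L, 20, 30)
  g[3:8, 3:8] <- 1L        # blob A
  g[12:17, 20:26] <- 2L    # blob B, far away
  g[1, 15] <- 3L           # speck below minimum size
  somitic <- c(TRUE, TRUE, TRUE)
  lab <- labelSomiteClusters(g, somitic, minSize = 5L)
  expect_identical(length(lab$sizes), 2L)
  expect_setequal(lab$sizes, c(36L, 42L))
  expect_identical(sum(lab$clusters[1, ] > 0), 0L)

  # background classes are ignored
  lab2 <- labelSomiteClusters(g, c(TRUE, FALSE, FALSE), minSize = 5L)
  expect_identical(length(lab2$sizes), 1L)

  # diagonal touching joins components (8-connectivity)
  g2 <- matrix(0L, 10, 10)
  g2[2:4, 2:4] <- 1L; g2[5:7, 5:7] <- 2L
  lab3 <- labelSomiteClusters(g2, c(TRUE, TRUE), minSize = 5L)
  expect_identical(length(lab3$sizes), 1L)
})

test_that("epithelial fraction and somitocoel size count cells", {
  cls <- c(rep("epithelial", 24), rep("mesenchymal", 12))
  expect_equal(epithelialFraction(cls), 2 / 3, tolerance = 1e-12)
  expect_identical(epithelialFraction(rep("epithelial", 5)), 1)
  expect_error(epithelialFraction(character(0)), "empty")
  # fractions of the two classes always sum to one
  expect_equal(epithelialFraction(cls) +
               somitocoelSize(cls)$cells / (24 + 12), 1)
  expect_identical(somitocoelSize(cls)$cells, 12L)
  expect_identical(somitocoelSize(rep("epithelial", 4))$cells, 0L)
})

test_that("MET shifts the epithelial fraction by exactly one cell", {
  m <- metFixture()
  m@cells$streak[2] <- 600L
  cls0 <- cellTable(m)$class
  m2 <- executeMet(m, 2L)
  cls1 <- cellTable(m2)$class
  expect_equal(epithelialFraction(cls1) - epithelialFraction(cls0),
               1 / 2, tolerance = 1e-12)  # 1/2 -> 2/2 in this 2-cell fixture
})

test_that("scripted division trajectories are detected at the right frame", {
  fx <- genDivisionTrajectory(frames = 30L, splitFrame = 15L, seed = 1L)
  ev <- detectDivision(fx$trajectory)
  expect_identical(nrow(ev), 1L)
  expect_lte(abs(ev$mcs - fx$truth$splitMcs), 500)
  expect_gte(ev$daughters, 2)

  # no-split control
  fx0 <- genDivisionTrajectory(frames = 30L, split = FALSE, seed = 1L)
  expect_identical(nrow(detectDivision(fx0$trajectory)), 0L)

  # strongly unequal daughters still count
  fx3 <- genDivisionTrajectory(frames = 30L, splitFrame = 15L,
                               sizes = c(1, 3), seed = 2L)
  expect_identical(nrow(detectDivision(fx3$trajectory)), 1L)
})

test_that("a transient one-frame split does not count as division", {
  # mother everywhere, except exactly one frame showing two daughters
  fx <- genDivisionTrajectory(frames = 30L, splitFrame = 15L, seed = 1L)
  mother <- fx$trajectory@snapshots[[1]]
  daughters <- fx$trajectory@snapshots[[20]]
  snaps <- lapply(seq_len(30L), function(i) {
    s <- if (i == 15L) daughters else mother
    s$mcs <- (i - 1) * 500
    s
  })
  tr <- fx$trajectory
  tr@snapshots <- snaps
  expect_identical(nrow(detectDivision(tr)), 0L)
})

test_that("midline force and stress follow linear elasticity", {
  r <- midlineForceStress(0.23)
  expect_equal(r$stress, 552)
  expect_equal(r$force, 552 * 84 * 200 * 1e-6)  # ~9.27 uN
  expect_identical(midlineForceStress(0)$force, 0)
  r2 <- midlineForceStress(0.46)
  expect_equal(r2$stress, 2 * r$stress)
  expect_equal(r2$force, 2 * r$force)
  expect_error(midlineForceStress(0.2, stiffness = -1), "positive")
})
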