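# Hamiltonian, Metropolis dynamics and spring bookkeeping.

test_that("total energy matches hand-computed cases", {
  # single compartment filling the interior, no springs, area at target
  g <- matrix(1L, 6, 6)
  m <- makeModel(g, cellOf = 1L, roleOf = "body", classOf = "mesenchymal",
                 params = simpleParams(lambdaA = 2))
  expect_equal(totalEnergy(m), 0)

  # two 2x2 compartments side by side on a 4x2 grid, J = 1 between them,
  # first-order neighbours only would give 2 heterotypic pairs; with the
  # engine's 8-neighbourhood the brute-force count adds the two diagonals
  g <- matrix(0L, 2, 4)
  g[, 1:2] <- 1L; g[, 3:4] <- 2L
  J <- matrix(0, 6, 6); J[2, 2] <- 1  # mesenchymal-mesenchymal
  m <- makeModel(g, cellOf = c(1L, 2L), roleOf = c("body", "body"),
                 classOf = c("mesenchymal", "mesenchymal"),
                 params = simpleParams(J = J, Jintra = 0, lambdaA = 0))
  # brute force over all unordered in-grid neighbour pairs (orders 1+2)
  brute <- 0
  for (y in 1:2) for (x in 1:4)
    for (d in list(c(0, 1), c(1, 0), c(1, 1), c(-1, 1))) {
      ny <- y + d[1]; nx <- x + d[2]
      if (ny < 1 || ny > 2 || nx < 1 || nx > 4) next
      if (g[y, x] != g[ny, nx]) brute <- brute + 1
    }
  expect_equal(totalEnergy(m), brute)
  expect_equal(brute, 4)  # 2 first-order + 2 diagonal pairs

  # one spring with rest 3, length 5, k = 2 -> 1/2*2*(5-3)^2 = 4
  g <- matrix(0L, 3, 7)
  g[2, 1] <- 1L; g[2, 6] <- 2L
  spr <- springRow(1L, 2L, rest = 3, k = 2)
  m <- makeModel(g, cellOf = c(1L, 2L), roleOf = c("body", "body"),
                 classOf = c("mesenchymal", "mesenchymal"), springs = spr,
                 params = simpleParams(J = matrix(0, 6, 6), Jintra = 0,
                                       lambdaA = 0))
  expect_equal(totalEnergy(m), 4)
})

test_that("total energy agrees with the independent R oracle", {
  for (seed in 1:8) {
    m <- randomModel(seed)
    expect_equal(totalEnergy(m), oracleEnergy(m), tolerance = 1e-12)
  }
})

test_that("delta energy equals full recomputation on random attempts", {
  worst <- 0
  nOk <- 0
  for (seed in 1:25) {
    m <- randomModel(seed)
    W <- ncol(m@grid); H <- nrow(m@grid)
    set.seed(1000 + seed)
    # sample copy attempts at label boundaries, where the move is real
    g <- m@grid
    inner <- expand.grid(x = 2:(W - 1), y = 2:(H - 1))
    onBd <- with(inner, g[cbind(y, x)] != g[cbind(y, x + 1)] |
                        g[cbind(y, x)] != g[cbind(y, x - 1)] |
                        g[cbind(y, x)] != g[cbind(y + 1, x)] |
                        g[cbind(y, x)] != g[cbind(y - 1, x)])
    bd <- inner[onBd, ]
    for (i in 1:60) {
      p <- bd[sample(nrow(bd), 1), ]
      x <- p$x; y <- p$y
      dxs <- c(1, -1, 0, 0); dys <- c(0, 0, 1, -1)
      differs <- which(g[cbind(y + dys, x + dxs)] != g[y, x])
      d <- differs[sample(length(differs), 1)]
      nx <- x + dxs[d]; ny <- y + dys[d]
      s <- m@grid[ny, nx]; t <- m@grid[y, x]
      res <- deltaEnergy(m, c(x, y), s)
      if (s == t) {
        expect_identical(res$status, "noop")
        expect_equal(res$delta, 0)
        next
      }
      if (t > 0 && m@comp$area[t] == 1L) {
        expect_identical(res$status, "forbidden")
        next
      }
      m2 <- applyCopyRescan(m, x, y, s)
      full <- oracleEnergy(m2) - oracleEnergy(m)
      worst <- max(worst, abs(res$delta - full))
      nOk <- nOk + 1
    }
  }
  expect_gte(nOk, 1000)
  expect_lt(worst, 1e-9)
})

test_that("no-op and extinction-guard attempts are signalled", {
  g <- matrix(1L, 5, 5); g[3, 3] <- 2L
  m <- makeModel(g, cellOf = c(1L, 2L), roleOf = c("body", "body"),
                 classOf = c("mesenchymal", "mesenchymal"))
  expect_identical(deltaEnergy(m, c(2, 2), 1L)$status, "noop")
  # copying label 1 over the single remaining site of label 2 is forbidden
  expect_identical(deltaEnergy(m, c(3, 3), 1L)$status, "forbidden")
})

test_that("unregistered grid labels raise an integrity error", {
  g <- matrix(1L, 5, 5); g[2, 2] <- 7L
  m <- makeModel(matrix(1L, 5, 5), cellOf = 1L, roleOf = "body",
                 classOf = "mesenchymal")
  m@grid <- g
  expect_error(totalEnergy(m), "unregistered label")
})

test_that("Metropolis acceptance matches exp(-dH/T) for a fixed attempt", {
  # areas at target; J = 0; copying shrinks one compartment and grows the
  # other, so dH = lambda * 2 exactly
  g <- matrix(0L, 6, 6)
  g[2:5, 2:3] <- 1L; g[2:5, 4:5] <- 2L
  m <- makeModel(g, cellOf = c(1L, 2L), roleOf = c("body", "body"),
                 classOf = c("mesenchymal", "mesenchymal"),
                 params = simpleParams(J = matrix(0, 6, 6), Jintra = 0,
                                       lambdaA = 1, temp = 2))
  res <- acceptanceTrials(m, c(4, 3), 1L, n = 40000L, seed = 11L)
  expect_equal(res$delta, 2)
  pHat <- res$accepted / res$trials
  pTrue <- exp(-2 / 2)
  se <- sqrt(pTrue * (1 - pTrue) / res$trials)
  expect_lt(abs(pHat - pTrue), 3 * se)
})

test_that("energy-decreasing attempts are always accepted at T -> 0", {
  g <- matrix(0L, 6, 6)
  g[2:5, 2:3] <- 1L; g[2:5, 4:5] <- 2L
  m <- makeModel(g, cellOf = c(1L, 2L), roleOf = c("body", "body"),
                 classOf = c("mesenchymal", "mesenchymal"),
                 params = simpleParams(J = matrix(0, 6, 6), Jintra = 0,
                                       lambdaA = 1, temp = 1e-9))
  # uphill move: never accepted at vanishing temperature
  res <- acceptanceTrials(m, c(4, 3), 1L, n = 5000L, seed = 3L)
  expect_identical(res$accepted, 0L)
})

test_that("somitic cell count is conserved and bookkeeping stays exact", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 4L)
  before <- cellCounts(m)
  r <- metropolisMCS(m, 300L, seed = 9L)
  after <- cellCounts(r$model)
  expect_identical(after$somitic, before$somitic)
  expect_identical(after$mesenchymal, before$mesenchymal)
  expect_identical(after$epithelial, before$epithelial)
  # incremental areas and centroid sums equal a full rescan
  expect_identical(nrow(validateConfiguration(r$model)), 0L)
})

test_that("identical seeds give bit-identical trajectories", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 2L)
  a <- metropolisMCS(m, 60L, seed = 42L)
  b <- metropolisMCS(m, 60L, seed = 42L)
  c <- metropolisMCS(m, 60L, seed = 43L)
  expect_identical(a$model@grid, b$model@grid)
  expect_identical(a$accepted, b$accepted)
  expect_false(identical(a$model@grid, c$model@grid))
})

test_that("over-extended junction springs snap permanently", {
  g <- matrix(0L, 3, 12)
  g[2, 1:2] <- 1L; g[2, 8:9] <- 2L  # centroids 7 apart
  spr <- rbind(
    springRow(1L, 2L, rest = 3, k = 1, snap = 6, kind = "junction"),
    springRow(1L, 2L, rest = 3, k = 1, snap = Inf, kind = "cytoskeleton"))
  m <- makeModel(g, cellOf = c(1L, 2L), roleOf = c("apical", "apical"),
                 classOf = c("epithelial", "epithelial"), springs = spr)
  r <- updateSprings(m)
  expect_identical(r$snapped, 1L)
  expect_false(r$model@springs$alive[1])
  expect_true(r$model@springs$alive[2])
  # removal is permanent: a second update reports nothing new
  r2 <- updateSprings(r$model)
  expect_length(r2$snapped, 0)
})

test_that("springs below threshold are left alone", {
  g <- matrix(0L, 3, 12)
  g[2, 1:2] <- 1L; g[2, 4:5] <- 2L
  spr <- springRow(1L, 2L, rest = 3, k = 1, snap = 6, kind = "junction")
  m <- makeModel(g, cellOf = c(1L, 2L), roleOf = c("apical", "apical"),
                 classOf = c("epithelial", "epithelial"), springs = spr)
  r <- updateSprings(m)
  expect_length(r$snapped, 0)
  expect_identical(r$model@springs$alive, TRUE)
})

test_that("snapped-junction count is non-decreasing under a scripted pull", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 1L)
  proto <- protocolForStrain(m, 0.7, totalMcs = 6000L, pullStart = 500L,
                             pullEnd = 4500L)
  tr <- runExperiment(m, proto, "none", seed = 1L)
  snaps <- tr@events[tr@events$event == "snap", ]
  expect_true(!is.unsorted(snaps$mcs))
  expect_identical(sum(!tr@finalModel@springs$alive), nrow(snaps))
})
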