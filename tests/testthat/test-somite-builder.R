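# Initial-configuration construction and validation.

test_that("the built somite satisfies every structural invariant", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 1L)
  expect_identical(nrow(validateConfiguration(m)), 0L)

  cc <- cellCounts(m)
  expect_identical(cc$epithelial, 24L)
  expect_identical(cc$mesenchymal, 12L)
  expect_equal(cc$epithelial / cc$somitic, 24 / 36, tolerance = 1e-12)

  # apical junction graph is one closed cycle over all 24 ring cells
  jg <- junctionGraph(m)
  expect_true(jg$isSingleCycle)
  expect_identical(nrow(jg$edges), 24L)
})

test_that("ring cells are radially polarized at build time", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 2L)
  comp <- m@comp
  ctr <- m@meta$center
  epi <- m@cells$id[m@cells$class == somiteCPM:::CLASS_CODES[["epithelial"]]]
  for (cid in epi) {
    mine <- comp[comp$cell == cid, ]
    d <- sqrt((mine$sumx / mine$area - ctr[1])^2 +
              (mine$sumy / mine$area - ctr[2])^2)
    names(d) <- somiteCPM:::decodeRole(mine$role)
    expect_lt(d[["apical"]], d[["basal"]])
  }
})

test_that("the built cluster is isotropic (aspect ratio ~ 1)", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 1L)
  met <- somiteCPM:::snapshotMetrics(m@grid, m@comp$cell, m@cells$class)
  expect_identical(nrow(met), 1L)
  expect_lt(abs(met$aspect - 1), 0.1)
  expect_equal(met$epiFraction, 2 / 3, tolerance = 1e-12)
  expect_identical(met$coelCells, 12L)
})

test_that("too few ring cells is a geometry error", {
  expect_error(somiteGeometry(ringCells = 5L), "ringCells")
})

test_that("validateConfiguration reports an orphan label", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 1L)
  bad <- m
  bad@grid[30, 5] <- max(bad@comp$label) + 50L
  v <- validateConfiguration(bad)
  expect_true(any(v$check == "registry"))
})

test_that("the configuration stays valid through Metropolis dynamics", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 5L)
  r <- metropolisMCS(m, 2500L, seed = 5L)
  expect_identical(nrow(validateConfiguration(r$model)), 0L)
})

test_that("imposed strain is the anchor-displacement ratio", {
  m <- buildSomite(somiteGeometry(), cpmParams(), seed = 1L)
  expect_identical(imposedStrain(m), 0)
  m2 <- applyStrainStep(m, 0.23 * m@anchorSep0)
  expect_equal(imposedStrain(m2), 0.23, tolerance = 1e-12)
  expect_identical(applyStrainStep(m, 0), m)
  expect_error(applyStrainStep(m, -1))
  expect_error(applyStrainStep(m, 1e6), "domain-overflow")
})
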