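# Synthetic fixtures: labelled somite images emulating segmented
# micrographs, scripted division trajectories, and (score, label) datasets
# with known generative structure. All generators are seed-deterministic.

#' Generate a labelled somite image
#'
#' An elliptical cluster at the requested aspect ratio — epithelial ring
#' cells around mesenchymal core cells, random orientation — on an otherwise
#' empty lattice, with ground truth recorded. Emulates a segmented somite
#' micrograph; no microscopy noise, only labelled territories.
#'
#' @param aspectRatio requested cluster aspect ratio (>= 1); realized within
#'   about 5 percent.
#' @param radius geometric-mean radius of the ellipse (lattice units).
#' @param ringCells,coreCells,ringFrac ring/core composition.
#' @param seed integer seed (orientation and core-partition jitter).
#' @return list(grid, comp, cells, truth) where truth records the requested
#'   aspect ratio, cell counts and the exact epithelial fraction.
#' @export
genSomiteImage <- function(aspectRatio = 1, radius = 16, ringCells = 24L,
                           coreCells = 12L, ringFrac = 1 / 3, seed = 1L) {
  stopifnot(aspectRatio >= 1)
  a <- radius * sqrt(aspectRatio)
  b <- radius / sqrt(aspectRatio)
  n <- 2L * ceiling(a) + 10L
  grid <- matrix(0L, n, n)
  theta <- withSeed(seed, runif(1, 0, pi))
  som <- rasterizeSomite(grid, center = c((n + 1) / 2, (n + 1) / 2),
                         semiA = a, semiB = b, theta = theta,
                         ringCells = ringCells, coreCells = coreCells,
                         ringFrac = ringFrac, seed = seed)
  list(grid = som$grid, comp = som$comp, cells = som$cells,
       truth = list(aspectRatio = aspectRatio, orientation = theta,
                    ringCells = ringCells, coreCells = coreCells,
                    epiFraction = ringCells / (ringCells + coreCells)))
}

snapshotFromPieces <- function(mcs, grid, comp, cells) {
  list(mcs = mcs, grid = grid, compCell = comp$cell, compRole = comp$role,
       compType = comp$ctype, cellClass = cells$class,
       cellMet = cells$metOrigin, anchorShift = 0)
}

syntheticTrajectory <- function(snapshots, meta = list()) {
  last <- snapshots[[length(snapshots)]]
  nComp <- length(last$compCell)
  comp <- data.frame(label = seq_len(nComp), cell = last$compCell,
                     role = last$compRole, ctype = last$compType,
                     area = tabulate(last$grid[last$grid > 0], nComp),
                     target = 0, lam = 0, sumx = 0, sumy = 0)
  cells <- data.frame(id = seq_along(last$cellClass), class = last$cellClass,
                      metOrigin = last$cellMet, streak = 0L)
  finalModel <- new("SomiteModel", grid = last$grid, comp = comp,
                    cells = cells,
                    springs = data.frame(a = integer(), b = integer(),
                                         ax = numeric(), ay = numeric(),
                                         rest = numeric(), k = numeric(),
                                         snap = numeric(), kind = integer(),
                                         side = integer(), alive = logical()),
                    params = cpmParams(), anchorSep0 = 0, anchorShift = 0,
                    meta = list())
  proto <- strainProtocol(totalMcs = last$mcs, pullStart = 0L, pullEnd = 0L,
                          rate = 0, snapshotInterval = 500L)
  new("SomiteTrajectory", snapshots = snapshots,
      events = data.frame(mcs = numeric(), event = character(),
                          id = integer(), extra = numeric()),
      protocol = proto, finalModel = finalModel, meta = meta)
}

#' Generate a scripted division trajectory
#'
#' A fixture for division detection: an elongated mother somite that, at a
#' known frame, is replaced by two ring-enclosed daughter somites (possibly
#' of unequal size) separated by background. With `split = FALSE` the
#' mother persists unchanged.
#'
#' @param frames number of snapshots (>= the detector's persistence window
#'   for the event to count).
#' @param splitFrame frame index at which the split appears.
#' @param sizes relative daughter areas, e.g. `c(1, 3)` for unequal
#'   daughters.
#' @param split if `FALSE`, generate the no-split control.
#' @param seed integer seed.
#' @return list(trajectory, truth) with the scripted event frame and time.
#' @export
genDivisionTrajectory <- function(frames = 30L, splitFrame = 15L,
                                  sizes = c(1, 1), split = TRUE, seed = 1L) {
  stopifnot(frames >= 2L, splitFrame >= 2L, splitFrame <= frames)
  R0 <- 14
  motherAR <- 3
  n <- 2L * ceiling(R0 * sqrt(motherAR)) + 14L
  interval <- 500
  mkMother <- function() {
    grid <- matrix(0L, n, n)
    rasterizeSomite(grid, c((n + 1) / 2, (n + 1) / 2),
                    semiA = R0 * sqrt(motherAR), semiB = R0 / sqrt(motherAR),
                    theta = 0, ringCells = 24L, coreCells = 12L,
                    ringFrac = 1 / 3, seed = seed)
  }
  mkDaughters <- function() {
    grid <- matrix(0L, n, n)
    aTot <- pi * R0^2
    r <- sqrt(aTot * sizes / sum(sizes) / pi) * 0.95
    cx <- (n + 1) / 2; cy <- (n + 1) / 2
    off <- R0 * sqrt(motherAR) / 2 + 1
    d1 <- rasterizeSomite(grid, c(cx - off, cy), semiA = r[1], semiB = r[1],
                          theta = 0, ringCells = 8L, coreCells = 3L,
                          ringFrac = 0.45, seed = seed)
    d2 <- rasterizeSomite(d1$grid, c(cx + off, cy), semiA = r[2],
                          semiB = r[2], theta = 0, ringCells = 8L,
                          coreCells = 3L, ringFrac = 0.45, seed = seed + 1L,
                          labelOffset = max(d1$comp$label),
                          cellOffset = max(d1$cells$id))
    list(grid = d2$grid, comp = rbind(d1$comp, d2$comp),
         cells = rbind(d1$cells, d2$cells))
  }
  mother <- mkMother()
  daughters <- if (split) mkDaughters() else NULL
  snaps <- lapply(seq_len(frames), function(f) {
    if (split && f >= splitFrame)
      snapshotFromPieces((f - 1) * interval, daughters$grid, daughters$comp,
                         daughters$cells)
    else
      snapshotFromPieces((f - 1) * interval, mother$grid, mother$comp,
                         mother$cells)
  })
  list(trajectory = syntheticTrajectory(
         snaps, meta = list(scenario = "scripted", strain = 0)),
       truth = list(splitFrame = if (split) splitFrame else NA_integer_,
                    splitMcs = if (split) (splitFrame - 1) * interval else NA_real_))
}

#' Population spec for synthetic aspect-ratio datasets
#'
#' Describes three groups emulating measured somite populations — control,
#' stretched-undivided, stretched-divided — by their aspect-ratio
#' distributions, plus a hard division threshold and a label-noise rate.
#'
#' @slot nControl,nUndivided,nDivided group sizes.
#' @slot controlMeanlog,controlSdlog lognormal parameters of the control
#'   group (centred near aspect ratio 1.2).
#' @slot undividedMean,undividedSd,dividedMean,dividedSd normal parameters
#'   of the stretched groups (truncated at 1).
#' @slot threshold generative division threshold on the score.
#' @slot noiseRate probability of flipping a label, in `[0, 0.5)`.
#' @export
setClass("ShapePopulationSpec", representation(
  nControl = "integer", nUndivided = "integer", nDivided = "integer",
  controlMeanlog = "numeric", controlSdlog = "numeric",
  undividedMean = "numeric", undividedSd = "numeric",
  dividedMean = "numeric", dividedSd = "numeric",
  threshold = "numeric", noiseRate = "numeric"))

setValidity("ShapePopulationSpec", function(object) {
  msg <- character()
  if (any(c(object@nControl, object@nUndivided, object@nDivided) <= 0L))
    msg <- c(msg, "group counts must be > 0")
  if (any(c(object@controlSdlog, object@undividedSd, object@dividedSd) < 0))
    msg <- c(msg, "spreads must be >= 0")
  if (object@noiseRate < 0 || object@noiseRate >= 0.5)
    msg <- c(msg, "noiseRate must be in [0, 0.5)")
  if (length(msg)) msg else TRUE
})

#' @describeIn ShapePopulationSpec-class constructor with stand-in defaults
#'   anchored near the printed thresholds (control near 1.2, stretched up to
#'   about 4).
#' @param nControl,nUndivided,nDivided,controlMeanlog,controlSdlog,undividedMean,undividedSd,dividedMean,dividedSd,threshold,noiseRate see slots.
#' @export
shapePopulationSpec <- function(nControl = 30L, nUndivided = 25L,
                                nDivided = 25L,
                                controlMeanlog = log(1.2), controlSdlog = 0.1,
                                undividedMean = 2.0, undividedSd = 0.3,
                                dividedMean = 3.2, dividedSd = 0.4,
                                threshold = 2.5, noiseRate = 0) {
  new("ShapePopulationSpec", nControl = as.integer(nControl),
      nUndivided = as.integer(nUndivided), nDivided = as.integer(nDivided),
      controlMeanlog = controlMeanlog, controlSdlog = controlSdlog,
      undividedMean = undividedMean, undividedSd = undividedSd,
      dividedMean = dividedMean, dividedSd = dividedSd,
      threshold = threshold, noiseRate = noiseRate)
}

#' Generate a (score, label) dataset from a population spec
#'
#' Aspect ratios are drawn per group (truncated at 1); divided labels are
#' assigned by the hard threshold rule `score > threshold`, then flipped
#' with probability `noiseRate`.
#'
#' @param spec a [ShapePopulationSpec-class].
#' @param seed integer seed.
#' @return list(scores, labels, group, truth).
#' @export
genARDataset <- function(spec = shapePopulationSpec(), seed = 1L) {
  validObject(spec)
  withSeed(seed, {
    ctrl <- rlnorm(spec@nControl, spec@controlMeanlog, spec@controlSdlog)
    und <- pmax(1, rnorm(spec@nUndivided, spec@undividedMean, spec@undividedSd))
    div <- pmax(1, rnorm(spec@nDivided, spec@dividedMean, spec@dividedSd))
    scores <- c(ctrl, und, div)
    labels <- scores > spec@threshold
    flip <- runif(length(scores)) < spec@noiseRate
    labels <- xor(labels, flip)
    list(scores = scores, labels = as.integer(labels),
         group = rep(c("control", "stretched-undivided", "stretched-divided"),
                     c(spec@nControl, spec@nUndivided, spec@nDivided)),
         truth = list(threshold = spec@threshold, noiseRate = spec@noiseRate,
                      flipped = sum(flip)))
  })
}
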