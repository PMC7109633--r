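#' Somite geometry specification
#'
#' Describes the initial layout: a circular somite (mesenchymal core wrapped
#' in a one-cell-thick epithelial ring) centred in an ECM mesh that fills the
#' active region of the lattice. The lattice is allocated wider than the
#' active region (`reserve` extra columns of medium on the right) so the ECM
#' can be pulled outward without resizing the grid.
#'
#' @slot width,height active region size in lattice sites.
#' @slot reserve extra medium columns allocated right of the active region.
#' @slot center somite centre (x, y) in lattice coordinates.
#' @slot outerRadius outer radius of the epithelial ring (lattice units).
#' @slot ringThickness radial thickness of the epithelial ring.
#' @slot ringCells number of epithelial cells on the ring (>= 6).
#' @slot coreCells number of mesenchymal cells in the somitocoel.
#' @slot ecmSpacing node spacing of the hexagonally packed ECM mesh.
#' @slot anchorBand width (columns) of the anchored ECM strips at the left
#'   (fixed) and right (pulled) edges of the active region.
#' @export
setClass("SomiteGeometry", representation(
  width = "integer", height = "integer", reserve = "integer",
  center = "numeric", outerRadius = "numeric", ringThickness = "numeric",
  ringCells = "integer", coreCells = "integer", ecmSpacing = "numeric",
  anchorBand = "numeric"))

setValidity("SomiteGeometry", function(object) {
  msg <- character()
  if (object@ringCells < 6L)
    msg <- c(msg, "geometry error: ringCells must be >= 6 to close the ring")
  if (object@coreCells < 1L) msg <- c(msg, "coreCells must be >= 1")
  if (object@ringThickness >= object@outerRadius)
    msg <- c(msg, "ring thickness must be smaller than the outer radius")
  r <- object@outerRadius
  c <- object@center
  if (c[1] - r < 2 || c[1] + r > object@width - 1 ||
      c[2] - r < 2 || c[2] + r > object@height - 1)
    msg <- c(msg, "somite does not fit inside the active region")
  if (length(msg)) msg else TRUE
})

#' Construct a somite geometry
#'
#' Defaults are the desk-scale preset: a 120 x 60 active region holding a
#' 24-cell epithelial ring around a 12-cell mesenchymal core, with 100
#' reserve columns for stretching.
#'
#' @param width,height active region (sites).
#' @param reserve medium columns kept right of the active region.
#' @param center somite centre; default is the centre of the active region.
#' @param outerRadius,ringThickness ring geometry (lattice units).
#' @param ringCells,coreCells cell counts.
#' @param ecmSpacing ECM mesh node spacing.
#' @param anchorBand width of the anchored ECM edge strips.
#' @return a validated [SomiteGeometry-class].
#' @export
somiteGeometry <- function(width = 120L, height = 60L, reserve = 100L,
                           center = c(width / 2, height / 2),
                           outerRadius = 15, ringThickness = 5,
                           ringCells = 24L, coreCells = 12L,
                           ecmSpacing = 7, anchorBand = 6) {
  new("SomiteGeometry", width = as.integer(width),
      height = as.integer(height), reserve = as.integer(reserve),
      center = center, outerRadius = outerRadius,
      ringThickness = ringThickness, ringCells = as.integer(ringCells),
      coreCells = as.integer(coreCells), ecmSpacing = ecmSpacing,
      anchorBand = anchorBand)
}

setMethod("show", "SomiteGeometry", function(object) {
  cat(sprintf(
    "SomiteGeometry: %d x %d (+%d reserve), ring %d cells / core %d cells, R = %g\n",
    object@width, object@height, object@reserve, object@ringCells,
    object@coreCells, object@outerRadius))
})

#' Strain protocol
#'
#' Schedule of axial pulls applied to the right-edge ECM anchors, in MCS
#' units. During each pull window the anchors move outward by `rate` lattice
#' units per MCS; outside the windows they hold position (the in-silico
#' analogue of a rest period).
#'
#' @slot totalMcs run length in Monte Carlo steps.
#' @slot pullStart,pullEnd pull window boundaries (MCS), parallel vectors.
#' @slot rate displacement per MCS during each pull (lattice units).
#' @slot snapshotInterval record a snapshot every this many MCS (500
#'   matches one video frame per 500 MCS).
#' @export
setClass("StrainProtocol", representation(
  totalMcs = "integer", pullStart = "integer", pullEnd = "integer",
  rate = "numeric", snapshotInterval = "integer"))

setValidity("StrainProtocol", function(object) {
  msg <- character()
  if (length(object@pullStart) != length(object@pullEnd) ||
      length(object@rate) != length(object@pullStart))
    msg <- c(msg, "pullStart, pullEnd, rate must have equal length")
  if (any(object@pullStart < 0)) msg <- c(msg, "pull onset must be >= 0")
  if (any(object@rate < 0)) msg <- c(msg, "rates must be >= 0")
  if (any(object@pullEnd > object@totalMcs))
    msg <- c(msg, "total run must cover all pulls")
  if (any(object@pullEnd < object@pullStart))
    msg <- c(msg, "pull windows must have pullEnd >= pullStart")
  if (length(msg)) msg else TRUE
})

#' Construct a strain protocol
#'
#' @param totalMcs total run length (MCS).
#' @param pullStart,pullEnd pull windows (MCS).
#' @param rate per-MCS anchor displacement during each pull.
#' @param snapshotInterval snapshot cadence (MCS).
#' @return a validated [StrainProtocol-class].
#' @export
strainProtocol <- function(totalMcs = 20000L, pullStart = 3000L,
                           pullEnd = 7000L, rate = 0.01,
                           snapshotInterval = 500L) {
  rate <- rep_len(rate, length(pullStart))
  new("StrainProtocol", totalMcs = as.integer(totalMcs),
      pullStart = as.integer(pullStart), pullEnd = as.integer(pullEnd),
      rate = rate, snapshotInterval = as.integer(snapshotInterval))
}

setMethod("show", "StrainProtocol", function(object) {
  cat(sprintf("StrainProtocol: %d MCS, %d pull(s), snapshots every %d MCS\n",
              object@totalMcs, length(object@pullStart),
              object@snapshotInterval))
  for (i in seq_along(object@pullStart))
    cat(sprintf("  pull %d: MCS %d-%d at %.4g sites/MCS\n", i,
                object@pullStart[i], object@pullEnd[i], object@rate[i]))
})

#' Full simulation state of the compartmental CPM
#'
#' The label lattice plus the cell, compartment and spring registries and
#' the energy parameters. Use the accessors ([labelGrid()], [cellTable()],
#' [compartmentTable()], [springTable()], [energyParams()]) rather than
#' reading slots.
#'
#' @slot grid integer label matrix (rows = y, columns = x); 0 is medium.
#' @slot comp compartment registry (label, cell, role, ctype, area, target,
#'   lam, sumx, sumy); `area`/`sumx`/`sumy` are maintained incrementally by
#'   the engine and equal a full rescan of the grid.
#' @slot cells cell registry (id, class, metOrigin, streak); `streak` is the
#'   MET contact timer in MCS.
#' @slot springs spring registry (a, b, ax, ay, rest, k, snap, kind, side,
#'   alive); `b = 0` marks a fixed anchor point at (ax, ay); snapped springs
#'   stay listed with `alive = FALSE`.
#' @slot params a [CPMParams-class].
#' @slot anchorSep0 initial separation of the left/right anchor strips
#'   (lattice units); the denominator of the imposed-strain readout.
#' @slot anchorShift cumulative displacement applied to the right anchors.
#' @slot meta free-form list (geometry, preset name, build seed).
#' @export
setClass("SomiteModel", representation(
  grid = "matrix", comp = "data.frame", cells = "data.frame",
  springs = "data.frame", params = "CPMParams", anchorSep0 = "numeric",
  anchorShift = "numeric", meta = "list"))

setValidity("SomiteModel", function(object) {
  msg <- character()
  labs <- sort(unique(object@grid[object@grid > 0]))
  if (length(labs) && max(labs) > nrow(object@comp))
    msg <- c(msg, "grid contains unregistered labels")
  if (nrow(object@comp) && any(object@comp$area <= 0))
    msg <- c(msg, "compartment with non-positive area")
  if (length(msg)) msg else TRUE
})

#' @describeIn SomiteModel-class the integer label lattice.
#' @param model a [SomiteModel-class].
#' @export
labelGrid <- function(model) model@grid

#' @describeIn SomiteModel-class cell registry with decoded classes.
#' @export
cellTable <- function(model) {
  df <- model@cells
  df$class <- decodeClass(df$class)
  df
}

#' @describeIn SomiteModel-class compartment registry with decoded roles.
#' @export
compartmentTable <- function(model) {
  df <- model@comp
  df$role <- decodeRole(df$role)
  df$type <- TYPE_NAMES[df$ctype + 1L]
  df
}

#' @describeIn SomiteModel-class spring registry with decoded kinds.
#' @export
springTable <- function(model) {
  df <- model@springs
  df$kind <- decodeKind(df$kind)
  df
}

#' @describeIn SomiteModel-class the [CPMParams-class] in use.
#' @export
energyParams <- function(model) model@params

#' @describeIn SomiteModel-class imposed strain: cumulative anchor
#'   displacement over initial anchor separation.
#' @export
imposedStrain <- function(model) {
  if (model@anchorSep0 <= 0) return(0)
  model@anchorShift / model@anchorSep0
}

#' @describeIn SomiteModel-class cell counts by class.
#' @export
cellCounts <- function(model) {
  cls <- decodeClass(model@cells$class)
  counts <- table(factor(cls, levels = names(CLASS_CODES)))
  c(as.list(counts), somitic = sum(cls %in% c("mesenchymal", "epithelial")))
}

setMethod("show", "SomiteModel", function(object) {
  cc <- cellCounts(object)
  cat(sprintf("SomiteModel: %d x %d lattice, %d compartments, %d cells\n",
              ncol(object@grid), nrow(object@grid), nrow(object@comp),
              nrow(object@cells)))
  cat(sprintf("  %d mesenchymal + %d epithelial (+%d ECM), strain %.3f\n",
              cc$mesenchymal, cc$epithelial, cc$ecm, imposedStrain(object)))
  cat(sprintf("  springs: %d alive / %d total\n",
              sum(object@springs$alive), nrow(object@springs)))
})

# ---- model <-> engine state -----------------------------------------------

engineState <- function(model) {
  list(grid = model@grid,
       comp = list(cell = model@comp$cell, role = model@comp$role,
                   ctype = model@comp$ctype, target = model@comp$target,
                   lam = model@comp$lam),
       cellClass = model@cells$class,
       cellMet = model@cells$metOrigin,
       cellStreak = model@cells$streak,
       spr = as.list(model@springs[c("a", "b", "ax", "ay", "rest", "k",
                                     "snap", "kind", "side", "alive")]),
       anchorShift = model@anchorShift,
       params = paramsToList(model@params))
}

modelFromState <- function(state, template) {
  comp <- as.data.frame(state$comp)
  comp$label <- seq_len(nrow(comp))
  comp <- comp[c("label", "cell", "role", "ctype", "area", "target", "lam",
                 "sumx", "sumy")]
  cells <- data.frame(id = seq_along(state$cellClass),
                      class = state$cellClass,
                      metOrigin = state$cellMet,
                      streak = state$cellStreak)
  springs <- as.data.frame(state$spr)
  initialize(template, grid = state$grid, comp = comp, cells = cells,
             springs = springs, anchorShift = state$anchorShift)
}

#' Simulation trajectory: ordered snapshots plus an event log
#'
#' @slot snapshots list of snapshots; each is a list with `mcs`, `grid`,
#'   per-label registry vectors (`compCell`, `compRole`, `compType`),
#'   per-cell `cellClass`/`cellMet`, and `anchorShift`.
#' @slot events data.frame (mcs, event, id, extra): `snap` rows are ruptured
#'   junction springs, `met` rows are executed transitions (id = cell).
#' @slot protocol the [StrainProtocol-class] that produced the run.
#' @slot finalModel the [SomiteModel-class] at the end of the run.
#' @slot meta list: seed, scenario, imposed strain, acceptance count.
#' @export
setClass("SomiteTrajectory", representation(
  snapshots = "list", events = "data.frame", protocol = "StrainProtocol",
  finalModel = "SomiteModel", meta = "list"))

#' @describeIn SomiteTrajectory-class number of snapshots.
#' @param trajectory a [SomiteTrajectory-class].
#' @export
snapshotTimes <- function(trajectory)
  vapply(trajectory@snapshots, function(s) s$mcs, numeric(1))

setMethod("show", "SomiteTrajectory", function(object) {
  ev <- table(object@events$event)
  cat(sprintf(
    "SomiteTrajectory: %d snapshots (MCS %s-%s), scenario '%s', strain %.2f\n",
    length(object@snapshots), min(snapshotTimes(object)),
    max(snapshotTimes(object)), object@meta$scenario %||% "none",
    object@meta$strain %||% 0))
  cat(sprintf("  events: %d snapped junctions, %d MET\n",
              ev["snap"] %|0|% 0L, ev["met"] %|0|% 0L))
})

`%||%` <- function(a, b) if (is.null(a)) b else a
`%|0|%` <- function(a, b) if (is.na(a)) b else a

#' ROC analysis result
#'
#' @slot points data.frame (threshold, fpr, tpr), monotone from (0,0) to
#'   (1,1).
#' @slot auc area under the empirical ROC curve.
#' @slot ci bootstrap 95 percent confidence interval (lower, upper).
#' @slot threshold estimated class-separating score at the Youden-optimal
#'   operating point.
#' @slot n named counts of negatives and positives.
#' @export
setClass("RocResult", representation(
  points = "data.frame", auc = "numeric", ci = "numeric",
  threshold = "numeric", n = "integer"))

setMethod("show", "RocResult", function(object) {
  cat(sprintf("RocResult: AUC = %.4f (95%% CI %.3f-%.3f), threshold = %.3f\n",
              object@auc, object@ci[1], object@ci[2], object@threshold))
  cat(sprintf("  n = %d negative / %d positive, %d ROC points\n",
              object@n[["negative"]], object@n[["positive"]],
              nrow(object@points)))
})
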