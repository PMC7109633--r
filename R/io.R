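# Plain-text serialization. A snapshot prefix `p` expands to:
#   p.grid.txt      label matrix, one row per line, space-separated integers
#   p.registry.tsv  per-label registry: label, cell, role, class, metOrigin,
#                   streak, target, lam
#   p.springs.tsv   spring table (written for full models)
#   p.params.yaml   energy parameters + anchor bookkeeping
# Numeric columns are written with 17 significant digits so that energies
# round-trip exactly.

fmtNum <- function(x) formatC(x, digits = 17, format = "g")

#' Write a model or snapshot to plain-text files
#'
#' @param model a [SomiteModel-class].
#' @param path file prefix (suffixes are appended).
#' @return invisibly, the vector of files written.
#' @export
writeSnapshot <- function(model, path) {
  gridFile <- paste0(path, ".grid.txt")
  writeLines(apply(model@grid, 1, paste, collapse = " "), gridFile)

  comp <- model@comp
  cells <- model@cells
  reg <- data.frame(label = comp$label, cell = comp$cell,
                    role = decodeRole(comp$role),
                    class = decodeClass(cells$class[comp$cell]),
                    metOrigin = cells$metOrigin[comp$cell],
                    streak = cells$streak[comp$cell],
                    target = fmtNum(comp$target), lam = fmtNum(comp$lam))
  regFile <- paste0(path, ".registry.tsv")
  write.table(reg, regFile, sep = "\t", quote = FALSE, row.names = FALSE)

  spr <- model@springs
  sprOut <- data.frame(a = spr$a, b = spr$b, ax = fmtNum(spr$ax),
                       ay = fmtNum(spr$ay), rest = fmtNum(spr$rest),
                       k = fmtNum(spr$k), snap = fmtNum(spr$snap),
                       kind = decodeKind(spr$kind), side = spr$side,
                       alive = spr$alive)
  sprFile <- paste0(path, ".springs.tsv")
  write.table(sprOut, sprFile, sep = "\t", quote = FALSE, row.names = FALSE)

  p <- model@params
  parFile <- paste0(path, ".params.yaml")
  yaml::write_yaml(list(
    J = apply(unname(p@J), 1, fmtNum, simplify = FALSE),
    Jintra = fmtNum(p@Jintra), lambdaA = fmtNum(p@lambdaA),
    lambdaEcm = fmtNum(p@lambdaEcm),
    temp = fmtNum(p@temp), snapExt = fmtNum(p@snapExt),
    captureRadius = fmtNum(p@captureRadius),
    junctionRest = fmtNum(p@junctionRest), kJunction = fmtNum(p@kJunction),
    kCyto = fmtNum(p@kCyto), kEcm = fmtNum(p@kEcm),
    kMatrix = fmtNum(p@kMatrix), kAnchor = fmtNum(p@kAnchor),
    kConfine = fmtNum(p@kConfine), metThreshold = p@metThreshold,
    metMinContact = p@metMinContact, mcsPerHour = fmtNum(p@mcsPerHour),
    anchorSep0 = fmtNum(model@anchorSep0),
    anchorShift = fmtNum(model@anchorShift)), parFile)
  invisible(c(gridFile, regFile, sprFile, parFile))
}

#' Read a model back from plain-text files
#'
#' Lossless inverse of [writeSnapshot()]: grids, registries, springs and
#' parameters round-trip exactly (including the total energy). Malformed
#' rows and unknown class tokens raise parse errors with the offending line.
#'
#' @param path file prefix used at write time.
#' @return a [SomiteModel-class].
#' @export
readSnapshot <- function(path) {
  gridFile <- paste0(path, ".grid.txt")
  lines <- readLines(gridFile)
  rows <- strsplit(trimws(lines), "\\s+")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop(sprintf("parse error in %s: ragged row at line %d (%d values, expected %d)",
                 gridFile, which(lens != lens[1])[1], lens[lens != lens[1]][1],
                 lens[1]))
  vals <- suppressWarnings(as.integer(unlist(rows)))
  if (anyNA(vals))
    stop(sprintf("parse error in %s: non-integer label at line %d", gridFile,
                 ceiling(which(is.na(vals))[1] / lens[1])))
  grid <- matrix(vals, nrow = length(rows), byrow = TRUE)

  reg <- read.table(paste0(path, ".registry.tsv"), header = TRUE, sep = "\t",
                    colClasses = c("integer", "integer", "character",
                                   "character", "integer", "integer",
                                   "numeric", "numeric"))
  badClass <- !reg$class %in% names(CLASS_CODES)
  if (any(badClass))
    stop(sprintf("parse error in %s.registry.tsv: unknown class token '%s' at line %d",
                 path, reg$class[badClass][1], which(badClass)[1] + 1L))
  badRole <- !reg$role %in% names(ROLE_CODES)
  if (any(badRole))
    stop(sprintf("parse error in %s.registry.tsv: unknown role token '%s' at line %d",
                 path, reg$role[badRole][1], which(badRole)[1] + 1L))

  comp <- data.frame(label = reg$label, cell = reg$cell,
                     role = unname(ROLE_CODES[reg$role]),
                     ctype = roleToCtype(reg$role, reg$class, reg$metOrigin),
                     area = 0L, target = reg$target, lam = reg$lam,
                     sumx = 0, sumy = 0)
  geo <- compartmentGeometry(grid, nrow(comp))
  comp$area <- geo$area; comp$sumx <- geo$sumx; comp$sumy <- geo$sumy

  cellIds <- sort(unique(reg$cell))
  first <- match(cellIds, reg$cell)
  cells <- data.frame(id = cellIds,
                      class = unname(CLASS_CODES[reg$class[first]]),
                      metOrigin = reg$metOrigin[first],
                      streak = reg$streak[first])

  sprIn <- read.table(paste0(path, ".springs.tsv"), header = TRUE,
                      sep = "\t",
                      colClasses = c("integer", "integer", "numeric",
                                     "numeric", "numeric", "numeric",
                                     "numeric", "character", "integer",
                                     "logical"))
  springs <- data.frame(a = sprIn$a, b = sprIn$b, ax = sprIn$ax,
                        ay = sprIn$ay, rest = sprIn$rest, k = sprIn$k,
                        snap = sprIn$snap,
                        kind = unname(KIND_CODES[sprIn$kind]),
                        side = sprIn$side, alive = sprIn$alive)

  y <- yaml::read_yaml(paste0(path, ".params.yaml"))
  J <- t(vapply(y$J, as.numeric, numeric(9)))
  dimnames(J) <- list(TYPE_NAMES, TYPE_NAMES)
  params <- cpmParams(J = J, Jintra = as.numeric(y$Jintra),
                      lambdaA = as.numeric(y$lambdaA),
                      lambdaEcm = as.numeric(y$lambdaEcm),
                      temp = as.numeric(y$temp),
                      snapExt = as.numeric(y$snapExt),
                      captureRadius = as.numeric(y$captureRadius),
                      junctionRest = as.numeric(y$junctionRest),
                      kJunction = as.numeric(y$kJunction),
                      kCyto = as.numeric(y$kCyto), kEcm = as.numeric(y$kEcm),
                      kMatrix = as.numeric(y$kMatrix),
                      kAnchor = as.numeric(y$kAnchor),
                      kConfine = as.numeric(y$kConfine),
                      metThreshold = y$metThreshold,
                      metMinContact = y$metMinContact,
                      mcsPerHour = as.numeric(y$mcsPerHour))
  new("SomiteModel", grid = grid, comp = comp, cells = cells,
      springs = springs, params = params,
      anchorSep0 = as.numeric(y$anchorSep0),
      anchorShift = as.numeric(y$anchorShift), meta = list(path = path))
}

roleToCtype <- function(role, class, metOrigin = 0L) {
  ct <- integer(length(role))
  ct[role == "apical"] <- 3L
  ct[role == "lateral"] <- 4L
  ct[role == "basal"] <- 5L
  ct[role == "ecm"] <- 2L
  ct[role == "body" & class == "mesenchymal"] <- 1L
  nascent <- metOrigin > 0L & ct %in% 3:5
  ct[nascent] <- ct[nascent] + 3L
  ct
}

#' Write a metrics table as CSV
#'
#' @param metrics data.frame, e.g. from [trajectoryMetrics()] or
#'   [runSweep()].
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeMetricsCsv <- function(metrics, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
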