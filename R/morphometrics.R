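#' Connected somite clusters in a label lattice
#'
#' 8-connected components of sites whose cell class is mesenchymal or
#' epithelial; ECM and medium are background. Components smaller than
#' `minSize` sites are discarded.
#'
#' @param grid integer label matrix.
#' @param registry either a logical vector over labels (`TRUE` = somitic) or
#'   a data.frame with columns `label` and `class` (classes `mesenchymal` /
#'   `epithelial` are somitic), or a [SomiteModel-class].
#' @param minSize minimum component size in sites.
#' @return list(clusters = integer matrix of cluster ids (0 background),
#'   sizes = site counts per cluster).
#' @export
labelSomiteClusters <- function(grid, registry, minSize = 5L) {
  somitic <- somiticFlags(grid, registry)
  cppLabelClusters(grid, somitic, as.integer(minSize))
}

somiticFlags <- function(grid, registry) {
  if (is(registry, "SomiteModel")) {
    cls <- registry@cells$class[registry@comp$cell]
    return(cls %in% c(CLASS_CODES[["mesenchymal"]], CLASS_CODES[["epithelial"]]))
  }
  if (is.data.frame(registry)) {
    nLab <- max(0L, max(grid))
    out <- logical(nLab)
    somiticClass <- registry$class %in% c("mesenchymal", "epithelial") |
      registry$class %in% c(CLASS_CODES[["mesenchymal"]], CLASS_CODES[["epithelial"]])
    out[registry$label[somiticClass]] <- TRUE
    return(out)
  }
  as.logical(registry)
}

#' Aspect ratio from the gyration tensor
#'
#' `sqrt(lambda_max / lambda_min)` of the eigenvalues of the second central
#' moment (gyration) tensor of the site coordinates; 1 for isotropic shapes,
#' invariant under translation and rotation, and >= 1 by construction.
#'
#' @param sites two-column matrix or data.frame of site coordinates (x, y).
#' @return aspect ratio (numeric scalar >= 1).
#' @export
aspectRatio <- function(sites) {
  sites <- as.matrix(sites)
  if (nrow(sites) < 3L)
    stop("degenerate-shape error: need at least 3 sites")
  cc <- sweep(sites, 2, colMeans(sites))
  g <- crossprod(cc) / nrow(sites)
  ev <- eigen(g, symmetric = TRUE, only.values = TRUE)$values
  if (ev[2] <= 1e-9 * max(ev[1], 1))
    stop("degenerate-shape error: collinear sites")
  sqrt(ev[1] / ev[2])
}

#' Epithelial cell fraction
#'
#' Number of epithelial cells over epithelial plus mesenchymal cells,
#' counting cells (not sites).
#'
#' @param classes character or coded vector of cell classes for the cells in
#'   one cluster.
#' @return fraction in `[0, 1]`.
#' @export
epithelialFraction <- function(classes) {
  if (!length(classes)) stop("empty cluster")
  if (is.numeric(classes)) classes <- decodeClass(classes)
  ep <- sum(classes == "epithelial")
  ms <- sum(classes == "mesenchymal")
  if (ep + ms == 0L) stop("cluster contains no somitic cells")
  ep / (ep + ms)
}

#' Somitocoel size of a cluster
#'
#' @param cellClasses classes of the cluster's cells (as in
#'   [epithelialFraction()]).
#' @param siteClasses optional classes of the cluster's sites, to also count
#'   mesenchymal sites.
#' @return list(cells, sites) of mesenchymal counts (sites `NA` if site
#'   classes not given).
#' @export
somitocoelSize <- function(cellClasses, siteClasses = NULL) {
  if (!length(cellClasses)) stop("empty cluster")
  if (is.numeric(cellClasses)) cellClasses <- decodeClass(cellClasses)
  n <- sum(cellClasses == "mesenchymal")
  s <- if (is.null(siteClasses)) NA_integer_ else {
    if (is.numeric(siteClasses)) siteClasses <- decodeClass(siteClasses)
    sum(siteClasses == "mesenchymal")
  }
  list(cells = n, sites = s)
}

# Per-cluster morphometrics for one snapshot (or model). A cell is assigned
# to the cluster holding the majority of its sites.
snapshotMetrics <- function(grid, compCell, cellClass, minSize = 5L) {
  somitic <- cellClass[compCell] %in%
    c(CLASS_CODES[["mesenchymal"]], CLASS_CODES[["epithelial"]])
  lab <- cppLabelClusters(grid, somitic, as.integer(minSize))
  CL <- lab$clusters
  K <- length(lab$sizes)
  empty <- data.frame(cluster = integer(), nSites = integer(),
                      nCells = integer(), aspect = numeric(),
                      epiFraction = numeric(), coelCells = integer(),
                      coelSites = integer(), periEpiFrac = numeric(),
                      cx = numeric(), cy = numeric())
  if (K == 0L) return(empty)

  idx <- which(CL > 0L)
  cl <- CL[idx]
  cellAt <- compCell[grid[idx]]
  ij <- arrayInd(idx, dim(CL))           # [,1] = y, [,2] = x

  # majority-cluster assignment of cells
  tab <- table(cell = cellAt, cluster = cl)
  cellCluster <- as.integer(colnames(tab))[max.col(unclass(tab), "first")]
  cellIds <- as.integer(rownames(tab))

  periEpi <- perimeterEpiFraction(CL, grid, compCell, cellClass, K)

  rows <- lapply(seq_len(K), function(k) {
    sel <- cl == k
    sites <- cbind(x = ij[sel, 2], y = ij[sel, 1])
    ar <- tryCatch(aspectRatio(sites), error = function(e) NA_real_)
    mem <- cellIds[cellCluster == k]
    cls <- cellClass[mem]
    coelSites <- sum(cellClass[cellAt[sel]] == CLASS_CODES[["mesenchymal"]])
    data.frame(cluster = k, nSites = sum(sel), nCells = length(mem),
               aspect = ar,
               epiFraction = if (length(mem)) epithelialFraction(cls) else NA_real_,
               coelCells = sum(cls == CLASS_CODES[["mesenchymal"]]),
               coelSites = coelSites, periEpiFrac = periEpi[k],
               cx = mean(sites[, "x"]), cy = mean(sites[, "y"]))
  })
  do.call(rbind, rows)
}

# Fraction of each cluster's boundary sites (8-neighbourhood) belonging to
# epithelial cells.
perimeterEpiFraction <- function(CL, grid, compCell, cellClass, K) {
  H <- nrow(CL); W <- ncol(CL)
  pad <- matrix(0L, H + 2L, W + 2L)
  pad[2:(H + 1), 2:(W + 1)] <- CL
  core <- pad[2:(H + 1), 2:(W + 1)]
  boundary <- matrix(FALSE, H, W)
  for (dy in -1:1) for (dx in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- pad[(2 + dy):(H + 1 + dy), (2 + dx):(W + 1 + dx)]
    boundary <- boundary | (core > 0L & nb != core)
  }
  bIdx <- which(boundary)
  bcl <- core[bIdx]
  isEpi <- cellClass[compCell[grid[bIdx]]] == CLASS_CODES[["epithelial"]]
  tot <- tabulate(bcl, nbins = K)
  epi <- tabulate(bcl[isEpi], nbins = K)
  ifelse(tot > 0, epi / tot, 0)
}

#' Per-snapshot morphometrics of a trajectory
#'
#' @param trajectory a [SomiteTrajectory-class].
#' @param minSize minimum cluster size in sites.
#' @return data.frame with one row per (snapshot, cluster): mcs, cluster,
#'   nSites, nCells, aspect, epiFraction, coelCells, coelSites, periEpiFrac,
#'   cx, cy.
#' @export
trajectoryMetrics <- function(trajectory, minSize = 5L) {
  out <- lapply(trajectory@snapshots, function(s) {
    m <- snapshotMetrics(s$grid, s$compCell, s$cellClass, minSize)
    if (nrow(m)) cbind(mcs = s$mcs, m) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(mcs = numeric(), cluster = integer())
  rownames(out) <- NULL
  out
}

#' Detect somite division events in a trajectory
#'
#' A division is recorded when the tracked somite splits into two or more
#' clusters, each with at least `minCells` cells and an epithelial-majority
#' perimeter (at least `periEpiFrac` of boundary sites belonging to
#' epithelial cells), and the split persists for at least `persist`
#' consecutive snapshots. Transient splits that re-merge within the window
#' are ignored, as are bare mesenchymal fragments.
#'
#' @param trajectory a [SomiteTrajectory-class].
#' @param minCells minimum cells per daughter.
#' @param periEpiFrac minimum epithelial fraction of a daughter's perimeter.
#' @param persist persistence window in snapshots.
#' @param minSize minimum cluster size in sites.
#' @return data.frame (mcs, daughters) with one row per division event;
#'   zero rows if the somite never divides.
#' @export
detectDivision <- function(trajectory, minCells = 4L, periEpiFrac = 0.6,
                           persist = 10L, minSize = 5L) {
  if (length(trajectory@snapshots) < 2L)
    stop("trajectory needs at least 2 snapshots")
  met <- trajectoryMetrics(trajectory, minSize)
  times <- snapshotTimes(trajectory)
  qual <- vapply(times, function(t) {
    m <- met[met$mcs == t, , drop = FALSE]
    sum(m$nCells >= minCells & m$periEpiFrac >= periEpiFrac, na.rm = TRUE)
  }, numeric(1))
  events <- list()
  established <- max(1, qual[1])
  i <- 2L
  n <- length(qual)
  while (i <= n) {
    if (qual[i] > established) {
      win <- i:min(n, i + persist - 1L)
      if (length(win) >= persist && all(qual[win] > established)) {
        daughters <- min(qual[win])
        events[[length(events) + 1L]] <-
          data.frame(mcs = times[i], daughters = daughters)
        established <- daughters
      }
    }
    i <- i + 1L
  }
  if (length(events)) do.call(rbind, events)
  else data.frame(mcs = numeric(), daughters = numeric())
}

#' Per-run division score
#'
#' The run's classifier score for ROC analysis: the maximum aspect ratio of
#' the dominant (largest) cluster attained before division, or over the
#' whole run if the somite never divides.
#'
#' @param trajectory a [SomiteTrajectory-class].
#' @param ... passed to [detectDivision()].
#' @return list(score, divided, divisionMcs).
#' @export
divisionScore <- function(trajectory, ...) {
  met <- trajectoryMetrics(trajectory)
  ev <- detectDivision(trajectory, ...)
  divided <- nrow(ev) > 0L
  cutoff <- if (divided) ev$mcs[1] else Inf
  pre <- met[met$mcs < cutoff, , drop = FALSE]
  if (!nrow(pre)) pre <- met
  # dominant cluster per snapshot
  dom <- do.call(rbind, lapply(split(pre, pre$mcs), function(m)
    m[which.max(m$nSites), , drop = FALSE]))
  list(score = max(dom$aspect, na.rm = TRUE), divided = divided,
       divisionMcs = if (divided) ev$mcs[1] else NA_real_)
}

#' Midline force and stress for a given strain
#'
#' Linear-elastic estimate: stress = E * strain; force = stress times the
#' rectangular cross-section width x depth. With the literature values for
#' the chick embryo midline (E = 2,400 Pa, 84 x 200 um section) a 23 percent
#' strain gives a stress of 552 Pa and a force of about 9.3 uN.
#'
#' @param strain imposed strain (dimensionless, >= 0).
#' @param stiffness Young's modulus E in Pa (default 2400).
#' @param width,depth cross-section in micrometres (default 84 x 200).
#' @return list(stress in Pa, force in microNewton).
#' @export
midlineForceStress <- function(strain, stiffness = 2400, width = 84,
                               depth = 200) {
  if (stiffness <= 0 || width <= 0 || depth <= 0 || strain < 0)
    stop("all mechanical parameters must be positive (strain >= 0)")
  stress <- stiffness * strain
  force <- stress * width * depth * 1e-6   # Pa * um^2 -> uN
  list(stress = stress, force = force)
}
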