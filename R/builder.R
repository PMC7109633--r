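# Rasterize an elliptical somite: a ring of polarized epithelial cells
# (basal outside, lateral middle, apical inside, areas ~1:2:1) around a
# mesenchymal core partitioned into coreCells Voronoi territories.
# Works in normalized ellipse coordinates so the same code draws the
# circular build-time somite and the elliptical synthetic fixtures.
rasterizeSomite <- function(grid, center, semiA, semiB, theta = 0,
                            ringCells, coreCells, ringFrac,
                            labelOffset = 0L, cellOffset = 0L, seed = 1L) {
  H <- nrow(grid); W <- ncol(grid)
  cx <- center[1]; cy <- center[2]
  bbx <- max(2, floor(cx - max(semiA, semiB) - 1)):min(W - 1, ceiling(cx + max(semiA, semiB) + 1))
  bby <- max(2, floor(cy - max(semiA, semiB) - 1)):min(H - 1, ceiling(cy + max(semiA, semiB) + 1))
  pts <- expand.grid(x = bbx, y = bby)
  dx <- pts$x - cx; dy <- pts$y - cy
  rx <- (cos(theta) * dx + sin(theta) * dy) / semiA
  ry <- (-sin(theta) * dx + cos(theta) * dy) / semiB
  rho2 <- rx^2 + ry^2
  inside <- rho2 <= 1
  if (!any(inside)) stop("geometry error: somite rasterizes to zero sites")

  rhoC2 <- (1 - ringFrac)^2      # core boundary in normalized rho^2
  q <- (1 - rhoC2) / 4           # 1:2:1 band split by equal rho^2 (area)
  phi <- atan2(ry, rx)
  ringIdx <- (floor((phi + pi) / (2 * pi) * ringCells)) %% ringCells  # 0-based

  nRingComp <- 3L * ringCells
  # ring cell i (1-based): apical = off+3(i-1)+1, lateral +2, basal +3
  lab <- integer(nrow(pts))
  isRing <- inside & rho2 >= rhoC2
  band <- integer(nrow(pts))                       # 1 apical, 2 lateral, 3 basal
  band[isRing & rho2 < rhoC2 + q] <- 1L
  band[isRing & rho2 >= rhoC2 + q & rho2 < rhoC2 + 3 * q] <- 2L
  band[isRing & rho2 >= rhoC2 + 3 * q] <- 3L
  lab[isRing] <- labelOffset + 3L * ringIdx[isRing] + band[isRing]

  # core: nearest-seed partition in normalized coordinates (sunflower layout)
  isCore <- inside & rho2 < rhoC2
  set.seed(seed)
  k <- coreCells
  i <- seq_len(k)
  sr <- sqrt((i - 0.5) / k) * sqrt(rhoC2) * 0.92
  sphi <- i * 2.399963 + runif(k, 0, 0.3)
  seedX <- sr * cos(sphi); seedY <- sr * sin(sphi)
  if (any(isCore)) {
    d2 <- outer(rx[isCore], seedX, "-")^2 + outer(ry[isCore], seedY, "-")^2
    lab[isCore] <- labelOffset + nRingComp + max.col(-d2, ties.method = "first")
  }

  sel <- lab > 0L
  grid[cbind(pts$y[sel], pts$x[sel])] <- lab[sel]

  comp <- data.frame(
    label = labelOffset + seq_len(nRingComp + coreCells),
    cell = cellOffset + c(rep(seq_len(ringCells), each = 3L), ringCells + seq_len(coreCells)),
    role = c(rep(c(ROLE_CODES[["apical"]], ROLE_CODES[["lateral"]],
                   ROLE_CODES[["basal"]]), ringCells),
             rep(ROLE_CODES[["body"]], coreCells)),
    ctype = c(rep(c(3L, 4L, 5L), ringCells), rep(1L, coreCells)))
  cells <- data.frame(
    id = cellOffset + seq_len(ringCells + coreCells),
    class = c(rep(CLASS_CODES[["epithelial"]], ringCells),
              rep(CLASS_CODES[["mesenchymal"]], coreCells)),
    metOrigin = 0L, streak = 0L)

  counts <- tabulate(lab[sel] - labelOffset, nbins = nRingComp + coreCells)
  if (any(counts == 0))
    stop("geometry error: somite too small, ", sum(counts == 0),
         " empty compartment(s); enlarge the somite or reduce cell counts")
  list(grid = grid, comp = comp, cells = cells, ringCells = ringCells,
       apicalLabels = labelOffset + 3L * (seq_len(ringCells) - 1L) + 1L)
}

compartmentGeometry <- function(grid, nComp) {
  idx <- which(grid > 0, arr.ind = TRUE)
  lab <- grid[idx]
  area <- tabulate(lab, nbins = nComp)
  sumx <- vapply(seq_len(nComp), function(l) 0, numeric(1))
  sumx <- as.numeric(rowsum(as.numeric(idx[, 2]), lab)[, 1][as.character(seq_len(nComp))])
  sumy <- as.numeric(rowsum(as.numeric(idx[, 1]), lab)[, 1][as.character(seq_len(nComp))])
  sumx[is.na(sumx)] <- 0; sumy[is.na(sumy)] <- 0
  list(area = area, sumx = sumx, sumy = sumy,
       cx = ifelse(area > 0, sumx / area, NA_real_),
       cy = ifelse(area > 0, sumy / area, NA_real_))
}

#' Build the initial somite configuration
#'
#' Constructs the full starting state: a circular somite (mesenchymal core,
#' one-cell-thick polarized epithelial ring with apical facing inward),
#' embedded in a hexagonally packed mesh of small ECM cells joined by
#' elastic springs. Apical domains of ring neighbours are connected by
#' tight-junction springs forming a single closed cycle; each epithelial
#' cell's three compartments are linked by cytoskeletal springs. ECM cells
#' in the left edge strip are anchored to fixed points, those in the right
#' strip to points that the strain protocol displaces outward.
#'
#' @param geometry a [SomiteGeometry-class].
#' @param params a [CPMParams-class].
#' @param seed integer seed for the core-partition jitter.
#' @return a [SomiteModel-class] with target areas set to the as-built
#'   compartment areas.
#' @examples
#' m <- buildSomite(somiteGeometry(), cpmParams(), seed = 1)
#' cellCounts(m)
#' @export
buildSomite <- function(geometry = somiteGeometry(), params = cpmParams(),
                        seed = 1L) {
  validObject(geometry)
  W <- geometry@width + geometry@reserve
  H <- geometry@height
  grid <- matrix(0L, H, W)

  som <- rasterizeSomite(grid, geometry@center,
                         semiA = geometry@outerRadius,
                         semiB = geometry@outerRadius, theta = 0,
                         ringCells = geometry@ringCells,
                         coreCells = geometry@coreCells,
                         ringFrac = geometry@ringThickness / geometry@outerRadius,
                         seed = seed)
  grid <- som$grid
  comp <- som$comp
  cells <- som$cells

  # --- ECM: sparse fibre-network mesh -----------------------------------
  # Small ECM node cells on a hexagonal layout with medium in between; the
  # matrix mechanics live in the spring network joining the nodes, not in
  # dense cell packing (which cannot sustain large tensile strain).
  h <- geometry@ecmSpacing
  rows <- seq(2 + h / 2, geometry@height - 1.5, by = h * sqrt(3) / 2)
  nodes <- do.call(rbind, lapply(seq_along(rows), function(j) {
    xs <- seq(2 + h / 2 + (j %% 2) * h / 2, geometry@width - 1.5, by = h)
    cbind(x = xs, y = rows[j])
  }))
  ndx <- nodes[, 1] - geometry@center[1]; ndy <- nodes[, 2] - geometry@center[2]
  nodes <- nodes[sqrt(ndx^2 + ndy^2) > geometry@outerRadius + h * 0.3, , drop = FALSE]

  rNode <- max(1.6, h * 0.32)
  act <- expand.grid(x = 2:(geometry@width - 1), y = 2:(H - 1))
  act <- act[grid[cbind(act$y, act$x)] == 0L, ]
  d2 <- outer(act$x, nodes[, 1], "-")^2 + outer(act$y, nodes[, 2], "-")^2
  nearest <- max.col(-d2, ties.method = "first")
  nd <- d2[cbind(seq_len(nrow(act)), nearest)]
  inNode <- nd <= rNode^2
  act <- act[inNode, ]; nearest <- nearest[inNode]
  used <- sort(unique(nearest))
  nodeLab <- match(nearest, used) + nrow(comp)
  grid[cbind(act$y, act$x)] <- as.integer(nodeLab)
  nodes <- nodes[used, , drop = FALSE]
  nEcm <- nrow(nodes)

  ecmCell0 <- nrow(cells)
  comp <- rbind(comp, data.frame(
    label = nrow(comp) + seq_len(nEcm),
    cell = ecmCell0 + seq_len(nEcm),
    role = ROLE_CODES[["ecm"]], ctype = 2L))
  cells <- rbind(cells, data.frame(
    id = ecmCell0 + seq_len(nEcm), class = CLASS_CODES[["ecm"]],
    metOrigin = 0L, streak = 0L))

  geo <- compartmentGeometry(grid, nrow(comp))
  comp$area <- geo$area
  comp$target <- as.numeric(geo$area)
  comp$lam <- ifelse(comp$ctype == 2L, params@lambdaEcm, params@lambdaA)
  comp$sumx <- geo$sumx
  comp$sumy <- geo$sumy

  # --- springs ---------------------------------------------------------
  cdist <- function(a, b) sqrt((geo$cx[a] - geo$cx[b])^2 + (geo$cy[a] - geo$cy[b])^2)
  springs <- list()
  addSprings <- function(a, b, rest, k, snap, kind, side = 0L,
                         ax = 0, ay = 0) {
    data.frame(a = a, b = b, ax = ax, ay = ay, rest = rest, k = k,
               snap = snap, kind = kind, side = side, alive = TRUE)
  }
  apical <- som$apicalLabels
  nxt <- c(apical[-1], apical[1])
  springs$junction <- addSprings(apical, nxt, rest = cdist(apical, nxt),
                                 k = params@kJunction,
                                 snap = cdist(apical, nxt) + params@snapExt,
                                 kind = KIND_CODES[["junction"]])
  ringA <- apical; ringL <- apical + 1L; ringB <- apical + 2L
  springs$cyto <- addSprings(
    c(ringA, ringL, ringA), c(ringL, ringB, ringB),
    rest = cdist(c(ringA, ringL, ringA), c(ringL, ringB, ringB)),
    k = params@kCyto, snap = Inf, kind = KIND_CODES[["cytoskeleton"]])

  ecmLab <- nrow(som$comp) + seq_len(nEcm)
  pairs <- which(outer(nodes[, 1], nodes[, 1], "-")^2 +
                 outer(nodes[, 2], nodes[, 2], "-")^2 < (1.45 * h)^2,
                 arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  springs$mesh <- addSprings(ecmLab[pairs[, 1]], ecmLab[pairs[, 2]],
                             rest = cdist(ecmLab[pairs[, 1]], ecmLab[pairs[, 2]]),
                             k = params@kEcm, snap = Inf,
                             kind = KIND_CODES[["anchor"]])

  # fibronectin-like adhesion: each basal domain tethered to its nearest
  # ECM nodes so matrix tension reaches the somite surface
  basal <- som$apicalLabels + 2L
  bd <- outer(geo$cx[basal], nodes[, 1], "-")^2 +
        outer(geo$cy[basal], nodes[, 2], "-")^2
  tether <- do.call(rbind, lapply(seq_along(basal), function(i) {
    near <- order(bd[i, ])[1:2]
    data.frame(a = basal[i], b = ecmLab[near])
  }))
  # tethers remodel: they snap at 1.25x the junction extension, which caps
  # the force the matrix can exert on the somite surface
  springs$matrix <- addSprings(tether$a, tether$b,
                               rest = cdist(tether$a, tether$b),
                               k = params@kMatrix,
                               snap = cdist(tether$a, tether$b) + 1.25 * params@snapExt,
                               kind = KIND_CODES[["matrix"]])

  leftStrip <- which(geo$cx[ecmLab] <= 2 + geometry@anchorBand)
  rightStrip <- which(geo$cx[ecmLab] >= geometry@width - 1 - geometry@anchorBand)
  anchor <- function(strip, side) {
    l <- ecmLab[strip]
    addSprings(l, 0L, rest = 0, k = params@kAnchor, snap = Inf,
               kind = KIND_CODES[["anchor"]], side = side,
               ax = geo$cx[l], ay = geo$cy[l])
  }
  springs$anchorL <- anchor(leftStrip, -1L)
  springs$anchorR <- anchor(rightStrip, 1L)
  # dorsoventral confinement: every node rides a vertical rail at its build
  # height (y-only restoring force; axial motion free)
  springs$rails <- addSprings(ecmLab, 0L, rest = 0, k = params@kConfine,
                              snap = Inf, kind = KIND_CODES[["anchor"]],
                              side = 2L, ax = geo$cx[ecmLab],
                              ay = geo$cy[ecmLab])
  springs <- do.call(rbind, unname(springs))
  rownames(springs) <- NULL

  anchorSep0 <- mean(springs$ax[springs$side == 1L]) -
                mean(springs$ax[springs$side == -1L])

  new("SomiteModel", grid = grid, comp = comp, cells = cells,
      springs = springs, params = params, anchorSep0 = anchorSep0,
      anchorShift = 0,
      meta = list(geometry = geometry, seed = seed,
                  center = geometry@center))
}

#' Check all structural invariants of a configuration
#'
#' Verifies the label registry (every grid label registered, every
#' compartment present in the grid), the incremental area/centroid
#' bookkeeping against a full rescan, compartment-role composition per cell
#' class, and spring endpoint validity. Violations are reported, not thrown.
#'
#' @param model a [SomiteModel-class].
#' @return data.frame (check, id, message); zero rows means valid.
#' @export
validateConfiguration <- function(model) {
  v <- list()
  bad <- function(check, id, message)
    data.frame(check = check, id = id, message = message)
  grid <- model@grid; comp <- model@comp; cells <- model@cells
  spr <- model@springs

  labs <- grid[grid > 0L]
  orphan <- setdiff(unique(labs), comp$label)
  for (l in orphan) v[[length(v) + 1]] <- bad("registry", l, "unregistered label in grid")

  area <- tabulate(labs, nbins = nrow(comp))
  for (l in which(area == 0L))
    v[[length(v) + 1]] <- bad("registry", l, "registered compartment absent from grid")
  mism <- which(area != comp$area & area > 0L)
  for (l in mism)
    v[[length(v) + 1]] <- bad("area", l, sprintf(
      "bookkept area %d != rescan %d", comp$area[l], area[l]))
  geo <- compartmentGeometry(grid, nrow(comp))
  off <- which(abs(geo$sumx - comp$sumx) > 1e-6 | abs(geo$sumy - comp$sumy) > 1e-6)
  for (l in off)
    v[[length(v) + 1]] <- bad("centroid", l, "bookkept centroid sums differ from rescan")

  for (i in seq_len(nrow(cells))) {
    rl <- sort(comp$role[comp$cell == cells$id[i]])
    cls <- cells$class[i]
    ok <- switch(as.character(cls),
      "1" = identical(rl, ROLE_CODES[["body"]]),
      "2" = identical(rl, sort(unname(ROLE_CODES[c("apical", "lateral", "basal")]))) ||
            identical(rl, sort(unname(ROLE_CODES[c("apical", "lateral")]))),
      "3" = identical(rl, unname(ROLE_CODES[["ecm"]])))
    if (!isTRUE(ok))
      v[[length(v) + 1]] <- bad("roles", cells$id[i], sprintf(
        "cell class %s has roles {%s}", decodeClass(cls),
        paste(decodeRole(rl), collapse = ",")))
  }

  al <- spr[spr$alive, , drop = FALSE]
  badEnd <- which(al$a < 1 | al$a > nrow(comp) | al$b < 0 | al$b > nrow(comp))
  for (i in badEnd)
    v[[length(v) + 1]] <- bad("spring", i, "spring references unknown compartment")
  ju <- al[al$kind == KIND_CODES[["junction"]], , drop = FALSE]
  if (nrow(ju)) {
    aOK <- comp$role[ju$a] == ROLE_CODES[["apical"]] &
           comp$role[ju$b] == ROLE_CODES[["apical"]] &
           comp$cell[ju$a] != comp$cell[ju$b]
    for (i in which(!aOK))
      v[[length(v) + 1]] <- bad("spring", i,
        "junction spring must join apical domains of distinct cells")
    if (any(ju$snap <= ju$rest))
      v[[length(v) + 1]] <- bad("spring", NA,
        "junction snap threshold must exceed rest length")
  }
  cy <- al[al$kind == KIND_CODES[["cytoskeleton"]], , drop = FALSE]
  for (i in which(comp$cell[cy$a] != comp$cell[cy$b]))
    v[[length(v) + 1]] <- bad("spring", i,
      "cytoskeleton spring must stay within one cell")

  if (length(v)) do.call(rbind, v)
  else data.frame(check = character(), id = integer(), message = character())
}

#' Junction-ring topology
#'
#' Returns the graph of alive tight-junction springs as an edge list of cell
#' ids, plus whether it forms a single closed cycle over all epithelial
#' cells (the as-built topology).
#'
#' @param model a [SomiteModel-class].
#' @return list(edges, isSingleCycle).
#' @export
junctionGraph <- function(model) {
  spr <- model@springs
  ju <- spr[spr$alive & spr$kind == KIND_CODES[["junction"]], , drop = FALSE]
  edges <- cbind(model@comp$cell[ju$a], model@comp$cell[ju$b])
  epi <- model@cells$id[model@cells$class == CLASS_CODES[["epithelial"]]]
  deg <- tabulate(factor(c(edges), levels = epi), nbins = length(epi))
  single <- length(epi) > 0 && nrow(edges) == length(epi) && all(deg == 2L) &&
    isSingleComponent(edges, epi)
  list(edges = edges, isSingleCycle = single)
}

isSingleComponent <- function(edges, nodes) {
  if (!length(nodes)) return(FALSE)
  seen <- setNames(rep(FALSE, length(nodes)), nodes)
  stack <- nodes[1]
  while (length(stack)) {
    n <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (seen[as.character(n)]) next
    seen[as.character(n)] <- TRUE
    nb <- c(edges[edges[, 1] == n, 2], edges[edges[, 2] == n, 1])
    stack <- c(stack, nb[!seen[as.character(nb)]])
  }
  all(seen)
}
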