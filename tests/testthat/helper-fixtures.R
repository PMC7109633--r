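# Shared fixtures: hand-built miniature models and an independent R
# implementation of the Hamiltonian used as the energy oracle.

simpleParams <- function(J = matrix(1, 6, 6), Jintra = 0.5,
                         lambdaA = 0, temp = 2, ...) {
  if (all(dim(J) == 6L)) J <- expandContactMatrix((J + t(J)) / 2)
  cpmParams(J = (J + t(J)) / 2, Jintra = Jintra, lambdaA = lambdaA,
            temp = temp, ...)
}

# Build a SomiteModel directly from a label grid and registry vectors.
# roles: named by label; classes: named by cell id.
makeModel <- function(grid, cellOf, roleOf, classOf, springs = NULL,
                      params = simpleParams(), target = NULL, lam = NULL) {
  nComp <- length(cellOf)
  roleCode <- somiteCPM:::ROLE_CODES[roleOf]
  classCode <- somiteCPM:::CLASS_CODES[classOf]
  ctype <- integer(nComp)
  for (l in seq_len(nComp)) {
    cls <- classOf[cellOf[l]]
    ctype[l] <- switch(roleOf[l], body = if (cls == "mesenchymal") 1L else 0L,
                       apical = 3L, lateral = 4L, basal = 5L, ecm = 2L)
  }
  geo <- somiteCPM:::compartmentGeometry(grid, nComp)
  if (is.null(target)) target <- as.numeric(geo$area)
  if (is.null(lam)) lam <- rep(params@lambdaA, nComp)
  comp <- data.frame(label = seq_len(nComp), cell = cellOf,
                     role = unname(roleCode), ctype = ctype,
                     area = geo$area, target = target, lam = lam,
                     sumx = geo$sumx, sumy = geo$sumy)
  cells <- data.frame(id = seq_along(classOf),
                      class = unname(classCode),
                      metOrigin = 0L, streak = 0L)
  if (is.null(springs))
    springs <- data.frame(a = integer(), b = integer(), ax = numeric(),
                          ay = numeric(), rest = numeric(), k = numeric(),
                          snap = numeric(), kind = integer(),
                          side = integer(), alive = logical())
  new("SomiteModel", grid = grid, comp = comp, cells = cells,
      springs = springs, params = params, anchorSep0 = 0, anchorShift = 0,
      meta = list())
}

springRow <- function(a, b = 0L, ax = 0, ay = 0, rest = 1, k = 1,
                      snap = Inf, kind = "cytoskeleton", side = 0L) {
  data.frame(a = a, b = b, ax = ax, ay = ay, rest = rest, k = k, snap = snap,
             kind = somiteCPM:::KIND_CODES[[kind]], side = side, alive = TRUE)
}

# Independent full-recomputation Hamiltonian (pure R, no engine code).
oracleEnergy <- function(model) {
  grid <- model@grid; comp <- model@comp; p <- model@params
  H <- nrow(grid); W <- ncol(grid)
  cellOf <- comp$cell; ctype <- comp$ctype
  typeAt <- function(lab) {
    out <- ctype[pmax(lab, 1L)]
    out[lab == 0L] <- 0L
    out
  }
  E <- 0
  offs <- list(c(1, 0), c(0, 1), c(1, 1), c(-1, 1))  # forward half of 8-nbhd
  for (d in offs) {
    dy <- d[1]; dx <- d[2]
    ys <- seq_len(H); xs <- seq_len(W)
    ysA <- ys[ys + dy >= 1 & ys + dy <= H]
    xsA <- xs[xs + dx >= 1 & xs + dx <= W]
    a <- grid[ysA, xsA, drop = FALSE]
    b <- grid[ysA + dy, xsA + dx, drop = FALSE]
    same <- a == b
    sameCell <- !same & a > 0L & b > 0L &
      matrix(cellOf[pmax(a, 1L)] == cellOf[pmax(b, 1L)], nrow(a))
    sameCell[is.na(sameCell)] <- FALSE
    het <- !same & !sameCell
    E <- E + sum(sameCell) * p@Jintra
    if (any(het)) {
      ta <- typeAt(a[het]); tb <- typeAt(b[het])
      E <- E + sum(p@J[cbind(ta + 1L, tb + 1L)])
    }
  }
  area <- tabulate(grid[grid > 0L], nbins = nrow(comp))
  E <- E + sum(comp$lam * (area - comp$target)^2)
  spr <- model@springs
  spr <- spr[spr$alive, , drop = FALSE]
  if (nrow(spr)) {
    idx <- which(grid > 0L, arr.ind = TRUE)
    lab <- grid[idx]
    cx <- tapply(idx[, 2], lab, mean)[as.character(seq_len(nrow(comp)))]
    cy <- tapply(idx[, 1], lab, mean)[as.character(seq_len(nrow(comp)))]
    for (i in seq_len(nrow(spr))) {
      ax <- cx[spr$a[i]]; ay <- cy[spr$a[i]]
      if (spr$b[i] > 0L) { bx <- cx[spr$b[i]]; by <- cy[spr$b[i]] }
      else if (spr$side[i] == 2L) { bx <- ax; by <- spr$ay[i] }
      else { bx <- spr$ax[i]; by <- spr$ay[i] }
      d <- sqrt((ax - bx)^2 + (ay - by)^2)
      E <- E + 0.5 * spr$k[i] * (d - spr$rest[i])^2
    }
  }
  unname(E)
}

# Random compartmental configurations on small grids (all labels present).
randomModel <- function(seed, W = 15L, H = 15L, nCellGroups = 4L) {
  set.seed(seed)
  repeat {
    # three-compartment cells plus single-compartment cells
    cellOf <- integer(0); roleOf <- character(0); classOf <- character(0)
    for (g in seq_len(nCellGroups)) {
      kind <- sample(c("epi", "mes", "ecm"), 1)
      cid <- length(classOf) + 1L
      if (kind == "epi") {
        classOf <- c(classOf, "epithelial")
        cellOf <- c(cellOf, rep(cid, 3L))
        roleOf <- c(roleOf, "apical", "lateral", "basal")
      } else if (kind == "mes") {
        classOf <- c(classOf, "mesenchymal")
        cellOf <- c(cellOf, cid); roleOf <- c(roleOf, "body")
      } else {
        classOf <- c(classOf, "ecm")
        cellOf <- c(cellOf, cid); roleOf <- c(roleOf, "ecm")
      }
    }
    nComp <- length(cellOf)
    seeds <- cbind(x = sample(2:(W - 1), nComp), y = sample(2:(H - 1), nComp))
    pts <- expand.grid(y = 1:H, x = 1:W)
    d2 <- outer(pts$x, seeds[, "x"], "-")^2 + outer(pts$y, seeds[, "y"], "-")^2
    grid <- matrix(max.col(-d2, ties.method = "first"), H, W)
    # punch a medium pocket and freeze the frame to medium
    hx <- sample(3:(W - 2), 1); hy <- sample(3:(H - 2), 1)
    grid[abs(row(grid) - hy) + abs(col(grid) - hx) <= 2] <- 0L
    grid[c(1, H), ] <- 0L; grid[, c(1, W)] <- 0L
    if (all(seq_len(nComp) %in% grid)) break
  }
  J <- matrix(runif(36, 0, 10), 6)
  springs <- rbind(
    springRow(sample(nComp, 1), sample(nComp, 1), rest = runif(1, 1, 4),
              k = runif(1, 0.5, 3)),
    springRow(sample(nComp, 1), 0L, ax = runif(1, 1, W), ay = runif(1, 1, H),
              rest = runif(1, 0, 3), k = runif(1, 0.5, 3), kind = "anchor"),
    springRow(sample(nComp, 1), 0L, ay = runif(1, 1, H),
              rest = 0, k = runif(1, 0.5, 3), kind = "anchor", side = 2L))
  makeModel(grid, cellOf, roleOf, classOf, springs = springs,
            params = simpleParams(J = J, Jintra = runif(1, 0, 3),
                                  lambdaA = runif(1, 0.5, 2), temp = 5))
}

# Apply one copy to a model the slow way (grid edit + full rescan).
applyCopyRescan <- function(model, x, y, s) {
  grid <- model@grid
  grid[y, x] <- s
  geo <- somiteCPM:::compartmentGeometry(grid, nrow(model@comp))
  model@grid <- grid
  model@comp$area <- geo$area
  model@comp$sumx <- geo$sumx
  model@comp$sumy <- geo$sumy
  model
}

# A small fixture with one epithelial cell (three vertical bands) and one
# mesenchymal blob touching its lateral band. Used by the MET-rule tests.
metFixture <- function(gap = FALSE, params = NULL) {
  W <- 14L; H <- 10L
  grid <- matrix(0L, H, W)
  grid[3:8, 3:4] <- 1L   # apical
  grid[3:8, 5:6] <- 2L   # lateral
  grid[3:8, 7:8] <- 3L   # basal
  mesCols <- if (gap) 11:12 else 9:10
  grid[3:8, mesCols] <- 4L
  if (is.null(params))
    params <- simpleParams(lambdaA = 1, metMinContact = 3L,
                           metThreshold = 600L)
  makeModel(grid, cellOf = c(1L, 1L, 1L, 2L),
            roleOf = c("apical", "lateral", "basal", "body"),
            classOf = c("epithelial", "mesenchymal"),
            params = params)
}
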