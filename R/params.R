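#' Energy and rule parameters for the compartmental CPM
#'
#' Holds the contact-energy matrix, area-constraint strength, Metropolis
#' temperature, spring constants and the MET contact-timer settings. Contact
#' energies are indexed by site type: `medium`, `mesenchymal` (body of a
#' somitocoel cell), `ecm`, and the three epithelial compartment roles
#' `apical`, `lateral`, `basal`. Contacts between two compartments of the
#' same cell use the single intracellular energy `Jintra` (strongly negative,
#' holding a cell's compartments together).
#'
#' @slot J symmetric 9x9 contact-energy matrix (energy units), rows/columns
#'   ordered `medium, mesenchymal, ecm, apical, lateral, basal, metApical,
#'   metLateral, metBasal`. The `met*` types are the compartments of nascent
#'   epithelial cells created by MET: slightly less cohesive than the mature
#'   ring, so that daughter somites separate along the newly formed
#'   epithelium.
#' @slot Jintra contact energy between compartments of the same cell.
#' @slot lambdaA area-constraint strength (energy per site^2) for somitic
#'   compartments.
#' @slot lambdaEcm area-constraint strength for ECM cells; softer than
#'   lambdaA so the matrix can comply with imposed stretch instead of
#'   cavitating.
#' @slot temp Metropolis temperature (energy units), > 0.
#' @slot neighborOrder neighbour order for contact energy (fixed at 2, i.e.
#'   the 8-neighbourhood; copy attempts use 1st-order neighbours).
#' @slot snapExt extension beyond rest length (lattice units) at which a
#'   tight-junction spring snaps; snapped springs are removed permanently.
#' @slot captureRadius radius (lattice units) within which a newly
#'   epithelialized cell forms junctions to existing apical domains.
#' @slot junctionRest rest length for junction springs created at MET.
#' @slot kConfine stiffness of the vertical rail anchors confining each ECM
#'   node to its build height, emulating the dorsoventral confinement of the
#'   midline; axial motion is unconstrained.
#' @slot kJunction,kCyto,kEcm,kMatrix,kAnchor spring stiffnesses
#'   (energy / lattice-unit^2) for tight junctions, cytoskeletal links, the
#'   ECM mesh, the fibronectin-like basal-to-matrix adhesion links, and the
#'   boundary anchors.
#' @slot metThreshold qualifying-contact streak (MCS) required for MET;
#'   default 600 MCS, about 4 minutes at the model's time calibration.
#' @slot metMinContact minimum boundary site-pairs per MCS for a contact to
#'   qualify (suppresses single-site flicker).
#' @slot mcsPerHour time calibration: Monte Carlo steps per hour (10,000).
#'
#' @seealso [cpmParams()]
#' @export
setClass("CPMParams", representation(
  J = "matrix", Jintra = "numeric", lambdaA = "numeric",
  lambdaEcm = "numeric", temp = "numeric",
  neighborOrder = "integer", snapExt = "numeric", captureRadius = "numeric",
  junctionRest = "numeric", kJunction = "numeric", kCyto = "numeric",
  kEcm = "numeric", kMatrix = "numeric", kAnchor = "numeric",
  kConfine = "numeric", metThreshold = "integer",
  metMinContact = "integer", mcsPerHour = "numeric"))

setValidity("CPMParams", function(object) {
  msg <- character()
  J <- object@J
  if (!is.numeric(J) || !identical(dim(J), c(9L, 9L)))
    msg <- c(msg, "J must be a numeric 9x9 matrix")
  else if (!isTRUE(all.equal(J, t(J))))
    msg <- c(msg, "J must be symmetric")
  if (object@temp <= 0) msg <- c(msg, "temp must be > 0")
  if (object@snapExt <= 0)
    msg <- c(msg, "snapExt must be > 0 (snap threshold above rest length)")
  if (object@metThreshold <= 0) msg <- c(msg, "metThreshold must be > 0")
  if (object@lambdaA < 0) msg <- c(msg, "lambdaA must be >= 0")
  if (object@lambdaEcm < 0) msg <- c(msg, "lambdaEcm must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Default contact-energy matrix
#'
#' The published model's energy constants are not printed; these defaults are
#' calibrated so an unstretched somite remains intact over a full run while
#' pulls beyond the division threshold rupture the apical junction ring (see
#' the calibration script in `inst/scripts/`). Low values mean strong
#' adhesion. The ordering encodes epithelial polarity: apical surfaces
#' adhere to each other and face the mesenchymal core; basal surfaces adhere
#' to the ECM; lateral surfaces adhere to neighbouring lateral surfaces.
#'
#' @return symmetric 9x9 numeric matrix with type dimnames.
#' @export
defaultContactEnergies <- function() {
  J <- matrix(0, 6, 6)
  J[1, ] <- c(0, 26, 6, 26, 16, 14)     # medium
  J[2, ] <- c(26, 0, 16, 4, 5.5, 7.5)   # mesenchymal
  J[3, ] <- c(6, 16, 3, 26, 18, 2)      # ecm
  J[4, ] <- c(26, 4, 26, 4, 9, 12)      # apical
  J[5, ] <- c(16, 5.5, 18, 9, 8, 8)     # lateral
  J[6, ] <- c(14, 7.5, 2, 12, 8, 40)    # basal
  J <- expandContactMatrix((J + t(J)) / 2)
  # nascent epithelium: weaker mutual and cross cohesion of lateral faces,
  # lower surface tension -- the seam along which daughters separate
  J["metLateral", "metLateral"] <- 16
  J["metLateral", "lateral"] <- J["lateral", "metLateral"] <- 12
  J["metLateral", "medium"] <- J["medium", "metLateral"] <- 14
  J
}

#' Expand a 6-type contact matrix to the full 9-type matrix
#'
#' Copies the apical/lateral/basal rows and columns onto the corresponding
#' nascent (`met*`) types; overrides can then be applied entry-wise.
#'
#' @param J6 symmetric 6x6 matrix (types medium..basal).
#' @return symmetric 9x9 matrix with full type dimnames.
#' @export
expandContactMatrix <- function(J6) {
  stopifnot(identical(dim(J6), c(6L, 6L)))
  map <- c(1:6, 4:6)
  J <- J6[map, map]
  dimnames(J) <- list(TYPE_NAMES, TYPE_NAMES)
  J
}

#' Construct CPM energy/rule parameters
#'
#' @param J contact-energy matrix, see [defaultContactEnergies()].
#' @param Jintra intracellular (same-cell) contact energy.
#' @param lambdaA area-constraint strength (somitic compartments).
#' @param lambdaEcm area-constraint strength for ECM cells.
#' @param temp Metropolis temperature.
#' @param snapExt junction snap extension (lattice units beyond rest).
#' @param captureRadius junction capture radius at MET.
#' @param junctionRest rest length of MET-formed junction springs.
#' @param kJunction,kCyto,kEcm,kMatrix,kAnchor,kConfine spring stiffnesses.
#' @param metThreshold MET contact-timer threshold in MCS (600 = ~4 min).
#' @param metMinContact minimum qualifying boundary site-pairs per MCS.
#' @param mcsPerHour time calibration (10,000 MCS per hour).
#' @return a validated [CPMParams-class] object.
#' @examples
#' p <- cpmParams()
#' p@metThreshold   # 600 MCS, ~4 min
#' @export
cpmParams <- function(J = defaultContactEnergies(), Jintra = 2,
                      lambdaA = 2, lambdaEcm = 0.3, temp = 10, snapExt = 4,
                      captureRadius = 5, junctionRest = 2,
                      kJunction = 20, kCyto = 1.5, kEcm = 8, kMatrix = 18,
                      kAnchor = 50, kConfine = 2,
                      metThreshold = 600L, metMinContact = 3L,
                      mcsPerHour = 10000) {
  new("CPMParams", J = J, Jintra = Jintra, lambdaA = lambdaA,
      lambdaEcm = lambdaEcm, temp = temp,
      neighborOrder = 2L, snapExt = snapExt, captureRadius = captureRadius,
      junctionRest = junctionRest, kJunction = kJunction, kCyto = kCyto,
      kEcm = kEcm, kMatrix = kMatrix, kAnchor = kAnchor,
      kConfine = kConfine,
      metThreshold = as.integer(metThreshold),
      metMinContact = as.integer(metMinContact), mcsPerHour = mcsPerHour)
}

#' Parameter preset for the reduced-cohesion "subsomite" variant
#'
#' Lowers the cohesion between lateral domains of neighbouring epithelial
#' cells (and between lateral and apical surfaces), which fragments the
#' epithelial ring into small epithelioid clusters instead of a single
#' coherent shell.
#'
#' @param params base parameters to modify.
#' @param lateralPenalty amount added to the lateral-lateral contact energy.
#' @return modified [CPMParams-class] object.
#' @export
subsomiteParams <- function(params = cpmParams(), lateralPenalty = 12) {
  J <- params@J
  for (lt in c("lateral", "metLateral"))
    J[lt, c("lateral", "metLateral")] <- J[lt, c("lateral", "metLateral")] +
      lateralPenalty
  J["apical", "apical"] <- J["apical", "apical"] + lateralPenalty / 2
  initialize(params, J = (J + t(J)) / 2, kJunction = params@kJunction / 4)
}

setMethod("show", "CPMParams", function(object) {
  cat("CPMParams: T =", object@temp, ", lambdaA =", object@lambdaA,
      ", Jintra =", object@Jintra, "\n")
  cat("  MET: threshold", object@metThreshold, "MCS, min contact",
      object@metMinContact, "site-pairs\n")
  cat("  springs: kJ =", object@kJunction, ", kCyto =", object@kCyto,
      ", kEcm =", object@kEcm, ", snapExt =", object@snapExt, "\n")
})

paramsToList <- function(p) {
  list(J = unname(p@J), Jintra = p@Jintra, temp = p@temp,
       snapExt = p@snapExt, captureRadius = p@captureRadius,
       junctionRest = p@junctionRest, kJunction = p@kJunction,
       kCyto = p@kCyto, metThreshold = p@metThreshold,
       metMinContact = p@metMinContact)
}
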