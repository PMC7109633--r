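#' Total Hamiltonian energy of a configuration
#'
#' Sum of (i) contact energy over all unordered neighbour pairs with
#' differing labels, up to 2nd-order (8-connected) neighbours, (ii) the
#' quadratic area constraint `lam * (area - target)^2` per compartment, and
#' (iii) elastic spring energy `1/2 k (length - rest)^2` over alive springs,
#' with spring endpoints at compartment centroids (or fixed anchor points).
#'
#' @param model a [SomiteModel-class].
#' @return energy (numeric scalar).
#' @export
totalEnergy <- function(model) cppTotalEnergy(engineState(model))

#' Energy change of a hypothetical copy attempt
#'
#' Local computation of `H(after copying sourceLabel into site) - H(before)`.
#' A copy whose source equals the site's current label is signalled as a
#' no-op; a copy that would annihilate a compartment's last site is
#' forbidden (the compartment-extinction guard).
#'
#' @param model a [SomiteModel-class].
#' @param site integer `c(x, y)` (1-based lattice coordinates).
#' @param sourceLabel label to copy in (0 = medium).
#' @return list(delta, status) with status one of `"ok"`, `"noop"`,
#'   `"forbidden"`; delta is 0 unless `"ok"`.
#' @export
deltaEnergy <- function(model, site, sourceLabel) {
  res <- cppDeltaEnergy(engineState(model), as.integer(site[1]),
                        as.integer(site[2]), as.integer(sourceLabel))
  list(delta = res$delta,
       status = c("ok", "noop", "forbidden")[res$status + 1L])
}

#' Run Metropolis Monte Carlo steps
#'
#' One MCS performs `width * height` random copy attempts: a random interior
#' site, a random 1st-order neighbour as source. An attempt is accepted with
#' probability 1 if the energy change is non-positive, else
#' `exp(-deltaH / T)`. Areas, centroids and the somite-cluster centroid are
#' maintained incrementally. Fully reproducible from the seed.
#'
#' @param model a [SomiteModel-class].
#' @param n number of MCS.
#' @param seed integer RNG seed (engine-internal generator; R's RNG state is
#'   untouched).
#' @return list(model, accepted) with the updated model and the total number
#'   of accepted copies.
#' @export
metropolisMCS <- function(model, n = 1L, seed = 1L) {
  res <- cppRun(engineState(model), as.integer(n), integer(0), integer(0),
                numeric(0), 0L, 0L, as.integer(seed), 0L)
  list(model = modelFromState(res$state, model), accepted = res$accepted)
}

#' Recompute spring lengths and snap over-extended junctions
#'
#' Junction springs whose current centroid-to-centroid length exceeds their
#' snap threshold are removed permanently (marked dead) and reported.
#' Cytoskeletal and ECM springs never snap.
#'
#' @param model a [SomiteModel-class].
#' @return list(model, snapped) where snapped is an integer vector of spring
#'   row indices.
#' @export
updateSprings <- function(model) {
  res <- cppUpdateSprings(engineState(model))
  list(model = modelFromState(res$state, model), snapped = res$snapped)
}

#' Displace the pulled ECM anchors outward
#'
#' Shifts the anchor points of the right-edge ECM strip by `displacement`
#' lattice units along the pull axis; the left strip stays fixed. The
#' elastic mesh transmits the tension inward over subsequent MCS. The
#' imposed strain is exactly `anchorShift / anchorSep0` ([imposedStrain()]).
#'
#' @param model a [SomiteModel-class].
#' @param displacement non-negative displacement in lattice units.
#' @return the updated [SomiteModel-class].
#' @export
applyStrainStep <- function(model, displacement) {
  stopifnot(displacement >= 0)
  if (displacement == 0) return(model)
  res <- cppApplyStrain(engineState(model), displacement)
  modelFromState(res$state, model)
}

#' Empirical acceptance probability of one fixed copy attempt
#'
#' Computes the attempt's energy change once, then repeats the Metropolis
#' accept/reject decision `n` times. Used to verify the acceptance rule
#' against `exp(-deltaH / T)`.
#'
#' @param model a [SomiteModel-class].
#' @param site integer `c(x, y)`.
#' @param sourceLabel label to copy in.
#' @param n number of trials.
#' @param seed RNG seed.
#' @return list(delta, accepted, trials).
#' @export
acceptanceTrials <- function(model, site, sourceLabel, n = 10000L, seed = 1L) {
  cppAcceptanceTrials(engineState(model), as.integer(site[1]),
                      as.integer(site[2]), as.integer(sourceLabel),
                      as.integer(n), as.integer(seed))
}

#' Update MET contact timers for one MCS
#'
#' For each mesenchymal cell, the qualifying-contact streak increments by 1
#' if the cell's boundary shares at least `metMinContact` site-pairs with
#' the qualifying neighbour class this MCS — ECM compartments under scenario
#' `"ecm"`, lateral or basal epithelial compartments under scenario
#' `"lateral"` — and resets to 0 otherwise. Scenario `"none"` leaves all
#' timers at zero.
#'
#' @param model a [SomiteModel-class].
#' @param scenario `"none"`, `"ecm"` or `"lateral"`.
#' @return the updated [SomiteModel-class] (timers live in
#'   `cellTable(model)$streak`).
#' @export
updateContactTimers <- function(model, scenario = c("none", "ecm", "lateral")) {
  code <- scenarioCode(match.arg(scenario))
  res <- cppUpdateTimers(engineState(model), code)
  modelFromState(res$state, model)
}

#' Qualifying-contact counts for mesenchymal cells
#'
#' @param model a [SomiteModel-class].
#' @param scenario `"ecm"` or `"lateral"`.
#' @return data.frame (cell, count) of boundary site-pairs with the
#'   qualifying class in the current configuration.
#' @export
contactCounts <- function(model, scenario = c("ecm", "lateral")) {
  code <- scenarioCode(match.arg(scenario))
  as.data.frame(cppContactCounts(engineState(model), code))
}

#' Execute a mesenchymal-to-epithelial transition
#'
#' Partitions the cell's single compartment into apical, lateral and basal
#' bands (areas ~1:2:1) along the outward normal — away from the somite
#' cluster centroid, apical innermost — adds cytoskeletal springs between
#' the new compartments, and connects the new apical domain to the nearest
#' (at most 2) apical domains of other epithelial cells within the capture
#' radius. The cell's class becomes epithelial and its MET-origin flag is
#' set; total cell count is unchanged.
#'
#' @param model a [SomiteModel-class].
#' @param cellId a mesenchymal cell whose contact streak has reached the MET
#'   threshold (calling below threshold is a precondition error).
#' @return the updated [SomiteModel-class].
#' @export
executeMet <- function(model, cellId) {
  res <- cppExecuteMet(engineState(model), as.integer(cellId))
  modelFromState(res$state, model)
}

#' Run a full strain-protocol experiment
#'
#' Interleaves Metropolis sweeps, spring updates, MET contact-timer
#' bookkeeping and anchor displacement per the protocol schedule, recording
#' a snapshot every `snapshotInterval` MCS and logging snapped junctions and
#' MET events.
#'
#' @param model the starting [SomiteModel-class].
#' @param protocol a [StrainProtocol-class].
#' @param scenario MET scenario: `"none"`, `"ecm"` or `"lateral"`.
#' @param seed integer seed; identical model + protocol + seed reproduce the
#'   trajectory bit for bit.
#' @return a [SomiteTrajectory-class].
#' @examples
#' \donttest{
#' m <- buildSomite(somiteGeometry(), cpmParams(), seed = 1)
#' tr <- runExperiment(m, strainProtocol(totalMcs = 1000, pullStart = 200,
#'                     pullEnd = 600, rate = 0.02), "lateral", seed = 1)
#' tr
#' }
#' @export
runExperiment <- function(model, protocol = strainProtocol(),
                          scenario = c("none", "ecm", "lateral"),
                          seed = 1L) {
  scenario <- match.arg(scenario)
  validObject(protocol)
  res <- cppRun(engineState(model), protocol@totalMcs, protocol@pullStart,
                protocol@pullEnd, protocol@rate, scenarioCode(scenario),
                protocol@snapshotInterval, as.integer(seed), 0L)
  final <- modelFromState(res$state, model)
  new("SomiteTrajectory", snapshots = res$snapshots, events = res$events,
      protocol = protocol, finalModel = final,
      meta = list(seed = seed, scenario = scenario,
                  strain = imposedStrain(final), accepted = res$accepted))
}

#' Strain protocol reaching a target imposed strain
#'
#' Converts a target strain into a per-MCS anchor displacement rate over the
#' given pull windows, using the model's initial anchor separation.
#'
#' @param model a [SomiteModel-class] (for the anchor separation).
#' @param strain target imposed strain (e.g. 0.23 for 23 percent).
#' @param totalMcs,pullStart,pullEnd,snapshotInterval schedule, as in
#'   [strainProtocol()].
#' @return a [StrainProtocol-class].
#' @export
protocolForStrain <- function(model, strain, totalMcs = 20000L,
                              pullStart = 3000L, pullEnd = 7000L,
                              snapshotInterval = 500L) {
  stopifnot(strain >= 0)
  dur <- sum(pullEnd - pullStart)
  rate <- if (dur > 0) strain * model@anchorSep0 / dur else 0
  strainProtocol(totalMcs = totalMcs, pullStart = pullStart,
                 pullEnd = pullEnd, rate = rate,
                 snapshotInterval = snapshotInterval)
}
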