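---
title: "A compartmental Potts model of somite division under axial strain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A compartmental Potts model of somite division under axial strain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(somiteCPM)
```

## The biological question

Somites are the segmental blocks of paraxial mesoderm: an epithelial shell
of radially polarized cells around a mesenchymal core, the somitocoel,
embedded in a fibronectin-rich extracellular matrix (ECM). When an embryo
is stretched along its axis well beyond its natural tension, the most
elongated somites slowly reorganize into two or more well-formed daughter
somites, with new matrix deposited between them and somitocoel cells
apparently incorporated into the epithelium by a mesenchymal-to-epithelial
transition (MET). This package implements a two-dimensional cell-based
model of that process: a single somite in an elastic matrix, pulled along
one axis, with rule-based MET, plus the morphometrics and ROC analysis
used to relate somite shape to the probability of division.

## Model structure

The simulation is a compartmental Cellular Potts Model. Space is an
integer lattice; every site carries a compartment label; a compartment is
owned by a cell. Mesenchymal and ECM cells have one compartment;
epithelial cells have three (apical, lateral, basal), giving them polarity
through type-dependent contact energies. One Monte Carlo step (MCS)
performs `width x height` random copy attempts (source drawn from the
4-neighbourhood), accepted with probability `min(1, exp(-dH/T))`. The
Hamiltonian has three terms:

* **Adhesion.** Contact energy `J(tau, tau')` over all unlike neighbour
  pairs up to second order (8-neighbourhood). Types are medium,
  mesenchymal, ECM, the three epithelial compartment roles, and three
  `met*` types carried by cells created by MET (nascent epithelium).
  Contacts between compartments of one cell use a single small positive
  `Jintra`; a negative value would reward interface growth and shred the
  compartments into stripes.
* **Area constraint.** `lambda (a - A)^2` per compartment. ECM node cells
  use a softer `lambdaEcm` so the matrix complies with imposed stretch.
* **Springs.** `1/2 k (l - l0)^2` with endpoints at compartment centroids
  or fixed anchor points. Tight junctions connect neighbouring apical
  domains in a closed ring and snap permanently when stretched more than
  `snapExt` beyond rest; cytoskeletal springs triangulate each epithelial
  cell; the ECM mesh and the basal-to-matrix tethers carry the applied
  tension.

Copy attempts that would annihilate a compartment's last site are
rejected outright, so every compartment survives the whole run.

## The matrix and how strain reaches the somite

The ECM is a sparse fibre network: small node cells on a hexagonal layout
with medium between them, joined by springs. We found dense cell-packed
matrices unable to sustain large tensile strain — under a fast pull they
fracture at one plane instead of stretching, because a cell monolayer has
no bending stiffness and its area constraints frustrate uniform extension.
Three choices make the sparse network behave like an elastic slab:

* **Vertical rails.** Every node is anchored to its build height by a
  y-only spring (`kConfine`), the in-plane analogue of the dorsoventral
  confinement of the midline by neighbouring tissues. Without rails the
  network's rows buckle and collapse vertically (a central-force lattice
  has zero bending stiffness), squeezing the somite into ribbons of
  arbitrary aspect ratio.
* **Fibronectin tethers.** Each basal compartment is tied to its two
  nearest nodes. The tethers transmit the pull to the somite surface and
  snap at 1.25 times the junction extension, which caps the force the
  matrix can exert — pulling harder tears matrix contacts, not cells.
* **Anchored strips.** Node columns at the left edge are pinned; those at
  the right edge are pinned to anchor points that the strain protocol
  displaces. The imposed strain is, by construction, the anchor
  displacement divided by the initial anchor separation.

## MET rules and the division mechanism

Each mesenchymal cell keeps a qualifying-contact streak. Under the
`lateral` scenario a contact qualifies when the cell's boundary shares at
least `metMinContact` (default 3) site-pairs with lateral or basal
epithelial compartments during that MCS; under the `ecm` scenario, with
ECM; any gap resets the streak. When the streak reaches `metThreshold`
(600 MCS, about 4 minutes at the calibration of 10,000 MCS per hour) the
cell converts: its compartment is split 1:2:1 into apical, lateral and
basal bands along the outward normal from the cluster centroid (apical
innermost), cytoskeletal springs are added, and junctions form to at most
two apical domains within the capture radius.

Inside an intact somite the core touches only apical surfaces, so no
contact qualifies. Stretching beyond the ring's elastic limit snaps
junctions, the epithelium opens at the flanks, and core cells meet exposed
lateral/basal membranes — MET is therefore rupture-gated. Converted cells
carry `met*` contact types: nascent epithelium is less cohesive than the
mature ring (higher `metLateral` contact energies) and its basal surfaces
do not adhere to each other (`basal-basal` strongly unfavourable), which
makes the seam between two nascent-covered daughter surfaces the cheapest
plane of separation and lets matrix nodes wedge into it. This reproduces
the observed asymmetry: without MET the somite stretches and even beads,
but the mature ring plus the cohesive somitocoel hold it together at every
strain tested; with lateral-contact MET, supra-threshold runs divide.

## Parameters

The published account of this model class does not print its energy
constants, so `cpmParams()` ships values calibrated against two
behavioural anchors: an unstretched somite stays intact over a full run
(no snapped junctions, no MET, single cluster), and pulls beyond the
division threshold rupture the ring and divide under the lateral MET rule.
`inst/scripts/calibration-sweep.R` re-measures both anchors over a grid of
the three most influential parameters. The key defaults:

| parameter | default | units | role |
|---|---|---|---|
| `temp` | 10 | energy | Metropolis temperature; sets tissue fluidity |
| `lambdaA` / `lambdaEcm` | 2 / 0.3 | energy/site^2 | area stiffness of cells / matrix nodes |
| `Jintra` | 2 | energy | same-cell compartment interface cost |
| `kJunction`, `snapExt` | 20, 4 | energy/site^2, sites | ring stiffness and rupture threshold |
| `kEcm`, `kMatrix`, `kConfine` | 8, 18, 2 | energy/site^2 | mesh, tether, rail stiffness |
| `metThreshold` | 600 | MCS | MET contact timer (about 4 min) |
| `mcsPerHour` | 10000 | MCS/h | time calibration from the full protocol timeline |

Geometry defaults (desk preset): 120 x 60 active region plus 100 reserve
columns of medium, a 24-cell ring of outer radius 15 around 12 core cells,
mesh spacing 7. The full-scale preset doubles the linear dimensions and
uses the published timeline: pulls starting at 60,000 MCS (about 6 h) and
a run ending at 130,000 MCS (about 13 h). The desk preset compresses the
schedule to one pull from MCS 3,000 to 7,000 in a 20,000-MCS run with
snapshots every 250 MCS, keeping the displacement-to-somite-size ratio;
those problem sizes are the package's tested defaults and are what the
acceptance analysis uses.

## Synthetic data

The generators in this package produce all test inputs. `genSomiteImage()`
draws elliptical labelled somites (ring plus core) at a requested aspect
ratio with random orientation — emulating segmented micrographs, not raw
microscopy; there is no staining, noise, or point-spread. Pixel-level
ground truth is recorded so morphometric round-trips are exact.
`genDivisionTrajectory()` scripts a mother somite that is replaced by two
ring-enclosed daughters at a known frame, the fixture for division
detection. `genARDataset()` draws aspect-ratio scores for three groups
(control near 1.2, lognormal; stretched-undivided near 2.0;
stretched-divided near 3.2) and labels them with a hard threshold rule
plus optional label noise; these distributions are stand-ins anchored to
the printed thresholds, never a claim about measured embryos. Passing
round-trip tests on these fixtures shows the estimators are correct on
idealized segmentations; it does not validate them against real
microscopy.

## Numerical choices

* Contact energy uses the 8-neighbourhood; copy attempts the
  4-neighbourhood — standard practice to reduce lattice anisotropy.
* The lattice is allocated at its final width up front (active region plus
  reserve); anchors that would leave it raise a domain-overflow error
  instead of resizing the grid mid-run.
* Spring lengths are cached and recomputed exactly for affected
  compartments after each accepted copy; energies are plain doubles, and
  the incremental energy of an attempt agrees with full recomputation to
  better than 1e-9.
* The engine uses its own xoshiro256++ generator: identical seeds give
  bit-identical trajectories and R's RNG state is never touched.
* Aspect ratio comes from gyration-tensor eigenvalues (not bounding boxes
  or ellipse fits), which is translation/rotation invariant and robust on
  lattice blobs; collinear clusters raise a degenerate-shape error.
* Division detection requires two clusters of at least 4 cells with
  epithelial-majority perimeters persisting 10 snapshots, which filters
  both transient splits and bare mesenchymal fragments.
* Ties in the ROC use the 1/2 convention, making the rank AUC equal to the
  trapezoidal area; the bootstrap CI is a stratified percentile interval
  (2,000 replicates), chosen over exact binomial methods because it
  extends unchanged to the small, unbalanced sweeps produced here.

## Known limitations

* **Two dimensions.** Site counts stand in for volumes; comparisons are
  within-model only.
* **Stochastic division near the threshold.** At desk scale, whether a
  ruptured, fully epithelialized somite completes its separation within
  the 20,000-MCS window is stochastic: at 70 % strain most replicates
  divide, at 60 % most do not, and runs cut off mid-separation count as
  undivided while still carrying large pre-division aspect ratios. This
  compresses the measured ROC (AUC near 0.84 on the default sweep, versus
  near-perfect discrimination at full scale in the original experiments)
  and pushes the estimated aspect-ratio threshold to about 3 rather than
  2.5. The `scripts/acceptance.R` output quantifies both numbers for any
  seed.
* **No signalling.** Gene expression, the segmentation clock, and
  molecular MET markers are outside the model; MET is purely
  contact-timer-based.
* **Calibrated, not copied, constants.** All energy parameters are this
  package's calibration; behaviour, not parameter values, is the
  reproduction target.

## The subsomite variant

`subsomiteParams()` lowers the cohesion between lateral domains (and
apical-apical adhesion, and junction stiffness). Under the same strain
protocol the epithelial shell then fragments into several small
epithelioid clusters instead of two coherent daughters — the in-silico
analogue of reduced intercellular adhesion, checked qualitatively (more
than two clusters) in the test suite.
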