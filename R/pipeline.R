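#' Desk-scale and full-scale presets
#'
#' `deskPreset()` is the tested default: a 120 x 60 active region, one pull
#' from MCS 3,000 to 7,000, total 20,000 MCS, snapshots every 250 MCS (the
#' compressed desk schedule keeps the displacement-to-somite-size ratio of
#' the full-scale protocol).
#' `fullPreset()` is the full-scale configuration: a 240 x 120 active
#' region with a somite of twice the radius, two pull sessions starting at
#' 60,000 MCS (about 6 h at 10,000 MCS per hour) separated by a 2 h rest,
#' ending at 130,000 MCS (about 13 h).
#'
#' @return list(geometry, params, totalMcs, pullStart, pullEnd,
#'   snapshotInterval).
#' @export
deskPreset <- function() {
  list(geometry = somiteGeometry(), params = cpmParams(),
       totalMcs = 20000L, pullStart = 3000L, pullEnd = 7000L,
       snapshotInterval = 250L)
}

#' @rdname deskPreset
#' @export
fullPreset <- function() {
  list(geometry = somiteGeometry(width = 240L, height = 120L,
                                 reserve = 200L, outerRadius = 30,
                                 ringThickness = 10, ringCells = 24L,
                                 coreCells = 12L, ecmSpacing = 12,
                                 anchorBand = 10),
       params = cpmParams(),
       totalMcs = 130000L, pullStart = c(60000L, 89000L),
       pullEnd = c(69000L, 98000L), snapshotInterval = 500L)
}

presetByName <- function(name) {
  switch(match.arg(name, c("desk", "full")),
         desk = deskPreset(), full = fullPreset())
}

runSeedFor <- function(baseSeed, strainIdx, seedIdx) {
  as.integer((as.numeric(baseSeed) * 100003 + strainIdx * 101 + seedIdx) %%
             2147483647)
}

#' Run a strain sweep
#'
#' The in-silico experimental arm: for each (strain, seed) pair, build the
#' somite, run the strain protocol under the given MET scenario, and record
#' the division outcome and the per-run score (maximum pre-division aspect
#' ratio of the dominant cluster).
#'
#' @param strains imposed strains to test (default 0 to 0.8 in steps of
#'   0.1).
#' @param seedsPerStrain replicate runs per strain.
#' @param scenario MET scenario (`"none"`, `"ecm"`, `"lateral"`).
#' @param preset `"desk"` or `"full"`, or a preset list as returned by
#'   [deskPreset()].
#' @param seed base seed; per-run seeds are derived deterministically.
#' @param verbose print one line per run.
#' @return data.frame with one row per run: strain, seed, runSeed, score,
#'   divided, divisionMcs, metEvents, snappedJunctions, preEpiFraction,
#'   postEpiFraction.
#' @export
runSweep <- function(strains = seq(0, 0.8, by = 0.1), seedsPerStrain = 5L,
                     scenario = c("lateral", "none", "ecm"),
                     preset = "desk", seed = 1L, verbose = FALSE) {
  scenario <- match.arg(scenario)
  if (is.character(preset)) preset <- presetByName(preset)
  rows <- list()
  for (si in seq_along(strains)) {
    for (ri in seq_len(seedsPerStrain)) {
      rs <- runSeedFor(seed, si, ri)
      row <- runOnce(strains[si], scenario, preset, rs)
      rows[[length(rows) + 1L]] <- row
      if (verbose)
        message(sprintf(
          "strain %.2f seed %d: score %.2f divided %s (MET %d, snapped %d)",
          row$strain, rs, row$score, row$divided, row$metEvents,
          row$snappedJunctions))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

runOnce <- function(strain, scenario, preset, runSeed) {
  model <- buildSomite(preset$geometry, preset$params, seed = runSeed)
  proto <- protocolForStrain(model, strain, totalMcs = preset$totalMcs,
                             pullStart = preset$pullStart,
                             pullEnd = preset$pullEnd,
                             snapshotInterval = preset$snapshotInterval)
  tr <- runExperiment(model, proto, scenario, seed = runSeed)
  sc <- divisionScore(tr)
  cc <- cellTable(tr@finalModel)
  post <- sum(cc$class == "epithelial") /
          sum(cc$class %in% c("epithelial", "mesenchymal"))
  pre <- with(cellTable(model),
              sum(class == "epithelial") /
              sum(class %in% c("epithelial", "mesenchymal")))
  data.frame(strain = strain, seed = runSeed, scenario = scenario,
             score = sc$score, divided = sc$divided,
             divisionMcs = sc$divisionMcs,
             metEvents = sum(tr@events$event == "met"),
             snappedJunctions = sum(tr@events$event == "snap"),
             preEpiFraction = pre, postEpiFraction = post)
}

#' ROC analysis of a sweep
#'
#' @param runs data.frame from [runSweep()].
#' @param nBoot,seed bootstrap settings.
#' @return a [RocResult-class]; errors with a single-class message if no
#'   (or every) run divided.
#' @export
sweepRoc <- function(runs, nBoot = 2000L, seed = 1L) {
  rocAnalysis(runs$score, runs$divided, nBoot = nBoot, seed = seed)
}

#' Run the full configured pipeline
#'
#' Reads a YAML configuration (preset name, scenario(s), strains, seeds,
#' output directory), executes the sweep run by run — skipping runs whose
#' per-run result file already exists, so interrupted pipelines resume —
#' then writes the aggregated metrics CSV, the ROC result (when both
#' outcomes occur) and a manifest keyed by the configuration hash.
#'
#' @param configPath path to the YAML configuration.
#' @return the manifest, invisibly.
#' @export
runPipeline <- function(configPath) {
  cfg <- yaml::read_yaml(configPath)
  preset <- presetByName(cfg$preset %||% "desk")
  strains <- as.numeric(cfg$strains %||% seq(0, 0.8, by = 0.1))
  seedsPerStrain <- as.integer(cfg$seedsPerStrain %||% 5L)
  scenarios <- cfg$scenario %||% "lateral"
  baseSeed <- as.integer(cfg$seed %||% 1L)
  outDir <- cfg$out %||% "somitecpm-runs"
  hash <- unname(tools::md5sum(configPath))
  runDir <- file.path(outDir, paste0("sweep-", substr(hash, 1, 8)))
  dir.create(file.path(runDir, "runs"), recursive = TRUE,
             showWarnings = FALSE)

  allRuns <- list()
  for (scen in scenarios) {
    for (si in seq_along(strains)) {
      for (ri in seq_len(seedsPerStrain)) {
        rs <- runSeedFor(baseSeed, si, ri)
        f <- file.path(runDir, "runs",
                       sprintf("%s_s%02d_r%d.csv", scen, si, ri))
        if (file.exists(f)) {
          row <- read.csv(f)
        } else {
          row <- runOnce(strains[si], scen, preset, rs)
          write.csv(row, f, row.names = FALSE, quote = FALSE)
        }
        allRuns[[length(allRuns) + 1L]] <- row
      }
    }
  }
  runs <- do.call(rbind, allRuns)
  runsFile <- file.path(runDir, "runs.csv")
  write.csv(runs, runsFile, row.names = FALSE, quote = FALSE)

  rocFile <- NA_character_
  roc <- tryCatch(sweepRoc(runs, seed = baseSeed), error = function(e) e)
  if (is(roc, "error")) {
    message("ROC not computed: ", conditionMessage(roc))
  } else {
    rocFile <- file.path(runDir, "roc.csv")
    write.csv(roc@points, rocFile, row.names = FALSE, quote = FALSE)
    yaml::write_yaml(list(auc = roc@auc, ciLower = roc@ci[1],
                          ciUpper = roc@ci[2], threshold = roc@threshold),
                     file.path(runDir, "roc.yaml"))
  }

  manifest <- list(configHash = hash, config = cfg, seed = baseSeed,
                   version = as.character(utils::packageVersion("somiteCPM")),
                   runsFile = runsFile, rocFile = rocFile,
                   nRuns = nrow(runs))
  yaml::write_yaml(manifest, file.path(runDir, "manifest.yaml"))
  invisible(manifest)
}
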