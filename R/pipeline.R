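#' Run the full communal-nursing analysis pipeline
#'
#' Orchestrates simulate -> track -> choice sets -> relatedness calibration ->
#' spatial autocorrelation -> inference with one configuration and one master
#' seed (each stage derives its own stream). All stage outputs are written
#' under `outDir` together with a reproducible run manifest
#' (configuration snapshot, seeds, file checksums, package version);
#' re-running with the same configuration reproduces the outputs
#' byte-for-byte.
#'
#' @param config a [simConfig()], or a path to a YAML file whose keys
#'   override [simConfig()] defaults (unknown keys are rejected).
#' @param outDir output directory.
#' @param nPerm,nBoot permutation/bootstrap effort for the correlogram.
#' @param writeOutputs write files (default TRUE); FALSE returns results only.
#' @return object of class `runManifest`: list with the headline results
#'   (`powerFit`, `decisionFit`, `partnerFit`, `calibration`, `correlogram`,
#'   `relatednessTest`, `pupAgeTest`), the `choices` table, the `colony`, and
#'   the manifest metadata.
#' @export
runPipeline <- function(config = simConfig(), outDir = tempfile("nestshare_run"),
                        nPerm = 999, nBoot = 1000, writeOutputs = TRUE) {
  if (is.character(config)) config <- loadConfig(config)
  stopifnot(inherits(config, "simConfig"))
  seed <- config$seed
  stages <- list()

  colony <- simulateColony(config)
  stages$simulate <- "ok"

  choices <- buildChoiceTable(colony, seed = deriveSeed(seed, "cryptic"))
  ev <- choices$events

  powerFit <- fitPowerNull(ev$P, ev$y)

  decisionFit <- fitDecisionModel(ev, predictors = c("nOptions", "nRegular"))

  partnerOpts <- choices$options[choices$options$eventId %in%
                                   ev$eventId[ev$y == 1 & !ev$incomplete], ]
  partnerFit <- tryCatch(
    fitPartnerModel(partnerOpts,
                    covariates = c("pupAge", "litterDiff", "sharedBoxes",
                                   "ageDiff", "optionAge", "rhat", "assocS")),
    error = function(e) structure(list(kind = "conditional logit",
                                       error = conditionMessage(e)),
                                  class = "choiceFit"))

  calib <- estimatorCalibration(colonyPedigree(colony),
                                colonyGenotypes(colony),
                                seed = deriveSeed(seed, "calibration"))

  det <- colonyDetections(colony)
  lay <- colonyLayout(colony)
  located <- data.frame(id = det$id, check = det$check,
                        x = lay$x[match(det$box, lay$box)],
                        y = lay$y[match(det$box, lay$box)])
  cgram <- correlogram(located, colonyGenotypes(colony), nPerm = nPerm,
                       nBoot = nBoot, seed = deriveSeed(seed, "correlogram"))

  # option-level scenario comparisons
  scen <- ifelse(ev$y[match(choices$options$eventId, ev$eventId)] == 1,
                 "communal", "solitary")
  relTest <- tryCatch(
    permutationMeanDiff(choices$options$rhat, scen, choices$options$eventId,
                        seed = deriveSeed(seed, "permutation")),
    error = function(e) list(error = conditionMessage(e)))
  pupTest <- mannWhitney(choices$options$pupAge[scen == "communal"],
                         choices$options$pupAge[scen == "solitary"])

  manifest <- list(
    package = "nestshare",
    version = as.character(packageVersion("nestshare")),
    seed = seed,
    stageSeeds = c(pedigree = deriveSeed(seed, "pedigree"),
                   genotypes = deriveSeed(seed, "genotypes"),
                   settlement = deriveSeed(seed, "settlement"),
                   decisions = deriveSeed(seed, "decisions"),
                   cryptic = deriveSeed(seed, "cryptic"),
                   calibration = deriveSeed(seed, "calibration"),
                   correlogram = deriveSeed(seed, "correlogram"),
                   permutation = deriveSeed(seed, "permutation")),
    config = unclass(config),
    outDir = if (writeOutputs) outDir else NA_character_)

  out <- structure(list(powerFit = powerFit, decisionFit = decisionFit,
                        partnerFit = partnerFit, calibration = calib,
                        correlogram = cgram, relatednessTest = relTest,
                        pupAgeTest = pupTest, choices = choices,
                        colony = colony, manifest = manifest),
                   class = "runManifest")
  if (writeOutputs) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeColony(colony, outDir)
    writeChoiceOutputs(choices, colony, outDir)
    utils::write.csv(as.data.frame(calib), file.path(outDir, "calibration_report.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(cgram), file.path(outDir, "correlogram.csv"),
                     row.names = FALSE)
    jsonlite::write_json(list(a = powerFit$a, se = powerFit$se, t = powerFit$t,
                              df = powerFit$df, p = powerFit$p, n = powerFit$n),
                         file.path(outDir, "navail_fit.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(decisionFit$coef, file.path(outDir, "decision_fit.csv"),
                     row.names = FALSE)
    if (!is.null(partnerFit$coef))
      utils::write.csv(partnerFit$coef, file.path(outDir, "partner_fit.csv"),
                       row.names = FALSE)
    files <- list.files(outDir, full.names = TRUE)
    manifest$checksums <- setNames(as.character(tools::md5sum(files)),
                                   basename(files))
    out$manifest <- manifest
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
  }
  out
}

# Write the home-area, association and choice-set tables of a run.
writeChoiceOutputs <- function(choices, colony, outDir) {
  ev <- choices$events
  utils::write.csv(ev, file.path(outDir, "choice_events.csv"), row.names = FALSE)
  utils::write.csv(choices$options, file.path(outDir, "options_long.csv"),
                   row.names = FALSE)
  utils::write.csv(choices$excluded, file.path(outDir, "excluded_births.csv"),
                   row.names = FALSE)
  # per-event home areas
  dt <- eventsDT(colonyEvents(colony))
  trkWin <- colony@config$trackingWindowDays %||% 30L
  ha <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    h <- homeAreaDT(dt, ev$mother[i], ev$day[i], trkWin, 300)
    if (!length(h$regularBoxes)) return(NULL)
    data.frame(eventId = ev$eventId[i], female = ev$mother[i],
               birthDay = ev$day[i], box = h$regularBoxes,
               seconds = as.numeric(h$boxSeconds[as.character(h$regularBoxes)]),
               visits = as.integer(h$boxVisits[as.character(h$regularBoxes)]))
  }))
  utils::write.csv(ha, file.path(outDir, "home_areas.csv"), row.names = FALSE)
  assoc <- choices$options[, c("eventId", "focal", "optionId", "assocS")]
  utils::write.csv(assoc, file.path(outDir, "associations.csv"),
                   row.names = FALSE)
  invisible(NULL)
}

#' @export
print.runManifest <- function(x, ...) {
  cat("nestshare pipeline run\n")
  cat(sprintf("  seed %d, decision mode '%s'\n", x$manifest$seed,
              x$manifest$config$decisionMode))
  ev <- x$choices$events
  cat(sprintf("  %d choice events (%d communal), mean options %.2f, mean regular boxes %.2f\n",
              nrow(ev), sum(ev$y), mean(ev$nOptions), mean(ev$nRegular)))
  print(x$powerFit)
  best <- x$calibration[1, ]
  cat(sprintf("  calibration: best estimator '%s' (R = %.2f)\n",
              best$estimator, best$correlation))
  sig <- x$correlogram$p <= 0.05 & x$correlogram$nDyads > 0
  cat(sprintf("  correlogram: positive structure at classes <= %s cm\n",
              if (any(sig, na.rm = TRUE))
                max(x$correlogram$upperCm[which(sig)]) else "none"))
  invisible(x)
}

# Load a YAML configuration, rejecting unknown keys.
loadConfig <- function(path) {
  y <- yaml::read_yaml(path)
  known <- names(formals(simConfig))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$preferenceWeights))
    y$preferenceWeights <- lapply(y$preferenceWeights, unlist)
  do.call(simConfig, y)
}
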