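## cli_pipeline: config-driven front ends tying the stages into the three
## standard analyses (bend-angle survey, interface report, ITC fit). Each run
## echoes its configuration and input checksums into a manifest so identical
## inputs reproduce identical outputs. A thin Rscript wrapper around these
## functions is installed at `inst/scripts/bendkit`.

.writeManifest <- function(outDir, config, inputs) {
  manifest <- list(
    package = "bendkit",
    version = as.character(utils::packageVersion("bendkit")),
    config = config,
    inputs = lapply(inputs[file.exists(inputs)], function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Bend-angle survey command
#'
#' Reads every coordinate file, measures per-heterodimer bend angles and
#' per-entry means, and writes `bend_survey.csv`, `bend_survey_entries.csv`,
#' `bend_survey.json` and a manifest into `outDir`. Entries that cannot be
#' annotated are listed in the JSON `skipped` section with their reason.
#' The tool never downloads coordinates; fetching entries is the user's step.
#'
#' @param inputs coordinate file paths (PDB or mmCIF).
#' @param outDir output directory (created if needed).
#' @param registryPath optional replacement registry TSV.
#' @return the survey list from [bendAngleSurvey()], invisibly.
#' @export
cmdBendSurvey <- function(inputs, outDir, registryPath = NULL) {
  if (!length(inputs)) stop("usage error: empty input list")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  registry <- loadSseRegistry(registryPath)
  survey <- bendAngleSurvey(inputs, registry)
  utils::write.csv(survey$perDimer, file.path(outDir, "bend_survey.csv"),
                   row.names = FALSE)
  utils::write.csv(survey$perEntry,
                   file.path(outDir, "bend_survey_entries.csv"),
                   row.names = FALSE)
  jsonlite::write_json(survey, file.path(outDir, "bend_survey.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  .writeManifest(outDir, list(command = "bend-survey", inputs = inputs,
                              registry = registryPath), inputs)
  if (!nrow(survey$perDimer))
    stop("no entry could be analyzed; see skipped list in bend_survey.json")
  invisible(survey)
}

#' Interface report command
#'
#' Annotates one complex file, reports the buried surface area between the
#' tubulin heterodimer and its binder, the 5-Angstrom contact list with
#' registry-element attribution, and - when a lattice file is given - the
#' graft-clash count of the binder modeled onto the first lattice alpha
#' subunit. Results go to `interface_report.json` (plus `contacts.csv`).
#'
#' @param complexPath coordinate file of the complex.
#' @param outDir output directory.
#' @param latticePath optional lattice coordinate file for the graft test.
#' @param contactCutoff contact distance, Angstrom.
#' @param clashCutoff clash distance, Angstrom.
#' @param nSpherePoints SASA quadrature size.
#' @param registryPath optional replacement registry TSV.
#' @return report list, invisibly.
#' @export
cmdInterface <- function(complexPath, outDir, latticePath = NULL,
                         contactCutoff = 5, clashCutoff = 2.2,
                         nSpherePoints = 960L, registryPath = NULL) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  registry <- loadSseRegistry(registryPath)
  model <- readStructure(complexPath)
  ann <- annotateModel(model, registry)
  pair <- Filter(function(p) length(p$binders) > 0L, ann$pairs)
  if (!length(pair))
    stop("annotation failure: no heterodimer with an attached binder")
  pair <- pair[[1L]]
  binder <- pair$binders[1L]
  bsa <- buriedSurfaceArea(model, c(pair$alpha, pair$beta), binder,
                           nSpherePoints = nSpherePoints)
  contacts <- contactResidues(model, binder, pair$alpha,
                              cutoff = contactCutoff,
                              mapB = ann$maps[[pair$alpha]],
                              registry = registry)
  report <- list(
    complex = complexPath, alpha = pair$alpha, beta = pair$beta,
    binder = binder, bsa_total = bsa@bsaTotal,
    contacted_elements = sort(unique(stats::na.omit(contacts$sse_b))),
    n_contacts = nrow(contacts))
  if (!is.null(latticePath)) {
    lattice <- readStructure(latticePath)
    rolesL <- classifyChains(lattice)
    target <- rolesL$chain_id[rolesL$role == "alpha_tubulin"][1L]
    clash <- latticeGraftClash(model, lattice, target,
                               binderChain = binder,
                               clashCutoff = clashCutoff,
                               registry = registry)
    report$graft <- list(target_alpha = target,
                         clash_count = clash@clashCount)
  }
  utils::write.csv(contacts, file.path(outDir, "contacts.csv"),
                   row.names = FALSE)
  jsonlite::write_json(report, file.path(outDir, "interface_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  .writeManifest(outDir, list(command = "interface", complex = complexPath,
                              lattice = latticePath,
                              contactCutoff = contactCutoff,
                              clashCutoff = clashCutoff),
                 c(complexPath, latticePath))
  invisible(report)
}

#' ITC fit command
#'
#' Reads a titration CSV ([readTitrationCsv()] layout), fits the one-site
#' model and writes `itc_fit.json` plus a fitted-curve CSV (observed and
#' model heats per injection).
#'
#' @param dataPath titration CSV.
#' @param outDir output directory.
#' @param cellVolume,syringeConcentration,cellConcentration cell geometry.
#' @param temperature K.
#' @return the [ItcFitResult-class], invisibly.
#' @export
cmdItc <- function(dataPath, outDir, cellVolume = 0.24e-3,
                   syringeConcentration = 160e-6,
                   cellConcentration = 15e-6, temperature = 293.15) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  series <- readTitrationCsv(dataPath, cellVolume, syringeConcentration,
                             cellConcentration)
  fit <- fitOneSite(series, temperature = temperature)
  g <- series@geometry
  curve <- titrationToFrame(series)
  curve$model_ucal <- .itcModelHeats(fit@n, fit@kd, fit@dh, g)
  utils::write.csv(curve, file.path(outDir, "itc_fitted_curve.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(n = fit@n, kd_M = fit@kd, dh_kcal_mol = fit@dh,
         dg_kcal_mol = fit@dg, tds_kcal_mol = fit@tds,
         se = as.list(fit@se), residual_norm = fit@residualNorm,
         c_value = fit@cValue, notes = fit@notes),
    file.path(outDir, "itc_fit.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  .writeManifest(outDir, list(command = "itc-fit", data = dataPath,
                              cellVolume = cellVolume,
                              syringeConcentration = syringeConcentration,
                              cellConcentration = cellConcentration),
                 dataPath)
  invisible(fit)
}
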