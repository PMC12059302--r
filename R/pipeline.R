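#' @include bundle.R reporting.R
NULL

#' Default pipeline configuration
#'
#' A complete nested configuration: the pipeline runs with no user input.
#' User YAML documents (see [loadConfig()]) override individual keys.
#'
#' Keys:
#' \describe{
#'   \item{cohort}{`n_patients`, `stress`, and the prescription `mix` of the
#'     synthetic cohort.}
#'   \item{imaging}{`frequency_hz` (real-time imaging rate), `spacing_mm`
#'     (resolution of the per-image kV dose grid before resampling onto the
#'     treatment grid), `n_samples` (line-integral samples), `field_halfangle_deg`,
#'     `blocked` (per-tube gantry blocking, degrees), `bone_factor`,
#'     `air_kerma_ref_gy_per_mas`, `ref_dist_mm`, and the patient-size
#'     technique `table`.}
#'   \item{dvh}{`strict_threshold`: use > instead of >= at volume-metric
#'     dose thresholds; `bin_width_gy` for exported DVH curves.}
#'   \item{aliases}{structure-name alias table, variant -> canonical.}
#' }
#' @export
defaultConfig <- function() {
  list(
    cohort = list(n_patients = 30L, stress = 0.9,
                  mix = list(rx = c(48, 60, 60), fr = c(4L, 8L, 15L),
                             count = c(26L, 3L, 1L))),
    imaging = list(frequency_hz = 1.67, spacing_mm = 5,
                   n_samples = 96, field_halfangle_deg = 8,
                   blocked = list(center_a = 240, center_b = 120,
                                  halfwidth = 60),
                   bone_factor = 4, air_kerma_ref_gy_per_mas = 2e-05,
                   ref_dist_mm = 1000,
                   table = list(max_wet_mm = c(110, 135, Inf),
                                kvp = c(110, 120, 130),
                                mas = c(10, 16, 25),
                                mu_water = c(0.0235, 0.0223, 0.0212))),
    dvh = list(strict_threshold = FALSE, bin_width_gy = 0.01),
    aliases = list("Lung_L" = "Lt Lung", "Lung_R" = "Rt Lung",
                   "SpinalCord" = "Spinal Cord", "ChestWall" = "Chest Wall")
  )
}

#' Load a pipeline configuration
#'
#' Reads a YAML document and merges it over [defaultConfig()]; `overrides`
#' (named `key.subkey = value` pairs) are applied last.
#'
#' @param path YAML file, or `NULL` for the defaults
#' @param overrides named list of dotted-key overrides,
#'   e.g. `list("cohort.stress" = 0.5)`
#' @return nested configuration list
#' @export
loadConfig <- function(path = NULL, overrides = NULL) {
  cfg <- defaultConfig()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    cfg <- utils::modifyList(cfg, user)
  }
  for (key in names(overrides)) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    cfg <- .assignNested(cfg, parts, overrides[[key]])
  }
  cfg
}

.assignNested <- function(node, parts, value) {
  if (length(parts) == 1L) {
    node[[parts]] <- value
    return(node)
  }
  node[[parts[1]]] <- .assignNested(node[[parts[1]]], parts[-1], value)
  node
}

# Coarsened geometry covering the same extent, for the per-image kV dose.
.imagingGeometry <- function(geometry, spacingMm) {
  if (all(abs(spacingMm - geometry@spacing) < 1e-9)) return(geometry)
  ext <- geometry@spacing * (geometry@dims - 1)
  dims <- pmax(2L, as.integer(ceiling(ext / spacingMm)) + 1L)
  GridGeometry(origin = geometry@origin, spacing = rep(spacingMm, 3),
               dims = dims)
}

#' Course imaging dose for one case
#'
#' Aims the default posterior-oblique tube pair at the case isocenter,
#' selects the imaging technique from the patient's water-equivalent lateral
#' thickness, partitions every arc into stereoscopic/monoscopic periods, and
#' accumulates the per-image kV dose over all images and fractions.
#'
#' @param case a [PatientCase-class]
#' @param config see [defaultConfig()]
#' @return imaging-dose [DoseGrid-class] on the configured imaging grid
#' @export
imagingDoseForCase <- function(case, config = defaultConfig()) {
  imcfg <- config$imaging
  tubes <- defaultTubes(case@isocenter, imcfg$field_halfangle_deg)
  wet <- waterEquivalentThickness(case@density, case@isocenter)
  technique <- techniqueForSize(
    wet, table = as.data.frame(imcfg$table),
    boneFactor = imcfg$bone_factor,
    airKermaRef = imcfg$air_kerma_ref_gy_per_mas,
    refDistMm = imcfg$ref_dist_mm)
  blocked <- defaultBlockedRanges(imcfg$blocked$center_a,
                                  imcfg$blocked$center_b,
                                  imcfg$blocked$halfwidth)
  geomIm <- .imagingGeometry(case@density@geometry, imcfg$spacing_mm)
  accumulateCourse(case@density, case@arcs, tubes, technique,
                   case@prescription@nFractions, blocked,
                   imcfg$frequency_hz, geomIm, imcfg$n_samples)
}

#' Run the full analysis pipeline
#'
#' Generates (or loads) the cohort, computes the course imaging dose per
#' case, evaluates every protocol constraint under Tx and Tx + Im, writes
#' per-patient CSV and text tables plus a cohort JSON summary, and returns
#' the results. Deterministic for a fixed seed.
#'
#' @param config nested configuration (see [defaultConfig()])
#' @param seed integer master seed for cohort generation
#' @param outDir output directory, or `NULL` to skip writing artifacts
#' @param noImaging evaluate with zero imaging dose (Tx-only control)
#' @param cases optional pre-built list of [PatientCase-class] (e.g. from
#'   [readCaseBundle()]); skips generation
#' @param verbose log per-case progress
#' @return list with `results` (combined data.frame), `summary`
#'   (a [CohortSummary-class]) and `paired` (bone vs chest-wall comparison)
#' @export
runPipeline <- function(config = defaultConfig(), seed = 1L, outDir = NULL,
                        noImaging = FALSE, cases = NULL, verbose = TRUE) {
  if (is.null(cases)) {
    recipe <- cohortRecipe(config$cohort$n_patients,
                           as.data.frame(config$cohort$mix),
                           stress = config$cohort$stress, seed = seed)
    if (verbose) message(sprintf(
      "generating %d-case cohort (stress %.2f, seed %d)",
      recipe@nPatients, recipe@stress, recipe@seed))
    cases <- makeCohort(recipe, verbose = verbose)
  }
  if (!is.null(outDir))
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  strict <- isTRUE(config$dvh$strict_threshold)
  aliases <- unlist(config$aliases)
  allRes <- vector("list", length(cases))
  for (i in seq_along(cases)) {
    cs <- cases[[i]]
    stage <- "imaging dose"
    res <- tryCatch({
      imDose <- if (noImaging) NULL else imagingDoseForCase(cs, config)
      stage <- "constraint evaluation"
      evaluatePatient(cs, imDose, aliases = aliases, strict = strict)
    }, error = function(e)
      stop(sprintf("case '%s' failed during %s: %s", cs@id, stage,
                   conditionMessage(e)), call. = FALSE))
    if (verbose)
      message(sprintf("evaluated %s: %d constraints, %d failed under Tx+Im",
                      cs@id, sum(res$evaluated & !res$report_only),
                      sum(res$evaluated & !res$report_only & !res$pass_total)))
    if (!is.null(outDir))
      writePatientReport(res,
                         csvFile = file.path(outDir, paste0(cs@id, ".csv")),
                         txtFile = file.path(outDir, paste0(cs@id, ".txt")))
    allRes[[i]] <- res
  }
  results <- do.call(rbind, allRes)
  summary <- summarizeCohort(results)
  paired <- tryCatch(pairedBoneChestwall(results), error = function(e) NULL)
  if (!is.null(outDir)) {
    out <- summaryAsList(summary)
    out$paired_bone_chestwall <- paired
    jsonlite::write_json(out, file.path(outDir, "cohort_summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (verbose) {
    message(sprintf(
      "cohort: %d OAR constraints evaluated, %d failed Tx (%.1f%%), %d flips (%.1f%%)",
      summary@nConstraintsEvaluated, summary@nFailedTx, summary@pctFailedTx,
      summary@nFlipped, summary@pctFlipped))
  }
  list(results = results, summary = summary, paired = paired)
}
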