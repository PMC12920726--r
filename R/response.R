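#' PERCIST response classification result
#'
#' @slot classification one of CMR, PMR, PMD, SMD.
#' @slot rule text of the condition that fired.
#' @slot inputs the echoed classifier inputs.
#' @export
setClass("ResponseResult", representation(classification = "character",
                                          rule = "character",
                                          inputs = "list"))

setValidity("ResponseResult", function(object) {
  if (!object@classification %in% c("CMR", "PMR", "PMD", "SMD"))
    "class must be one of CMR, PMR, PMD, SMD" else TRUE
})

setMethod("show", "ResponseResult", function(object) {
  cat("PERCIST response:", object@classification, "\n  rule:", object@rule, "\n")
})

#' PERCIST response classification
#'
#' Applies the PERCIST 1.0 rules in order:
#' \enumerate{
#'   \item no lesions at follow-up: complete metabolic response (CMR);
#'   \item no new lesions, no unequivocal progression, and the target
#'     SULpeak decreased by at least 30 percent and at least 0.8 SUL units:
#'     partial metabolic response (PMR);
#'   \item target SULpeak increased by more than 30 percent and at least
#'     0.8 SUL units, or any lesion increased unequivocally, or new lesions:
#'     progressive metabolic disease (PMD);
#'   \item otherwise stable metabolic disease (SMD).
#' }
#' Boundary semantics: "at least" is inclusive (-30.0 percent with an
#' absolute decrease of at least 0.8 is PMR), "more than" is exclusive
#' (+30.0 percent is not PMD).
#'
#' @param lesionsPresent any confirmed lesions in the follow-up scan?
#' @param newLesions new lesions indicated?
#' @param unequivocalProgression any lesion with unequivocal progression?
#' @param percentChange target SULpeak change, percent (signed).
#' @param absoluteChange target SULpeak change, SUL units (signed).
#' @return A \linkS4class{ResponseResult}.
#' @examples
#' classifyResponse(FALSE, FALSE, FALSE)@classification            # "CMR"
#' classifyResponse(TRUE, FALSE, FALSE, -30, -0.9)@classification  # "PMR"
#' classifyResponse(TRUE, FALSE, FALSE, 30, 0.9)@classification    # "SMD"
#' classifyResponse(TRUE, TRUE, FALSE, -40, -2.0)@classification   # "PMD"
#' @export
classifyResponse <- function(lesionsPresent, newLesions = FALSE,
                             unequivocalProgression = FALSE,
                             percentChange = NA_real_,
                             absoluteChange = NA_real_) {
  stopifnot(is.logical(lesionsPresent), is.logical(newLesions),
            is.logical(unequivocalProgression))
  inputs <- list(lesionsPresent = lesionsPresent, newLesions = newLesions,
                 unequivocalProgression = unequivocalProgression,
                 percentChange = percentChange,
                 absoluteChange = absoluteChange)
  result <- function(class, rule)
    new("ResponseResult", classification = class, rule = rule,
        inputs = inputs)

  if (!lesionsPresent)
    return(result("CMR", "no lesions indicated in the follow-up scan"))
  if (is.na(percentChange) || is.na(absoluteChange))
    stop("lesions are present but the target SULpeak changes are missing")

  if (!newLesions && !unequivocalProgression &&
      percentChange <= -30 && absoluteChange <= -0.8)
    return(result("PMR", paste("target SULpeak decreased by at least 30%",
                               "and at least 0.8 SUL units,",
                               "no new or unequivocally progressing lesions")))
  if (newLesions)
    return(result("PMD", "new lesions indicated"))
  if (unequivocalProgression)
    return(result("PMD", "a lesion increased unequivocally"))
  if (percentChange > 30 && absoluteChange >= 0.8)
    return(result("PMD", paste("target SULpeak increased by more than 30%",
                               "and at least 0.8 SUL units")))
  result("SMD", "none of the CMR/PMR/PMD conditions held")
}

#' Run the baseline analysis
#'
#' The baseline workflow: SUL conversion, background VOI placement and
#' statistics, threshold derivation, hotspot detection, classification
#' against the normal-activity mask, and ranking. Manual steps of the
#' clinical workflow (VOI acceptance, hotspot confirmation) enter as
#' explicit arguments and are recorded in the report.
#'
#' @param pet \linkS4class{ScalarVolume}: PET activity (kBq/mL) or
#'   pre-computed SUL.
#' @param organs organ \linkS4class{LabelVolume} with liver (and optionally
#'   aorta) in its legend.
#' @param normal normal-activity mask (\linkS4class{LabelVolume}).
#' @param meta \linkS4class{PatientMeta} (may be NULL when \code{pet} is
#'   already SUL).
#' @param backgroundOrgan "liver" (default) or "aorta" (the PERCIST
#'   fallback when the liver is diseased).
#' @param hotspotOverrides optional named character vector: hotspot id ->
#'   class, mirroring manual review.
#' @param outDir optional directory to write the JSON report and CSV
#'   tables.
#' @return A list report (class \code{"percistBaselineReport"}): sul,
#'   organs, normal, voi, stats, threshold, hotspots, settings.
#' @export
runBaseline <- function(pet, organs, normal, meta = NULL,
                        backgroundOrgan = c("liver", "aorta"),
                        hotspotOverrides = NULL, outDir = NULL) {
  backgroundOrgan <- match.arg(backgroundOrgan)
  stopIfGridMismatch(pet@grid, organs@grid, "PET and organ label volumes")
  stopIfGridMismatch(pet@grid, normal@grid, "PET and normal-activity volumes")
  sul <- if (identical(pet@kind, "SUL")) pet else toSUL(pet, meta)

  lab <- organLabel(organs, backgroundOrgan)
  mask <- organs@labels == lab
  voi <- if (backgroundOrgan == "liver") placeLiverVOI(sul, mask)
         else placeAortaVOI(sul, mask)
  stats <- backgroundStats(sul, voi)

  body <- sul@values > 0.05 * stats@SULmean   # crude body envelope
  hs <- detectHotspots(sul, stats@threshold, body)
  hs <- classifyHotspots(hs, normal, sul@grid)
  if (!is.null(hotspotOverrides) && nrow(hs)) {
    ids <- as.integer(names(hotspotOverrides))
    for (i in seq_along(ids)) {
      hit <- hs$id == ids[i]
      hs$class[hit] <- unname(hotspotOverrides[i])
    }
  }
  hs <- rankHotspots(hs)

  lesions <- hs[hs$class == "lesion", , drop = FALSE]
  report <- list(sul = sul, organs = organs, normal = normal, voi = voi,
                 stats = stats, threshold = stats@threshold, hotspots = hs,
                 targetSULpeak = if (nrow(lesions)) max(lesions$SULpeak)
                                 else NA_real_,
                 settings = list(backgroundOrgan = backgroundOrgan,
                                 overrides = hotspotOverrides))
  class(report) <- "percistBaselineReport"
  if (!is.null(outDir)) writeStudyReport(report, outDir, "baseline")
  report
}

organLabel <- function(organs, name) {
  hit <- names(organs@legend)[organs@legend == name]
  if (!length(hit))
    stop("organ '", name, "' is not present in the label legend")
  as.integer(hit[1L])
}

#' Run the follow-up analysis and response assessment
#'
#' All baseline steps on the follow-up scan, plus: background comparability
#' check, segmentation-guided alignment to the baseline scan, uncertainty
#' map, lesion pairing with percent changes, and the automatic PERCIST
#' classification. A comparability failure is flagged in the report but does
#' not stop the run. New-lesion and unequivocal-progression calls are manual
#' inputs (\code{flags}), mirroring the clinical workflow.
#'
#' @param baseline report from \code{\link{runBaseline}}.
#' @param pet,organs,normal,meta the follow-up study (as in
#'   \code{\link{runBaseline}}).
#' @param uncertainty an \linkS4class{UncertaintyTable}; default is the
#'   phantom-calibrated table shipped with the package.
#' @param flags list with \code{newLesions} and
#'   \code{unequivocalProgression} logicals (manual review outcome).
#' @param hotspotOverrides optional manual class overrides (id -> class).
#' @param backgroundOrgan background organ, matching the baseline.
#' @param coarsen Laplace solver coarsening factor.
#' @param outDir optional output directory.
#' @return A list report (class \code{"percistFollowupReport"}) including
#'   \code{pairs}, \code{comparability}, \code{response}.
#' @export
runFollowup <- function(baseline, pet, organs, normal, meta = NULL,
                        uncertainty = defaultUncertaintyTable(),
                        flags = list(newLesions = FALSE,
                                     unequivocalProgression = FALSE),
                        hotspotOverrides = NULL,
                        backgroundOrgan = baseline$settings$backgroundOrgan,
                        coarsen = 2L, outDir = NULL) {
  fu <- runBaseline(pet, organs, normal, meta,
                    backgroundOrgan = backgroundOrgan,
                    hotspotOverrides = hotspotOverrides)
  comparability <- checkComparability(baseline$stats, fu$stats)

  alignment <- alignImages(organs, baseline$organs, coarsen = coarsen)
  uncMap <- uncertaintyMap(organs, uncertainty)
  pairs <- buildLesionPairs(fu$hotspots, alignment$field, uncMap,
                            baseline$sul, baseline$normal)

  lesionsPresent <- nrow(pairs) > 0L
  if (lesionsPresent) {
    # target = highest confirmed lesion SULpeak at each time point
    targetFu <- max(pairs$followupSULpeak)
    targetBl <- baseline$targetSULpeak
    pct <- percentChange(targetBl, targetFu)
    absch <- if (is.na(targetBl)) NA_real_ else targetFu - targetBl
    if (is.na(pct)) {   # lesions appeared where baseline had none
      flags$newLesions <- TRUE
      pct <- NA_real_
      response <- classifyResponse(TRUE, TRUE, flags$unequivocalProgression,
                                   percentChange = 0, absoluteChange = 0)
    } else {
      response <- classifyResponse(TRUE, isTRUE(flags$newLesions),
                                   isTRUE(flags$unequivocalProgression),
                                   pct, absch)
    }
  } else {
    pct <- NA_real_; absch <- NA_real_
    response <- classifyResponse(FALSE, isTRUE(flags$newLesions),
                                 isTRUE(flags$unequivocalProgression))
  }

  report <- c(fu, list(comparability = comparability, alignment = alignment,
                       uncertaintyMap = uncMap, pairs = pairs,
                       targetPercentChange = pct,
                       targetAbsoluteChange = absch, flags = flags,
                       response = response, baselineReport = baseline))
  class(report) <- "percistFollowupReport"
  if (!is.null(outDir)) writeStudyReport(report, outDir, "followup")
  report
}

#' Phantom-calibrated default uncertainty table
#'
#' The table shipped with the package, produced by running the full
#' alignment on a small phantom calibration set and pooling the per-organ
#' Hausdorff distances (see \code{\link{makeCalibrationSet}} with
#' \code{method = "estimate"}). Stored as JSON under \code{inst/extdata};
#' the values are synthetic (phantom-derived), not clinical.
#'
#' @return An \linkS4class{UncertaintyTable}.
#' @export
defaultUncertaintyTable <- function() {
  path <- system.file("extdata", "default_uncertainty_table.json",
                      package = "petrack")
  if (!nzchar(path)) stop("default uncertainty table not found")
  readUncertaintyTable(path)
}

#' Write a study report to disk
#'
#' One JSON per study (thresholds, VOI statistics, comparability verdict,
#' response and triggered rule) plus CSV hotspot and lesion-pair tables.
#'
#' @param report a baseline or follow-up report.
#' @param outDir output directory (created if needed).
#' @param prefix file name prefix.
#' @return \code{outDir}, invisibly.
#' @export
writeStudyReport <- function(report, outDir, prefix = "study") {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  j <- list(
    backgroundOrgan = report$stats@organ,
    SULmean = report$stats@SULmean, SD = report$stats@SD,
    threshold = report$threshold,
    voiCentre = report$voi@centre,
    targetSULpeak = report$targetSULpeak,
    nHotspots = nrow(report$hotspots))
  if (!is.null(report$response)) {
    j$comparability <- report$comparability
    j$response <- report$response@classification
    j$rule <- report$response@rule
    j$targetPercentChange <- report$targetPercentChange
    j$targetAbsoluteChange <- report$targetAbsoluteChange
    j$flags <- report$flags
    utils::write.csv(report$pairs,
                     file.path(outDir, paste0(prefix, "_pairs.csv")),
                     row.names = FALSE)
  }
  jsonlite::write_json(j, file.path(outDir, paste0(prefix, "_report.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  exportHotspots(report$hotspots,
                 csv = file.path(outDir, paste0(prefix, "_hotspots.csv")))
  invisible(outDir)
}
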