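#' @include AllClasses.R
NULL

#' Accessors for study objects
#'
#' Small accessor generics: \code{intervals()} returns the schedule's
#' interval table, \code{midpoints()} the per-interval midpoint times,
#' \code{ledgerEntries()} the catheter table, \code{activeCatheters()} the
#' ok-status subset, \code{studySamples()}/\code{calibrationSamples()} the
#' observable tables of a study, \code{studyTruth()} the simulation truth,
#' and \code{profilePoints()} the point table of a profile.
#'
#' @param object the object to access.
#' @return A data.frame (or numeric vector for \code{midpoints}).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("intervals", function(object) standardGeneric("intervals"))

#' @rdname accessors
#' @export
setGeneric("midpoints", function(object) standardGeneric("midpoints"))

#' @rdname accessors
#' @export
setGeneric("ledgerEntries", function(object) standardGeneric("ledgerEntries"))

#' @rdname accessors
#' @export
setGeneric("activeCatheters",
           function(object) standardGeneric("activeCatheters"))

#' @rdname accessors
#' @export
setGeneric("studySamples", function(object) standardGeneric("studySamples"))

#' @rdname accessors
#' @export
setGeneric("calibrationSamples",
           function(object) standardGeneric("calibrationSamples"))

#' @rdname accessors
#' @export
setGeneric("studyTruth", function(object) standardGeneric("studyTruth"))

#' @rdname accessors
#' @export
setGeneric("profilePoints", function(object) standardGeneric("profilePoints"))

#' @rdname accessors
#' @export
setMethod("intervals", "SamplingSchedule", function(object) object@intervals)

#' @rdname accessors
#' @export
setMethod("midpoints", "SamplingSchedule", function(object)
  intervalMidpoint(object@intervals$start_min, object@intervals$end_min))

#' @rdname accessors
#' @export
setMethod("ledgerEntries", "CatheterLedger", function(object) object@entries)

#' @rdname accessors
#' @export
setMethod("activeCatheters", "CatheterLedger", function(object)
  object@entries[object@entries$status == "ok", , drop = FALSE])

#' @rdname accessors
#' @export
setMethod("studySamples", "HipecStudy", function(object) object@samples)

#' @rdname accessors
#' @export
setMethod("calibrationSamples", "HipecStudy",
          function(object) object@calibration)

#' @rdname accessors
#' @export
setMethod("studyTruth", "HipecStudy", function(object) object@truth)

#' @rdname accessors
#' @export
setMethod("ledgerEntries", "HipecStudy",
          function(object) ledgerEntries(object@ledger))

#' @rdname accessors
#' @export
setMethod("profilePoints", "ConcentrationTimeProfile",
          function(object) object@points)

setMethod("show", "SamplingSchedule", function(object) {
  iv <- object@intervals
  cat(sprintf("SamplingSchedule: %d intervals covering [0, %g] min\n",
              nrow(iv), iv$end_min[nrow(iv)]))
  cat(sprintf("  midpoints: %s ... %s min\n",
              format(midpoints(object)[1L]),
              format(midpoints(object)[nrow(iv)])))
})

setMethod("show", "CatheterLedger", function(object) {
  e <- object@entries
  cat(sprintf("CatheterLedger: %d catheters (%d animals x %d sites)\n",
              nrow(e), length(unique(e$animal_id)),
              length(unique(e$compartment))))
  print(table(status = e$status))
})

setMethod("show", "StudyConfig", function(object) {
  cat(sprintf(
    "StudyConfig: %d animals (%.0f-%.0f kg), %g mg/m2, HIPEC %g min\n",
    object@nAnimals, min(object@weightsKg), max(object@weightsKg),
    object@dosePerM2, object@hipecDurationMin))
  cat(sprintf("  schedule %g/%g min steps, switch %g, end %g; LOQ %g ug/mL; seed %d\n",
              object@fineStepMin, object@coarseStepMin, object@switchMin,
              object@endMin, object@loqUgPerMl, object@seed))
})

setMethod("show", "TissueKinetics", function(object) {
  cat(sprintf(
    "TissueKinetics[%s]: A=%.3g ug/mL, kUptake=%.4g/min, kElim=%.4g/min\n",
    object@compartment, object@amplitude, object@kUptake, object@kElim))
})

setMethod("show", "HipecStudy", function(object) {
  cat(sprintf("HipecStudy: %d sample rows, %d calibration rows\n",
              nrow(object@samples), nrow(object@calibration)))
  show(object@ledger)
})

setMethod("show", "ConcentrationTimeProfile", function(object) {
  cat(sprintf(
    "ConcentrationTimeProfile[%s, %s]: %d points (in %d, censored %d, excluded %d)\n",
    object@animalId, object@compartment, nrow(object@points),
    object@nIn, object@nCensored, object@nExcluded))
})
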