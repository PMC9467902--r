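#' @import methods
NULL

.CATHETER_STATUS <- c("ok", "malfunction", "displaced")

#' Sampling schedule of contiguous dialysate collection intervals
#'
#' Ordered collection intervals, in minutes from HIPEC initiation (t = 0 is
#' the start of perfusion). Each dialysate sample integrates drug over one
#' interval and is timestamped at the interval midpoint.
#'
#' @slot intervals data.frame with columns \code{start_min}, \code{end_min};
#'   contiguous, non-overlapping, strictly increasing, first start at 0.
#' @seealso [buildSchedule()], [midpoints()]
#' @export
setClass("SamplingSchedule", representation(intervals = "data.frame"))

setValidity("SamplingSchedule", function(object) {
  iv <- object@intervals
  if (!all(c("start_min", "end_min") %in% names(iv)))
    return("intervals must have columns start_min, end_min")
  if (nrow(iv) < 1L) return("schedule must contain at least one interval")
  if (iv$start_min[1L] != 0) return("first interval must start at 0")
  if (any(iv$end_min <= iv$start_min)) return("intervals must have end > start")
  if (nrow(iv) > 1L && any(iv$start_min[-1L] != iv$end_min[-nrow(iv)]))
    return("intervals must be contiguous (each start equals previous end)")
  TRUE
})

#' Catheter ledger: one row per animal x catheter site
#'
#' The per-study accounting of microdialysis catheters. QC marks individual
#' catheters as \code{malfunction} or \code{displaced}; downstream stages use
#' only \code{ok} catheters, whole-catheter (no partial salvage of samples).
#'
#' @slot entries data.frame with columns \code{animal_id},
#'   \code{compartment}, \code{depth_mm} (NA allowed) and \code{status}
#'   (one of ok, malfunction, displaced).
#' @seealso [buildLedger()], [applyQC()]
#' @export
setClass("CatheterLedger", representation(entries = "data.frame"))

setValidity("CatheterLedger", function(object) {
  e <- object@entries
  need <- c("animal_id", "compartment", "depth_mm", "status")
  if (!all(need %in% names(e)))
    return(paste("entries must have columns", paste(need, collapse = ", ")))
  if (nrow(e) < 1L) return("ledger must contain at least one entry")
  if (!all(e$status %in% .CATHETER_STATUS))
    return("status must be one of ok, malfunction, displaced")
  if (anyDuplicated(e[, c("animal_id", "compartment")]))
    return("duplicate animal_id x compartment entries")
  TRUE
})

#' Study configuration
#'
#' All scalar design parameters of a (real or simulated) HIPEC microdialysis
#' study: animals and body weights, BSA-based dosing rate, perfusion duration,
#' the sampling-schedule parameters, assay LOQ, the retrodialysis calibration
#' perfusate concentration, and catheter-dropout probabilities for the
#' simulator. Flow rate is informational metadata.
#'
#' @slot nAnimals integer number of animals.
#' @slot weightsKg numeric body weights (kg), length \code{nAnimals}.
#' @slot dosePerM2 dosing rate in mg per m2 body surface area.
#' @slot hipecDurationMin perfusion duration (min).
#' @slot fineStepMin,coarseStepMin,switchMin,endMin sampling-schedule
#'   parameters in minutes (fine intervals on \code{[0, switch]}, coarse on
#'   \code{[switch, end]}).
#' @slot loqUgPerMl assay lower limit of quantification (ug/mL).
#' @slot calibPerfusateUgPerMl retrodialysis perfusate concentration (ug/mL).
#' @slot flowRateUlPerMin microdialysis pump flow rate (uL/min, metadata).
#' @slot pMalfunction,pDisplaced per-catheter dropout probabilities used by
#'   the simulator.
#' @slot seed integer RNG seed for the simulator.
#' @seealso [defaultStudyConfig()]
#' @export
setClass("StudyConfig", representation(
  nAnimals = "integer", weightsKg = "numeric", dosePerM2 = "numeric",
  hipecDurationMin = "numeric",
  fineStepMin = "numeric", coarseStepMin = "numeric",
  switchMin = "numeric", endMin = "numeric",
  loqUgPerMl = "numeric", calibPerfusateUgPerMl = "numeric",
  flowRateUlPerMin = "numeric",
  pMalfunction = "numeric", pDisplaced = "numeric",
  seed = "integer"))

setValidity("StudyConfig", function(object) {
  if (object@nAnimals < 1L) return("nAnimals must be >= 1")
  if (length(object@weightsKg) != object@nAnimals)
    return("weightsKg must have one weight per animal")
  if (any(object@weightsKg <= 0)) return("weights must be > 0")
  if (object@dosePerM2 < 0) return("dosePerM2 must be >= 0")
  if (object@hipecDurationMin <= 0) return("hipecDurationMin must be > 0")
  if (object@loqUgPerMl <= 0) return("LOQ must be > 0")
  if (object@calibPerfusateUgPerMl <= 0)
    return("calibration perfusate concentration must be > 0")
  if (object@pMalfunction < 0 || object@pMalfunction > 1 ||
      object@pDisplaced < 0 || object@pDisplaced > 1)
    return("dropout probabilities must lie in [0, 1]")
  TRUE
})

#' Double-exponential (Bateman) tissue kinetics
#'
#' Truth model for one compartment of the simulator:
#' \eqn{C(t) = A (e^{-k_e t} - e^{-k_u t})} with uptake rate strictly above
#' elimination rate. Cmax, Tmax and AUC have closed forms, which serve as
#' analytic oracles for the non-compartmental analysis.
#'
#' @slot compartment compartment name.
#' @slot amplitude amplitude A (ug/mL).
#' @slot kUptake uptake rate constant (1/min).
#' @slot kElim elimination rate constant (1/min); \code{kUptake > kElim > 0}.
#' @seealso [trueConcentration()], [closedFormNCA()], [defaultKinetics()]
#' @export
setClass("TissueKinetics", representation(
  compartment = "character", amplitude = "numeric",
  kUptake = "numeric", kElim = "numeric"))

setValidity("TissueKinetics", function(object) {
  if (object@amplitude <= 0) return("amplitude must be > 0")
  if (!(object@kUptake > object@kElim && object@kElim > 0))
    return("rates must satisfy kUptake > kElim > 0")
  TRUE
})

#' Assay noise model: LC-MS/MS precision ladder plus LOQ
#'
#' Multiplicative lognormal measurement noise whose coefficient of variation
#' is interpolated, linearly in log10(concentration), between tabulated
#' (target concentration, CV\%) pairs and clamped at the ends. The default
#' ladder is the assay's printed intermediate-precision series.
#'
#' @slot ladder data.frame with columns \code{conc_ug_per_ml},
#'   \code{cv_percent}, sorted by concentration.
#' @slot loqUgPerMl lower limit of quantification (ug/mL).
#' @seealso [defaultNoiseModel()], [noiselessModel()]
#' @export
setClass("NoiseModel", representation(ladder = "data.frame",
                                      loqUgPerMl = "numeric"))

setValidity("NoiseModel", function(object) {
  l <- object@ladder
  if (!all(c("conc_ug_per_ml", "cv_percent") %in% names(l)))
    return("ladder must have columns conc_ug_per_ml, cv_percent")
  if (any(l$cv_percent < 0)) return("CVs must be >= 0")
  if (is.unsorted(l$conc_ug_per_ml, strictly = TRUE))
    return("ladder must be sorted by strictly increasing concentration")
  if (object@loqUgPerMl <= 0) return("LOQ must be > 0")
  TRUE
})

#' Simulation truth record
#'
#' Everything needed to recompute every simulated observable: the
#' per-compartment kinetics, the per-catheter true relative recoveries and
#' failure statuses, the closed-form NCA parameters of each compartment, and
#' the seed.
#'
#' @slot kinetics named list of [TissueKinetics-class] objects.
#' @slot catheterStates data.frame: animal_id, compartment, true_rr_percent,
#'   status.
#' @slot closedForm data.frame of analytic Cmax/Tmax/AUC/half-life per
#'   compartment, evaluated at the last scheduled midpoint.
#' @slot seed integer seed the study was generated under.
#' @export
setClass("SimTruth", representation(
  kinetics = "list", catheterStates = "data.frame",
  closedForm = "data.frame", seed = "integer"))

#' A complete (simulated) HIPEC microdialysis study
#'
#' Container bundling the observable tables (dialysate/plasma samples and
#' retrodialysis calibration samples) with the design objects and, for
#' simulated studies, the truth record.
#'
#' @slot samples data.frame of dialysate and plasma measurements.
#' @slot calibration data.frame of retrodialysis recovery samples.
#' @slot ledger [CatheterLedger-class].
#' @slot schedule [SamplingSchedule-class].
#' @slot config [StudyConfig-class].
#' @slot truth [SimTruth-class].
#' @seealso [simulateStudy()]
#' @export
setClass("HipecStudy", representation(
  samples = "data.frame", calibration = "data.frame",
  ledger = "CatheterLedger", schedule = "SamplingSchedule",
  config = "StudyConfig", truth = "SimTruth"))

#' Concentration-time profile for one animal x compartment
#'
#' RR-corrected free concentrations (or plasma concentrations, which need no
#' correction) at interval midpoints, with bookkeeping of how many input
#' samples were censored or excluded.
#'
#' @slot animalId animal identifier.
#' @slot compartment compartment name.
#' @slot points data.frame: midpoint_min, conc_ug_per_ml, censored (0/1),
#'   sorted by strictly increasing time.
#' @slot nIn number of samples entering profile construction.
#' @slot nCensored number of below-LOQ samples.
#' @slot nExcluded number of samples dropped (censoring policy or invalid
#'   catheter).
#' @seealso [buildProfile()], [buildProfiles()]
#' @export
setClass("ConcentrationTimeProfile", representation(
  animalId = "character", compartment = "character",
  points = "data.frame",
  nIn = "integer", nCensored = "integer", nExcluded = "integer"))

setValidity("ConcentrationTimeProfile", function(object) {
  p <- object@points
  need <- c("midpoint_min", "conc_ug_per_ml", "censored")
  if (!all(need %in% names(p)))
    return(paste("points must have columns", paste(need, collapse = ", ")))
  if (nrow(p) > 1L && is.unsorted(p$midpoint_min, strictly = TRUE))
    return("point times must be strictly increasing")
  if (any(p$conc_ug_per_ml[p$censored == 0] <= 0))
    return("non-censored concentrations must be > 0")
  TRUE
})
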