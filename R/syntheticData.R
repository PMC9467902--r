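#' @include AllClasses.R studyDesign.R
NULL

#' Default study configuration
#'
#' The stated study world: 8 animals with body weights spanning 71-83 kg,
#' carboplatin 800 mg/m2, 90 min perfusion, 30/60-min sampling intervals
#' switching at 240 min and ending at 480 min, assay LOQ 0.100 ug/mL,
#' retrodialysis perfusate 100 ug/mL, 1 uL/min pump flow, and per-catheter
#' dropout probabilities equal to the observed study rates (3/64
#' malfunction, 8/64 displaced).
#'
#' @param nAnimals number of animals.
#' @param weightsKg body weights; default evenly spaced over 71-83 kg.
#' @param dosePerM2 dose rate (mg/m2).
#' @param hipecDurationMin perfusion duration (min).
#' @param fineStepMin,coarseStepMin,switchMin,endMin schedule parameters.
#' @param loqUgPerMl assay LOQ (ug/mL).
#' @param calibPerfusateUgPerMl retrodialysis perfusate (ug/mL).
#' @param flowRateUlPerMin pump flow rate (uL/min, metadata).
#' @param pMalfunction,pDisplaced per-catheter dropout probabilities.
#' @param seed integer RNG seed.
#' @return A [StudyConfig-class].
#' @export
defaultStudyConfig <- function(nAnimals = 8L,
                               weightsKg = seq(71, 83, length.out = nAnimals),
                               dosePerM2 = 800,
                               hipecDurationMin = 90,
                               fineStepMin = 30, coarseStepMin = 60,
                               switchMin = 240, endMin = 480,
                               loqUgPerMl = 0.100,
                               calibPerfusateUgPerMl = 100,
                               flowRateUlPerMin = 1,
                               pMalfunction = 3 / 64, pDisplaced = 8 / 64,
                               seed = 1L) {
  new("StudyConfig", nAnimals = as.integer(nAnimals), weightsKg = weightsKg,
      dosePerM2 = dosePerM2, hipecDurationMin = hipecDurationMin,
      fineStepMin = fineStepMin, coarseStepMin = coarseStepMin,
      switchMin = switchMin, endMin = endMin, loqUgPerMl = loqUgPerMl,
      calibPerfusateUgPerMl = calibPerfusateUgPerMl,
      flowRateUlPerMin = flowRateUlPerMin,
      pMalfunction = pMalfunction, pDisplaced = pDisplaced,
      seed = as.integer(seed))
}

#' Construct tissue kinetics
#'
#' @param compartment compartment name.
#' @param amplitude amplitude A (ug/mL).
#' @param kUptake,kElim rate constants (1/min), \code{kUptake > kElim > 0}.
#' @return A [TissueKinetics-class].
#' @export
tissueKinetics <- function(compartment, amplitude, kUptake, kElim) {
  new("TissueKinetics", compartment = compartment, amplitude = amplitude,
      kUptake = kUptake, kElim = kElim)
}

#' Kinetics calibrated to a target peak
#'
#' Parameterises a Bateman curve by its peak: given target Cmax and Tmax and
#' a fixed uptake/elimination rate ratio r, solves
#' \eqn{k_e = \ln r / ((r - 1) T_{max})}, \eqn{k_u = r k_e}, and scales the
#' amplitude so the curve's maximum equals Cmax.
#'
#' @param compartment compartment name.
#' @param cmax target peak concentration (ug/mL).
#' @param tmax target time of peak (min).
#' @param rateRatio uptake/elimination rate ratio (> 1); default 4.
#' @return A [TissueKinetics-class] with closed-form Cmax/Tmax equal to the
#'   targets.
#' @export
kineticsFromPeak <- function(compartment, cmax, tmax, rateRatio = 4) {
  stopifnot(cmax > 0, tmax > 0, rateRatio > 1)
  ke <- log(rateRatio) / ((rateRatio - 1) * tmax)
  ku <- rateRatio * ke
  a <- cmax / (exp(-ke * tmax) - exp(-ku * tmax))
  tissueKinetics(compartment, a, ku, ke)
}

#' Default compartment kinetics
#'
#' One Bateman truth curve per compartment (eight solid tissues plus
#' plasma), calibrated so each compartment's closed-form Cmax and Tmax equal
#' the reported population means: Cmax 10.6-26.0 ug/mL and Tmax 105-206 min
#' across compartments, all peaks after the 90-min perfusion, and
#' end-of-sampling (450 min) concentrations in the single-digit ug/mL range.
#'
#' @return Named list of [TissueKinetics-class] objects.
#' @export
defaultKinetics <- function() {
  targets <- data.frame(
    compartment = c("liver", "hl_superficial", "hl_profound", "peritoneum",
                    "rectum_superficial", "rectum_profound", "mesentery",
                    "bladder_wall", "plasma"),
    cmax = c(13.0, 15.4, 12.6, 26.0, 15.1, 20.6, 12.4, 22.0, 10.6),
    tmax = c(206, 186, 178, 196, 175, 205, 197, 197, 105))
  kin <- mapply(kineticsFromPeak, targets$compartment, targets$cmax,
                targets$tmax, SIMPLIFY = FALSE)
  names(kin) <- targets$compartment
  kin
}

#' Default per-compartment relative-recovery distribution
#'
#' Mean and SD of the true catheter relative recovery (percent) for each
#' solid-tissue compartment; the simulator draws per-catheter RR from a
#' normal truncated to (0, 100].
#'
#' @return data.frame: compartment, rr_mean, rr_sd.
#' @export
defaultRecoveryParams <- function() {
  data.frame(
    compartment = c("liver", "hl_superficial", "hl_profound", "peritoneum",
                    "rectum_superficial", "rectum_profound", "mesentery",
                    "bladder_wall"),
    rr_mean = c(89.5, 91.0, 88.1, 75.3, 93.1, 87.0, 75.2, 78.7),
    rr_sd = c(4.6, 8.2, 5.1, 11.9, 3.6, 12.7, 10.1, 12.4))
}

#' Assay noise models
#'
#' \code{defaultNoiseModel()} carries the assay's intermediate-precision
#' ladder: CV 20.8\% at 0.100 ug/mL, 11.1\% at 1.00, 9.7\% at 4.00, 3.5\% at
#' 30.0 and 6.8\% at 100.0 ug/mL, with LOQ 0.100 ug/mL.
#' \code{noiselessModel()} zeroes all CVs (the exact, deterministic assay
#' used by oracle tests).
#'
#' @param loqUgPerMl lower limit of quantification (ug/mL).
#' @return A [NoiseModel-class].
#' @export
defaultNoiseModel <- function(loqUgPerMl = 0.100) {
  new("NoiseModel",
      ladder = data.frame(conc_ug_per_ml = c(0.100, 1.00, 4.00, 30.0, 100.0),
                          cv_percent = c(20.8, 11.1, 9.7, 3.5, 6.8)),
      loqUgPerMl = loqUgPerMl)
}

#' @rdname defaultNoiseModel
#' @export
noiselessModel <- function(loqUgPerMl = 0.100) {
  nm <- defaultNoiseModel(loqUgPerMl)
  nm@ladder$cv_percent[] <- 0
  nm
}

#' Interpolated assay CV at a concentration
#'
#' Linear interpolation of CV in log10(concentration) between the ladder
#' points, clamped to the end CVs outside the tabulated range.
#'
#' @param noise a [NoiseModel-class].
#' @param conc concentrations (ug/mL); non-positive values take the lowest
#'   tabulated CV.
#' @return CV as a fraction (not percent).
#' @export
assayCV <- function(noise, conc) {
  l <- noise@ladder
  if (nrow(l) == 1L) return(rep(l$cv_percent / 100, length(conc)))
  x <- log10(pmax(conc, min(l$conc_ug_per_ml)))
  stats::approx(log10(l$conc_ug_per_ml), l$cv_percent, xout = x,
                rule = 2)$y / 100
}

# Lognormal multiplicative noise factors with unit mean: sdlog chosen so the
# linear-scale CV matches, meanlog = -sdlog^2/2. cv = 0 gives exactly 1.
.noiseFactor <- function(cv) {
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(length(cv), meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' True tissue concentration of the Bateman truth curve
#'
#' \eqn{C(t) = A (e^{-k_e t} - e^{-k_u t})}; zero at t = 0, non-negative for
#' all t >= 0, peaking at \eqn{T_{max} = \ln(k_u/k_e) / (k_u - k_e)}.
#'
#' @param kinetics a [TissueKinetics-class].
#' @param tMin times in minutes (>= 0); vectorised.
#' @return Concentrations in ug/mL.
#' @export
trueConcentration <- function(kinetics, tMin) {
  stopifnot(is(kinetics, "TissueKinetics"))
  if (any(tMin < 0)) stop("time must be >= 0")
  kinetics@amplitude *
    (exp(-kinetics@kElim * tMin) - exp(-kinetics@kUptake * tMin))
}

#' Closed-form NCA parameters of a Bateman curve
#'
#' Analytic oracle for the non-compartmental analysis:
#' \eqn{T_{max} = \ln(k_u/k_e)/(k_u-k_e)}, \eqn{C_{max} = C(T_{max})},
#' \eqn{AUC_{0-t} = A[(1-e^{-k_e t})/k_e - (1-e^{-k_u t})/k_u]}, and
#' terminal half-life \eqn{\ln 2 / k_e}.
#'
#' @param kinetics a [TissueKinetics-class].
#' @param tLast end of the AUC window (min, > 0); \code{Inf} gives
#'   \eqn{A(1/k_e - 1/k_u)}.
#' @return list with \code{cmax}, \code{tmax}, \code{auc_0_tlast},
#'   \code{half_life}.
#' @export
closedFormNCA <- function(kinetics, tLast) {
  stopifnot(is(kinetics, "TissueKinetics"), tLast > 0)
  ku <- kinetics@kUptake; ke <- kinetics@kElim; a <- kinetics@amplitude
  tmax <- log(ku / ke) / (ku - ke)
  auc <- if (is.infinite(tLast)) a * (1 / ke - 1 / ku)
         else a * ((1 - exp(-ke * tLast)) / ke - (1 - exp(-ku * tLast)) / ku)
  list(cmax = trueConcentration(kinetics, tmax), tmax = tmax,
       auc_0_tlast = auc, half_life = log(2) / ke)
}

#' Exact time-average of the truth curve over an interval
#'
#' A dialysate integrates drug over its collection window; its noise-free
#' concentration is the time-average of the true curve, evaluated here in
#' closed form from the exponentials.
#'
#' @param kinetics a [TissueKinetics-class].
#' @param startMin,endMin interval bounds (min), \code{endMin > startMin};
#'   vectorised.
#' @return Mean concentrations over the intervals (ug/mL).
#' @export
intervalAverage <- function(kinetics, startMin, endMin) {
  stopifnot(is(kinetics, "TissueKinetics"))
  if (any(endMin <= startMin))
    stop("degenerate interval: end must exceed start")
  ku <- kinetics@kUptake; ke <- kinetics@kElim; a <- kinetics@amplitude
  a * ((exp(-ke * startMin) - exp(-ke * endMin)) / ke -
       (exp(-ku * startMin) - exp(-ku * endMin)) / ku) / (endMin - startMin)
}

#' Simulate the dialysate series of one catheter
#'
#' Per scheduled interval, the measured dialysate concentration is
#' interval-average x RR/100 x a lognormal noise factor whose CV is
#' interpolated from the precision ladder at the pre-noise concentration.
#' Values below the LOQ are flagged censored and reported at the LOQ marker
#' (how an assay reports "<LOQ"). Catheters with a failure status yield no
#' samples. Uses the current RNG state; seed upstream for reproducibility.
#'
#' @param kinetics a [TissueKinetics-class].
#' @param trueRRPercent true relative recovery of the catheter, in (0, 100].
#' @param schedule a [SamplingSchedule-class].
#' @param noise a [NoiseModel-class].
#' @param status catheter status; anything but \code{"ok"} yields zero rows.
#' @return data.frame: interval_start_min, interval_end_min, midpoint_min,
#'   conc_ug_per_ml, below_loq (0/1).
#' @export
simulateDialysateSeries <- function(kinetics, trueRRPercent, schedule,
                                    noise = defaultNoiseModel(),
                                    status = "ok") {
  stopifnot(is(schedule, "SamplingSchedule"), is(noise, "NoiseModel"))
  if (!(trueRRPercent > 0 && trueRRPercent <= 100))
    stop("true RR must lie in (0, 100]")
  iv <- intervals(schedule)
  if (status != "ok")
    return(data.frame(interval_start_min = numeric(0),
                      interval_end_min = numeric(0),
                      midpoint_min = numeric(0),
                      conc_ug_per_ml = numeric(0), below_loq = integer(0)))
  # (rr/100) first: at RR = 100 the factor is exactly 1, keeping the
  # noise-free pathway bit-identical to the closed-form interval averages
  clean <- intervalAverage(kinetics, iv$start_min, iv$end_min) *
    (trueRRPercent / 100)
  measured <- clean * .noiseFactor(assayCV(noise, clean))
  cens <- measured < noise@loqUgPerMl
  data.frame(interval_start_min = iv$start_min,
             interval_end_min = iv$end_min,
             midpoint_min = midpoints(schedule),
             conc_ug_per_ml = ifelse(cens, noise@loqUgPerMl, measured),
             below_loq = as.integer(cens))
}

#' Simulate a retrodialysis calibration pair
#'
#' After the sampling period the perfusate is switched to a known carboplatin
#' concentration and two 40-min recovery samples are collected. Each sample's
#' dialysate concentration is \code{calibConc * (1 - RR/100)} times a noise
#' factor: the fraction of drug NOT lost across the membrane.
#'
#' @param trueRRPercent true relative recovery, in (0, 100].
#' @param calibConc perfusate concentration (ug/mL, > 0); default 100.
#' @param noise a [NoiseModel-class].
#' @return data.frame with two rows: replicate, perfusate_conc_ug_per_ml,
#'   dialysate_conc_ug_per_ml.
#' @export
simulateRetrodialysisPair <- function(trueRRPercent, calibConc = 100,
                                      noise = defaultNoiseModel()) {
  stopifnot(calibConc > 0, is(noise, "NoiseModel"))
  if (!(trueRRPercent > 0 && trueRRPercent <= 100))
    stop("true RR must lie in (0, 100]")
  clean <- rep(calibConc * (1 - trueRRPercent / 100), 2L)
  meas <- clean * .noiseFactor(assayCV(noise, clean))
  data.frame(replicate = 1:2, perfusate_conc_ug_per_ml = calibConc,
             dialysate_conc_ug_per_ml = meas)
}

# one truncated-normal RR draw in (0, 100]; redraw outside the support
.drawRR <- function(mean, sd) {
  repeat {
    x <- stats::rnorm(1L, mean, sd)
    if (x > 0 && x <= 100) return(x)
  }
}

#' Simulate a complete HIPEC microdialysis study
#'
#' Generates the full observable dataset of a study under the configured
#' design: a catheter ledger with random malfunction/displacement, true
#' per-catheter relative recoveries drawn from truncated normals with the
#' per-compartment means/SDs, interval-averaged dialysate measurements with
#' assay noise and LOQ censoring for every ok catheter, plasma sampled at
#' the interval midpoints (no recovery correction applies to blood), and two
#' retrodialysis recovery samples per ok catheter. The returned truth record
#' is sufficient to recompute every observable; re-running with the same
#' config reproduces the dataset exactly.
#'
#' @param config a [StudyConfig-class]; its seed drives all randomness.
#' @param kinetics named list of [TissueKinetics-class] per compartment
#'   (solid tissues plus \code{plasma}); default [defaultKinetics()].
#' @param noise a [NoiseModel-class]; default the assay precision ladder.
#' @param recoveryParams data.frame compartment/rr_mean/rr_sd;
#'   default [defaultRecoveryParams()].
#' @param fixedRR if non-NULL, use this RR (percent) for every catheter
#'   instead of drawing — the deterministic pathway used by oracle tests.
#' @return A [HipecStudy-class].
#' @examples
#' study <- simulateStudy(defaultStudyConfig(seed = 7L))
#' study
#' @export
simulateStudy <- function(config = defaultStudyConfig(),
                          kinetics = defaultKinetics(),
                          noise = defaultNoiseModel(config@loqUgPerMl),
                          recoveryParams = defaultRecoveryParams(),
                          fixedRR = NULL) {
  stopifnot(is(config, "StudyConfig"))
  sites <- defaultSites()
  sites <- sites[sites$compartment %in% names(kinetics), , drop = FALSE]
  missing <- setdiff(sites$compartment, recoveryParams$compartment)
  if (length(missing))
    stop("no recovery parameters for compartment(s): ",
         paste(missing, collapse = ", "))
  if (!"plasma" %in% names(kinetics))
    stop("kinetics must include a plasma compartment")

  set.seed(config@seed)
  schedule <- buildSchedule(config@fineStepMin, config@coarseStepMin,
                            config@switchMin, config@endMin)
  ledger <- buildLedger(config@nAnimals, sites)
  e <- ledgerEntries(ledger)

  # per-catheter failure status and true RR
  u <- stats::runif(nrow(e))
  status <- ifelse(u < config@pMalfunction, "malfunction",
                   ifelse(u < config@pMalfunction + config@pDisplaced,
                          "displaced", "ok"))
  rrmu <- recoveryParams$rr_mean[match(e$compartment,
                                       recoveryParams$compartment)]
  rrsd <- recoveryParams$rr_sd[match(e$compartment,
                                     recoveryParams$compartment)]
  trueRR <- if (is.null(fixedRR))
    mapply(.drawRR, rrmu, rrsd) else rep(fixedRR, nrow(e))
  e$status <- status
  ledger <- new("CatheterLedger", entries = e)

  samples <- vector("list", nrow(e) + config@nAnimals)
  calib <- vector("list", nrow(e))
  for (i in seq_len(nrow(e))) {
    s <- simulateDialysateSeries(kinetics[[e$compartment[i]]], trueRR[i],
                                 schedule, noise, e$status[i])
    if (nrow(s)) {
      samples[[i]] <- cbind(animal_id = e$animal_id[i],
                            compartment = e$compartment[i],
                            sample_type = "dialysate", s)
      cp <- simulateRetrodialysisPair(trueRR[i],
                                      config@calibPerfusateUgPerMl, noise)
      calib[[i]] <- cbind(animal_id = e$animal_id[i],
                          compartment = e$compartment[i], cp)
    }
  }
  # plasma: point samples at midpoints, assay noise, no RR
  ids <- unique(e$animal_id)
  iv <- intervals(schedule)
  for (j in seq_along(ids)) {
    clean <- trueConcentration(kinetics[["plasma"]], midpoints(schedule))
    meas <- clean * .noiseFactor(assayCV(noise, clean))
    cens <- meas < noise@loqUgPerMl
    samples[[nrow(e) + j]] <- data.frame(
      animal_id = ids[j], compartment = "plasma", sample_type = "plasma",
      interval_start_min = iv$start_min, interval_end_min = iv$end_min,
      midpoint_min = midpoints(schedule),
      conc_ug_per_ml = ifelse(cens, noise@loqUgPerMl, meas),
      below_loq = as.integer(cens))
  }
  samples <- do.call(rbind, samples[!vapply(samples, is.null, logical(1L))])
  calib <- do.call(rbind, calib[!vapply(calib, is.null, logical(1L))])
  rownames(samples) <- rownames(calib) <- NULL

  tlast <- max(midpoints(schedule))
  cf <- do.call(rbind, lapply(names(kinetics), function(cmp) {
    z <- closedFormNCA(kinetics[[cmp]], tlast)
    data.frame(compartment = cmp, cmax = z$cmax, tmax = z$tmax,
               auc_0_last = z$auc_0_tlast, half_life = z$half_life)
  }))
  truth <- new("SimTruth", kinetics = kinetics,
               catheterStates = data.frame(
                 animal_id = e$animal_id, compartment = e$compartment,
                 true_rr_percent = trueRR, status = e$status),
               closedForm = cf, seed = config@seed)
  new("HipecStudy", samples = samples, calibration = calib, ledger = ledger,
      schedule = schedule, config = config, truth = truth)
}
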