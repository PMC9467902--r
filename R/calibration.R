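#' Relative recovery from a retrodialysis sample
#'
#' Retrodialysis-by-drug: a known drug concentration is perfused through the
#' catheter and the fraction lost across the membrane estimates the relative
#' recovery, \eqn{RR = 100 (1 - C_{dialysate} / C_{perfusate})} in percent.
#' RR(0) = 100 (total loss to tissue), RR(C_perfusate) = 0 (no diffusion).
#'
#' @param cDialysate dialysate concentration (ug/mL, >= 0); vectorised.
#' @param cPerfusate perfusate concentration (ug/mL, > 0).
#' @return RR in percent.
#' @examples
#' relativeRecovery(10.5, 100)  # 89.5
#' @export
relativeRecovery <- function(cDialysate, cPerfusate) {
  if (any(cPerfusate <= 0)) stop("perfusate concentration must be > 0")
  if (any(cDialysate < 0)) stop("dialysate concentration must be >= 0")
  100 * (1 - cDialysate / cPerfusate)
}

#' Validate a relative-recovery estimate
#'
#' QC gate for calibration results. RR outside \code{(lower, upper]}
#' (default (0, 100]) marks the catheter as malfunctioning: an apparent
#' RR <= 0 means the dialysate matched or exceeded the perfusate.
#'
#' @param rrPercent RR estimate in percent.
#' @param bounds numeric length 2, \code{c(lower, upper)}; RR must satisfy
#'   \code{lower < RR <= upper}.
#' @return list with \code{valid} (logical) and \code{reason} (character).
#' @export
validateRecovery <- function(rrPercent, bounds = c(0, 100)) {
  if (is.na(rrPercent))
    return(list(valid = FALSE, reason = "missing RR"))
  if (rrPercent <= bounds[1L])
    return(list(valid = FALSE,
                reason = "apparent non-positive recovery (dialysate >= perfusate)"))
  if (rrPercent > bounds[2L])
    return(list(valid = FALSE, reason = "RR above upper bound"))
  list(valid = TRUE, reason = "")
}

#' Per-catheter recovery from a replicate pair
#'
#' The catheter RR is the mean of the two per-replicate relative recoveries
#' from the two 40-min retrodialysis samples. A missing replicate yields an
#' invalid result (with reason), not an error.
#'
#' @param cDialysate1,cDialysate2 the two replicate dialysate concentrations
#'   (ug/mL); NA marks a missing replicate.
#' @param cPerfusate perfusate concentration (ug/mL, > 0).
#' @param bounds RR validity bounds, see [validateRecovery()].
#' @return list: \code{rr_percent}, \code{valid}, \code{reason}.
#' @examples
#' catheterRecovery(10, 11, 100)$rr_percent  # 89.5
#' @export
catheterRecovery <- function(cDialysate1, cDialysate2, cPerfusate,
                             bounds = c(0, 100)) {
  if (is.na(cDialysate1) || is.na(cDialysate2))
    return(list(rr_percent = NA_real_, valid = FALSE,
                reason = "missing replicate"))
  rr <- mean(relativeRecovery(c(cDialysate1, cDialysate2), cPerfusate))
  v <- validateRecovery(rr, bounds)
  list(rr_percent = rr, valid = v$valid, reason = v$reason)
}

#' Calibrate all catheters of a study
#'
#' Applies [catheterRecovery()] to every animal x compartment pair in a
#' calibration table (two replicates per catheter; catheters with fewer or
#' more rows come out invalid).
#'
#' @param calibration data.frame with columns animal_id, compartment,
#'   replicate, perfusate_conc_ug_per_ml, dialysate_conc_ug_per_ml (the
#'   calibration.csv contract, as emitted by [simulateStudy()]).
#' @param bounds RR validity bounds.
#' @return data.frame (the recovery.csv contract): animal_id, compartment,
#'   rr_percent, valid, reason.
#' @export
calibrateRecoveries <- function(calibration, bounds = c(0, 100)) {
  need <- c("animal_id", "compartment", "replicate",
            "perfusate_conc_ug_per_ml", "dialysate_conc_ug_per_ml")
  if (!all(need %in% names(calibration)))
    stop("calibration must have columns ", paste(need, collapse = ", "))
  key <- unique(calibration[, c("animal_id", "compartment")])
  key <- key[order(key$animal_id, key$compartment), , drop = FALSE]
  out <- lapply(seq_len(nrow(key)), function(i) {
    rows <- calibration[calibration$animal_id == key$animal_id[i] &
                        calibration$compartment == key$compartment[i], ]
    if (nrow(rows) != 2L)
      r <- list(rr_percent = NA_real_, valid = FALSE,
                reason = sprintf("expected 2 replicates, got %d", nrow(rows)))
    else
      r <- catheterRecovery(rows$dialysate_conc_ug_per_ml[1L],
                            rows$dialysate_conc_ug_per_ml[2L],
                            rows$perfusate_conc_ug_per_ml[1L], bounds)
    data.frame(animal_id = key$animal_id[i],
               compartment = key$compartment[i],
               rr_percent = r$rr_percent, valid = r$valid, reason = r$reason)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
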