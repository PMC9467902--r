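#' @include AllClasses.R
NULL

#' Convert a dialysate concentration to absolute free tissue concentration
#'
#' RR correction: \eqn{C_{tissue} = 100 \cdot C_{dialysate} / RR}. Exact
#' algebraic inverse of the recovery attenuation, so
#' \code{correctConcentration(c, RR) * RR / 100 == c}.
#'
#' @param cDialysate dialysate concentration (ug/mL, >= 0); vectorised.
#' @param rrPercent relative recovery in percent (> 0); a non-positive RR is
#'   an error — such catheters must be excluded upstream.
#' @return Free tissue concentration (ug/mL).
#' @examples
#' correctConcentration(5, 50)      # 10
#' correctConcentration(8.95, 89.5) # 10
#' @export
correctConcentration <- function(cDialysate, rrPercent) {
  if (any(rrPercent <= 0))
    stop("RR must be > 0 (invalid catheters are excluded, not corrected)")
  if (any(cDialysate < 0)) stop("dialysate concentration must be >= 0")
  100 * cDialysate / rrPercent
}

# shared point-assembly for one catheter; returns list(points, nIn,
# nCensored, nExcluded). rrPercent = NA means plasma passthrough.
.profilePoints <- function(samples, rrPercent, loqPolicy, loqUgPerMl) {
  n_in <- nrow(samples)
  cens <- samples$below_loq == 1L
  n_cens <- sum(cens)
  corr <- function(x) if (is.na(rrPercent)) x
                      else correctConcentration(x, rrPercent)
  if (loqPolicy == "exclude") {
    keep <- samples[!cens, , drop = FALSE]
    pts <- data.frame(midpoint_min = keep$midpoint_min,
                      conc_ug_per_ml = corr(keep$conc_ug_per_ml),
                      censored = integer(nrow(keep)))
    n_excl <- n_cens
  } else if (loqPolicy == "halve") {
    conc <- ifelse(cens, loqUgPerMl / 2, samples$conc_ug_per_ml)
    pts <- data.frame(midpoint_min = samples$midpoint_min,
                      conc_ug_per_ml = corr(conc),
                      censored = as.integer(cens))
    n_excl <- 0L
  } else stop("unknown loqPolicy: ", loqPolicy)
  pts <- pts[order(pts$midpoint_min), , drop = FALSE]
  rownames(pts) <- NULL
  list(points = pts, nIn = n_in, nCensored = n_cens, nExcluded = n_excl)
}

#' Build a concentration-time profile for one catheter
#'
#' RR-corrects each dialysate sample and timestamps it at its interval
#' midpoint; plasma samples (\code{rrPercent = NA}) pass through unchanged.
#' Below-LOQ samples are handled per policy: \code{"exclude"} (default)
#' drops them but counts them; \code{"halve"} includes them at LOQ/2
#' (RR-corrected for dialysates), flagged. An all-censored catheter under
#' the exclude policy yields an empty profile with the counts recording why.
#'
#' @param samples data.frame for one catheter with columns
#'   \code{midpoint_min}, \code{conc_ug_per_ml}, \code{below_loq}.
#' @param rrPercent the catheter's valid relative recovery (percent), or NA
#'   for plasma.
#' @param loqPolicy \code{"exclude"} or \code{"halve"}.
#' @param loqUgPerMl the assay LOQ, needed by the halve policy.
#' @param animalId,compartment identifiers carried into the profile.
#' @return A [ConcentrationTimeProfile-class].
#' @export
buildProfile <- function(samples, rrPercent, loqPolicy = c("exclude", "halve"),
                         loqUgPerMl = 0.100, animalId = "animal",
                         compartment = "tissue") {
  loqPolicy <- match.arg(loqPolicy)
  need <- c("midpoint_min", "conc_ug_per_ml", "below_loq")
  if (!all(need %in% names(samples)))
    stop("samples must have columns ", paste(need, collapse = ", "))
  z <- .profilePoints(samples, rrPercent, loqPolicy, loqUgPerMl)
  new("ConcentrationTimeProfile", animalId = animalId,
      compartment = compartment, points = z$points,
      nIn = as.integer(z$nIn), nCensored = as.integer(z$nCensored),
      nExcluded = as.integer(z$nExcluded))
}

#' Build all concentration-time profiles of a study
#'
#' Joins the sample table with per-catheter recoveries, drops every sample
#' of catheters with an invalid (or absent) recovery — whole-catheter
#' exclusion, mirroring the per-catheter QC accounting — RR-corrects
#' dialysates, passes plasma through, and applies the LOQ policy.
#'
#' @param samples data.frame in the samples.csv contract (animal_id,
#'   compartment, sample_type, midpoint_min, conc_ug_per_ml, below_loq).
#' @param recoveries data.frame in the recovery.csv contract as returned by
#'   [calibrateRecoveries()].
#' @param loqPolicy below-LOQ handling, see [buildProfile()].
#' @param loqUgPerMl assay LOQ.
#' @return data.frame (the profiles.csv contract): animal_id, compartment,
#'   midpoint_min, conc_ug_per_ml, censored; with an attribute
#'   \code{"counts"} (data.frame animal_id, compartment, n_in, n_censored,
#'   n_excluded, reason) covering every catheter seen, including emptied
#'   ones.
#' @export
buildProfiles <- function(samples, recoveries,
                          loqPolicy = c("exclude", "halve"),
                          loqUgPerMl = 0.100) {
  loqPolicy <- match.arg(loqPolicy)
  key <- unique(samples[, c("animal_id", "compartment", "sample_type")])
  key <- key[order(key$animal_id, key$compartment), , drop = FALSE]
  rrkey <- paste(recoveries$animal_id, recoveries$compartment, sep = "\r")
  pts <- list(); counts <- list()
  for (i in seq_len(nrow(key))) {
    rows <- samples[samples$animal_id == key$animal_id[i] &
                    samples$compartment == key$compartment[i], , drop = FALSE]
    plasma <- key$sample_type[i] == "plasma"
    reason <- ""
    if (plasma) {
      rr <- NA_real_
    } else {
      j <- match(paste(key$animal_id[i], key$compartment[i], sep = "\r"),
                 rrkey)
      if (is.na(j) || !recoveries$valid[j]) {
        reason <- if (is.na(j)) "no calibration"
                  else paste("invalid recovery:", recoveries$reason[j])
        counts[[i]] <- data.frame(
          animal_id = key$animal_id[i], compartment = key$compartment[i],
          n_in = nrow(rows), n_censored = sum(rows$below_loq == 1L),
          n_excluded = nrow(rows), reason = reason)
        next
      }
      rr <- recoveries$rr_percent[j]
    }
    z <- .profilePoints(rows, rr, loqPolicy, loqUgPerMl)
    if (nrow(z$points))
      pts[[i]] <- cbind(animal_id = key$animal_id[i],
                        compartment = key$compartment[i], z$points)
    counts[[i]] <- data.frame(
      animal_id = key$animal_id[i], compartment = key$compartment[i],
      n_in = z$nIn, n_censored = z$nCensored, n_excluded = z$nExcluded,
      reason = if (nrow(z$points)) "" else "all samples censored")
  }
  out <- do.call(rbind, pts[!vapply(pts, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(animal_id = character(0), compartment = character(0),
                      midpoint_min = numeric(0), conc_ug_per_ml = numeric(0),
                      censored = integer(0))
  rownames(out) <- NULL
  attr(out, "counts") <- do.call(rbind, counts)
  out
}
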