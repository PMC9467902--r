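#' @include AllClasses.R
NULL

#' Build the dialysate sampling schedule
#'
#' Constructs the contiguous collection schedule: fine intervals of
#' \code{fineStepMin} minutes from 0 to \code{switchMin}, then coarse
#' intervals of \code{coarseStepMin} minutes to \code{endMin}. The default
#' (30, 60, 240, 480) is the study design used throughout: 8 fine + 4 coarse
#' = 12 samples per catheter over 8 h of sampling from HIPEC initiation.
#'
#' @param fineStepMin fine interval width (min).
#' @param coarseStepMin coarse interval width (min).
#' @param switchMin time at which the width switches (min).
#' @param endMin end of sampling (min).
#' @return A [SamplingSchedule-class] object.
#' @examples
#' sched <- buildSchedule()
#' nrow(intervals(sched))   # 12
#' midpoints(sched)         # 15, 45, ..., 450
#' @export
buildSchedule <- function(fineStepMin = 30, coarseStepMin = 60,
                          switchMin = 240, endMin = 480) {
  stopifnot(fineStepMin > 0, coarseStepMin > 0)
  if (!(fineStepMin <= switchMin && switchMin <= endMin))
    stop("require 0 < fineStepMin <= switchMin <= endMin")
  .divides <- function(step, span)
    isTRUE(all.equal(span / step, round(span / step)))
  if (!.divides(fineStepMin, switchMin))
    stop(sprintf("fine step %g does not divide [0, %g] exactly",
                 fineStepMin, switchMin))
  if (switchMin < endMin && !.divides(coarseStepMin, endMin - switchMin))
    stop(sprintf("coarse step %g does not divide [%g, %g] exactly",
                 coarseStepMin, switchMin, endMin))
  starts <- c(seq(0, switchMin - fineStepMin, by = fineStepMin),
              if (switchMin < endMin)
                seq(switchMin, endMin - coarseStepMin, by = coarseStepMin))
  ends <- c(starts[-1L], endMin)
  new("SamplingSchedule",
      intervals = data.frame(start_min = starts, end_min = ends))
}

#' Midpoint of a sampling interval
#'
#' Each dialysate integrates drug over its collection window; the measured
#' concentration is assigned to the midpoint of that window. Vectorised.
#'
#' @param startMin,endMin interval bounds (min), \code{endMin > startMin}.
#' @return Numeric midpoint times \code{(startMin + endMin) / 2}.
#' @examples
#' intervalMidpoint(0, 30)    # 15
#' intervalMidpoint(420, 480) # 450, the last sampling time of the design
#' @export
intervalMidpoint <- function(startMin, endMin) {
  if (any(endMin <= startMin))
    stop("degenerate interval: end must exceed start")
  (startMin + endMin) / 2
}

#' Default catheter site table
#'
#' The eight solid-tissue microdialysis sites of the study design: liver,
#' hepatoduodenal ligament at 1 mm (superficial) and 4 mm (profound),
#' peritoneum of the right abdominal wall, rectum at 1 mm and 4 mm,
#' mesentery and bladder wall. Depth is an attribute of the site name; NA
#' means "as superficial as possible", not measured.
#'
#' @return data.frame with columns \code{compartment}, \code{depth_mm}.
#' @export
defaultSites <- function() {
  data.frame(
    compartment = c("liver", "hl_superficial", "hl_profound", "peritoneum",
                    "rectum_superficial", "rectum_profound", "mesentery",
                    "bladder_wall"),
    depth_mm = c(NA, 1, 4, NA, 1, 4, NA, NA))
}

#' Build the catheter ledger
#'
#' One entry per animal x catheter site, all initially status \code{ok}.
#' Animals are labelled \code{pig1 ... pigN}.
#'
#' @param nAnimals number of animals (>= 1).
#' @param siteTable data.frame with columns \code{compartment},
#'   \code{depth_mm}; defaults to [defaultSites()].
#' @return A [CatheterLedger-class] with \code{nAnimals * nrow(siteTable)}
#'   entries.
#' @examples
#' nrow(ledgerEntries(buildLedger(8)))  # 64
#' @export
buildLedger <- function(nAnimals, siteTable = defaultSites()) {
  if (nAnimals < 1L) stop("nAnimals must be >= 1")
  if (!all(c("compartment", "depth_mm") %in% names(siteTable)))
    stop("siteTable must have columns compartment, depth_mm")
  if (anyDuplicated(siteTable$compartment))
    stop("duplicate site names within an animal")
  ids <- paste0("pig", seq_len(nAnimals))
  entries <- data.frame(
    animal_id = rep(ids, each = nrow(siteTable)),
    compartment = rep(siteTable$compartment, nAnimals),
    depth_mm = rep(siteTable$depth_mm, nAnimals),
    status = "ok")
  new("CatheterLedger", entries = entries)
}

#' Apply quality-control exclusions to a ledger
#'
#' Marks individual catheters as malfunctioning or displaced. The number of
#' entries never changes, only statuses; downstream stages consume only
#' status-\code{ok} catheters. With the default 8 x 8 design and the
#' observed exclusions (3 malfunctions, 8 displacements) this leaves 53
#' active catheters.
#'
#' @param ledger a [CatheterLedger-class].
#' @param exclusions data.frame with columns \code{animal_id},
#'   \code{compartment}, \code{status} (malfunction or displaced). Every row
#'   must reference an existing ledger entry.
#' @return The updated [CatheterLedger-class].
#' @export
applyQC <- function(ledger, exclusions) {
  stopifnot(is(ledger, "CatheterLedger"))
  if (nrow(exclusions) == 0L) return(ledger)
  if (!all(c("animal_id", "compartment", "status") %in% names(exclusions)))
    stop("exclusions must have columns animal_id, compartment, status")
  if (!all(exclusions$status %in% c("malfunction", "displaced")))
    stop("exclusion status must be malfunction or displaced")
  e <- ledger@entries
  key <- paste(e$animal_id, e$compartment, sep = "\r")
  exkey <- paste(exclusions$animal_id, exclusions$compartment, sep = "\r")
  idx <- match(exkey, key)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1L]
    stop(sprintf("exclusion references unknown catheter: %s / %s",
                 exclusions$animal_id[bad], exclusions$compartment[bad]))
  }
  e$status[idx] <- exclusions$status
  new("CatheterLedger", entries = e)
}

#' @describeIn buildSchedule Export a schedule as the schedule.csv contract
#'   (interval_index, start_min, end_min, midpoint_min).
#' @param schedule a [SamplingSchedule-class].
#' @export
scheduleTable <- function(schedule) {
  iv <- intervals(schedule)
  data.frame(interval_index = seq_len(nrow(iv)),
             start_min = iv$start_min, end_min = iv$end_min,
             midpoint_min = midpoints(schedule))
}
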