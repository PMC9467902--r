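.PARAM_COLS <- c(auc = "auc0last_min_ugml", cmax = "cmax_ugml",
                 tmax = "tmax_min")

# two-sided 95% t-interval; n < 2 gives NA bounds
.tCI <- function(x, level = 0.95) {
  n <- length(x); m <- mean(x)
  if (n < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_))
  half <- stats::qt(1 - (1 - level) / 2, n - 1L) * stats::sd(x) / sqrt(n)
  c(mean = m, lo = m - half, hi = m + half)
}

#' Per-compartment PK parameter summaries
#'
#' Arithmetic mean and two-sided 95\% t-interval across animals, per
#' compartment, for AUC_0-last, Cmax and Tmax. Compartments with a single
#' animal are reported without a CI. Group summaries are independent:
#' dropping an animal changes only the groups it belonged to.
#'
#' @param nca data.frame from [runNCA()].
#' @param level confidence level (default 0.95).
#' @return data.frame (the summary.csv contract): compartment, n, auc_mean,
#'   auc_lo, auc_hi, cmax_mean, cmax_lo, cmax_hi, tmax_mean, tmax_lo,
#'   tmax_hi.
#' @export
summarizeByCompartment <- function(nca, level = 0.95) {
  if (nrow(nca) == 0L) stop("empty NCA input")
  cmps <- sort(unique(nca$compartment))
  out <- lapply(cmps, function(cmp) {
    rows <- nca[nca$compartment == cmp, , drop = FALSE]
    z <- lapply(.PARAM_COLS, function(col) .tCI(rows[[col]], level))
    data.frame(compartment = cmp, n = nrow(rows),
               auc_mean = z$auc["mean"], auc_lo = z$auc["lo"],
               auc_hi = z$auc["hi"],
               cmax_mean = z$cmax["mean"], cmax_lo = z$cmax["lo"],
               cmax_hi = z$cmax["hi"],
               tmax_mean = z$tmax["mean"], tmax_lo = z$tmax["lo"],
               tmax_hi = z$tmax["hi"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Mixed-model comparison of compartments
#'
#' Fits, by REML, a linear mixed model with compartment as fixed effect and
#' animal as random intercept (\code{lme4}), and reports the overall
#' fixed-effect F-test plus pairwise paired t-tests on within-animal
#' differences (complete pairs only). The denominator degrees of freedom for
#' the F-test use the classical repeated-measures convention:
#' \eqn{(a-1)(c-1)} for a balanced layout of a animals x c compartments,
#' \eqn{N - a - c + 1} otherwise — in the balanced compound-symmetry case
#' this coincides with the Satterthwaite approximation, and for two
#' compartments the F-test is exactly the squared paired t-test. Pairwise
#' p-values are unadjusted by default (an optional Holm adjustment is
#' provided); significance is declared at alpha = 0.05.
#'
#' @param nca data.frame from [runNCA()].
#' @param parameter one of \code{"auc"}, \code{"cmax"}, \code{"tmax"}, or an
#'   nca column name.
#' @param adjust \code{"none"} (default) or \code{"holm"} for the pairwise
#'   p-values.
#' @param alpha significance level for the flags.
#' @return list with \code{overall} (data.frame: parameter, f_statistic,
#'   df1, df2, p_value, significant) and \code{pairwise} (data.frame:
#'   parameter, compartment_a, compartment_b, n_pairs, estimate,
#'   t_statistic, p_value, significant).
#' @export
mixedModelCompare <- function(nca, parameter = c("auc", "cmax", "tmax"),
                              adjust = c("none", "holm"), alpha = 0.05) {
  adjust <- match.arg(adjust)
  parameter <- parameter[1L]
  col <- if (parameter %in% names(.PARAM_COLS)) .PARAM_COLS[[parameter]]
         else parameter
  if (!col %in% names(nca)) stop("unknown parameter: ", parameter)
  d <- data.frame(animal = nca$animal_id, cmp = nca$compartment,
                  value = nca[[col]])
  d <- d[is.finite(d$value), , drop = FALSE]
  a <- length(unique(d$animal)); cc <- length(unique(d$cmp))
  if (cc < 2L) stop("need at least 2 compartments to compare")
  if (a < 3L) stop("need at least 3 animals for the mixed model")

  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(value ~ cmp + (1 | animal), data = d, REML = TRUE)))
  fstat <- stats::anova(fit)[1L, "F value"]
  df1 <- cc - 1L
  balanced <- nrow(d) == a * cc &&
    all(table(d$animal, d$cmp) == 1L)
  df2 <- if (balanced) (a - 1L) * (cc - 1L)
         else max(1L, nrow(d) - a - cc + 1L)
  p <- stats::pf(fstat, df1, df2, lower.tail = FALSE)
  overall <- data.frame(parameter = parameter, f_statistic = fstat,
                        df1 = df1, df2 = df2, p_value = p,
                        significant = p < alpha)

  cmps <- sort(unique(d$cmp))
  pairs <- utils::combn(cmps, 2L, simplify = FALSE)
  pw <- lapply(pairs, function(pr) {
    x <- d[d$cmp == pr[1L], c("animal", "value")]
    y <- d[d$cmp == pr[2L], c("animal", "value")]
    common <- intersect(x$animal, y$animal)
    if (length(common) < 2L)
      return(data.frame(parameter = parameter, compartment_a = pr[1L],
                        compartment_b = pr[2L], n_pairs = length(common),
                        estimate = NA_real_, t_statistic = NA_real_,
                        p_value = NA_real_, significant = NA))
    dx <- x$value[match(common, x$animal)] -
          y$value[match(common, y$animal)]
    if (stats::sd(dx) == 0) {
      # degenerate paired test: all differences identical
      est <- mean(dx)
      tt <- list(statistic = if (est == 0) 0 else Inf * sign(est),
                 p.value = if (est == 0) 1 else 0)
    } else tt <- stats::t.test(dx)
    data.frame(parameter = parameter, compartment_a = pr[1L],
               compartment_b = pr[2L], n_pairs = length(common),
               estimate = mean(dx), t_statistic = unname(tt$statistic),
               p_value = tt$p.value, significant = NA)
  })
  pw <- do.call(rbind, pw)
  if (adjust == "holm") pw$p_value <- stats::p.adjust(pw$p_value, "holm")
  pw$significant <- pw$p_value < alpha
  rownames(pw) <- NULL
  list(overall = overall, pairwise = pw)
}

#' Mean concentration-time profiles per compartment
#'
#' Figure-style export: per compartment and midpoint, the across-animal mean
#' concentration with a 95\% t-interval.
#'
#' @param profiles data.frame in the profiles.csv contract.
#' @param level confidence level.
#' @return data.frame: compartment, midpoint_min, n, mean_conc, lo, hi.
#' @export
meanProfiles <- function(profiles, level = 0.95) {
  key <- unique(profiles[, c("compartment", "midpoint_min")])
  key <- key[order(key$compartment, key$midpoint_min), , drop = FALSE]
  out <- lapply(seq_len(nrow(key)), function(i) {
    v <- profiles$conc_ug_per_ml[
      profiles$compartment == key$compartment[i] &
      profiles$midpoint_min == key$midpoint_min[i]]
    z <- .tCI(v, level)
    data.frame(compartment = key$compartment[i],
               midpoint_min = key$midpoint_min[i], n = length(v),
               mean_conc = z["mean"], lo = z["lo"], hi = z["hi"])
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write the report files of a completed analysis
#'
#' Deterministically writes \code{summary.csv} (per-compartment means with
#' 95\% CIs), \code{comparisons.csv} (overall F-tests and pairwise paired
#' t-tests for AUC, Cmax and Tmax) and \code{mean_profiles.csv} to a
#' directory. Re-running on identical inputs reproduces identical files.
#'
#' @param nca data.frame from [runNCA()].
#' @param profiles data.frame from [buildProfiles()].
#' @param outDir output directory (created if absent).
#' @param adjust pairwise p-value adjustment, see [mixedModelCompare()].
#' @return Invisibly, a named list of the written data.frames.
#' @export
writeReport <- function(nca, profiles, outDir, adjust = "none") {
  if (nrow(nca) == 0L) stop("empty NCA input")
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  summ <- summarizeByCompartment(nca)
  cmpres <- lapply(c("auc", "cmax", "tmax"), function(p)
    tryCatch(mixedModelCompare(nca, p, adjust = adjust),
             error = function(e) NULL))
  cmpres <- cmpres[!vapply(cmpres, is.null, logical(1L))]
  overall <- do.call(rbind, lapply(cmpres, function(z) {
    o <- z$overall
    data.frame(parameter = o$parameter, test = "overall_F",
               compartment_a = NA, compartment_b = NA, n_pairs = NA,
               estimate = NA, statistic = o$f_statistic,
               p_value = o$p_value, significant = o$significant)
  }))
  pairwise <- do.call(rbind, lapply(cmpres, function(z) {
    p <- z$pairwise
    data.frame(parameter = p$parameter, test = "paired_t",
               compartment_a = p$compartment_a,
               compartment_b = p$compartment_b, n_pairs = p$n_pairs,
               estimate = p$estimate, statistic = p$t_statistic,
               p_value = p$p_value, significant = p$significant)
  }))
  comparisons <- rbind(overall, pairwise)
  if (is.null(comparisons)) comparisons <- data.frame()
  mp <- meanProfiles(profiles)
  .w <- function(x, f) utils::write.csv(x, file.path(outDir, f),
                                        row.names = FALSE)
  .w(summ, "summary.csv")
  .w(comparisons, "comparisons.csv")
  .w(mp, "mean_profiles.csv")
  invisible(list(summary = summ, comparisons = comparisons,
                 mean_profiles = mp))
}

#' Run the complete analysis pipeline
#'
#' Chains every stage on a (simulated or supplied) study: retrodialysis
#' calibration, whole-catheter QC on recovery validity, RR correction into
#' midpoint-timed profiles, non-compartmental analysis, per-compartment
#' summaries and mixed-model comparisons. With \code{outDir} set, also
#' writes the CSV contracts of each stage.
#'
#' @param config a [StudyConfig-class]; ignored when \code{study} is given.
#' @param study an existing [HipecStudy-class]; simulated from
#'   \code{config} when NULL.
#' @param loqPolicy below-LOQ policy, see [buildProfile()].
#' @param leadingZero AUC leading-segment switch, see [aucLinUpLogDown()].
#' @param outDir optional output directory for the CSV exports.
#' @return list: study, recoveries, profiles, nca, summary, comparisons.
#' @examples
#' res <- runStudyPipeline(defaultStudyConfig(seed = 3L))
#' res$summary[, c("compartment", "n", "auc_mean", "cmax_mean")]
#' @export
runStudyPipeline <- function(config = defaultStudyConfig(), study = NULL,
                             loqPolicy = "exclude", leadingZero = TRUE,
                             outDir = NULL) {
  if (is.null(study)) study <- simulateStudy(config)
  recov <- calibrateRecoveries(calibrationSamples(study))
  prof <- buildProfiles(studySamples(study), recov, loqPolicy = loqPolicy,
                        loqUgPerMl = study@config@loqUgPerMl)
  nca <- runNCA(prof, leadingZero = leadingZero)
  summ <- summarizeByCompartment(nca)
  cmp <- lapply(c(auc = "auc", cmax = "cmax", tmax = "tmax"),
                function(p) tryCatch(mixedModelCompare(nca, p),
                                     error = function(e) {
                                       message("comparisons skipped for ", p,
                                               ": ", conditionMessage(e))
                                       NULL
                                     }))
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    .w <- function(x, f) utils::write.csv(x, file.path(outDir, f),
                                          row.names = FALSE)
    .w(studySamples(study), "samples.csv")
    .w(calibrationSamples(study), "calibration.csv")
    .w(ledgerEntries(study), "ledger.csv")
    .w(scheduleTable(study@schedule), "schedule.csv")
    .w(recov, "recovery.csv")
    .w(prof, "profiles.csv")
    .w(nca, "nca.csv")
    writeReport(nca, prof, outDir)
  }
  list(study = study, recoveries = recov, profiles = prof, nca = nca,
       summary = summ, comparisons = cmp)
}
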