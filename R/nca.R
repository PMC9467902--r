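#' Observed peak concentration and its time
#'
#' Cmax is the maximum observed (non-censored) concentration during the
#' sampling period and Tmax the time of that observation; ties are broken by
#' the earliest time, which keeps the result deterministic.
#'
#' @param times observation times (min), strictly increasing.
#' @param concs concentrations (ug/mL), same length.
#' @return list with \code{cmax}, \code{tmax}.
#' @export
findCmaxTmax <- function(times, concs) {
  if (length(times) < 1L) stop("profile has no usable points")
  stopifnot(length(times) == length(concs))
  i <- which.max(concs)  # which.max returns the first maximum: earliest time
  list(cmax = concs[i], tmax = times[i])
}

#' Linear up-log down trapezoidal AUC
#'
#' Area under the concentration-time curve to the last observation. Rising
#' or flat segments (\eqn{C_2 \ge C_1}) use the linear trapezoid
#' \eqn{(C_1 + C_2)\Delta t / 2}; falling segments use the log trapezoid
#' \eqn{(C_1 - C_2)\Delta t / \ln(C_1 / C_2)}, which assumes exponential
#' decline between observations. A falling segment with a non-positive
#' endpoint falls back to the linear rule. With \code{leadingZero = TRUE}
#' (default) the area starts at t = 0 with concentration 0 — drug is absent
#' before perfusion starts — rising linearly to the first observation.
#'
#' @param times observation times (min), strictly increasing.
#' @param concs concentrations (ug/mL).
#' @param leadingZero include the linear leading segment from (0, 0)?
#' @return AUC in min.ug/mL.
#' @examples
#' aucLinUpLogDown(c(0, 60), c(10, 5), leadingZero = FALSE)  # 300/log(2)
#' @export
aucLinUpLogDown <- function(times, concs, leadingZero = TRUE) {
  .aucCheck(times, concs)
  auc <- if (leadingZero && times[1L] > 0) concs[1L] * times[1L] / 2 else 0
  if (length(times) > 1L) for (i in 2:length(times)) {
    dt <- times[i] - times[i - 1L]
    c1 <- concs[i - 1L]; c2 <- concs[i]
    auc <- auc + if (c2 < c1 && c2 > 0)
      (c1 - c2) * dt / log(c1 / c2) else (c1 + c2) * dt / 2
  }
  auc
}

#' All-linear trapezoidal AUC
#'
#' Reference rule for the lin-up/log-down comparison: the log trapezoid
#' never exceeds the linear one on a falling segment (log-mean inequality),
#' so [aucLinUpLogDown()] is bounded above by this rule, with equality iff
#' no strictly decreasing segment exists.
#'
#' @inheritParams aucLinUpLogDown
#' @return AUC in min.ug/mL.
#' @export
aucLinear <- function(times, concs, leadingZero = TRUE) {
  .aucCheck(times, concs)
  auc <- if (leadingZero && times[1L] > 0) concs[1L] * times[1L] / 2 else 0
  if (length(times) > 1L)
    auc <- auc + sum(diff(times) *
                       (concs[-1L] + concs[-length(concs)]) / 2)
  auc
}

.aucCheck <- function(times, concs) {
  if (length(times) < 1L) stop("profile has no usable points")
  stopifnot(length(times) == length(concs))
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(times < 0)) stop("times must be >= 0")
  invisible(TRUE)
}

#' Terminal elimination rate constant by log-linear regression
#'
#' Ordinary least squares of ln(concentration) on time over a terminal tail
#' of points strictly after Tmax; lambda_z is minus the slope. The default
#' selection policy considers every tail of the last k points (k = 3 up to
#' all post-Tmax points), requires a positive lambda_z, and keeps the tail
#' with maximal adjusted R-squared (ties go to the shortest tail). The
#' \code{"last3"} policy fixes k = 3. Fewer than \code{minPoints} usable
#' post-Tmax points, or no candidate with positive slope, flags the result
#' as non-estimable rather than failing: the short sampling window often
#' precludes a clean terminal phase.
#'
#' @param times observation times (min), strictly increasing.
#' @param concs concentrations (ug/mL, > 0 required for the log fit).
#' @param tmax time of the observed peak; points at or before it are never
#'   part of the tail. Computed from the data when NULL.
#' @param policy \code{"adjr2"} (default) or \code{"last3"}.
#' @param minPoints minimum tail size (>= 3).
#' @return list: \code{lambda_z} (1/min), \code{n_points}, \code{adj_r2},
#'   \code{estimable}, \code{reason}.
#' @export
fitLambdaZ <- function(times, concs, tmax = NULL,
                       policy = c("adjr2", "last3"), minPoints = 3L) {
  policy <- match.arg(policy)
  stopifnot(minPoints >= 3L)
  notEst <- function(reason) list(lambda_z = NA_real_, n_points = NA_integer_,
                                  adj_r2 = NA_real_, estimable = FALSE,
                                  reason = reason)
  if (is.null(tmax)) tmax <- findCmaxTmax(times, concs)$tmax
  sel <- times > tmax & concs > 0
  tt <- times[sel]; cc <- concs[sel]
  m <- length(tt)
  if (m < minPoints)
    return(notEst(sprintf("only %d usable points after Tmax", m)))
  ks <- if (policy == "last3") minPoints else minPoints:m
  best <- NULL
  for (k in ks) {
    idx <- (m - k + 1L):m
    x <- tt[idx]; y <- log(cc[idx])
    fit <- stats::lm.fit(cbind(1, x), y)
    lambda <- -fit$coefficients[2L]
    # 1e-12/min guards against a numerically-zero slope on flat tails
    if (!is.finite(lambda) || lambda <= 1e-12) next
    rss <- sum(fit$residuals^2)
    tss <- sum((y - mean(y))^2)
    if (tss <= 0) next  # constant tail: no decline to fit
    r2 <- 1 - rss / tss
    adj <- 1 - (1 - r2) * (k - 1) / (k - 2)
    if (is.null(best) || adj > best$adj_r2)
      best <- list(lambda_z = unname(lambda), n_points = k, adj_r2 = adj,
                   estimable = TRUE, reason = "")
  }
  if (is.null(best)) return(notEst("no tail with positive lambda_z"))
  best
}

#' Terminal half-life
#'
#' \eqn{T_{1/2} = \ln 2 / \lambda_z}.
#'
#' @param lambdaZ terminal elimination rate constant (1/min, > 0).
#' @return Half-life in minutes.
#' @examples
#' halfLife(0.01)  # 69.31
#' @export
halfLife <- function(lambdaZ) {
  if (any(lambdaZ <= 0)) stop("lambda_z must be > 0")
  log(2) / lambdaZ
}

#' Non-compartmental analysis of all profiles
#'
#' One result row per animal x compartment: Cmax/Tmax from the observed
#' points, AUC to the last observation by the linear up-log down rule (with
#' the t = 0 leading segment by default), lambda_z by terminal log-linear
#' regression and the derived half-life with its estimability flag. Censored
#' points retained by the halve policy participate in Cmax/AUC but are
#' excluded from the log-linear tail. Groups whose profile is empty are
#' skipped (absent from the output), not fatal; the output is sorted by
#' animal and compartment and invariant to input row order.
#'
#' @param profiles data.frame in the profiles.csv contract (animal_id,
#'   compartment, midpoint_min, conc_ug_per_ml, censored).
#' @param leadingZero include the linear segment from (0, 0), see
#'   [aucLinUpLogDown()].
#' @param lambdaPolicy tail-selection policy, see [fitLambdaZ()].
#' @return data.frame (the nca.csv contract): animal_id, compartment,
#'   cmax_ugml, tmax_min, auc0last_min_ugml, lambda_z_per_min, t_half_min,
#'   n_lambda_points, lambda_adj_r2, t_half_estimable.
#' @export
runNCA <- function(profiles, leadingZero = TRUE,
                   lambdaPolicy = c("adjr2", "last3")) {
  lambdaPolicy <- match.arg(lambdaPolicy)
  need <- c("animal_id", "compartment", "midpoint_min", "conc_ug_per_ml",
            "censored")
  if (!all(need %in% names(profiles)))
    stop("profiles must have columns ", paste(need, collapse = ", "))
  key <- unique(profiles[, c("animal_id", "compartment")])
  key <- key[order(key$animal_id, key$compartment), , drop = FALSE]
  out <- lapply(seq_len(nrow(key)), function(i) {
    rows <- profiles[profiles$animal_id == key$animal_id[i] &
                     profiles$compartment == key$compartment[i], ,
                     drop = FALSE]
    rows <- rows[order(rows$midpoint_min), , drop = FALSE]
    if (nrow(rows) == 0L) return(NULL)
    pk <- findCmaxTmax(rows$midpoint_min, rows$conc_ug_per_ml)
    auc <- aucLinUpLogDown(rows$midpoint_min, rows$conc_ug_per_ml,
                           leadingZero)
    nc <- rows[rows$censored == 0L, , drop = FALSE]
    lz <- fitLambdaZ(nc$midpoint_min, nc$conc_ug_per_ml, tmax = pk$tmax,
                     policy = lambdaPolicy)
    data.frame(animal_id = key$animal_id[i],
               compartment = key$compartment[i],
               cmax_ugml = pk$cmax, tmax_min = pk$tmax,
               auc0last_min_ugml = auc,
               lambda_z_per_min = lz$lambda_z,
               t_half_min = if (lz$estimable) halfLife(lz$lambda_z)
                            else NA_real_,
               n_lambda_points = lz$n_points,
               lambda_adj_r2 = lz$adj_r2,
               t_half_estimable = lz$estimable)
  })
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  if (is.null(res)) stop("no usable profiles")
  rownames(res) <- NULL
  res
}
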