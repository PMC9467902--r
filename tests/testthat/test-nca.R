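test_that("Cmax/Tmax pick the observed peak, earliest on ties", {
  expect_equal(findCmaxTmax(c(15, 45, 75), c(2, 8, 6)),
               list(cmax = 8, tmax = 45))
  expect_equal(findCmaxTmax(c(15, 45), c(8, 8))$tmax, 15)
  expect_error(findCmaxTmax(numeric(0), numeric(0)), "no usable points")
})

test_that("trapezoid rules reproduce hand-computed segment areas", {
  # rising from assumed zero at t = 0 to 10 ug/mL at 30 min
  expect_equal(aucLinUpLogDown(30, 10), 150)
  # falling pair: log trapezoid (10 -> 5 over 60 min)
  expect_equal(aucLinUpLogDown(c(0, 60), c(10, 5), leadingZero = FALSE),
               300 / log(2))
  expect_equal(aucLinUpLogDown(c(0, 60), c(10, 5), leadingZero = FALSE),
               432.8085, tolerance = 1e-4)
  # constant pair: both rules agree at c * dt
  expect_equal(aucLinUpLogDown(c(0, 60), c(7, 7), leadingZero = FALSE), 420)
  expect_equal(aucLinear(c(0, 60), c(7, 7), leadingZero = FALSE), 420)
  expect_error(aucLinUpLogDown(c(30, 30), c(1, 1)), "strictly increasing")
})

test_that("lin-up/log-down is bounded by the linear rule, equal iff no drop", {
  set.seed(21)
  for (i in 1:50) {
    p <- fixRandomProfile(n = sample(3:12, 1))
    a_ld <- aucLinUpLogDown(p$times, p$concs)
    a_lin <- aucLinear(p$times, p$concs)
    expect_lte(a_ld, a_lin + 1e-12)
    if (any(diff(p$concs) < 0)) expect_lt(a_ld, a_lin)
    else expect_equal(a_ld, a_lin)
  }
})

test_that("AUC is additive over a split at any observed point", {
  set.seed(22)
  p <- fixRandomProfile(n = 10)
  full <- aucLinUpLogDown(p$times, p$concs, leadingZero = FALSE)
  for (cut in c(3, 5, 8)) {
    left <- aucLinUpLogDown(p$times[1:cut], p$concs[1:cut],
                            leadingZero = FALSE)
    right <- aucLinUpLogDown(p$times[cut:10], p$concs[cut:10],
                             leadingZero = FALSE)
    expect_equal(left + right, full)
  }
})

test_that("lambda_z is exact on log-linear data and flags degenerate input", {
  t <- seq(270, 450, by = 60)
  fit <- fitLambdaZ(t, 10 * exp(-0.01 * t), tmax = 100)
  expect_true(fit$estimable)
  expect_equal(fit$lambda_z, 0.01, tolerance = 1e-12)
  expect_equal(fit$adj_r2, 1)
  # constant tail: zero slope is not a positive rate
  flat <- fitLambdaZ(t, rep(5, 4), tmax = 100)
  expect_false(flat$estimable)
  # fewer than 3 post-Tmax points
  few <- fitLambdaZ(c(400, 450), c(3, 2), tmax = 100)
  expect_false(few$estimable)
  expect_match(few$reason, "after Tmax")
})

test_that("half-life follows ln(2)/lambda and rejects non-positive rates", {
  expect_equal(halfLife(0.01), 69.31, tolerance = 1e-3)
  expect_equal(halfLife(0.005), 138.63, tolerance = 1e-4)
  expect_error(halfLife(0), "> 0")
})

test_that("refining the schedule shrinks the AUC discretization error", {
  k <- fixExampleKinetics()
  cfTmax <- closedFormNCA(k, 480)$tmax
  err <- sapply(c(60, 30, 15, 7.5), function(step) {
    sched <- buildSchedule(step, step, 480, 480)
    iv <- intervals(sched)
    conc <- intervalAverage(k, iv$start_min, iv$end_min)
    abs(aucLinUpLogDown(midpoints(sched), conc) -
        closedFormNCA(k, max(midpoints(sched)))$auc_0_tlast)
  })
  expect_true(all(diff(err) < 0))
})

test_that("NCA on noise-free simulated profiles matches the analytic oracle", {
  st <- fixCleanStudy(nAnimals = 2L)
  rec <- calibrateRecoveries(calibrationSamples(st))
  prof <- buildProfiles(studySamples(st), rec)
  nca <- runNCA(prof)
  cf <- studyTruth(st)@closedForm
  for (i in seq_len(nrow(nca))) {
    truth <- cf[cf$compartment == nca$compartment[i], ]
    expect_equal(nca$auc0last_min_ugml[i], truth$auc_0_last,
                 tolerance = 0.02)
    # observed Tmax within one interval width of the continuous peak
    expect_lte(abs(nca$tmax_min[i] - truth$tmax), 60)
    expect_lte(nca$cmax_ugml[i], truth$cmax + 1e-9)
  }
})

test_that("lambda_z from the pipeline recovers k_elim on a clean tail", {
  k <- fixFastKinetics()  # half-life 57.8 min; last-3 tail spans > 2 halves
  sched <- fixSchedule()
  s <- simulateDialysateSeries(k, 100, sched, noiselessModel())
  prof <- profilePoints(buildProfile(s, rrPercent = 100))
  pk <- findCmaxTmax(prof$midpoint_min, prof$conc_ug_per_ml)
  fit <- fitLambdaZ(prof$midpoint_min, prof$conc_ug_per_ml, tmax = pk$tmax)
  expect_true(fit$estimable)
  span <- 450 - prof$midpoint_min[length(prof$midpoint_min) - fit$n_points + 1]
  expect_gte(span + 1e-9, 2 * log(2) / k@kElim)
  expect_equal(fit$lambda_z, k@kElim, tolerance = 0.05)
})

test_that("runNCA contract: degenerate profiles, ordering, determinism", {
  single <- data.frame(animal_id = "p1", compartment = "liver",
                       midpoint_min = 15, conc_ug_per_ml = 4, censored = 0L)
  r <- runNCA(single)
  expect_equal(r$auc0last_min_ugml, 4 * 15 / 2)  # leading segment only
  expect_false(r$t_half_estimable)
  # permuting rows leaves all outputs unchanged
  st <- fixCleanStudy(nAnimals = 2L)
  prof <- buildProfiles(studySamples(st),
                        calibrateRecoveries(calibrationSamples(st)))
  shuffled <- prof[sample(nrow(prof)), ]
  expect_equal(runNCA(prof), runNCA(shuffled))
})
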