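test_that("Bateman truth curve has the right shape and closed-form peak", {
  k <- fixExampleKinetics()  # A=30, ku=0.02, ke=0.005
  expect_equal(trueConcentration(k, 0), 0)
  expect_lt(trueConcentration(k, 5000), 1e-6)  # vanishes at long times
  expect_true(all(trueConcentration(k, seq(0, 2000, by = 5)) >= 0))
  # dense grid search oracle for the peak, step 0.01 min
  grid <- seq(0, 500, by = 0.01)
  cg <- trueConcentration(k, grid)
  cf <- closedFormNCA(k, 480)
  expect_equal(cf$tmax, log(0.02 / 0.005) / (0.02 - 0.005))
  expect_equal(cf$tmax, 92.4196, tolerance = 1e-4)
  expect_equal(cf$tmax, grid[which.max(cg)], tolerance = 0.01 / cf$tmax)
  expect_equal(cf$cmax, max(cg), tolerance = 1e-8)
  expect_equal(cf$half_life, 138.6294, tolerance = 1e-4)
})

test_that("equal uptake and elimination rates are rejected", {
  expect_error(tissueKinetics("x", 10, 0.01, 0.01), "kUptake > kElim")
  expect_error(tissueKinetics("x", -1, 0.02, 0.01), "amplitude")
})

test_that("closed-form AUC matches quadrature and its t->Inf limit", {
  k <- fixExampleKinetics()
  quad <- integrate(function(t) trueConcentration(k, t), 0, 480,
                    rel.tol = 1e-10)$value
  expect_equal(closedFormNCA(k, 480)$auc_0_tlast, quad, tolerance = 1e-8)
  expect_equal(closedFormNCA(k, Inf)$auc_0_tlast,
               30 * (1 / 0.005 - 1 / 0.02))
})

test_that("interval averages agree with adaptive quadrature", {
  for (k in list(fixExampleKinetics(), fixFastKinetics())) {
    iv <- intervals(fixSchedule())
    got <- intervalAverage(k, iv$start_min, iv$end_min)
    want <- vapply(seq_len(nrow(iv)), function(i)
      integrate(function(t) trueConcentration(k, t), iv$start_min[i],
                iv$end_min[i], rel.tol = 1e-12)$value /
        (iv$end_min[i] - iv$start_min[i]), numeric(1))
    expect_equal(got, want, tolerance = 1e-8)
  }
  # mean of an increasing function is below its right endpoint
  k <- fixExampleKinetics()
  expect_lt(intervalAverage(k, 0, 30), trueConcentration(k, 30))
  expect_error(intervalAverage(k, 30, 30), "degenerate")
})

test_that("noise-free dialysate series equals scaled interval averages", {
  k <- fixExampleKinetics()
  sched <- fixSchedule()
  iv <- intervals(sched)
  s100 <- simulateDialysateSeries(k, 100, sched, noiselessModel())
  expect_identical(s100$conc_ug_per_ml,
                   intervalAverage(k, iv$start_min, iv$end_min))
  expect_true(all(s100$below_loq == 0L))
  s50 <- simulateDialysateSeries(k, 50, sched, noiselessModel())
  expect_identical(s50$conc_ug_per_ml, s100$conc_ug_per_ml / 2)
  expect_equal(s100$midpoint_min, midpoints(sched))
})

test_that("censoring flags appear iff the measured value is below LOQ", {
  # tiny amplitude drives late/early samples under the 0.100 ug/mL LOQ
  k <- tissueKinetics("tiny", 0.3, 0.02, 0.005)
  s <- simulateDialysateSeries(k, 100, fixSchedule(), noiselessModel())
  iv <- intervals(fixSchedule())
  truth <- intervalAverage(k, iv$start_min, iv$end_min)
  expect_identical(s$below_loq, as.integer(truth < 0.1))
  expect_gt(sum(s$below_loq), 0)
  # censored rows carry the LOQ marker, not the underlying value
  expect_true(all(s$conc_ug_per_ml[s$below_loq == 1] == 0.1))
})

test_that("failed catheters yield no samples and RR bounds are enforced", {
  k <- fixExampleKinetics()
  expect_equal(nrow(simulateDialysateSeries(k, 90, fixSchedule(),
                                            status = "malfunction")), 0L)
  expect_error(simulateDialysateSeries(k, 0, fixSchedule()), "RR")
  expect_error(simulateDialysateSeries(k, 101, fixSchedule()), "RR")
})

test_that("retrodialysis inverts the recovery equation", {
  p <- simulateRetrodialysisPair(89.5, 100, noiselessModel())
  expect_equal(p$dialysate_conc_ug_per_ml, c(10.5, 10.5))
  p100 <- simulateRetrodialysisPair(100, 100, noiselessModel())
  expect_equal(p100$dialysate_conc_ug_per_ml, c(0, 0))
  # round trip: calibration recovers the true RR exactly when noise is off
  for (rr in c(1, 25.5, 50, 75.3, 89.5, 100)) {
    pp <- simulateRetrodialysisPair(rr, 100, noiselessModel())
    got <- catheterRecovery(pp$dialysate_conc_ug_per_ml[1],
                            pp$dialysate_conc_ug_per_ml[2], 100)
    expect_equal(got$rr_percent, rr, tolerance = 1e-12)
    expect_true(got$valid)
  }
})

test_that("assay CV interpolates the precision ladder in log10 scale", {
  nm <- defaultNoiseModel()
  expect_equal(assayCV(nm, c(0.1, 1, 4, 30, 100)),
               c(20.8, 11.1, 9.7, 3.5, 6.8) / 100)
  # clamped outside the ladder
  expect_equal(assayCV(nm, 0.01), 0.208)
  expect_equal(assayCV(nm, 1000), 0.068)
  # between 1 and 4 ug/mL, interpolation in log10(conc)
  w <- (log10(2) - log10(1)) / (log10(4) - log10(1))
  expect_equal(assayCV(nm, 2), (11.1 * (1 - w) + 9.7 * w) / 100)
})

test_that("default study has the designed sample accounting", {
  cfg <- fixCleanConfig(nAnimals = 8L)
  st <- simulateStudy(cfg)  # dropout probabilities zero
  e <- ledgerEntries(st)
  expect_equal(nrow(e), 64L)
  expect_true(all(e$status == "ok"))
  s <- studySamples(st)
  expect_equal(sum(s$sample_type == "dialysate"), 64L * 12L)
  expect_equal(sum(s$sample_type == "plasma"), 8L * 12L)
  expect_equal(nrow(calibrationSamples(st)), 64L * 2L)
  expect_true(all(s$conc_ug_per_ml >= 0))
})

test_that("the truth record and seed reproduce the dataset exactly", {
  cfg <- defaultStudyConfig(seed = 42L)
  a <- simulateStudy(cfg)
  b <- simulateStudy(cfg)
  expect_identical(studySamples(a), studySamples(b))
  expect_identical(calibrationSamples(a), calibrationSamples(b))
  expect_identical(studyTruth(a)@catheterStates,
                   studyTruth(b)@catheterStates)
  # a different seed changes the data
  c <- simulateStudy(defaultStudyConfig(seed = 43L))
  expect_false(identical(studySamples(a), studySamples(c)))
})

test_that("default kinetics hit the reported Cmax/Tmax envelope", {
  kin <- defaultKinetics()
  cf <- lapply(kin, closedFormNCA, tLast = 450)
  cmax <- vapply(cf, `[[`, numeric(1), "cmax")
  tmax <- vapply(cf, `[[`, numeric(1), "tmax")
  solid <- setdiff(names(kin), "plasma")
  expect_true(all(cmax[solid] >= 10 & cmax[solid] <= 26))
  expect_true(all(tmax[solid] >= 105 & tmax[solid] <= 206))
  # peaks after the 90-min perfusion, plasma earliest
  expect_true(all(tmax > 90))
  expect_equal(unname(which.min(tmax)), which(names(kin) == "plasma"))
  # drug remains well quantifiable (and declining) at the 450-min sample
  c450 <- vapply(kin[solid], trueConcentration, numeric(1), tMin = 450)
  expect_true(all(c450 > 1 & c450 < cmax[solid]))
})
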