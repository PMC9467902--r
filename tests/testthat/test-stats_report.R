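makeNca <- function(values, animals = paste0("p", seq_len(nrow(values)))) {
  # values: matrix animals x compartments of AUCs; Cmax/Tmax filled in
  do.call(rbind, lapply(seq_len(nrow(values)), function(i)
    data.frame(animal_id = animals[i], compartment = colnames(values),
               cmax_ugml = 1, tmax_min = 100,
               auc0last_min_ugml = values[i, ],
               lambda_z_per_min = NA, t_half_min = NA,
               n_lambda_points = NA, lambda_adj_r2 = NA,
               t_half_estimable = FALSE)))
}

test_that("compartment summaries reproduce the hand-computed t-interval", {
  v <- matrix(c(1, 2, 3), ncol = 1, dimnames = list(NULL, "liver"))
  s <- summarizeByCompartment(makeNca(v))
  expect_equal(s$auc_mean, 2)
  half <- qt(0.975, 2) * sd(c(1, 2, 3)) / sqrt(3)
  expect_equal(s$auc_lo, 2 - half)
  expect_equal(s$auc_hi, 2 + half)
  expect_equal(round(c(s$auc_lo, s$auc_hi), 2), c(-0.48, 4.48))
  # zero variance gives a zero-width CI; n = 1 gives no CI
  v2 <- cbind(liver = c(5, 5), plasma = c(7, 7))
  s2 <- summarizeByCompartment(makeNca(v2))
  expect_equal(s2$auc_lo, s2$auc_hi)
  one <- summarizeByCompartment(makeNca(cbind(liver = 4)))
  expect_true(is.na(one$auc_lo))
  expect_error(summarizeByCompartment(makeNca(v)[0, ]), "empty")
})

test_that("summaries are invariant to animal order and group-independent", {
  set.seed(31)
  v <- matrix(rlnorm(24, 8), nrow = 8,
              dimnames = list(NULL, c("liver", "plasma", "mesentery")))
  nca <- makeNca(v)
  expect_equal(summarizeByCompartment(nca[sample(nrow(nca)), ]),
               summarizeByCompartment(nca))
  # dropping an animal only changes n, never other compartments' rows
  drop1 <- nca[!(nca$animal_id == "p1" & nca$compartment == "liver"), ]
  s <- summarizeByCompartment(nca); sd1 <- summarizeByCompartment(drop1)
  expect_equal(sd1[sd1$compartment != "liver", ],
               s[s$compartment != "liver", ])
  expect_equal(sd1$n[sd1$compartment == "liver"], 7L)
})

test_that("balanced two-compartment mixed model equals the paired t-test", {
  # a real between-animal effect keeps the variance estimate interior, where
  # the compound-symmetry F equals the squared paired t exactly
  set.seed(32)
  ai <- rnorm(8, 0, 2)
  v <- cbind(liver = 10 + ai + rnorm(8, 0, 0.5),
             plasma = 9.6 + ai + rnorm(8, 0, 0.5))
  cmp <- mixedModelCompare(makeNca(v), "auc")
  pt <- t.test(v[, "liver"] - v[, "plasma"])
  expect_equal(cmp$overall$df2, 7)
  expect_equal(cmp$overall$f_statistic, unname(pt$statistic)^2,
               tolerance = 1e-6)
  expect_equal(cmp$overall$p_value, pt$p.value, tolerance = 1e-6)
  expect_equal(cmp$pairwise$p_value, pt$p.value)
  expect_equal(cmp$pairwise$t_statistic, unname(pt$statistic))
})

test_that("identical per-animal values give t = 0, p = 1", {
  v <- cbind(liver = c(3, 5, 9, 4), plasma = c(3, 5, 9, 4))
  cmp <- mixedModelCompare(makeNca(v), "auc")
  expect_equal(cmp$pairwise$t_statistic, 0)
  expect_equal(cmp$pairwise$p_value, 1)
  expect_false(cmp$pairwise$significant)
})

test_that("a shifted compartment is detected by the pairwise tests", {
  set.seed(33)
  v <- matrix(rlnorm(32, meanlog = 8, sdlog = 0.1), nrow = 8,
              dimnames = list(NULL, c("liver", "plasma", "mesentery",
                                      "peritoneum")))
  v[, "peritoneum"] <- v[, "peritoneum"] * 1.5
  cmp <- mixedModelCompare(makeNca(v), "auc")
  expect_true(cmp$overall$significant)
  pw <- cmp$pairwise
  hits <- pw[pw$compartment_a == "peritoneum" |
             pw$compartment_b == "peritoneum", ]
  expect_true(all(hits$significant))
})

test_that("replication requirements are enforced with messages", {
  v <- cbind(liver = c(1, 2), plasma = c(2, 3))
  expect_error(mixedModelCompare(makeNca(v), "auc"), "3 animals")
  v2 <- cbind(liver = 1:4)
  expect_error(mixedModelCompare(makeNca(v2), "auc"), "2 compartments")
  expect_error(mixedModelCompare(makeNca(cbind(liver = 1:4,
                                               plasma = 2:5)), "nope"),
               "unknown parameter")
})

test_that("report files are complete, deterministic and re-readable", {
  res <- runStudyPipeline(defaultStudyConfig(seed = 5L))
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  writeReport(res$nca, res$profiles, d1)
  writeReport(res$nca, res$profiles, d2)
  for (f in c("summary.csv", "comparisons.csv", "mean_profiles.csv")) {
    expect_true(file.exists(file.path(d1, f)))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
  summ <- read.csv(file.path(d1, "summary.csv"))
  expect_equal(nrow(summ), 9L)  # 8 solid tissues + plasma
  expect_true(all(summ$auc_lo <= summ$auc_mean &
                  summ$auc_mean <= summ$auc_hi, na.rm = TRUE))
  expect_error(writeReport(res$nca[0, ], res$profiles,
                           withr::local_tempdir()), "empty")
})

test_that("config round-trips through JSON", {
  cfg <- defaultStudyConfig(nAnimals = 4L, seed = 9L, loqUgPerMl = 0.2)
  path <- withr::local_tempfile(fileext = ".json")
  writeStudyConfig(cfg, path)
  back <- readStudyConfig(path)
  for (s in slotNames(cfg)) expect_equal(slot(back, s), slot(cfg, s))
})
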