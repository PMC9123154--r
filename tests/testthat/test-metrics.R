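test_that("confusion counts match hand enumeration", {
  g <- array(0, c(1, 10, 10)); g[1, 1:5, 1:6] <- 1       # 30 fg
  s <- g
  cc <- confusionCounts(BinaryMask(s), BinaryMask(g))
  expect_equal(c(cc@TP, cc@TN, cc@FP, cc@FN), c(30, 70, 0, 0))
  inv <- confusionCounts(BinaryMask(1 - g), BinaryMask(g))
  expect_equal(c(inv@TP, inv@TN), c(0, 0))
  expect_equal(c(inv@FP, inv@FN), c(70, 30))
  # constructed overlap: flip 10 assignments and count by hand
  s2 <- g
  s2[1, 1, 1:5] <- 0    # 5 fg pixels dropped  -> FN
  s2[1, 9:10, 9] <- 1   # 2 bg pixels added    -> FP
  s2[1, 10, 1:3] <- 1   # 3 more               -> FP
  cc2 <- confusionCounts(BinaryMask(s2), BinaryMask(g))
  expect_equal(c(cc2@TP, cc2@FP, cc2@TN, cc2@FN), c(25, 5, 65, 5))
  expect_error(confusionCounts(matrix(1, 2, 2), matrix(1, 3, 3)), "mismatch")
})

test_that("the metric suite reproduces its defining ratios", {
  r <- computeMetrics(new("ConfusionCounts", TP = 90, FP = 10, TN = 890,
                          FN = 10))
  expect_equal(r@values[["Acc"]], 0.98, tolerance = 1e-12)
  expect_equal(r@values[["Se"]], 0.9, tolerance = 1e-12)
  expect_equal(r@values[["Sp"]], 890 / 900, tolerance = 1e-12)
  expect_equal(r@values[["P"]], 0.9, tolerance = 1e-12)
  expect_equal(r@values[["ER"]], 0.02, tolerance = 1e-12)
  expect_equal(r@values[["Vs"]], 1.0, tolerance = 1e-12)
  expect_equal(r@values[["DSC"]], 90, tolerance = 1e-12)
  expect_equal(r@values[["JC"]], 900 / 11, tolerance = 1e-12)
  # perfect segmentation
  p <- computeMetrics(new("ConfusionCounts", TP = 40, FP = 0, TN = 60,
                          FN = 0))
  expect_equal(unname(p@values[c("Acc", "Se", "Sp", "P", "Vs")]),
               rep(1, 5))
  expect_equal(p@values[["ER"]], 0)
  expect_equal(unname(p@values[c("DSC", "JC")]), c(100, 100))
  # 0/0 ratios come back as 0 with a degenerate flag, not an error
  z <- computeMetrics(new("ConfusionCounts", TP = 0, FP = 0, TN = 10,
                          FN = 0))
  expect_equal(z@values[["P"]], 0)
  expect_true(all(c("P", "Se", "Vs") %in% z@flags))
})

test_that("metric identities hold on 1000 random confusion tables", {
  set.seed(16)
  for (i in 1:1000) {
    cnt <- as.numeric(rmultinom(1, size = sample(10:500, 1),
                                prob = runif(4, 0.05, 1)))
    cc <- new("ConfusionCounts", TP = cnt[1], FP = cnt[2], TN = cnt[3],
              FN = cnt[4])
    v <- computeMetrics(cc)@values
    expect_equal(v[["Acc"]] + v[["ER"]], 1, tolerance = 1e-12)
    expect_gte(v[["DSC"]], v[["JC"]])
    if (v[["DSC"]] > 1e-9 && v[["DSC"]] < 100 - 1e-9)
      expect_gt(v[["DSC"]], v[["JC"]])
    # independent recomputation straight from the ratio definitions
    TP <- cnt[1]; FP <- cnt[2]; TN <- cnt[3]; FN <- cnt[4]
    tot <- sum(cnt)
    expect_equal(v[["Acc"]], (TP + TN) / tot, tolerance = 1e-12)
    if (TP + FN > 0) expect_equal(v[["Se"]], TP / (TP + FN), tolerance = 1e-12)
    if (TN + FP > 0) expect_equal(v[["Sp"]], TN / (TN + FP), tolerance = 1e-12)
    if (TP + FP > 0) expect_equal(v[["P"]], TP / (TP + FP), tolerance = 1e-12)
    if (2 * TP + FP + FN > 0) {
      expect_equal(v[["Vs"]], 1 - abs(FN - FP) / (2 * TP + FP + FN),
                   tolerance = 1e-12)
      expect_equal(v[["DSC"]], 200 * TP / (2 * TP + FP + FN),
                   tolerance = 1e-12)
      expect_equal(v[["JC"]], 100 * TP / (TP + FP + FN), tolerance = 1e-12)
    }
  }
})

test_that("ROC AUC: perfect, chance and constant scores", {
  g <- array(rep(c(0, 1), 50), c(1, 10, 10))
  expect_equal(rocAuc(g, g), 1)
  expect_equal(rocAuc(array(0.5, c(1, 10, 10)), g), 0.5)
  set.seed(17)
  gBig <- array(rbinom(1e4, 1, 0.4), c(1, 100, 100))
  sc <- array(runif(1e4), c(1, 100, 100))
  a <- rocAuc(sc, gBig)
  expect_gt(a, 0.48); expect_lt(a, 0.52)
  expect_error(rocAuc(sc, array(1, c(1, 100, 100))), "both classes")
})

test_that("AUC is (approximately) invariant under monotone transforms", {
  set.seed(18)
  g <- array(rbinom(2500, 1, 0.3), c(1, 50, 50))
  sc <- array(pmin(pmax(runif(2500) + 0.3 * g, 0), 1), c(1, 50, 50))
  a1 <- rocAuc(sc, g)
  a2 <- rocAuc(sc^2, g)
  a3 <- rocAuc(sqrt(sc), g)
  expect_lt(abs(a1 - a2), 0.01)
  expect_lt(abs(a1 - a3), 0.01)
})

test_that("AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  set.seed(19)
  g <- array(rbinom(2500, 1, 0.3), c(1, 50, 50))
  sc <- array(pmin(pmax(runif(2500) + 0.4 * g, 0), 1), c(1, 50, 50))
  ref <- as.numeric(pROC::auc(pROC::roc(as.numeric(g), as.numeric(sc),
                                        quiet = TRUE)))
  expect_equal(rocAuc(sc, g), ref, tolerance = 0.01)
})

test_that("PSNR closed forms", {
  v <- VolumeImage(array(100, c(1, 4, 4)))
  expect_equal(psnr(v, v), Inf)
  shifted <- VolumeImage(volData(v) + 1)       # MSE = 1
  expect_equal(psnr(v, shifted), 20 * log10(255), tolerance = 1e-9)
  expect_equal(psnr(v, shifted), 48.1308, tolerance = 1e-4)
  # doubling the MSE costs 10*log10(2) dB
  s2 <- VolumeImage(volData(v) + sqrt(2))
  expect_equal(psnr(v, shifted) - psnr(v, s2), 10 * log10(2),
               tolerance = 1e-9)
  expect_error(psnr(v, VolumeImage(array(0, c(1, 2, 2)))), "mismatch")
})

test_that("metric tables carry the standard report column layout", {
  r <- computeMetrics(new("ConfusionCounts", TP = 90, FP = 10, TN = 890,
                          FN = 10))
  tab <- metricsTable(list(case1 = r), auc = 0.97, psnr = 32.5)
  expect_identical(names(tab),
                   c("Acc", "Se", "Sp", "P", "ER", "Vs", "DSC", "JC",
                     "AUC", "PSNR"))
  f <- tempfile(fileext = ".csv")
  writeMetricsReport(tab, csv = f)
  back <- read.csv(f)
  expect_equal(back$DSC, 90)
  expect_equal(back$AUC, 0.97)
})
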