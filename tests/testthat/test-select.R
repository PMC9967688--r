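# Two-regime feature selection: calibration, oracles, invariances.

test_that("row-wise t and F statistics match stats::t.test and stats::aov", {
  set.seed(20)
  fs <- gaussianFeatures(6, 10)
  v <- featureValues(fs)
  cond <- observationLabels(fs)$condition
  a <- v[, cond == "excited"]; b <- v[, cond == "relaxed"]
  pMine <- EmoConn:::rowTTestP(a, b)
  for (i in 1:6) {
    ref <- t.test(a[i, ], b[i, ], var.equal = TRUE)$p.value
    expect_equal(unname(pMine[i]), ref, tolerance = 1e-12)
  }
  pA <- EmoConn:::rowAnovaP(v, cond)
  for (i in 1:6) {
    ref <- summary(aov(v[i, ] ~ factor(cond)))[[1]][["Pr(>F)"]][1]
    expect_equal(unname(pA[i]), ref, tolerance = 1e-10)
  }
})

test_that("phase-2 ANOVA retention is calibrated at alpha under the null", {
  fs <- gaussianFeatures(10000, 20, seed = 21)
  ph2 <- phase2Anova(fs, alpha = 0.01)
  rate <- mean(ph2$mask)
  # 3-sigma binomial band around 0.01 with 10000 trials
  expect_gt(rate, 0.01 - 3 * sqrt(0.01 * 0.99 / 10000))
  expect_lt(rate, 0.01 + 3 * sqrt(0.01 * 0.99 / 10000))
})

test_that("phase-2 ANOVA keeps any real group difference", {
  shifts <- list(
    msc.alpha.f1 = c(distressed = 2, excited = 0, depressed = 0,
                     relaxed = 0, neutral = 0),
    msc.alpha.f2 = c(distressed = 1, excited = 1, depressed = 0,
                     relaxed = 0, neutral = 0))
  fs <- gaussianFeatures(5, 300, shifts = shifts, seed = 22)
  ph2 <- phase2Anova(fs, alpha = 0.01)
  expect_true(all(ph2$mask[c("msc.alpha.f1", "msc.alpha.f2")]))
})

test_that("phase-1 baseline testing uses the all-conditions intersection", {
  conds <- c("distressed", "excited", "depressed", "relaxed", "neutral")
  allShift <- c(distressed = 1, excited = 1, depressed = 1, relaxed = 1,
                neutral = 0)
  oneShift <- c(distressed = 0, excited = 1, depressed = 0, relaxed = 0,
                neutral = 0)
  emo <- gaussianFeatures(200, 100, shifts = list(
    msc.alpha.f1 = allShift, msc.alpha.f2 = oneShift), seed = 23)
  bas <- gaussianFeatures(200, 100, seed = 24)   # baseline: no shifts
  ph1 <- phase1BaselineTtest(emo, bas)
  expect_true(ph1$mask[["msc.alpha.f1"]])     # shifted in all four
  expect_false(ph1$mask[["msc.alpha.f2"]])    # shifted only for excited
  # null columns essentially never survive four independent tests
  expect_lt(mean(ph1$mask[-(1:2)]), 0.005)
  expect_equal(ncol(ph1$p), 4L)               # neutral excluded
  expect_false("neutral" %in% colnames(ph1$p))
})

test_that("zero-variance columns are dropped and logged, not NaN", {
  fs <- gaussianFeatures(4, 20, seed = 25)
  v <- featureValues(fs)
  v[1, ] <- 7                      # constant everywhere
  fs0 <- FeatureSet(v, featureInfo(fs), observationLabels(fs))
  ph2 <- phase2Anova(fs0)
  expect_false(ph2$mask[[1]])
  expect_equal(ph2$dropped, rownames(v)[1])
  sel <- runSelection(fs0, mode = "non_normalized", alphaPhase2 = 0.9)
  expect_false(rownames(v)[1] %in% retainedFeatures(sel$result))
})

test_that("selection ignores row order (permutation invariance)", {
  shifts <- list(f3 = c(distressed = 1.5, excited = 0.5, depressed = 0,
                        relaxed = 1, neutral = 0))
  fs <- gaussianFeatures(50, 40, shifts = shifts, seed = 26, prefix = "f")
  names(shifts) <- "f3"
  sel1 <- runSelection(fs, mode = "non_normalized")
  perm <- sample(ncol(fs))
  sel2 <- runSelection(fs[, perm], mode = "non_normalized")
  expect_setequal(retainedFeatures(sel1$result),
                  retainedFeatures(sel2$result))
})

test_that("the ANOVA-only regime usually retains a superset", {
  superset <- vapply(1:30, function(s) {
    shifts <- list(
      a1 = c(distressed = 1, excited = 0.8, depressed = 0.6,
             relaxed = 0.4, neutral = 0),
      a2 = c(distressed = 0.8, excited = 0, depressed = 0, relaxed = 0,
             neutral = 0))
    emo <- gaussianFeatures(30, 60, shifts = shifts, seed = 100 + s,
                            prefix = "a")
    bas <- gaussianFeatures(30, 60, seed = 200 + s, prefix = "a")
    nn <- tryCatch(retainedFeatures(
      runSelection(emo, mode = "non_normalized")$result),
      error = function(e) character(0))
    no <- tryCatch(retainedFeatures(
      runSelection(emo, bas, mode = "normalized")$result),
      error = function(e) character(0))
    all(no %in% nn)
  }, logical(1))
  expect_gte(mean(superset), 0.95)
})

test_that("normalized mode needs baselines and nonzero survivors error", {
  fs <- gaussianFeatures(10, 10, seed = 27)
  expect_error(runSelection(fs, mode = "normalized"), "baseline")
  # pure-null features at a tiny alpha -> nothing retained -> error
  expect_error(runSelection(fs, mode = "non_normalized",
                            alphaPhase2 = 1e-12),
               "zero features retained")
})

test_that("count summaries have the bands-plus-total table layout", {
  shifts <- list(f1 = c(distressed = 2, excited = 2, depressed = 2,
                        relaxed = 2, neutral = 0))  # prefix 'f' below
  emo <- gaussianFeatures(20, 50, shifts = shifts, seed = 28, prefix = "f")
  bas <- gaussianFeatures(20, 50, seed = 29, prefix = "f")
  sel <- runSelection(emo, bas, mode = "normalized")
  cs <- countSummary(sel$result)
  expect_equal(colnames(cs), c("alpha", "total"))
  expect_equal(rownames(cs), c("input", "phase1", "retained"))
  expect_equal(cs["input", "total"], 20)
  expect_true(cs["retained", "total"] <= cs["phase1", "total"])

  tab <- featureCountTable(list(sel$result))
  expect_true(all(c("family", "mode", "phase") %in% colnames(tab)))
})

test_that("paired phase-1 testing and baseline subtraction are available", {
  allShift <- c(distressed = 1, excited = 1, depressed = 1, relaxed = 1,
                neutral = 0)
  emo <- gaussianFeatures(20, 80, shifts = list(msc.alpha.f1 = allShift),
                          seed = 33)
  bas <- gaussianFeatures(20, 80, seed = 34)
  # paired variant matches stats::t.test(paired = TRUE)
  ve <- featureValues(emo); vb <- featureValues(bas)
  cond <- observationLabels(emo)$condition
  cols <- which(cond == "excited")
  pp <- EmoConn:::rowPairedTTestP(ve[, cols], vb[, cols])
  ref <- t.test(ve[3, cols], vb[3, cols], paired = TRUE)$p.value
  expect_equal(unname(pp[3]), ref, tolerance = 1e-12)
  ph1 <- phase1BaselineTtest(emo, bas, paired = TRUE)
  expect_true(ph1$mask[["msc.alpha.f1"]])

  # subtract-baseline transform changes the tested values
  selDiff <- runSelection(emo, bas, mode = "non_normalized",
                          subtractBaseline = TRUE, alphaPhase2 = 0.05)
  expect_true("msc.alpha.f1" %in% retainedFeatures(selDiff$result))
  expect_error(runSelection(emo, mode = "non_normalized",
                            subtractBaseline = TRUE), "baseline")
})
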