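# Label schemes and one-vs-one SVM cross-validation.

test_that("label schemes map conditions onto affective-space classes", {
  expect_equal(as.character(makeLabels("excited", labelScheme("arousal"))),
               "high")
  expect_equal(as.character(makeLabels("excited", labelScheme("valence"))),
               "positive")
  expect_equal(as.character(makeLabels("distressed",
                                       labelScheme("valence"))),
               "negative")
  for (sc in c("arousal", "valence", "emotion"))
    expect_equal(as.character(makeLabels("neutral", labelScheme(sc))),
                 "neutral")
  conds <- rep(c("distressed", "excited", "depressed", "relaxed",
                 "neutral"), each = 4)
  lab <- makeLabels(conds, "arousal")
  expect_equal(unname(table(lab)[c("high", "low", "neutral")]),
               c(8L, 8L, 4L), ignore_attr = TRUE)
  expect_equal(levels(lab), c("high", "low", "neutral"))
  expect_error(makeLabels("bored", "arousal"), "unknown")
})

makeClusters <- function(nPer = 30, sep = 8, seed = 40, p = 6) {
  set.seed(seed)
  conds <- c("distressed", "excited", "depressed", "relaxed", "neutral")
  centers <- matrix(rnorm(5 * p), 5, p) * sep
  X <- do.call(rbind, lapply(1:5, function(i)
    sweep(matrix(rnorm(nPer * p), nPer, p), 2, centers[i, ], "+")))
  vals <- t(X)
  rownames(vals) <- paste0("msc.alpha.f", seq_len(p))
  FeatureSet(vals,
             data.frame(family = "msc", band = "alpha")[rep(1, p), ],
             data.frame(condition = rep(conds, each = nPer),
                        participant = 1L, session = 1L,
                        trial = seq_len(5 * nPer)))
}

test_that("well-separated clusters are classified nearly perfectly", {
  fs <- makeClusters()
  rep5 <- crossValidate(fs, scheme = "emotion", k = 5, seed = 1)
  expect_equal(rep5@nPairwise, 10L)           # C(5,2) binary machines
  expect_gt(testAccuracy(rep5), 98)
  expect_gt(trainAccuracy(rep5), 98)
  cm <- confusionMatrix(rep5)
  expect_equal(rownames(cm), labelScheme("emotion")$classOrder)
  expect_equal(unname(rowSums(cm)), rep(100, 5), tolerance = 1e-9)
  expect_gt(min(diag(cm)), 95)

  rep3 <- crossValidate(fs, scheme = "arousal", k = 5, seed = 1)
  expect_equal(rep3@nPairwise, 3L)            # C(3,2)
  expect_equal(rownames(confusionMatrix(rep3)),
               c("high", "low", "neutral"))
})

test_that("permuted labels give chance-level accuracy", {
  fs <- makeClusters(nPer = 60, seed = 41)
  set.seed(42)
  lab <- sample(makeLabels(observationLabels(fs)$condition, "arousal"))
  rep0 <- crossValidate(fs, labels = lab, scheme = "arousal", k = 5,
                        seed = 2)
  # 3 classes in 2:2:1 proportions: majority-class chance is 40 %;
  # accept the binomial band around [33, 40] at n = 300
  expect_gt(testAccuracy(rep0), 25)
  expect_lt(testAccuracy(rep0), 50)
})

test_that("cross-validation is deterministic given the seed", {
  fs <- makeClusters(nPer = 20, sep = 1.5, seed = 43)
  r1 <- crossValidate(fs, scheme = "emotion", k = 5, seed = 7)
  r2 <- crossValidate(fs, scheme = "emotion", k = 5, seed = 7)
  expect_identical(r1@foldTest, r2@foldTest)
  expect_identical(r1@confusionCounts, r2@confusionCounts)
  r3 <- crossValidate(fs, scheme = "emotion", k = 5, seed = 8)
  expect_false(identical(r1@foldTest, r3@foldTest))
})

test_that("folds partition the observations exactly", {
  fs <- makeClusters(nPer = 21, seed = 44)   # 105 rows, k = 5
  rep5 <- crossValidate(fs, scheme = "emotion", k = 5, seed = 3)
  expect_equal(length(rep5@foldTest), 5L)
  expect_equal(sum(rep5@confusionCounts), 105)
})

test_that("a class missing from training errors with stratify advice", {
  fs <- makeClusters(nPer = 12, seed = 45)
  # a single 'neutral' observation can never reach every training fold
  fsSub <- fs[, c(1:48, 49)]
  expect_error(crossValidate(fsSub, scheme = "emotion", k = 4, seed = 4),
               "stratify")
  # a small class (6 obs, k = 4) is guaranteed spread by stratification
  fsSmall <- fs[, c(1:48, 49:54)]
  repS <- crossValidate(fsSmall, scheme = "emotion", k = 4, seed = 4,
                        stratify = TRUE)
  expect_s4_class(repS, "CVReport")
  expect_equal(sum(repS@confusionCounts), 54)
})

test_that("accuracy tables report mean and sd per run", {
  fs <- makeClusters(nPer = 15, seed = 46)
  reps <- list(emo = crossValidate(fs, scheme = "emotion", seed = 5))
  at <- accuracyTable(reps)
  expect_equal(at$run, "emo")
  expect_equal(at$testMean, testAccuracy(reps$emo))
  expect_true(is.finite(at$testSd))
})

test_that("leave-one-group-out folds follow the grouping vector", {
  fs <- makeClusters(nPer = 24, seed = 47)
  groups <- rep(rep(1:4, each = 6), 5)   # 4 pseudo-participants
  rep4 <- crossValidate(fs, scheme = "emotion", seed = 6,
                        groupBy = groups)
  expect_equal(rep4@k, 4L)
  expect_equal(sum(rep4@confusionCounts), 120)
})

test_that("a cost grid picks one candidate per fold deterministically", {
  fs <- makeClusters(nPer = 20, sep = 2, seed = 48)
  r1 <- crossValidate(fs, scheme = "arousal", seed = 9,
                      cost = c(0.1, 1, 10))
  r2 <- crossValidate(fs, scheme = "arousal", seed = 9,
                      cost = c(0.1, 1, 10))
  expect_identical(r1@foldTest, r2@foldTest)
  expect_s4_class(r1, "CVReport")
})

test_that("confusion heatmaps render to file", {
  fs <- makeClusters(nPer = 10, seed = 49)
  rep5 <- crossValidate(fs, scheme = "emotion", k = 2, seed = 10)
  png <- file.path(tempdir(), "conf.png")
  m <- plotConfusion(rep5, file = png)
  expect_true(file.exists(png))
  expect_equal(dim(m), c(5L, 5L))
})
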