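# Pairwise Granger causality: nested AR fits, decision rules, features.

test_that("fitArPair matches lm on both nested models", {
  set.seed(10)
  n <- 200; p <- 3
  x <- rnorm(n)
  y <- filter(rnorm(n) + 0.4 * c(0, head(x, -1)), 0.3, "recursive")
  y <- as.numeric(y)
  fit <- fitArPair(y, x, p)
  idx <- (p + 1):n
  lagm <- function(v) sapply(1:p, function(k) v[idx - k])
  lmR <- lm.fit(lagm(y), y[idx])
  lmF <- lm.fit(cbind(lagm(y), lagm(x)), y[idx])
  expect_equal(fit@coefRestricted, unname(lmR$coefficients),
               tolerance = 1e-10)
  expect_equal(fit@coefFull, unname(lmF$coefficients), tolerance = 1e-10)
  expect_equal(fit@rssRestricted, sum(lmR$residuals^2), tolerance = 1e-10)
  expect_equal(fit@rssFull, sum(lmF$residuals^2), tolerance = 1e-10)
  expect_equal(fit@varFull,
               sum(lmF$residuals^2) / (length(idx) - 2 * p),
               tolerance = 1e-10)
})

test_that("independent white noise: adjusted rule ~ half, raw rule ~ always", {
  set.seed(11)
  bits <- t(replicate(300, {
    f <- fitArPair(rnorm(400), rnorm(400), 5)
    c(adj = grangerBinary(f, "dof_adjusted"),
      raw = grangerBinary(f, "raw"),
      ftest = grangerBinary(f, "ftest"))
  }))
  expect_gt(mean(bits[, "adj"]), 0.30)
  expect_lt(mean(bits[, "adj"]), 0.55)
  expect_gt(mean(bits[, "raw"]), 0.95)   # in-sample comparison degenerates
  expect_lt(mean(bits[, "ftest"]), 0.12)
})

test_that("a planted lagged coupling is detected almost surely", {
  set.seed(12)
  hits <- replicate(60, {
    x <- rnorm(1500)
    y <- 0.5 * c(0, head(x, -1)) + rnorm(1500)
    f <- fitArPair(y, x, 5)
    grangerBinary(f, "dof_adjusted") == 1L && f@varFull < f@varRestricted
  })
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate sources are flagged and give no causality", {
  y <- rnorm(100)
  f <- fitArPair(y, numeric(100), 5)
  expect_true(f@rankDeficient)
  expect_equal(f@varFull, f@varRestricted)
  for (rule in c("dof_adjusted", "ftest", "raw"))
    expect_equal(grangerBinary(f, rule), 0L)
})

test_that("the batched all-pairs path equals per-pair nested fits", {
  set.seed(13)
  W <- matrix(rnorm(400 * 4), 400, 4)
  W[, 2] <- W[, 2] + 0.5 * c(0, 0, head(W[, 1], -2))
  for (rule in c("dof_adjusted", "ftest", "raw")) {
    bits <- EmoConn:::gcWindowBits(W, 5L, rule)
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      ref <- grangerBinary(fitArPair(W[, j], W[, i], 5), rule)
      expect_equal(bits[i, j], ref,
                   info = paste(rule, i, "->", j))
    }
  }
})

test_that("gc features have the paper layout with a zero diagonal", {
  obs <- smallObs()
  fs <- gcFeatures(obs)
  expect_equal(nrow(fs), 500L)
  expect_true(all(table(featureInfo(fs)$band) == 100L))
  nm <- rownames(fs)[featureInfo(fs)$band == "beta"]
  expect_equal(nm[1:3], c("gc.beta.r1_to_r1", "gc.beta.r1_to_r2",
                          "gc.beta.r1_to_r3"))
  expect_equal(nm[11], "gc.beta.r2_to_r1")
  v <- featureValues(fs)
  diagRows <- paste0("gc.beta.r", 1:10, "_to_r", 1:10)
  expect_true(all(v[diagRows, ] == 0))
  expect_true(all(v >= 0 & v <= 1))
})

test_that("band-filtered null pairs keep a calibrated adjusted-rule rate", {
  obs <- smallObs()
  sp <- smallSpec()
  fs <- gcFeatures(obs)
  v <- featureValues(fs)
  cond <- observationLabels(fs)$condition
  # pairs never touched by the preset: 7..10 block minus planted 7-8 pair
  nullNames <- as.vector(outer(
    bandDefinitions()$name,
    c("r9_to_r10", "r10_to_r9", "r7_to_r9", "r9_to_r7"),
    function(b, p) paste0("gc.", b, ".", p)))
  m <- mean(v[nullNames, cond == "neutral"])
  expect_gt(m, 0.25)
  expect_lt(m, 0.65)
})
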