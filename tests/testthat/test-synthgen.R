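# Synthetic-cohort generator: schedules, determinism, planted structure.

test_that("cohort schedule is balanced, complete and seeded", {
  d <- studyDesign()   # full study grid, metadata only
  sched <- generateCohort(d, syntheticSpec(d), seed = 5, metadataOnly = TRUE)
  expect_equal(nrow(sched), 2000L)
  expect_true(all(table(sched$condition) == 400L))
  expect_true(all(table(sched$participant) == 200L))
  # blocked within session: every condition equally often per session
  perSession <- table(sched$participant, sched$session, sched$condition)
  expect_true(all(perSession == 10L))
  expect_true(all(sched$seed > 0 & sched$seed < 2^31))

  d1 <- tinyDesign(trialsPerSession = 5L)
  s1 <- generateCohort(d1, syntheticSpec(d1), seed = 1, metadataOnly = TRUE)
  expect_equal(sort(s1$condition), sort(conditions(d1)))
})

test_that("schedules warn and stay near-balanced on non-divisible counts", {
  d <- tinyDesign(trialsPerSession = 7L)
  expect_warning(s <- cohortSchedule(d, seed = 2), "near-balanced")
  expect_equal(nrow(s), 7L)
  expect_true(all(table(s$condition) %in% c(1L, 2L)))
})

test_that("generation is deterministic and rejects bad inputs", {
  d <- tinyDesign()
  sp <- defaultSyntheticSpec(d)
  t1 <- generateTrial(sp, d, condition = "excited", seed = 99)
  t2 <- generateTrial(sp, d, condition = "excited", seed = 99)
  expect_identical(t1@emotionalSignal, t2@emotionalSignal)
  expect_identical(t1@baselineSignal, t2@baselineSignal)
  t3 <- generateTrial(sp, d, condition = "excited", seed = 100)
  expect_false(identical(t1@emotionalSignal, t3@emotionalSignal))

  expect_error(generateTrial(sp, d, condition = "ecstatic", seed = 1),
               "unknown condition")
  unstable <- emptyDirected()
  unstable[1, ] <- list("excited", 1L, 2L, 1L, 1.5)
  expect_error(syntheticSpec(d, directed = unstable), "unstable")
})

test_that("same seed reproduces the whole cohort bit for bit", {
  d <- tinyDesign(trialsPerSession = 3L)
  sp <- defaultSyntheticSpec(d)
  expect_warning(c1 <- generateCohort(d, sp, seed = 7), "near-balanced")
  expect_warning(c2 <- generateCohort(d, sp, seed = 7), "near-balanced")
  expect_identical(attr(c1, "schedule"), attr(c2, "schedule"))
  expect_identical(c1[[2]]@emotionalSignal, c2[[2]]@emotionalSignal)
})

test_that("band-power gains control spectral power as gain squared", {
  d <- tinyDesign(trialsPerSession = 2L, rate = 250)
  gains <- list(excited = local({
    g <- matrix(1, 5, 10, dimnames = list(bandDefinitions()$name, NULL))
    g["alpha", ] <- 1.5
    g
  }))
  sp <- syntheticSpec(d, powerGains = gains, noiseSd = 0)
  base <- generateTrial(sp, d, condition = "neutral", seed = 21)
  up <- generateTrial(sp, d, condition = "excited", seed = 21)
  pow <- function(tr) {
    w <- extractWindows(tr@emotionalSignal, 250)
    mean(rowMeans(EmoConn:::windowBandPower(w, 250, 8, 12)))
  }
  ratio <- pow(up) / pow(base)
  expect_lt(abs(ratio - 1.5^2) / 1.5^2, 0.10)
})

test_that("planted coherence strength maps monotonically onto band MSC", {
  d <- tinyDesign(trialsPerSession = 2L, rate = 250)
  mscAt <- function(s) {
    coh <- emptyCoherence()
    if (s > 0) coh[1, ] <- list("excited", "alpha", 1L, 2L, s)
    sp <- syntheticSpec(d, coherence = coh, noiseSd = 0.05)
    vals <- vapply(1:3, function(k) {
      tr <- generateTrial(sp, d, condition = "excited", seed = 30 + k)
      w <- extractWindows(bandpass(tr@emotionalSignal, 8, 12, 250), 250)
      msc(estimateSpectra(w, 250), c(1, 2), "alpha")
    }, numeric(1))
    mean(vals)
  }
  curve <- vapply(c(0, 0.3, 0.6, 0.9), mscAt, numeric(1))
  expect_true(all(diff(curve) > 0))
  # full-strength shared source drives band MSC towards its upper bound
  expect_gt(mscAt(1), 0.95)
})

test_that("directed couplings are recovered by the Granger machinery", {
  # On the raw generated signals the nested-AR fits show the planted
  # direction: the full model reduces the adjusted variance much more
  # for source -> target than for the reverse regression.
  d <- tinyDesign(trialsPerSession = 2L, rate = 500)
  dir <- emptyDirected()
  dir[1, ] <- list("excited", 3L, 4L, 2L, 0.5)
  sp <- syntheticSpec(d, directed = dir, noiseSd = 0.05)
  asym <- vapply(1:10, function(seed) {
    tr <- generateTrial(sp, d, condition = "excited", seed = seed)
    x <- tr@emotionalSignal[3, 1501:3000]
    y <- tr@emotionalSignal[4, 1501:3000]
    fwd <- fitArPair(y, x, 5)
    rev <- fitArPair(x, y, 5)
    (fwd@varRestricted / fwd@varFull) - (rev@varRestricted / rev@varFull)
  }, numeric(1))
  expect_gt(mean(asym > 0), 0.85)

  # In the band-filtered feature path the coupled pair stands out from
  # uncoupled pairs (pair-level detection; band-limited signals are too
  # predictable for their own lags to leave a clean directional trace).
  tr <- generateTrial(sp, d, condition = "excited", seed = 77)
  obs <- buildObservationSet(list(tr), includeBaseline = FALSE)
  gf <- gcFeatures(obs, rule = "ftest")
  v <- featureValues(gf)[, 1]
  coupled <- v[paste0("gc.", c("alpha", "beta", "gamma"), ".r3_to_r4")]
  nullPairs <- expand.grid(from = c(1, 2, 5, 6), to = c(1, 2, 5, 6))
  nullPairs <- nullPairs[nullPairs$from != nullPairs$to, ]
  nullNames <- as.vector(outer(c("alpha", "beta", "gamma"),
                               paste0("r", nullPairs$from, "_to_r",
                                      nullPairs$to),
                               function(b, p) paste0("gc.", b, ".", p)))
  expect_gt(mean(coupled), mean(v[nullNames]) + 0.3)
})

test_that("signals stay bounded for the shipped preset", {
  tr <- generateTrial(smallSpec(), smallDesign(), condition = "distressed",
                      seed = 4)
  expect_true(all(is.finite(tr@emotionalSignal)))
  expect_lt(max(abs(tr@emotionalSignal)), 50)
})

test_that("planted truth enumerates exactly the non-baseline parameters", {
  d <- tinyDesign()
  expect_equal(nrow(plantedTruth(syntheticSpec(d))), 0L)

  coh <- emptyCoherence()
  coh[1, ] <- list("excited", "beta", 1L, 5L, 0.8)
  one <- syntheticSpec(d, coherence = coh)
  tt <- plantedTruth(one)
  expect_equal(nrow(tt), 1L)
  expect_equal(tt$type, "coherence")
  expect_equal(truthFeatureNames(tt), "msc.beta.r1_r5")

  full <- plantedTruth(defaultSyntheticSpec(d))
  expect_setequal(unique(full$type), c("power", "coherence", "directed"))
  expect_true(all(full$condition != "neutral"))
})
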