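# Re-referencing, ROI averaging, filtering, windowing, exclusion.

test_that("re-referencing subtracts the instantaneous reference mean", {
  sig <- matrix(rnorm(5 * 100), 5, 100,
                dimnames = list(c("F3", "F4", "Cz", "T7", "T8"), NULL))
  # zero references leave the input untouched
  z <- sig; z["T7", ] <- 0; z["T8", ] <- 0
  expect_equal(rereference(z), z)
  # channels identical to the references become all-zero
  same <- matrix(rep(rnorm(100), each = 5), 5, 100,
                 dimnames = dimnames(sig))
  expect_equal(max(abs(rereference(same))), 0)
  # idempotent: re-referencing twice equals once
  once <- rereference(sig)
  expect_equal(rereference(once), once)
  expect_error(rereference(sig[1:3, ]), "T7")
})

test_that("ROI averaging takes means of available members and flags gaps", {
  mont <- defaultMontage()
  chans <- unlist(mont@rois)
  sig <- matrix(0, length(chans), 10, dimnames = list(chans, NULL))
  sig["F3", ] <- 2; sig["F7", ] <- 4; sig["FC5", ] <- 6
  out <- averageChannelsToRois(sig, mont)
  expect_equal(unname(out["roi3", ]), rep(4, 10))   # mean(2, 4, 6)
  expect_false(any(attr(out, "missingRois")))

  # single available member: ROI equals that channel exactly
  out2 <- averageChannelsToRois(sig, mont,
                                available = setdiff(chans, c("F7", "FC5")))
  expect_equal(unname(out2["roi3", ]), unname(sig["F3", ]))

  # all members of an ROI removed -> flagged missing, all-NA row
  out3 <- averageChannelsToRois(sig, mont,
                                available = setdiff(chans,
                                                    mont@rois$roi7))
  expect_true(attr(out3, "missingRois")["roi7"])
  expect_true(all(is.na(out3["roi7", ])))
  expect_error(averageChannelsToRois(sig, mont, available = character(0)),
               "no channels resolvable")
})

test_that("montage validity rejects overlaps and reference membership", {
  expect_error(new("MontageMap",
                   rois = list(a = c("F3", "F4"), b = c("F4", "C3")),
                   reference = c("T7", "T8")),
               "two ROIs")
  expect_error(new("MontageMap", rois = list(a = c("T7", "F3")),
                   reference = c("T7", "T8")),
               "reference")
})

test_that("windows cover seconds 3 to 27 in half-open 3 s steps", {
  rate <- 500
  tvals <- seq(0, 30, length.out = 30 * rate + 1)[-1]
  seg <- matrix(tvals, 1, 30 * rate, byrow = TRUE)
  w <- extractWindows(seg, rate)
  expect_equal(dim(w), c(1L, 8L, 1500L))
  # window k starts at (3 + 3k) seconds: first sample value just past it
  for (k in 0:7)
    expect_equal(w[1, k + 1, 1], 3 + 3 * k + 1 / rate, tolerance = 1e-10)
  # 27 s is exactly enough; shorter input errors
  expect_silent(extractWindows(seg[, 1:(27 * rate), drop = FALSE], rate))
  expect_error(extractWindows(seg[, 1:(26.9 * rate), drop = FALSE], rate),
               "too short")
})

test_that("zero-phase bandpass keeps in-band tones and rejects octaves", {
  rate <- 500
  t <- seq_len(6 * rate) / rate
  amp <- function(f, lo, hi) {
    y <- bandpass(sin(2 * pi * f * t), lo, hi, rate)
    mid <- y[(2 * rate):(4 * rate)]
    sqrt(2 * mean(mid^2))
  }
  expect_gt(amp(10, 8, 12), 0.95)    # alpha passes 10 Hz
  expect_lt(amp(10, 30, 45), 0.05)   # gamma rejects 10 Hz
  expect_gt(amp(20, 12, 30), 0.95)   # beta passes 20 Hz
  expect_lt(amp(6, 12, 30), 0.05)    # one octave below beta
  expect_lt(amp(60, 12, 30), 0.05)   # one octave above beta
  expect_lt(amp(2, 8, 12), 0.05)     # alpha rejects delta content
  expect_equal(bandpass(numeric(1000), 8, 12, rate), numeric(1000))
  expect_error(bandpass(rnorm(100), 12, 8, rate), "invalid band edges")
  expect_error(bandpass(rnorm(100), 0, 45, rate), "invalid band edges")
})

test_that("the five sub-bands partition the 1-45 Hz broadband content", {
  rate <- 500
  set.seed(8)
  x <- rnorm(6 * rate)
  bd <- bandDefinitions()
  parts <- lapply(seq_len(nrow(bd)), function(i)
    bandpass(x, bd$low[i], bd$high[i], rate))
  total <- Reduce(`+`, parts)
  ref <- bandpass(x, 1, 45, rate)
  mid <- (rate + 1):(5 * rate)
  relErr <- sqrt(mean((total[mid] - ref[mid])^2) / mean(ref[mid]^2))
  expect_lt(relErr, 0.15)
})

test_that("observation sets align rows, log exclusions monotonically", {
  trials <- smallTrials()
  obs <- smallObs()
  n <- length(trials)
  expect_equal(observationCount(obs), n)
  expect_equal(dim(obs@bandTensors$alpha)[3:4], c(8L, 300L))  # 100 Hz
  # emotional and baseline rows come from the same trial, same order
  info <- observationInfo(obs)
  expect_equal(info$condition,
               vapply(trials, function(x) x@condition, ""))
  expect_equal(dim(obs@baselineTensors$alpha), dim(obs@bandTensors$alpha))

  # poison one trial's ROI 2 -> that row disappears everywhere,
  # remaining rows identical to the clean build (exclusion is monotone)
  bad <- trials
  poisoned <- bad[[3]]
  poisoned@emotionalSignal[2, ] <- NA_real_
  bad[[3]] <- poisoned
  obs2 <- buildObservationSet(bad)
  expect_equal(observationCount(obs2), n - 1L)
  expect_equal(exclusionLog(obs2)$reason, "missing ROI 2")
  keep <- setdiff(seq_len(n), 3L)
  for (b in bandNames(obs))
    expect_equal(obs2@bandTensors[[b]], obs@bandTensors[[b]][keep, , , ,
                                                             drop = FALSE])

  allBad <- lapply(bad[3], identity)
  expect_error(buildObservationSet(allBad), "all trials excluded")
})

test_that("streaming synthesis matches the two-step cohort path", {
  d <- tinyDesign(trialsPerSession = 5L)
  sp <- defaultSyntheticSpec(d)
  obs1 <- buildObservationSet(generateCohort(d, sp, seed = 9L))
  obs2 <- synthesizeObservationSet(d, sp, seed = 9L)
  expect_identical(obs1@bandTensors, obs2@bandTensors)
  expect_identical(obs1@baselineTensors, obs2@baselineTensors)
  expect_equal(obs1@broadbandPower, obs2@broadbandPower)
  expect_equal(as.data.frame(observationInfo(obs1)),
               as.data.frame(observationInfo(obs2)))
})

test_that("the 32-channel mode round-trips through the real-data path", {
  tr <- smallTrials()[[2]]
  chans <- trialToChannels(tr, seed = 9)
  expect_equal(nrow(chans), 32L)
  reref <- rereference(chans)
  rois <- averageChannelsToRois(reref, defaultMontage())
  expect_false(any(attr(rois, "missingRois")))
  # recovered ROI signals track the originals closely
  for (i in c(1, 5, 10))
    expect_gt(cor(rois[i, ], tr@emotionalSignal[i, ]), 0.95)
})
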