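# Shared fixtures, built once per test run.  Unit tests run at a reduced
# sampling rate (100 Hz) so filtering and windowing stay cheap; the
# band layout is unchanged (gamma tops out at 45 Hz < Nyquist).

tinyDesign <- function(trialsPerSession = 5L, rate = 100,
                       nParticipants = 1L, nSessions = 1L) {
  studyDesign(nParticipants = nParticipants, nSessions = nSessions,
              trialsPerSession = trialsPerSession,
              samplingRate = rate, segmentDuration = 30)
}

# Memoized small synthetic cohort + observation set used by several
# feature tests (1 participant, 10 trials, 100 Hz, shipped preset).
.fixtures <- new.env()

smallObs <- function() {
  if (is.null(.fixtures$smallObs)) {
    d <- tinyDesign(trialsPerSession = 10L)
    sp <- defaultSyntheticSpec(d)
    trials <- generateCohort(d, sp, seed = 11L)
    .fixtures$smallDesign <- d
    .fixtures$smallSpec <- sp
    .fixtures$smallTrials <- trials
    .fixtures$smallObs <- buildObservationSet(trials)
  }
  .fixtures$smallObs
}

smallTrials <- function() { smallObs(); .fixtures$smallTrials }
smallSpec   <- function() { smallObs(); .fixtures$smallSpec }
smallDesign <- function() { smallObs(); .fixtures$smallDesign }

# ObservationSet assembled directly from a list of per-band tensors
# (obs x roi x win x samples), bypassing filtering -- used to feed
# exactly known signals (VAR plants, tones) to the feature extractors.
obsFromTensors <- function(tensors, rate, conditions,
                           baselineTensors = list()) {
  n <- dim(tensors[[1]])[1]
  nroi <- dim(tensors[[1]])[2]
  meta <- S4Vectors::DataFrame(
    participant = rep(1L, n), session = rep(1L, n),
    trial = seq_len(n), condition = conditions)
  bd <- bandDefinitions()[match(names(tensors), bandDefinitions()$name), ]
  new("ObservationSet",
      bandTensors = tensors, baselineTensors = baselineTensors,
      broadbandPower = matrix(1, n, nroi),
      baselineBroadbandPower = if (length(baselineTensors))
        matrix(1, n, nroi) else matrix(numeric(0), 0, nroi),
      rowData = meta,
      exclusionLog = data.frame(participant = integer(),
                                session = integer(), trial = integer(),
                                reason = character()),
      bands = bd, samplingRate = rate)
}

# Gaussian FeatureSet with optional per-condition mean shifts:
# shifts is a list of named numeric vectors, one per feature name,
# giving the mean for each condition (default 0).
gaussianFeatures <- function(nFeatures, nPerCondition,
                             conditions = c("distressed", "excited",
                                            "depressed", "relaxed",
                                            "neutral"),
                             shifts = list(), sd = 1, seed = 1,
                             prefix = "msc.alpha.f") {
  set.seed(seed)
  cond <- rep(conditions, each = nPerCondition)
  n <- length(cond)
  vals <- matrix(rnorm(nFeatures * n, sd = sd), nFeatures, n)
  rownames(vals) <- paste0(prefix, seq_len(nFeatures))
  for (nm in names(shifts)) {
    mu <- shifts[[nm]]
    vals[nm, ] <- vals[nm, ] + unname(mu[cond])
  }
  FeatureSet(vals,
             data.frame(family = "msc", band = "alpha",
                        stringsAsFactors = FALSE)[rep(1, nFeatures), ],
             data.frame(condition = cond,
                        participant = rep(1L, n), session = rep(1L, n),
                        trial = seq_len(n), stringsAsFactors = FALSE))
}
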