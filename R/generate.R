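#' @include AllClasses.R AllGenerics.R filters.R syntheticSpec.R
NULL

## One global seed expands into per-trial (and per-session-shuffle)
## seeds through a counter scheme, so trials are independent and each is
## individually reproducible.  Kept below 2^31.
deriveSeed <- function(seed, index) {
  m <- 2147483647
  s <- ((seed %% m) * 48271 + index * 104729 + 12345) %% m
  as.integer(s) + 1L
}

## Band-filter taps for one design, cached per (rate, band).
.firCache <- new.env(parent = emptyenv())
bandFilters <- function(rate) {
  key <- paste0("r", rate)
  if (is.null(.firCache[[key]])) {
    bd <- bandDefinitions()
    taps <- lapply(seq_len(nrow(bd)), function(i)
      firBandpass(bd$low[i], bd$high[i], rate))
    names(taps) <- bd$name
    bb <- broadbandEdges()
    taps$broadband <- firBandpass(bb[1], bb[2], rate)
    .firCache[[key]] <- taps
  }
  .firCache[[key]]
}

## Squared-magnitude responses of the five band filters at circular FFT
## length n (generation path: circular filtering of white noise needs no
## padding -- the result is stationary band-limited noise either way).
bandResponses <- function(rate, n) {
  key <- paste0("r", rate, "n", n)
  if (is.null(.firCache[[key]])) {
    taps <- bandFilters(rate)
    .firCache[[key]] <- lapply(taps[bandDefinitions()$name],
                               firPowerResponse, nfft = n)
  }
  .firCache[[key]]
}

## x(t - lag) with zero fill at the head.
lagShift <- function(v, lag) c(numeric(lag), v[seq_len(length(v) - lag)])

## Synthesize one ROI x samples segment under one condition's parameters.
## RNG draw order is fixed: base noise, then one shared source per
## coherence coupling (spec row order), then observation noise.
synthesizeSegment <- function(spec, design, condition) {
  n    <- segmentSamples(design)
  nroi <- design@nRois
  rate <- design@samplingRate
  resps <- bandResponses(rate, n)
  gains <- spec@powerGains[[condition]]

  E <- matrix(stats::rnorm(n * nroi), n, nroi)
  FE <- stats::mvfft(E)
  coh <- spec@coherence[spec@coherence$condition == condition, , drop = FALSE]
  x <- matrix(0, n, nroi)
  for (b in spec@bandNames) {
    Xb <- Re(stats::mvfft(FE * resps[[b]], inverse = TRUE)) / n
    rows <- which(coh$band == b)
    for (r in rows) {
      # strength s = variance fraction of the shared source, so the mix
      # keeps unit variance and the planted band coherence is about s^2
      s <- coh$strength[r]
      z <- stats::rnorm(n)
      zb <- Re(stats::fft(stats::fft(z) * resps[[b]], inverse = TRUE)) / n
      for (roi in c(coh$roi1[r], coh$roi2[r]))
        Xb[, roi] <- sqrt(1 - s) * Xb[, roi] + sqrt(s) * zb
    }
    # skipped couplings for bands with no row still burn no RNG draws;
    # draw order stays deterministic because rows are visited in order
    x <- x + Xb * rep(gains[b, ], each = n)
  }
  dir <- spec@directed[spec@directed$condition == condition, , drop = FALSE]
  if (nrow(dir)) {
    xPre <- x
    for (r in seq_len(nrow(dir))) {
      cc <- dir$coeff[r]
      x[, dir$to[r]] <- sqrt(1 - cc^2) * x[, dir$to[r]] +
        cc * lagShift(xPre[, dir$from[r]], dir$lag[r])
    }
  }
  if (spec@noiseSd > 0)
    x <- x + spec@noiseSd * matrix(stats::rnorm(n * nroi), n, nroi)
  t(x)
}

#' Generate one synthetic trial (baseline + emotional segment)
#'
#' The baseline segment always uses the baseline (neutral) parameter
#' set; the emotional segment uses the requested condition's parameters.
#' Each ROI signal is a sum over the five bands of zero-phase
#' band-filtered white noise scaled by the condition's amplitude gain,
#' with shared band-limited latent sources mixed variance-preservingly
#' into coherence-coupled ROI pairs, lagged copies of source-ROI signals
#' mixed into directed-coupling targets, and white observation noise on
#' top.  Bit-identical output for identical (spec, design, seed).
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param design a \linkS4class{StudyDesign}.
#' @param participant,session,trial identity metadata.
#' @param condition condition label; must be one of the design's.
#' @param seed integer seed for this trial; it expands into two
#'   independent substreams (baseline, emotional), so either segment can
#'   be resynthesized on its own.
#' @return a \linkS4class{TrialRecording}.
#' @export
generateTrial <- function(spec, design, participant = 1L, condition,
                          seed, session = 1L, trial = 1L) {
  if (!condition %in% conditions(design))
    stop("unknown condition: ", condition)
  validObject(spec)
  set.seed(deriveSeed(seed, 1L))
  baseline  <- synthesizeSegment(spec, design, "neutral")
  set.seed(deriveSeed(seed, 2L))
  emotional <- synthesizeSegment(spec, design, condition)
  new("TrialRecording",
      participant = as.integer(participant), session = as.integer(session),
      trial = as.integer(trial), condition = condition,
      baselineSignal = baseline, emotionalSignal = emotional,
      samplingRate = design@samplingRate)
}

#' Cohort schedule with balanced, seeded condition order
#'
#' Conditions are blocked within each session (each appearing
#' trialsPerSession / nConditions times) and shuffled with a
#' session-specific seed derived from the global one.  When the trial
#' count is not divisible by the number of conditions a warning is
#' issued and a near-balanced assignment is used.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param seed global seed.
#' @return data.frame with participant, session, trial, condition, seed
#'   (the per-trial generator seed).
#' @export
cohortSchedule <- function(design, seed) {
  conds <- conditions(design)
  tps <- design@trialsPerSession
  if (tps %% length(conds) != 0)
    warning("trials per session not divisible by the number of conditions; ",
            "using a near-balanced assignment")
  block <- rep_len(rep(conds, ceiling(tps / length(conds))), tps)
  rows <- list()
  g <- 0L
  for (p in seq_len(design@nParticipants)) {
    for (s in seq_len(design@nSessions)) {
      idx <- (p - 1L) * design@nSessions + s
      set.seed(deriveSeed(seed, 1000000 + idx))
      cond <- block[sample.int(tps)]
      rows[[idx]] <- data.frame(
        participant = p, session = s, trial = seq_len(tps),
        condition = cond, seed = deriveSeed(seed, g + seq_len(tps)),
        stringsAsFactors = FALSE)
      g <- g + tps
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate a full synthetic cohort
#'
#' Produces exactly nParticipants x nSessions x trialsPerSession trials
#' following \code{\link{cohortSchedule}}.  With
#' \code{metadataOnly = TRUE} only the schedule is returned and no
#' signal is synthesized.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed global seed (defaults to the spec's).
#' @param metadataOnly logical.
#' @return list of \linkS4class{TrialRecording} (with the schedule as
#'   attribute \code{"schedule"}), or the schedule data.frame.
#' @examples
#' d <- studyDesign(nParticipants = 1, nSessions = 1, trialsPerSession = 5,
#'                  segmentDuration = 30)
#' sched <- generateCohort(d, syntheticSpec(d), seed = 1, metadataOnly = TRUE)
#' table(sched$condition)   # one trial per condition
#' @export
generateCohort <- function(design, spec, seed = spec@seed,
                           metadataOnly = FALSE) {
  validObject(design); validObject(spec)
  sched <- cohortSchedule(design, seed)
  if (metadataOnly) return(sched)
  trials <- vector("list", nrow(sched))
  for (i in seq_len(nrow(sched))) {
    trials[[i]] <- generateTrial(
      spec, design, participant = sched$participant[i],
      condition = sched$condition[i], seed = sched$seed[i],
      session = sched$session[i], trial = sched$trial[i])
  }
  attr(trials, "schedule") <- sched
  trials
}

#' Generate and preprocess a cohort trial by trial
#'
#' Streaming equivalent of \code{\link{generateCohort}} followed by
#' \code{\link{buildObservationSet}}: each trial is synthesized,
#' filtered and windowed into the preallocated observation tensors,
#' then discarded, so peak memory is the tensors themselves rather than
#' the raw cohort.  Output is identical to the two-step path for the
#' same (design, spec, seed).
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed global seed (defaults to the spec's).
#' @param includeBaseline keep baseline tensors.
#' @return an \linkS4class{ObservationSet}.
#' @export
synthesizeObservationSet <- function(design, spec, seed = spec@seed,
                                     includeBaseline = TRUE) {
  validObject(design); validObject(spec)
  sched <- cohortSchedule(design, seed)
  n <- nrow(sched)
  rate <- design@samplingRate
  wlen <- as.integer(3 * rate)
  nroi <- design@nRois
  bands <- bandDefinitions()
  mk <- function() {
    a <- vector("list", nrow(bands)); names(a) <- bands$name
    for (b in bands$name) a[[b]] <- array(NA_real_, c(n, nroi, 8L, wlen))
    a
  }
  emoT <- mk()
  basT <- if (includeBaseline) mk() else list()
  emoP <- matrix(NA_real_, n, nroi)
  basP <- if (includeBaseline) matrix(NA_real_, n, nroi) else
    matrix(numeric(0), 0, nroi)
  for (r in seq_len(n)) {
    # emotional substream only, unless baselines are kept: the two
    # segments draw from independent substreams of the trial seed
    set.seed(deriveSeed(sched$seed[r], 2L))
    emo <- synthesizeSegment(spec, design, sched$condition[r])
    filt <- filterSegment(emo, rate)
    emoP[r, ] <- rowMeans(windowBandPower(
      extractWindows(filt$broadband, rate), rate, 1, 45))
    for (b in bands$name)
      emoT[[b]][r, , , ] <- extractWindows(filt$bands[[b]], rate)
    if (includeBaseline) {
      set.seed(deriveSeed(sched$seed[r], 1L))
      bas <- synthesizeSegment(spec, design, "neutral")
      filt <- filterSegment(bas, rate)
      basP[r, ] <- rowMeans(windowBandPower(
        extractWindows(filt$broadband, rate), rate, 1, 45))
      for (b in bands$name)
        basT[[b]][r, , , ] <- extractWindows(filt$bands[[b]], rate)
    }
  }
  meta <- S4Vectors::DataFrame(
    participant = sched$participant, session = sched$session,
    trial = sched$trial, condition = sched$condition)
  new("ObservationSet",
      bandTensors = emoT, baselineTensors = basT,
      broadbandPower = emoP, baselineBroadbandPower = basP,
      rowData = meta,
      exclusionLog = data.frame(participant = integer(),
                                session = integer(), trial = integer(),
                                reason = character(),
                                stringsAsFactors = FALSE),
      bands = bands, samplingRate = rate)
}
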