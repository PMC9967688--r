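#' @include AllClasses.R AllGenerics.R filters.R studyDesign.R
NULL

#' Default 10-ROI montage for a 32-electrode 10-20 cap
#'
#' Groups the 30 non-reference electrodes of a 32-channel 10-20 layout
#' into the ten analysis ROIs: mid-frontal left (1) and right (2), left
#' (3) and right (4) frontal, centro-parietal left (5) and right (6),
#' parieto-occipital left (7) and right (8), fronto-central (9) and
#' central parieto-occipital (10).  T7 and T8 are the reference
#' electrodes and belong to no ROI.
#'
#' @return a \linkS4class{MontageMap}.
#' @export
defaultMontage <- function() {
  new("MontageMap",
      rois = list(
        roi1  = c("Fp1", "AF3"),
        roi2  = c("Fp2", "AF4"),
        roi3  = c("F7", "F3", "FC5"),
        roi4  = c("F8", "F4", "FC6"),
        roi5  = c("C3", "CP5", "CP1"),
        roi6  = c("C4", "CP6", "CP2"),
        roi7  = c("P7", "P3", "PO3", "O1"),
        roi8  = c("P8", "P4", "PO4", "O2"),
        roi9  = c("Fz", "FC1", "FC2"),
        roi10 = c("Cz", "Pz", "Oz")),
      reference = c("T7", "T8"))
}

#' Re-reference channels to the mean of the reference electrodes
#'
#' Subtracts the instantaneous mean of the reference channels (default
#' T7 and T8) from every channel.
#'
#' @param channelSignals numeric matrix, channels x samples, with channel
#'   names as rownames.
#' @param referenceNames character, reference channel names.
#' @return matrix of the same shape.
#' @export
rereference <- function(channelSignals, referenceNames = c("T7", "T8")) {
  missing <- setdiff(referenceNames, rownames(channelSignals))
  if (length(missing))
    stop("reference channel(s) missing: ", paste(missing, collapse = ", "))
  ref <- colMeans(channelSignals[referenceNames, , drop = FALSE])
  sweep(channelSignals, 2L, ref, "-")
}

#' Average channels into ROI signals
#'
#' Each ROI row is the arithmetic mean of its available member channels.
#' An ROI whose member channels are all unavailable is returned as an
#' all-NA row and flagged in the \code{"missingRois"} attribute; trials
#' with any missing ROI are later excluded by
#' \code{\link{buildObservationSet}}.
#'
#' @param channelSignals numeric matrix, channels x samples, rownames =
#'   channel names.
#' @param montage a \linkS4class{MontageMap}.
#' @param available character, channel names usable (default: all rows).
#' @return ROIs x samples matrix with attribute \code{missingRois}
#'   (logical per ROI).
#' @export
averageChannelsToRois <- function(channelSignals, montage,
                                  available = rownames(channelSignals)) {
  validObject(montage)
  usable <- intersect(available, rownames(channelSignals))
  if (!length(intersect(usable, unlist(montage@rois))))
    stop("no channels resolvable against the montage")
  out <- matrix(NA_real_, length(montage@rois), ncol(channelSignals),
                dimnames = list(names(montage@rois), NULL))
  missing <- logical(length(montage@rois))
  names(missing) <- names(montage@rois)
  for (i in seq_along(montage@rois)) {
    members <- intersect(montage@rois[[i]], usable)
    if (!length(members)) {
      missing[i] <- TRUE
    } else {
      out[i, ] <- colMeans(channelSignals[members, , drop = FALSE])
    }
  }
  attr(out, "missingRois") <- missing
  out
}

#' Cut a segment into eight non-overlapping 3 s windows
#'
#' Windows cover seconds [3, 27) of the segment contiguously: window k
#' (k = 0..7) covers samples [(3+3k) rate, (6+3k) rate) in 0-based,
#' half-open convention.  At 500 Hz each window holds 1500 samples.
#'
#' @param segment numeric matrix, ROIs x samples.
#' @param rate sampling rate in Hz.
#' @return array ROIs x 8 x (3 rate).
#' @examples
#' seg <- matrix(seq(0, 30, length.out = 15001)[-1], 1, 15000, byrow = TRUE)
#' w <- extractWindows(seg, 500)
#' dim(w)    # 1 x 8 x 1500
#' @export
extractWindows <- function(segment, rate) {
  n <- ncol(segment)
  need <- 27 * rate
  if (n < need)
    stop("segment too short: need at least 27 s (", need, " samples), got ", n)
  wlen <- as.integer(3 * rate)
  out <- array(NA_real_, c(nrow(segment), 8L, wlen))
  for (k in 0:7) {
    idx <- ((3 + 3 * k) * rate + 1L):((6 + 3 * k) * rate)
    out[, k + 1L, ] <- segment[, idx, drop = FALSE]
  }
  out
}

## Broadband + five sub-band zero-phase filtering of one ROI x samples
## segment, sharing one forward FFT.  Sub-bands are cascaded after the
## broadband stage (responses multiply), mirroring the preprocessing
## order: broadband 0.5-45 Hz first, then per-band decomposition.
filterSegment <- function(segment, rate) {
  taps <- bandFilters(rate)
  x <- t(segment)
  n <- nrow(x)
  maxTaps <- max(lengths(taps))
  padLen <- min(maxTaps, n - 1L)
  xp <- reflectPad(x, padLen)
  nfft <- goodFFTLength(nrow(xp) + maxTaps)
  xp <- rbind(xp, matrix(0, nfft - nrow(xp), ncol(x)))
  F <- stats::mvfft(xp)
  key <- paste0("casc_r", rate, "n", nfft)
  if (is.null(.firCache[[key]])) {
    respBB <- firPowerResponse(taps$broadband, nfft)
    resp <- lapply(bandDefinitions()$name, function(b)
      respBB * firPowerResponse(taps[[b]], nfft))
    names(resp) <- bandDefinitions()$name
    resp$broadband <- respBB
    .firCache[[key]] <- resp
  }
  resp <- .firCache[[key]]
  pick <- function(r) {
    y <- Re(stats::mvfft(F * r, inverse = TRUE)) / nfft
    t(y[padLen + seq_len(n), , drop = FALSE])
  }
  bands <- lapply(bandDefinitions()$name, function(b) pick(resp[[b]]))
  names(bands) <- bandDefinitions()$name
  list(broadband = pick(resp$broadband), bands = bands)
}

#' Build per-band windowed observation tensors from trials
#'
#' Applies the 0.5-45 Hz broadband filter, excludes any trial whose
#' baseline or emotional segment has a missing ROI (all-NA row), windows
#' both segments into eight 3 s windows, decomposes them into the five
#' sub-bands, and precomputes the broadband 1-45 Hz mean spectral power
#' per ROI (the relative-power denominator).  Emotional and baseline
#' tensors share row order; the exclusion log records every dropped
#' trial with its reason.
#'
#' @param trials list of \linkS4class{TrialRecording}.
#' @param bands band table (default \code{\link{bandDefinitions}}).
#' @param includeBaseline logical; set FALSE to skip baseline tensors
#'   (halves memory when only ANOVA-only selection is planned).
#' @return an \linkS4class{ObservationSet}.
#' @export
buildObservationSet <- function(trials, bands = bandDefinitions(),
                                includeBaseline = TRUE) {
  if (!length(trials)) stop("no trials supplied")
  rate <- trials[[1]]@samplingRate
  wlen <- as.integer(3 * rate)
  bb <- broadbandEdges()

  hasMissingRoi <- function(m) rowSums(is.na(m)) == ncol(m)
  keep <- logical(length(trials))
  reasons <- character(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    me <- which(hasMissingRoi(tr@emotionalSignal))
    mb <- which(hasMissingRoi(tr@baselineSignal))
    if (length(me) || length(mb)) {
      reasons[i] <- paste0("missing ROI ",
                           paste(sort(unique(c(me, mb))), collapse = ","))
    } else keep[i] <- TRUE
  }
  if (!any(keep)) stop("all trials excluded (missing ROIs everywhere)")

  kept <- which(keep)
  n <- length(kept)
  nroi <- nrow(trials[[kept[1]]]@emotionalSignal)
  bandNames <- bands$name
  mk <- function() {
    a <- vector("list", length(bandNames)); names(a) <- bandNames
    for (b in bandNames) a[[b]] <- array(NA_real_, c(n, nroi, 8L, wlen))
    a
  }
  emoT <- mk()
  basT <- if (includeBaseline) mk() else list()
  emoP <- matrix(NA_real_, n, nroi)
  basP <- if (includeBaseline) matrix(NA_real_, n, nroi) else
    matrix(numeric(0), 0, nroi)

  # filled in place; keep the tensors un-aliased so subassignment does
  # not trigger copy-on-write of multi-hundred-MB arrays
  for (r in seq_len(n)) {
    tr <- trials[[kept[r]]]
    filt <- filterSegment(tr@emotionalSignal, rate)
    wBB <- extractWindows(filt$broadband, rate)
    emoP[r, ] <- rowMeans(windowBandPower(wBB, rate, 1, 45))
    for (b in bandNames)
      emoT[[b]][r, , , ] <- extractWindows(filt$bands[[b]], rate)
    if (includeBaseline) {
      filt <- filterSegment(tr@baselineSignal, rate)
      wBB <- extractWindows(filt$broadband, rate)
      basP[r, ] <- rowMeans(windowBandPower(wBB, rate, 1, 45))
      for (b in bandNames)
        basT[[b]][r, , , ] <- extractWindows(filt$bands[[b]], rate)
    }
  }

  meta <- S4Vectors::DataFrame(
    participant = vapply(trials[kept], function(x) x@participant, 1L),
    session     = vapply(trials[kept], function(x) x@session, 1L),
    trial       = vapply(trials[kept], function(x) x@trial, 1L),
    condition   = vapply(trials[kept], function(x) x@condition, ""))
  excl <- data.frame(
    participant = vapply(trials[!keep], function(x) x@participant, 1L),
    session     = vapply(trials[!keep], function(x) x@session, 1L),
    trial       = vapply(trials[!keep], function(x) x@trial, 1L),
    reason      = reasons[!keep], stringsAsFactors = FALSE)

  new("ObservationSet",
      bandTensors = emoT, baselineTensors = basT,
      broadbandPower = emoP, baselineBroadbandPower = basP,
      rowData = meta, exclusionLog = excl, bands = bands,
      samplingRate = rate)
}

#' @describeIn buildObservationSet band names of the set.
#' @param object an ObservationSet.
#' @export
setMethod("bandNames", "ObservationSet", function(object)
  object@bands$name)

#' @describeIn buildObservationSet number of retained observations.
#' @export
setMethod("observationCount", "ObservationSet", function(object) {
  if (!length(object@bandTensors)) return(0L)
  dim(object@bandTensors[[1]])[1]
})

#' @describeIn buildObservationSet dropped trials and reasons.
#' @export
setMethod("exclusionLog", "ObservationSet", function(object)
  object@exclusionLog)

#' @describeIn buildObservationSet sampling rate (Hz).
#' @export
setMethod("samplingRate", "ObservationSet", function(object)
  object@samplingRate)

#' Observation metadata (participant, session, trial, condition)
#' @param object an ObservationSet.
#' @return DataFrame, one row per retained observation.
#' @export
observationInfo <- function(object) object@rowData

#' Extract one observation's windowed tensor
#' @param object an ObservationSet.
#' @param i observation row index.
#' @param band band name.
#' @param segment "emotional" or "baseline".
#' @return array ROIs x windows x window-samples.
#' @export
windowTensor <- function(object, i, band,
                         segment = c("emotional", "baseline")) {
  segment <- match.arg(segment)
  src <- if (segment == "emotional") object@bandTensors else
    object@baselineTensors
  if (!length(src)) stop("baseline tensors were not kept in this set")
  src[[band]][i, , , , drop = TRUE]
}

setMethod("show", "ObservationSet", function(object) {
  d <- if (length(object@bandTensors)) dim(object@bandTensors[[1]]) else
    rep(0L, 4)
  cat("ObservationSet:", d[1], "observations x", d[2], "ROIs x", d[3],
      "windows x", d[4], "samples per band\n")
  cat("  bands:", paste(bandNames(object), collapse = ", "), "\n")
  cat("  baseline kept:", length(object@baselineTensors) > 0,
      "| excluded trials:", nrow(object@exclusionLog), "\n")
})

#' Expand ROI-level trial signals to a 32-electrode layout
#'
#' The generator works at ROI level because every analysis step runs on
#' ROI-averaged signals; this helper exists to exercise the real-data
#' preprocessing path.  Each electrode receives its ROI's signal plus
#' independent sensor noise, and the reference electrodes (T7, T8)
#' receive pure sensor noise, so that re-referencing and ROI averaging
#' approximately recover the original ROI signals.
#'
#' @param trial a \linkS4class{TrialRecording}.
#' @param montage a \linkS4class{MontageMap} (default
#'   \code{\link{defaultMontage}}).
#' @param segment "emotional" or "baseline".
#' @param sensorNoiseSd sd of per-electrode white noise.
#' @param seed RNG seed for the sensor noise.
#' @return channels x samples matrix with electrode rownames (members of
#'   every ROI plus the reference electrodes).
#' @export
trialToChannels <- function(trial, montage = defaultMontage(),
                            segment = c("emotional", "baseline"),
                            sensorNoiseSd = 0.05, seed = 1L) {
  segment <- match.arg(segment)
  roiSig <- if (segment == "emotional") trial@emotionalSignal else
    trial@baselineSignal
  if (nrow(roiSig) != length(montage@rois))
    stop("trial ROI count does not match the montage")
  set.seed(seed)
  chans <- c(unlist(montage@rois, use.names = FALSE), montage@reference)
  out <- matrix(NA_real_, length(chans), ncol(roiSig),
                dimnames = list(chans, NULL))
  for (i in seq_along(montage@rois))
    for (e in montage@rois[[i]])
      out[e, ] <- roiSig[i, ] +
        sensorNoiseSd * stats::rnorm(ncol(roiSig))
  for (e in montage@reference)
    out[e, ] <- sensorNoiseSd * stats::rnorm(ncol(roiSig))
  out
}
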