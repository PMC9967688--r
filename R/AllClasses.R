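#' @import methods
#' @importFrom S4Vectors DataFrame
#' @importClassesFrom S4Vectors DataFrame
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' StudyDesign: cohort layout of a performed-emotion EEG study
#'
#' Describes the experimental grid: participants, recording sessions,
#' trials per session, the set of emotional conditions, the sampling rate,
#' the duration of each analysed performance segment and the number of
#' scalp regions of interest (ROIs).  The shipped defaults reproduce a
#' 10-participant, 4-session, 50-trial design with five conditions
#' (distressed, excited, depressed, relaxed, neutral), 500 Hz sampling,
#' 30 s segments and 10 ROIs, i.e. 2000 trials overall and 400 per
#' condition.
#'
#' @slot nParticipants integer, number of participants.
#' @slot nSessions integer, recording sessions per participant.
#' @slot trialsPerSession integer, trials within one session.
#' @slot conditions character, ordered condition labels; the label
#'   \code{"neutral"} doubles as the baseline parameter set.
#' @slot samplingRate numeric, Hz.
#' @slot segmentDuration numeric, seconds per analysed segment.
#' @slot nRois integer, number of regions of interest.
#' @export
setClass("StudyDesign",
  representation(
    nParticipants    = "integer",
    nSessions        = "integer",
    trialsPerSession = "integer",
    conditions       = "character",
    samplingRate     = "numeric",
    segmentDuration  = "numeric",
    nRois            = "integer"
  )
)

setValidity("StudyDesign", function(object) {
  msg <- NULL
  counts <- c(object@nParticipants, object@nSessions,
              object@trialsPerSession, object@nRois)
  if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
  if (length(object@conditions) < 1L || anyDuplicated(object@conditions))
    msg <- c(msg, "conditions must be a non-empty set of unique labels")
  if (object@samplingRate <= 0 || object@segmentDuration <= 0)
    msg <- c(msg, "samplingRate and segmentDuration must be positive")
  nsamp <- object@samplingRate * object@segmentDuration
  if (abs(nsamp - round(nsamp)) > 1e-9)
    msg <- c(msg, "samplingRate * segmentDuration must be an integer sample count")
  if (is.null(msg)) TRUE else msg
})

#' SyntheticSpec: planted ground-truth structure for synthetic EEG
#'
#' Collects every condition-dependent parameter of the generator:
#' per-condition band-power gains (dimensionless multipliers on the
#' band-limited signal amplitude), shared-source coherence couplings
#' between ROI pairs (strength in [0, 1] is the variance fraction of a
#' shared band-limited latent source, mixed in variance-preservingly, so
#' strength s plants a band coherence of about s^2 without changing band
#' power), directed lagged couplings (source ROI, target
#' ROI, lag in samples, coefficient), and the white observation-noise
#' standard deviation.  The \code{"neutral"} condition's parameters are
#' the baseline set used for every trial's baseline segment.
#'
#' @slot conditions character, condition labels covered by the spec.
#' @slot powerGains named list; per condition a bands x ROIs matrix of
#'   amplitude gains (power scales with the square of the gain).
#' @slot coherence data.frame with columns condition, band, roi1, roi2,
#'   strength.
#' @slot directed data.frame with columns condition, from, to, lag, coeff.
#' @slot noiseSd numeric, sd of added white observation noise relative to
#'   the unit-variance pre-filter noise driving each band.
#' @slot bandNames character, band names the gain matrices are indexed by.
#' @slot seed integer, default generator seed.
#' @export
setClass("SyntheticSpec",
  representation(
    conditions = "character",
    powerGains = "list",
    coherence  = "data.frame",
    directed   = "data.frame",
    noiseSd    = "numeric",
    bandNames  = "character",
    seed       = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msg <- NULL
  if (!all(names(object@powerGains) == object@conditions))
    msg <- c(msg, "powerGains must be named by the conditions, in order")
  for (g in object@powerGains) {
    if (!is.matrix(g) || nrow(g) != length(object@bandNames))
      msg <- c(msg, "each powerGains entry must be a bands x ROIs matrix")
    else if (any(g < 0)) msg <- c(msg, "power gains must be non-negative")
  }
  if (nrow(object@coherence)) {
    if (any(object@coherence$strength < 0 | object@coherence$strength > 1))
      msg <- c(msg, "coherence coupling strengths must lie in [0, 1]")
    if (any(object@coherence$roi1 == object@coherence$roi2))
      msg <- c(msg, "coherence couplings must join two distinct ROIs")
    if (!all(object@coherence$band %in% object@bandNames))
      msg <- c(msg, "coherence bands must be among the spec's band names")
  }
  if (nrow(object@directed)) {
    if (any(object@directed$lag < 1))
      msg <- c(msg, "directed-coupling lags must be >= 1 sample")
    if (any(object@directed$from == object@directed$to))
      msg <- c(msg, "directed couplings must join two distinct ROIs")
    rad <- companionSpectralRadius(object@directed)
    if (rad >= 1 || any(abs(object@directed$coeff) >= 1))
      msg <- c(msg, "unstable coupling specification (companion spectral radius must be < 1 and |coeff| < 1)")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' TrialRecording: one trial's baseline and emotional ROI signals
#'
#' @slot participant integer id.
#' @slot session integer id.
#' @slot trial integer index within the session.
#' @slot condition character label.
#' @slot baselineSignal numeric matrix, ROIs x samples, the neutral
#'   baseline performance segment.
#' @slot emotionalSignal numeric matrix, ROIs x samples, the emotional
#'   performance segment.
#' @slot samplingRate numeric, Hz.
#' @export
setClass("TrialRecording",
  representation(
    participant     = "integer",
    session         = "integer",
    trial           = "integer",
    condition       = "character",
    baselineSignal  = "matrix",
    emotionalSignal = "matrix",
    samplingRate    = "numeric"
  )
)

setValidity("TrialRecording", function(object) {
  msg <- NULL
  if (!identical(dim(object@baselineSignal), dim(object@emotionalSignal)))
    msg <- c(msg, "baseline and emotional signals must have identical shape")
  if (!all(is.finite(object@emotionalSignal)) ||
      !all(is.finite(object@baselineSignal)))
    msg <- c(msg, "all signal values must be finite")
  if (is.null(msg)) TRUE else msg
})

#' ObservationSet: per-band windowed observation tensors
#'
#' The central preprocessing output.  For every frequency band it holds a
#' 4-dimensional tensor (observations x ROIs x windows x window-samples)
#' of band-filtered, windowed emotional-segment signals, and (optionally)
#' an identically ordered tensor for the paired neutral-baseline
#' segments.  Broadband (0.5-45 Hz) per-ROI mean spectral power over the
#' full 1-45 Hz range is precomputed at build time and stored as the
#' denominator for relative band power.  Row metadata carries
#' participant, session, trial and condition per observation; the
#' exclusion log records every dropped trial and its reason.
#'
#' @slot bandTensors named list of 4-d arrays (emotional segments).
#' @slot baselineTensors named list of 4-d arrays (baseline segments);
#'   empty when the set was built with \code{includeBaseline = FALSE}.
#' @slot broadbandPower matrix, observations x ROIs: mean per-bin 1-45 Hz
#'   Hann-periodogram power of the emotional broadband windows.
#' @slot baselineBroadbandPower matrix, same for baseline windows (0-row
#'   when baseline is not kept).
#' @slot rowData DataFrame with participant, session, trial, condition.
#' @slot exclusionLog data.frame with participant, session, trial, reason.
#' @slot bands data.frame with name, low, high (Hz).
#' @slot samplingRate numeric, Hz.
#' @export
setClass("ObservationSet",
  representation(
    bandTensors            = "list",
    baselineTensors        = "list",
    broadbandPower         = "matrix",
    baselineBroadbandPower = "matrix",
    rowData                = "DataFrame",
    exclusionLog           = "data.frame",
    bands                  = "data.frame",
    samplingRate           = "numeric"
  )
)

setValidity("ObservationSet", function(object) {
  msg <- NULL
  dims <- lapply(object@bandTensors, dim)
  if (length(unique(dims)) > 1L)
    msg <- c(msg, "all band tensors must share one shape")
  n <- if (length(dims)) dims[[1]][1] else 0L
  if (nrow(object@rowData) != n)
    msg <- c(msg, "rowData must have one row per observation")
  if (length(object@baselineTensors)) {
    if (!identical(lapply(object@baselineTensors, dim), dims))
      msg <- c(msg, "baseline tensors must mirror the emotional tensors")
  }
  if (is.null(msg)) TRUE else msg
})

#' MontageMap: electrode-to-ROI grouping for the real-data path
#'
#' @slot rois named list; ROI name -> character vector of 10-20 electrode
#'   names.  No electrode may belong to two ROIs and the reference
#'   electrodes are excluded from ROI membership.
#' @slot reference character, the reference electrode names (default T7, T8).
#' @export
setClass("MontageMap",
  representation(rois = "list", reference = "character"))

setValidity("MontageMap", function(object) {
  msg <- NULL
  all_e <- unlist(object@rois, use.names = FALSE)
  if (any(lengths(object@rois) < 1L))
    msg <- c(msg, "every ROI needs at least one electrode")
  if (anyDuplicated(all_e))
    msg <- c(msg, "no electrode may belong to two ROIs")
  if (any(object@reference %in% all_e))
    msg <- c(msg, "reference electrodes must not belong to any ROI")
  if (is.null(msg)) TRUE else msg
})

#' SpectralEstimate: Welch-style averaged auto- and cross-spectra
#'
#' Across-window means of Hann-tapered periodogram auto-spectra (per ROI)
#' and cross-spectra (per unordered ROI pair) for one observation.
#'
#' @slot freq numeric, frequency grid in Hz (resolution = rate / window
#'   samples).
#' @slot auto numeric matrix, bins x ROIs, real and non-negative.
#' @slot cross complex matrix, bins x pairs, upper-triangle pair order.
#' @slot pairs integer matrix, pairs x 2 (roi1 < roi2).
#' @slot ensembleSize integer, number of averaged windows.
#' @export
setClass("SpectralEstimate",
  representation(
    freq         = "numeric",
    auto         = "matrix",
    cross        = "matrix",
    pairs        = "matrix",
    ensembleSize = "integer"
  )
)

setValidity("SpectralEstimate", function(object) {
  msg <- NULL
  if (any(object@auto < -1e-12)) msg <- c(msg, "auto-spectra must be >= 0")
  if (object@ensembleSize < 1L) msg <- c(msg, "ensemble size must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' ARModelFit: nested autoregressive fits for pairwise Granger causality
#'
#' Least-squares fits of the restricted model (target's own lags only)
#' and the full model (own plus source lags) on the same sample range.
#' Residual variances are degrees-of-freedom adjusted (residual sum of
#' squares divided by n - number of coefficients); the raw in-sample sums
#' of squares are kept for the literal and F-test decision rules.
#'
#' @slot order integer, AR order p.
#' @slot coefRestricted numeric, own-lag coefficients a(i).
#' @slot coefFull numeric, own-lag then source-lag coefficients a(i), b(j).
#' @slot varRestricted numeric, dof-adjusted residual variance of the
#'   restricted model.
#' @slot varFull numeric, dof-adjusted residual variance of the full model.
#' @slot rssRestricted numeric, residual sum of squares, restricted.
#' @slot rssFull numeric, residual sum of squares, full.
#' @slot nUsed integer, samples entering the regressions.
#' @slot nEffective integer, effective sample size used for the
#'   degrees-of-freedom adjustment and F test.  Defaults to nUsed; for
#'   band-limited signals the caller should supply about
#'   2 x bandwidth x duration, the number of effectively independent
#'   samples a band-limited window carries (an oversampled narrow-band
#'   series is nearly deterministic given its own past, so the literal
#'   sample count wildly overstates the information content and every
#'   nested-model comparison fires).
#' @slot rankDeficient logical, TRUE when either design was rank
#'   deficient (variances are then set equal so the causality bit is 0).
#' @export
setClass("ARModelFit",
  representation(
    order          = "integer",
    coefRestricted = "numeric",
    coefFull       = "numeric",
    varRestricted  = "numeric",
    varFull        = "numeric",
    rssRestricted  = "numeric",
    rssFull        = "numeric",
    nUsed          = "integer",
    nEffective     = "integer",
    rankDeficient  = "logical"
  )
)

setValidity("ARModelFit", function(object) {
  msg <- NULL
  if (object@order < 1L) msg <- c(msg, "model order must be >= 1")
  if (object@varRestricted < 0 || object@varFull < 0)
    msg <- c(msg, "residual variances must be >= 0")
  if (is.null(msg)) TRUE else msg
})

#' FeatureSet: named features x observations with provenance
#'
#' A \linkS4class{SummarizedExperiment} whose single assay
#' (\code{"values"}) holds features in rows and observations in columns.
#' \code{rowData} carries per-feature provenance (family, band, ROI or
#' ROI pair, measure/direction); \code{colData} carries the observation
#' labels (condition, participant, session, trial).  A metadata flag
#' marks matrices computed on baseline rather than emotional segments.
#'
#' @export
setClass("FeatureSet", contains = "SummarizedExperiment")

setValidity("FeatureSet", function(object) {
  msg <- NULL
  if (!"values" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "FeatureSet needs an assay named 'values'")
  if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
    msg <- c(msg, "feature names must be present and unique")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("family", "band") %in% colnames(rd)))
    msg <- c(msg, "rowData must carry 'family' and 'band' provenance")
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    msg <- c(msg, "colData must carry 'condition'")
  if (is.null(msg)) TRUE else msg
})

#' SelectionResult: outcome of one feature-selection run
#'
#' @slot mode character, "normalized" (baseline t-test phase then ANOVA
#'   phase) or "non_normalized" (ANOVA only).
#' @slot family character, feature family the selection ran on.
#' @slot retained character, retained feature names (across bands).
#' @slot phase1P numeric matrix, features x non-neutral conditions,
#'   two-sample t-test p-values (all NA in non_normalized mode).
#' @slot phase2P named numeric, one-way ANOVA p-value per feature tested
#'   in phase 2 (NA where undefined).
#' @slot bandOf named character, band of every input feature.
#' @slot alphas named numeric, thresholds used (phase1, phase2).
#' @slot droppedLog data.frame, features dropped for undefined p-values.
#' @export
setClass("SelectionResult",
  representation(
    mode       = "character",
    family     = "character",
    retained   = "character",
    phase1P    = "matrix",
    phase2P    = "numeric",
    bandOf     = "character",
    alphas     = "numeric",
    droppedLog = "data.frame"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- NULL
  if (!object@mode %in% c("normalized", "non_normalized"))
    msg <- c(msg, "mode must be 'normalized' or 'non_normalized'")
  if (!all(object@retained %in% names(object@bandOf)))
    msg <- c(msg, "retained features must be a subset of the input features")
  if (is.null(msg)) TRUE else msg
})

#' CVReport: k-fold one-vs-one SVM evaluation of one labeling scheme
#'
#' @slot scheme character, labeling scheme name (arousal, valence, emotion).
#' @slot classOrder character, class labels in scheme order; confusion
#'   rows/columns follow it.
#' @slot foldTrain numeric, per-fold training accuracy in percent.
#' @slot foldTest numeric, per-fold test accuracy in percent.
#' @slot confusionCounts matrix, pooled test-fold counts, rows = actual.
#' @slot seed integer, fold-assignment seed.
#' @slot k integer, number of folds.
#' @slot nPairwise integer, number of pairwise binary SVMs (C(nclass, 2)).
#' @slot hyperparams list, cost, gamma rule etc.
#' @export
setClass("CVReport",
  representation(
    scheme          = "character",
    classOrder      = "character",
    foldTrain       = "numeric",
    foldTest        = "numeric",
    confusionCounts = "matrix",
    seed            = "integer",
    k               = "integer",
    nPairwise       = "integer",
    hyperparams     = "list"
  )
)

setValidity("CVReport", function(object) {
  msg <- NULL
  if (length(object@foldTrain) != object@k ||
      length(object@foldTest) != object@k)
    msg <- c(msg, "one train and one test accuracy per fold required")
  if (!identical(rownames(object@confusionCounts), object@classOrder))
    msg <- c(msg, "confusion rows must follow the scheme class order")
  if (is.null(msg)) TRUE else msg
})
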