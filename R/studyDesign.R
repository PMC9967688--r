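#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a StudyDesign
#'
#' Defaults reproduce the performed-emotion study grid: 10 participants,
#' 4 sessions, 50 trials per session, five conditions, 500 Hz sampling,
#' 30 s segments, 10 ROIs (2000 trials, 400 per condition).
#'
#' @param nParticipants,nSessions,trialsPerSession cohort counts.
#' @param conditions ordered character vector of condition labels; must
#'   contain \code{"neutral"}, which doubles as the baseline set.
#' @param samplingRate Hz.
#' @param segmentDuration seconds per analysed segment.
#' @param nRois number of scalp regions of interest.
#' @return a \linkS4class{StudyDesign}.
#' @examples
#' d <- studyDesign()
#' nTrials(d)          # 2000
#' @export
studyDesign <- function(nParticipants = 10L, nSessions = 4L,
                        trialsPerSession = 50L,
                        conditions = c("distressed", "excited", "depressed",
                                       "relaxed", "neutral"),
                        samplingRate = 500, segmentDuration = 30,
                        nRois = 10L) {
  new("StudyDesign",
      nParticipants    = as.integer(nParticipants),
      nSessions        = as.integer(nSessions),
      trialsPerSession = as.integer(trialsPerSession),
      conditions       = conditions,
      samplingRate     = samplingRate,
      segmentDuration  = segmentDuration,
      nRois            = as.integer(nRois))
}

#' Total number of trials in a design
#' @param design a StudyDesign.
#' @return integer.
#' @export
nTrials <- function(design) {
  design@nParticipants * design@nSessions * design@trialsPerSession
}

#' Samples per analysed segment
#' @param design a StudyDesign.
#' @return integer.
#' @export
segmentSamples <- function(design) {
  as.integer(round(design@samplingRate * design@segmentDuration))
}

#' @describeIn studyDesign condition labels.
#' @param object a StudyDesign.
#' @export
setMethod("conditions", "StudyDesign", function(object) object@conditions)

#' @describeIn studyDesign sampling rate in Hz.
#' @export
setMethod("samplingRate", "StudyDesign", function(object) object@samplingRate)

setMethod("show", "StudyDesign", function(object) {
  cat("StudyDesign:", object@nParticipants, "participants x",
      object@nSessions, "sessions x", object@trialsPerSession, "trials\n")
  cat("  conditions:", paste(object@conditions, collapse = ", "), "\n")
  cat("  ", object@samplingRate, " Hz, ", object@segmentDuration,
      " s segments, ", object@nRois, " ROIs (", nTrials(object),
      " trials total)\n", sep = "")
})

setMethod("samplingRate", "TrialRecording", function(object)
  object@samplingRate)

setMethod("show", "TrialRecording", function(object) {
  cat("TrialRecording: participant", object@participant, "session",
      object@session, "trial", object@trial, "--", object@condition, "\n")
  cat("  ", nrow(object@emotionalSignal), " ROIs x ",
      ncol(object@emotionalSignal), " samples @ ", object@samplingRate,
      " Hz (baseline + emotional)\n", sep = "")
})
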