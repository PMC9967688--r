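#' @include AllClasses.R
NULL

#' Condition labels of an object
#' @param object a StudyDesign or SyntheticSpec.
#' @return character vector of condition labels.
#' @export
setGeneric("conditions", function(object) standardGeneric("conditions"))

#' Sampling rate in Hz
#' @param object an object carrying signals.
#' @return numeric, Hz.
#' @export
setGeneric("samplingRate", function(object) standardGeneric("samplingRate"))

#' Band names of an object
#' @param object an ObservationSet or band table.
#' @return character vector.
#' @export
setGeneric("bandNames", function(object) standardGeneric("bandNames"))

#' Number of observations (retained trials)
#' @param object an ObservationSet or FeatureSet.
#' @return integer.
#' @export
setGeneric("observationCount",
           function(object) standardGeneric("observationCount"))

#' Exclusion log of dropped trials
#' @param object an ObservationSet.
#' @return data.frame with one row per dropped trial and the reason.
#' @export
setGeneric("exclusionLog", function(object) standardGeneric("exclusionLog"))

#' Planted ground truth of a synthetic specification
#'
#' Lists every (type, condition, band, ROI or ROI pair) where a
#' condition's generator parameter differs from the neutral/baseline
#' parameter set, as ground truth for selection-recovery studies.
#' @param object a SyntheticSpec.
#' @return data.frame with columns type, condition, band, roi1, roi2.
#' @export
setGeneric("plantedTruth", function(object) standardGeneric("plantedTruth"))

#' Retained feature names of a selection result
#' @param object a SelectionResult.
#' @return character vector.
#' @export
setGeneric("retainedFeatures",
           function(object) standardGeneric("retainedFeatures"))

#' Per-band retained-feature counts
#'
#' Summarizes a selection result as one row per phase with the number of
#' surviving features per band plus a total column, the layout used for
#' retained-feature tables.
#' @param object a SelectionResult.
#' @return data.frame, rows = phases, columns = bands + total.
#' @export
setGeneric("countSummary", function(object) standardGeneric("countSummary"))

#' Mean test accuracy (percent)
#' @param object a CVReport.
#' @return numeric scalar.
#' @export
setGeneric("testAccuracy", function(object) standardGeneric("testAccuracy"))

#' Mean training accuracy (percent)
#' @param object a CVReport.
#' @return numeric scalar.
#' @export
setGeneric("trainAccuracy",
           function(object) standardGeneric("trainAccuracy"))

#' Confusion matrix of a cross-validation report
#'
#' Pooled over test folds; rows are the actual classes, columns the
#' predicted classes, in scheme class order.
#' @param object a CVReport.
#' @param percent logical; row-normalize to percentages (rows sum to 100,
#'   empty actual classes yield a flagged all-zero row).
#' @return numeric matrix.
#' @export
setGeneric("confusionMatrix",
           function(object, percent = TRUE) standardGeneric("confusionMatrix"))
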