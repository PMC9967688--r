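#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a FeatureSet
#'
#' @param values numeric matrix, features x observations, with unique
#'   feature rownames.
#' @param info DataFrame (or data.frame) of per-feature provenance;
#'   must contain \code{family} and \code{band}.
#' @param labels DataFrame (or data.frame) of per-observation labels;
#'   must contain \code{condition}.
#' @param baseline logical flag: computed on baseline segments?
#' @return a \linkS4class{FeatureSet}.
#' @export
FeatureSet <- function(values, info, labels, baseline = FALSE) {
  info <- S4Vectors::DataFrame(info)
  rownames(info) <- rownames(values)
  labels <- S4Vectors::DataFrame(labels)
  rownames(labels) <- colnames(values)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    rowData = info, colData = labels)
  S4Vectors::metadata(se)$baseline <- baseline
  new("FeatureSet", se)
}

#' Feature values matrix (features x observations)
#' @param object a FeatureSet.
#' @return numeric matrix.
#' @export
featureValues <- function(object)
  SummarizedExperiment::assay(object, "values")

#' Per-feature provenance (family, band, ROI / pair, measure)
#' @param object a FeatureSet.
#' @return DataFrame.
#' @export
featureInfo <- function(object) SummarizedExperiment::rowData(object)

#' Per-observation labels (condition, participant, session, trial)
#' @param object a FeatureSet.
#' @return DataFrame.
#' @export
observationLabels <- function(object)
  SummarizedExperiment::colData(object)

#' Was this FeatureSet computed on baseline segments?
#' @param object a FeatureSet.
#' @return logical.
#' @export
isBaseline <- function(object)
  isTRUE(S4Vectors::metadata(object)$baseline)

#' @describeIn FeatureSet number of observations (columns).
#' @param object a FeatureSet.
#' @export
setMethod("observationCount", "FeatureSet", function(object) ncol(object))

#' @describeIn FeatureSet bands present among the features.
#' @export
setMethod("bandNames", "FeatureSet", function(object)
  unique(SummarizedExperiment::rowData(object)$band))

#' Concatenate feature families over the same observations
#'
#' Row-binds several FeatureSets that share identical observation
#' columns (same order, same labels).
#'
#' @param ... FeatureSets.
#' @return a \linkS4class{FeatureSet}.
#' @export
combineFeatures <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && is.list(sets[[1]]) && !is(sets[[1]], "FeatureSet"))
    sets <- sets[[1]]
  out <- do.call(rbind, lapply(sets, function(x) as(x, "SummarizedExperiment")))
  S4Vectors::metadata(out)$baseline <- isBaseline(sets[[1]])
  new("FeatureSet", out)
}

setMethod("show", "FeatureSet", function(object) {
  fams <- unique(SummarizedExperiment::rowData(object)$family)
  cat("FeatureSet:", nrow(object), "features x", ncol(object),
      "observations", if (isBaseline(object)) "(baseline segments)" else "",
      "\n")
  cat("  families:", paste(fams, collapse = ", "),
      "| bands:", paste(bandNames(object), collapse = ", "), "\n")
})
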