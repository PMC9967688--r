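#' @include AllClasses.R featureSet.R select.R classify.R
NULL

#' Write a FeatureSet as CSV (observations x features)
#'
#' Column names encode feature provenance (e.g. \code{msc.alpha.r1_r2},
#' \code{gc.beta.r3_to_r4}, \code{pow.delta.r5.abs}); a JSON sidecar
#' (\code{<path>.labels.json}) stores the per-observation labels.
#'
#' @param features a \linkS4class{FeatureSet}.
#' @param path output CSV path.
#' @return invisibly, the path.
#' @export
writeFeatureCSV <- function(features, path) {
  m <- t(featureValues(features))
  utils::write.csv(as.data.frame(m), path, row.names = FALSE)
  labels <- as.data.frame(observationLabels(features))
  jsonlite::write_json(labels, paste0(path, ".labels.json"),
                       dataframe = "columns", auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

## Reconstruct rowData provenance from deterministic feature names.
featureInfoFromNames <- function(nm) {
  parts <- strsplit(nm, ".", fixed = TRUE)
  fam <- vapply(parts, `[`, "", 1L)
  band <- vapply(parts, `[`, "", 2L)
  fam <- c(pow = "power", msc = "msc", gc = "gc")[fam]
  data.frame(family = unname(fam), band = band, stringsAsFactors = FALSE)
}

#' Read a FeatureSet written by \code{\link{writeFeatureCSV}}
#' @param path CSV path (sidecar expected alongside).
#' @return a \linkS4class{FeatureSet}.
#' @export
readFeatureCSV <- function(path) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  labels <- jsonlite::read_json(paste0(path, ".labels.json"),
                                simplifyVector = TRUE)
  FeatureSet(t(m), featureInfoFromNames(colnames(m)),
             as.data.frame(labels))
}

#' Write a trial's signals as plain-text TSV
#'
#' Two files: \code{<stem>_baseline.tsv} and \code{<stem>_emotional.tsv},
#' each ROIs x samples with ROI rownames.
#'
#' @param trial a \linkS4class{TrialRecording}.
#' @param stem output path stem.
#' @return invisibly, the two paths.
#' @export
writeTrialSignals <- function(trial, stem) {
  paths <- paste0(stem, c("_baseline.tsv", "_emotional.tsv"))
  for (i in 1:2) {
    m <- if (i == 1) trial@baselineSignal else trial@emotionalSignal
    rownames(m) <- paste0("roi", seq_len(nrow(m)))
    utils::write.table(m, paths[i], sep = "\t", col.names = FALSE,
                       quote = FALSE)
  }
  invisible(paths)
}

#' Read a channels x samples plain-text TSV signal matrix
#'
#' First column = channel names.  This is the text-based real-data entry
#' point (alongside in-memory matrices).
#'
#' @param path TSV path.
#' @return numeric matrix with channel rownames.
#' @export
readSignalMatrix <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = FALSE,
                         row.names = 1L)
  as.matrix(d)
}

#' Serialize a SelectionResult to JSON
#' @param result a \linkS4class{SelectionResult}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSelectionJSON <- function(result, path) {
  obj <- list(
    mode = result@mode, family = result@family,
    retained = result@retained,
    phase2P = as.list(result@phase2P[result@retained]),
    alphas = as.list(result@alphas),
    counts = countSummary(result))
  if (nrow(result@phase1P))
    obj$phase1P <- as.data.frame(result@phase1P)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a CVReport to JSON
#' @param report a \linkS4class{CVReport}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeCVReportJSON <- function(report, path) {
  obj <- list(
    scheme = report@scheme, classOrder = report@classOrder,
    k = report@k, seed = report@seed, nPairwise = report@nPairwise,
    foldTrain = report@foldTrain, foldTest = report@foldTest,
    trainMean = mean(report@foldTrain), testMean = mean(report@foldTest),
    confusionCounts = report@confusionCounts,
    confusionPercent = round(confusionMatrix(report), 4),
    hyperparams = report@hyperparams)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Serialize a SyntheticSpec to JSON
#'
#' Gains, couplings, noise level and seed, as a plain JSON object the
#' schedule CSV can be paired with.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSyntheticSpecJSON <- function(spec, path) {
  obj <- list(
    conditions = spec@conditions,
    bandNames = spec@bandNames,
    powerGains = lapply(spec@powerGains, function(g) as.data.frame(g)),
    coherence = spec@coherence,
    directed = spec@directed,
    noiseSd = spec@noiseSd,
    seed = spec@seed)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
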