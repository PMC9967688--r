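#' @include AllClasses.R generate.R preprocess.R powerFeatures.R mscFeatures.R granger.R select.R classify.R io.R
NULL

#' Assemble a pipeline configuration
#'
#' One list drives every stage.  Defaults run the shipped synthetic
#' preset end to end at a reduced cohort size; pass a full
#' \code{\link{studyDesign}} for study-scale runs.
#'
#' @param design a \linkS4class{StudyDesign}.
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param seed global seed used by every random stage.
#' @param families feature families to compute ("power", "msc", "gc").
#' @param modes selection regimes to run.
#' @param schemes labeling schemes to evaluate.
#' @param k folds.
#' @param cost SVM cost.
#' @param arOrder Granger AR order.
#' @param gcRule Granger decision rule.
#' @param alphaPhase1,alphaPhase2 selection thresholds.
#' @param includeBaseline keep baseline tensors (required for the
#'   normalized mode).
#' @param writeSignals also write every trial's signals as TSV.
#' @return named list (a validated pipeline configuration).
#' @export
pipelineConfig <- function(design = studyDesign(nParticipants = 2L,
                                                nSessions = 1L,
                                                trialsPerSession = 25L),
                           spec = defaultSyntheticSpec(design),
                           seed = 42L,
                           families = c("power", "msc", "gc"),
                           modes = c("non_normalized", "normalized"),
                           schemes = c("arousal", "valence", "emotion"),
                           k = 5L, cost = 1, arOrder = 5L,
                           gcRule = "dof_adjusted",
                           alphaPhase1 = 0.05, alphaPhase2 = 0.01,
                           includeBaseline = TRUE,
                           writeSignals = FALSE) {
  config <- list(design = design, spec = spec, seed = as.integer(seed),
                 families = families, modes = modes, schemes = schemes,
                 k = as.integer(k), cost = cost,
                 arOrder = as.integer(arOrder), gcRule = gcRule,
                 alphaPhase1 = alphaPhase1, alphaPhase2 = alphaPhase2,
                 includeBaseline = includeBaseline,
                 writeSignals = writeSignals)
  validatePipelineConfig(config)
  config
}

#' Validate a pipeline configuration
#'
#' Checks field presence, types and value domains before any stage
#' runs; stops with an informative message otherwise.
#'
#' @param config a list as produced by \code{\link{pipelineConfig}} (or
#'   read from YAML via \code{\link{readPipelineConfig}}).
#' @return invisibly TRUE.
#' @export
validatePipelineConfig <- function(config) {
  need <- c("design", "spec", "seed", "families", "modes", "schemes",
            "k", "cost", "arOrder", "gcRule", "alphaPhase1",
            "alphaPhase2", "includeBaseline", "writeSignals")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config fields missing: ", paste(missing, collapse = ", "))
  stopifnot(is(config$design, "StudyDesign"),
            is(config$spec, "SyntheticSpec"))
  validObject(config$design); validObject(config$spec)
  if (!all(config$families %in% c("power", "msc", "gc")))
    stop("families must be among power, msc, gc")
  if (!all(config$modes %in% c("non_normalized", "normalized")))
    stop("modes must be among non_normalized, normalized")
  if (!all(config$schemes %in% c("arousal", "valence", "emotion")))
    stop("schemes must be among arousal, valence, emotion")
  if (config$k < 2L) stop("k must be >= 2")
  if ("normalized" %in% config$modes && !config$includeBaseline)
    stop("normalized mode requires includeBaseline = TRUE")
  invisible(TRUE)
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields (seed, families, modes, schemes, k, cost, arOrder,
#' gcRule, alphas, includeBaseline) plus a \code{design} block of
#' \code{\link{studyDesign}} arguments.  The synthetic spec is the
#' shipped preset unless \code{spec: none} requests an effect-free one.
#'
#' @param path YAML file.
#' @return a validated configuration list.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  design <- do.call(studyDesign, as.list(y$design))
  spec <- if (identical(y$spec, "none")) syntheticSpec(design) else
    defaultSyntheticSpec(design)
  args <- y[setdiff(names(y), c("design", "spec"))]
  do.call(pipelineConfig, c(list(design = design, spec = spec), args))
}

## FNV-1a hash of the deparsed config, for provenance metadata.
configHash <- function(config) {
  s <- utf8ToInt(paste(deparse(config[setdiff(names(config),
                                              c("design", "spec"))]),
                       collapse = ""))
  h <- 2166136261
  for (b in s) h <- bitwXor(as.integer(h %% 2^31), b) * 16777619 %% 2^31
  sprintf("%08x", as.integer(abs(h) %% 2^31))
}

stageLog <- function(quiet, ...) if (!quiet) message("[EmoConn] ", ...)

#' Run the analysis pipeline
#'
#' Orchestrates the stages \code{synth} (generate the synthetic cohort),
#' \code{preprocess} (observation tensors), \code{features} (the
#' requested families), \code{select} (the requested regimes),
#' \code{classify} (CV per family, mode and scheme), or \code{all}.
#' Later stages need the in-memory \code{state} of the earlier ones
#' (returned by this function) and stop with a missing-input error
#' otherwise.  Every artifact is written under \code{outdir} together
#' with provenance metadata (config hash, seed); rerunning an identical
#' configuration reproduces the outputs byte for byte.  Existing files
#' are never overwritten unless \code{overwrite = TRUE}.
#'
#' @param config configuration from \code{\link{pipelineConfig}}.
#' @param stage one of synth, preprocess, features, select, classify, all.
#' @param outdir output directory (created if needed).
#' @param state state list from a previous call (for stage-wise runs).
#' @param quiet suppress progress messages.
#' @param overwrite allow overwriting existing artifacts.
#' @return invisibly, the updated state list (fields: schedule, trials,
#'   obs, features, baselineFeatures, selections, reports, outputs).
#' @export
runPipeline <- function(config = pipelineConfig(),
                        stage = c("all", "synth", "preprocess",
                                  "features", "select", "classify"),
                        outdir = tempfile("emoconn_run_"),
                        state = list(), quiet = FALSE,
                        overwrite = FALSE) {
  stage <- match.arg(stage)
  validatePipelineConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  emit <- function(name, writer) {
    path <- file.path(outdir, name)
    if (file.exists(path) && !overwrite)
      stop("refusing to overwrite existing artifact: ", path)
    writer(path)
    state$outputs <<- c(state$outputs, path)
    path
  }
  jsonlite::write_json(
    list(configHash = configHash(config), seed = config$seed,
         stage = stage, package = "EmoConn",
         version = as.character(utils::packageVersion("EmoConn"))),
    file.path(outdir, paste0("provenance_", stage, ".json")),
    auto_unbox = TRUE)

  stages <- if (stage == "all")
    c("synth", "preprocess", "features", "select", "classify") else stage

  if ("synth" %in% stages) {
    stageLog(quiet, "synth: generating ", nTrials(config$design), " trials")
    state$trials <- generateCohort(config$design, config$spec,
                                   seed = config$seed)
    state$schedule <- attr(state$trials, "schedule")
    emit("schedule.csv", function(p)
      utils::write.csv(state$schedule, p, row.names = FALSE))
    emit("planted_truth.csv", function(p)
      utils::write.csv(plantedTruth(config$spec), p, row.names = FALSE))
    emit("synthetic_spec.json", function(p)
      writeSyntheticSpecJSON(config$spec, p))
    if (config$writeSignals) {
      sigDir <- file.path(outdir, "signals")
      dir.create(sigDir, showWarnings = FALSE)
      for (i in seq_along(state$trials))
        writeTrialSignals(state$trials[[i]],
                          file.path(sigDir, sprintf("trial%04d", i)))
    }
  }

  if ("preprocess" %in% stages) {
    if (is.null(state$trials))
      stop("missing input for 'preprocess': run the 'synth' stage first")
    stageLog(quiet, "preprocess: building observation tensors")
    state$obs <- buildObservationSet(
      state$trials, includeBaseline = config$includeBaseline)
    emit("exclusions.csv", function(p)
      utils::write.csv(exclusionLog(state$obs), p, row.names = FALSE))
    emit("observations.csv", function(p)
      utils::write.csv(as.data.frame(observationInfo(state$obs)), p,
                       row.names = FALSE))
  }

  if ("features" %in% stages) {
    if (is.null(state$obs))
      stop("missing input for 'features': run the 'preprocess' stage first")
    state$features <- list(); state$baselineFeatures <- list()
    for (fam in config$families) {
      stageLog(quiet, "features: ", fam)
      extract <- function(segment) switch(fam,
        power = bandPowerFeatures(state$obs, segment = segment),
        msc = mscFeatures(state$obs, segment = segment),
        gc = gcFeatures(state$obs, order = config$arOrder,
                        rule = config$gcRule, segment = segment))
      state$features[[fam]] <- extract("emotional")
      emit(paste0("features_", fam, ".csv"), function(p)
        writeFeatureCSV(state$features[[fam]], p))
      if (config$includeBaseline) {
        state$baselineFeatures[[fam]] <- extract("baseline")
        emit(paste0("features_", fam, "_baseline.csv"), function(p)
          writeFeatureCSV(state$baselineFeatures[[fam]], p))
      }
    }
  }

  if ("select" %in% stages) {
    if (is.null(state$features))
      stop("missing input for 'select': run the 'features' stage first")
    state$selections <- list()
    for (fam in config$families) for (mode in config$modes) {
      stageLog(quiet, "select: ", fam, " / ", mode)
      sel <- runSelection(
        state$features[[fam]],
        baselineFeatures = state$baselineFeatures[[fam]],
        mode = mode, alphaPhase1 = config$alphaPhase1,
        alphaPhase2 = config$alphaPhase2)
      key <- paste(fam, mode, sep = ".")
      state$selections[[key]] <- sel
      emit(paste0("selection_", fam, "_", mode, ".json"), function(p)
        writeSelectionJSON(sel$result, p))
    }
    emit("feature_counts.csv", function(p)
      utils::write.csv(featureCountTable(
        lapply(state$selections, `[[`, "result")), p, row.names = FALSE))
  }

  if ("classify" %in% stages) {
    if (is.null(state$selections))
      stop("missing input for 'classify': run the 'select' stage first")
    state$reports <- list()
    for (key in names(state$selections)) for (sc in config$schemes) {
      stageLog(quiet, "classify: ", key, " / ", sc)
      rep <- crossValidate(state$selections[[key]]$features, scheme = sc,
                           k = config$k, seed = config$seed,
                           cost = config$cost)
      rkey <- paste(key, sc, sep = ".")
      state$reports[[rkey]] <- rep
      emit(paste0("cv_", gsub("\\.", "_", rkey), ".json"), function(p)
        writeCVReportJSON(rep, p))
      emit(paste0("confusion_", gsub("\\.", "_", rkey), ".csv"),
           function(p) utils::write.csv(
             round(confusionMatrix(rep), 4), p))
    }
    emit("accuracy_summary.csv", function(p)
      utils::write.csv(accuracyTable(state$reports), p, row.names = FALSE))
  }

  invisible(state)
}
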