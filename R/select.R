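#' @include AllClasses.R AllGenerics.R featureSet.R
NULL

## Row-wise paired t-test p-values (columns of xa and xb are aligned
## trial pairs).  NA where the difference variance is zero.
rowPairedTTestP <- function(xa, xb) {
  d <- xa - xb
  n <- ncol(d)
  m <- rowMeans(d)
  v <- rowSums((d - m)^2) / (n - 1L)
  tstat <- m / sqrt(v / n)
  p <- 2 * stats::pt(abs(tstat), n - 1L, lower.tail = FALSE)
  p[v <= 0] <- NA_real_
  p
}

## Row-wise two-sample pooled-variance (classic Student) t-test
## p-values.  xa, xb: features x observations matrices.  Returns NA for
## rows where the pooled variance is zero (undefined statistic).
rowTTestP <- function(xa, xb) {
  na <- ncol(xa); nb <- ncol(xb)
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  va <- rowSums((xa - ma)^2); vb <- rowSums((xb - mb)^2)
  df <- na + nb - 2L
  sp2 <- (va + vb) / df
  se <- sqrt(sp2 * (1 / na + 1 / nb))
  tstat <- (ma - mb) / se
  p <- 2 * stats::pt(abs(tstat), df, lower.tail = FALSE)
  p[sp2 <= 0] <- NA_real_
  p
}

## Row-wise one-way (single-factor) ANOVA p-values across the groups of
## `groups`.  Returns NA where the within-group variance is zero
## everywhere (F undefined).
rowAnovaP <- function(values, groups) {
  groups <- as.factor(groups)
  k <- nlevels(groups)
  n <- ncol(values)
  gm <- rowMeans(values)
  ssb <- 0; ssw <- 0
  for (lev in levels(groups)) {
    cols <- which(groups == lev)
    m <- rowMeans(values[, cols, drop = FALSE])
    ssb <- ssb + length(cols) * (m - gm)^2
    ssw <- ssw + rowSums((values[, cols, drop = FALSE] - m)^2)
  }
  df1 <- k - 1L; df2 <- n - k
  Fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  p[ssw <= 0] <- NA_real_
  p
}

#' Phase 1: baseline-aware t-test screening
#'
#' For each of the non-neutral conditions separately, a two-sample
#' two-sided pooled-variance Student's t-test compares that condition's
#' emotional-segment rows of every feature column against the aligned
#' baseline-segment rows.  A feature survives iff p < alpha for all
#' non-neutral conditions (the "shared across conditions" intersection
#' rule).  Neutral observations are excluded from testing, since no
#' difference between neutral playing and its baseline is expected.
#' Features whose statistic is undefined (zero variance in both groups)
#' are dropped and logged.
#'
#' @param emotional a \linkS4class{FeatureSet} (emotional segments).
#' @param baseline the aligned baseline \linkS4class{FeatureSet} (same
#'   features, same observation order).
#' @param alpha significance threshold (default 0.05).
#' @param neutralLabel condition label to skip (default "neutral").
#' @param paired use a paired t-test over the aligned trial pairs
#'   instead of the default two-sample test.  Off by default: the
#'   screening procedure is specified as a plain two-sample comparison,
#'   even though rows are aligned.
#' @return list with \code{mask} (logical per feature), \code{p}
#'   (features x conditions matrix) and \code{dropped} (character).
#' @export
phase1BaselineTtest <- function(emotional, baseline, alpha = 0.05,
                                neutralLabel = "neutral",
                                paired = FALSE) {
  stopifnot(identical(rownames(emotional), rownames(baseline)),
            ncol(emotional) == ncol(baseline))
  ve <- featureValues(emotional)
  vb <- featureValues(baseline)
  cond <- observationLabels(emotional)$condition
  conds <- setdiff(unique(cond), neutralLabel)
  p <- matrix(NA_real_, nrow(ve), length(conds),
              dimnames = list(rownames(ve), conds))
  testFun <- if (paired) rowPairedTTestP else rowTTestP
  for (cc in conds) {
    cols <- which(cond == cc)
    p[, cc] <- testFun(ve[, cols, drop = FALSE], vb[, cols, drop = FALSE])
  }
  undefined <- apply(p, 1L, function(r) anyNA(r))
  mask <- !undefined & apply(p < alpha, 1L, all)
  list(mask = mask, p = p, dropped = rownames(ve)[undefined])
}

#' Phase 2: one-way ANOVA across the condition groups
#'
#' Per feature, a single-factor ANOVA across all condition groups
#' (including neutral); the feature is retained iff p < alpha.  No
#' multiple-testing correction is applied.  Features with undefined F
#' (zero within-group variance with equal means, e.g. constant columns)
#' are dropped and logged.
#'
#' @param features a \linkS4class{FeatureSet}.
#' @param alpha significance threshold (default 0.01).
#' @return list with \code{mask}, \code{p} (named numeric) and
#'   \code{dropped}.
#' @export
phase2Anova <- function(features, alpha = 0.01) {
  v <- featureValues(features)
  cond <- observationLabels(features)$condition
  if (min(table(cond)) < 2L) stop("need >= 2 observations per condition")
  p <- rowAnovaP(v, cond)
  names(p) <- rownames(v)
  undefined <- is.na(p)
  mask <- !undefined & p < alpha
  list(mask = mask, p = p, dropped = rownames(v)[undefined])
}

#' Run a feature-selection regime
#'
#' \code{mode = "normalized"}: phase-1 baseline t-test screening, then
#' phase-2 ANOVA on the survivors.  \code{mode = "non_normalized"}:
#' phase-2 ANOVA only.  "Normalized" means baseline-aware screening, not
#' arithmetic normalization; an optional baseline-subtraction transform
#' (\code{subtractBaseline}) exists but is off by default.  The reduced FeatureSet concatenates the
#' retained features across all bands (and per-band column groups for
#' the power family).  Selection depends only on values and labels,
#' never on row order.
#'
#' @param features emotional-segment \linkS4class{FeatureSet}.
#' @param baselineFeatures aligned baseline \linkS4class{FeatureSet}
#'   (required for normalized mode).
#' @param mode "normalized" or "non_normalized".
#' @param alphaPhase1,alphaPhase2 thresholds (defaults 0.05, 0.01).
#' @param neutralLabel condition excluded from phase 1.
#' @param paired passed to \code{\link{phase1BaselineTtest}}.
#' @param subtractBaseline replace the feature values by
#'   emotional - baseline before any testing (off by default).
#' @return list with \code{result} (a \linkS4class{SelectionResult}) and
#'   \code{features} (the reduced \linkS4class{FeatureSet}).
#' @export
runSelection <- function(features, baselineFeatures = NULL,
                         mode = c("non_normalized", "normalized"),
                         alphaPhase1 = 0.05, alphaPhase2 = 0.01,
                         neutralLabel = "neutral", paired = FALSE,
                         subtractBaseline = FALSE) {
  mode <- match.arg(mode)
  if (subtractBaseline) {
    if (is.null(baselineFeatures))
      stop("subtractBaseline needs the aligned baseline FeatureSet")
    diffVals <- featureValues(features) - featureValues(baselineFeatures)
    features <- FeatureSet(diffVals, featureInfo(features),
                           observationLabels(features))
  }
  fam <- unique(featureInfo(features)$family)
  bandOf <- as.character(featureInfo(features)$band)
  names(bandOf) <- rownames(features)
  dropped <- character(0)
  p1 <- matrix(NA_real_, 0, 0)

  if (mode == "normalized") {
    if (is.null(baselineFeatures))
      stop("normalized mode needs the aligned baseline FeatureSet")
    ph1 <- phase1BaselineTtest(features, baselineFeatures, alphaPhase1,
                               neutralLabel, paired = paired)
    p1 <- ph1$p
    dropped <- c(dropped, ph1$dropped)
    survivors <- features[ph1$mask, ]
    if (!nrow(survivors))
      stop("zero features retained after phase 1; review thresholds or ",
           "effect sizes")
  } else {
    survivors <- features
  }

  ph2 <- phase2Anova(survivors, alphaPhase2)
  dropped <- c(dropped, ph2$dropped)
  retained <- rownames(survivors)[ph2$mask]
  if (!length(retained))
    stop("zero features retained; review thresholds or effect sizes")

  res <- new("SelectionResult",
             mode = mode, family = paste(fam, collapse = "+"),
             retained = retained, phase1P = p1, phase2P = ph2$p,
             bandOf = bandOf,
             alphas = c(phase1 = alphaPhase1, phase2 = alphaPhase2),
             droppedLog = data.frame(feature = unique(dropped),
                                     stringsAsFactors = FALSE))
  list(result = res, features = features[retained, ])
}

#' @describeIn runSelection retained feature names.
#' @param object a SelectionResult.
#' @export
setMethod("retainedFeatures", "SelectionResult",
          function(object) object@retained)

#' @describeIn runSelection per-band retained counts, one row per phase.
#' @export
setMethod("countSummary", "SelectionResult", function(object) {
  bands <- unique(unname(object@bandOf))
  rows <- list(input = names(object@bandOf))
  if (object@mode == "normalized" && nrow(object@phase1P))
    rows$phase1 <- rownames(object@phase1P)[
      apply(object@phase1P < object@alphas["phase1"], 1L,
            function(r) all(!is.na(r)) && all(r))]
  rows$retained <- object@retained
  out <- do.call(rbind, lapply(rows, function(nm) {
    cnt <- table(factor(object@bandOf[nm], levels = bands))
    c(as.integer(cnt), total = length(nm))
  }))
  colnames(out) <- c(bands, "total")
  as.data.frame(out)
})

setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult (", object@mode, ", family ", object@family, "): ",
      length(object@retained), " of ", length(object@bandOf),
      " features retained\n", sep = "")
  print(countSummary(object))
})

#' Retained-feature count table across families and modes
#'
#' Combines several selection results into the standard summary layout:
#' one row per (family, mode, phase), one column per band plus a total.
#'
#' @param results list of \linkS4class{SelectionResult}.
#' @return data.frame.
#' @export
featureCountTable <- function(results) {
  out <- do.call(rbind, lapply(results, function(r) {
    cs <- countSummary(r)
    cbind(family = r@family, mode = r@mode, phase = rownames(cs), cs,
          row.names = NULL)
  }))
  rownames(out) <- NULL
  out
}
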