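#' @include AllClasses.R AllGenerics.R filters.R
NULL

## Spectral radius of the VAR companion matrix implied by the directed
## couplings (treating every condition's couplings as one process; a
## conservative bound since conditions never mix within a trial).
companionSpectralRadius <- function(directed) {
  if (!nrow(directed)) return(0)
  nroi <- max(directed$from, directed$to)
  p <- max(directed$lag)
  A <- array(0, c(nroi, nroi, p))
  for (r in seq_len(nrow(directed)))
    A[directed$to[r], directed$from[r], directed$lag[r]] <-
      A[directed$to[r], directed$from[r], directed$lag[r]] +
      abs(directed$coeff[r])
  C <- matrix(0, nroi * p, nroi * p)
  for (k in seq_len(p)) C[seq_len(nroi), (k - 1) * nroi + seq_len(nroi)] <- A[, , k]
  if (p > 1)
    C[nroi + seq_len(nroi * (p - 1)), seq_len(nroi * (p - 1))] <-
      diag(nroi * (p - 1))
  max(Mod(eigen(C, only.values = TRUE)$values))
}

#' Construct a SyntheticSpec
#'
#' @param design a \linkS4class{StudyDesign} fixing conditions, bands are
#'   taken from \code{\link{bandDefinitions}}.
#' @param powerGains named list (one entry per condition, in design
#'   order) of bands x ROIs gain matrices; missing conditions default to
#'   all-ones.
#' @param coherence data.frame(condition, band, roi1, roi2, strength).
#' @param directed data.frame(condition, from, to, lag, coeff).
#' @param noiseSd white observation-noise sd.
#' @param seed default generator seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @seealso \code{\link{defaultSyntheticSpec}} for the shipped preset.
#' @export
syntheticSpec <- function(design = studyDesign(), powerGains = list(),
                          coherence = emptyCoherence(),
                          directed = emptyDirected(),
                          noiseSd = 0.1, seed = 42L) {
  bands <- bandDefinitions()$name
  conds <- conditions(design)
  gains <- lapply(conds, function(cc) {
    g <- powerGains[[cc]]
    if (is.null(g)) {
      g <- matrix(1, length(bands), design@nRois,
                  dimnames = list(bands, NULL))
    }
    g
  })
  names(gains) <- conds
  new("SyntheticSpec",
      conditions = conds, powerGains = gains,
      coherence = coherence, directed = directed,
      noiseSd = noiseSd, bandNames = bands, seed = as.integer(seed))
}

#' @rdname syntheticSpec
#' @export
emptyCoherence <- function() {
  data.frame(condition = character(), band = character(),
             roi1 = integer(), roi2 = integer(), strength = numeric(),
             stringsAsFactors = FALSE)
}

#' @rdname syntheticSpec
#' @export
emptyDirected <- function() {
  data.frame(condition = character(), from = integer(), to = integer(),
             lag = integer(), coeff = numeric(), stringsAsFactors = FALSE)
}

#' The shipped synthetic preset with planted condition effects
#'
#' Encodes the study conditions the generator emulates.  Design choices
#' (fixed a priori from effect-size arithmetic, discussed in the methods
#' vignette):
#' \itemize{
#'   \item \emph{Common graded coherence}: ROI pairs (1,2) and (3,4)
#'     carry a shared-source coupling in alpha and beta for all four
#'     non-neutral conditions, with strength graded by condition
#'     (distressed 0.95, excited 0.85, depressed 0.75, relaxed 0.65).
#'     Because every non-neutral condition differs from baseline here,
#'     these features survive baseline-aware (phase-1) selection.
#'   \item \emph{Condition-specific coherence}: one extra pair per
#'     condition (beta 5-6 distressed, beta 7-8 excited, theta 5-6
#'     depressed, theta 7-8 relaxed, strength 0.85) that only the
#'     ANOVA-only regime can retain.
#'   \item \emph{Directed couplings}: a common ROI 10 -> 7 edge (lag 3)
#'     with condition-graded coefficient 0.5/0.4/0.3/0.2 plus two
#'     condition-specific edges each (distressed 3->7 and 5->10, excited
#'     the reverses, depressed 4->8 and 6->10, relaxed the reverses;
#'     lag 2, coefficient 0.55).  Directed edges avoid the
#'     shared-source pairs and the power-plant ROI so the plants stay
#'     orthogonal in band power.
#'   \item \emph{Band power}: alpha-band amplitude gains on ROI 9
#'     (1.25/1.22/1.19/1.16): every condition differs strongly from
#'     baseline (so baseline-aware selection keeps the features) while
#'     the between-condition spread stays small, keeping power features
#'     less class-informative than the connectivity plants, the ordering
#'     the study design emulates.
#' }
#' Coupling mixes are variance preserving, so coherence and directed
#' plants do not move band power.  Neutral keeps baseline parameters
#' everywhere.
#'
#' @param design a \linkS4class{StudyDesign} (default study grid).
#' @param noiseSd observation-noise sd (default 0.1).
#' @param seed default generator seed (default 42).
#' @return a \linkS4class{SyntheticSpec}.
#' @export
defaultSyntheticSpec <- function(design = studyDesign(), noiseSd = 0.1,
                                 seed = 42L) {
  bands <- bandDefinitions()$name
  conds  <- c("distressed", "excited", "depressed", "relaxed")
  stopifnot(all(c(conds, "neutral") %in% conditions(design)))
  # strong against baseline (phase-1 must keep these) but with a small
  # between-condition spread, so power carries less class information
  # than the connectivity plants
  gainLevels <- c(distressed = 1.25, excited = 1.22,
                  depressed = 1.19, relaxed = 1.16)
  gains <- lapply(conds, function(cc) {
    g <- matrix(1, length(bands), design@nRois, dimnames = list(bands, NULL))
    g["alpha", 9L] <- gainLevels[[cc]]
    g
  })
  names(gains) <- conds

  cohLevels <- c(distressed = 0.95, excited = 0.85,
                 depressed = 0.75, relaxed = 0.65)
  common <- do.call(rbind, lapply(conds, function(cc)
    data.frame(condition = cc, band = rep(c("alpha", "beta"), each = 2),
               roi1 = c(1L, 3L, 1L, 3L), roi2 = c(2L, 4L, 2L, 4L),
               strength = cohLevels[[cc]], stringsAsFactors = FALSE)))
  specific <- data.frame(
    condition = conds,
    band = c("beta", "beta", "theta", "theta"),
    roi1 = c(5L, 7L, 5L, 7L), roi2 = c(6L, 8L, 6L, 8L),
    strength = 0.85, stringsAsFactors = FALSE)

  # directed edges live on ROI pairs that carry no shared-source
  # coupling, and never use ROI 9 (the power-plant ROI) as a source:
  # lagged-copy mixing is variance preserving only when source and
  # target are independent and equal-variance, and keeping the supports
  # disjoint stops connectivity plants from leaking into band power
  gcLevels <- c(distressed = 0.5, excited = 0.4,
                depressed = 0.3, relaxed = 0.2)
  dirCommon <- data.frame(
    condition = conds, from = 10L, to = 7L, lag = 3L,
    coeff = unname(gcLevels[conds]), stringsAsFactors = FALSE)
  dirSpecific <- data.frame(
    condition = rep(conds, each = 2),
    from = c(3L, 5L, 7L, 10L, 4L, 6L, 8L, 10L),
    to   = c(7L, 10L, 3L, 5L, 8L, 10L, 4L, 6L),
    lag = 2L, coeff = 0.55, stringsAsFactors = FALSE)

  syntheticSpec(design, powerGains = gains,
                coherence = rbind(common, specific),
                directed = rbind(dirCommon, dirSpecific),
                noiseSd = noiseSd, seed = seed)
}

#' @describeIn syntheticSpec condition labels covered by the spec.
#' @param object a SyntheticSpec.
#' @export
setMethod("conditions", "SyntheticSpec", function(object) object@conditions)

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec over", length(object@conditions), "conditions\n")
  planted <- plantedTruth(object)
  cat("  planted effects:", nrow(planted), "(",
      sum(planted$type == "power"), "power,",
      sum(planted$type == "coherence"), "coherence,",
      sum(planted$type == "directed"), "directed )\n")
  cat("  observation noise sd:", object@noiseSd,
      " default seed:", object@seed, "\n")
})

#' @describeIn plantedTruth enumerate parameters deviating from baseline.
#' @export
setMethod("plantedTruth", "SyntheticSpec", function(object) {
  base <- object@powerGains[["neutral"]]
  out <- list()
  for (cc in setdiff(object@conditions, "neutral")) {
    g <- object@powerGains[[cc]]
    d <- which(g != base, arr.ind = TRUE)
    if (nrow(d))
      out[[length(out) + 1L]] <- data.frame(
        type = "power", condition = cc,
        band = object@bandNames[d[, 1]],
        roi1 = as.integer(d[, 2]), roi2 = NA_integer_,
        stringsAsFactors = FALSE)
  }
  coh <- object@coherence
  coh <- coh[coh$strength > 0 & coh$condition != "neutral", , drop = FALSE]
  if (nrow(coh))
    out[[length(out) + 1L]] <- data.frame(
      type = "coherence", condition = coh$condition, band = coh$band,
      roi1 = pmin(coh$roi1, coh$roi2), roi2 = pmax(coh$roi1, coh$roi2),
      stringsAsFactors = FALSE)
  dir <- object@directed
  dir <- dir[dir$coeff != 0 & dir$condition != "neutral", , drop = FALSE]
  if (nrow(dir))
    out[[length(out) + 1L]] <- data.frame(
      type = "directed", condition = dir$condition, band = NA_character_,
      roi1 = dir$from, roi2 = dir$to, stringsAsFactors = FALSE)
  if (!length(out))
    return(data.frame(type = character(), condition = character(),
                      band = character(), roi1 = integer(),
                      roi2 = integer(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
})

#' Feature names implied by planted truth entries
#'
#' Maps a \code{\link{plantedTruth}} record onto the deterministic
#' feature-column names produced by the feature extractors, for
#' selection-recovery checks.  Directed entries (broadband plants) map to
#' the corresponding Granger feature in every band.
#'
#' @param truth data.frame as returned by \code{plantedTruth}.
#' @return character vector of feature names (unique).
#' @export
truthFeatureNames <- function(truth) {
  bands <- bandDefinitions()$name
  nm <- character(0)
  for (r in seq_len(nrow(truth))) {
    tr <- truth[r, ]
    nm <- c(nm, switch(tr$type,
      power = paste0("pow.", tr$band, ".r", tr$roi1, ".abs"),
      coherence = paste0("msc.", tr$band, ".r", tr$roi1, "_r", tr$roi2),
      directed = paste0("gc.", bands, ".r", tr$roi1, "_to_r", tr$roi2)))
  }
  unique(nm)
}
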