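#' @include AllClasses.R spectra.R featureSet.R preprocess.R
NULL

#' Magnitude-squared-coherence connectivity features
#'
#' For every band and observation, builds the symmetric 10 x 10
#' coherence connectivity matrix from the 8-window ensemble spectral
#' estimate and vectorizes its upper triangle in row-major order
#' ((1,2), (1,3), ..., (1,10), (2,3), ...) into 45 named columns per
#' band (e.g. \code{msc.alpha.r1_r2}).  The diagonal (self-coherence,
#' identically 1) is not stored; \code{\link{coherenceMatrix}} restores
#' the full matrix.
#'
#' @param obs an \linkS4class{ObservationSet}.
#' @param segment "emotional" or "baseline".
#' @return a \linkS4class{FeatureSet} of family \code{"msc"} with
#'   45 features per band.
#' @export
mscFeatures <- function(obs, segment = c("emotional", "baseline")) {
  segment <- match.arg(segment)
  tensors <- if (segment == "emotional") obs@bandTensors else
    obs@baselineTensors
  if (!length(tensors)) stop("requested segment not present in this set")
  rate <- obs@samplingRate
  bd <- obs@bands
  n <- observationCount(obs)
  nroi <- dim(tensors[[1]])[2]
  pairs <- roiPairs(nroi)

  vals <- NULL; info <- NULL
  for (bi in seq_len(nrow(bd))) {
    b <- bd$name[bi]
    block <- matrix(NA_real_, nrow(pairs), n)
    for (i in seq_len(n)) {
      w <- tensors[[b]][i, , , , drop = TRUE]
      dim(w) <- dim(tensors[[b]])[2:4]
      se <- estimateSpectra(w, rate)
      keep <- which(se@freq >= bd$low[bi] & se@freq < bd$high[bi])
      den <- se@auto[keep, pairs[, 1], drop = FALSE] *
        se@auto[keep, pairs[, 2], drop = FALSE]
      num <- Mod(se@cross[keep, , drop = FALSE])^2
      g <- ifelse(den > 0, num / den, 0)
      block[, i] <- colMeans(pmin(g, 1))
    }
    rownames(block) <- paste0("msc.", b, ".r", pairs[, 1], "_r", pairs[, 2])
    vals <- rbind(vals, block)
    info <- rbind(info, data.frame(
      family = "msc", band = b, roi1 = pairs[, 1], roi2 = pairs[, 2],
      stringsAsFactors = FALSE))
  }
  FeatureSet(vals, info, as.data.frame(obs@rowData),
             baseline = segment == "baseline")
}

#' Rebuild a coherence connectivity matrix from its vectorized row
#'
#' Inverse of the upper-triangle vectorization used by
#' \code{\link{mscFeatures}}: returns the symmetric matrix with
#' diagonal 1.
#'
#' @param values numeric vector of length nroi (nroi - 1) / 2 in
#'   row-major upper-triangle order.
#' @param nroi number of ROIs.
#' @return nroi x nroi symmetric matrix.
#' @export
coherenceMatrix <- function(values, nroi = 10L) {
  pairs <- roiPairs(nroi)
  stopifnot(length(values) == nrow(pairs))
  m <- diag(nroi)
  m[cbind(pairs[, 1], pairs[, 2])] <- values
  m[cbind(pairs[, 2], pairs[, 1])] <- values
  m
}
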