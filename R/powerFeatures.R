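#' @include AllClasses.R spectra.R featureSet.R preprocess.R
NULL

#' Absolute and relative band-power features
#'
#' Per observation, ROI and band: the absolute power is the mean
#' Hann-tapered periodogram power per frequency bin within the band's
#' range, averaged over the eight 3 s windows of the band-filtered
#' signal; the relative power divides it by the mean per-bin power of
#' the broadband signal over the entire 1-45 Hz range (zero denominator
#' yields relative power 0).  A zero-variance window contributes power
#' 0, never NaN.  Columns are ordered band-major, then ROI, then
#' abs/rel, giving 100 named features at the 5-band, 10-ROI defaults
#' (e.g. \code{pow.alpha.r3.abs}).  Scaling a signal by c multiplies
#' absolute powers by c^2 and leaves relative powers unchanged.
#'
#' @param obs an \linkS4class{ObservationSet}.
#' @param segment "emotional" or "baseline".
#' @return a \linkS4class{FeatureSet} of family \code{"power"}.
#' @export
bandPowerFeatures <- function(obs, segment = c("emotional", "baseline")) {
  segment <- match.arg(segment)
  tensors <- if (segment == "emotional") obs@bandTensors else
    obs@baselineTensors
  if (!length(tensors)) stop("requested segment not present in this set")
  denom <- if (segment == "emotional") obs@broadbandPower else
    obs@baselineBroadbandPower
  rate <- obs@samplingRate
  bd <- obs@bands
  n <- observationCount(obs)
  nroi <- dim(tensors[[1]])[2]

  vals <- NULL; info <- NULL
  for (bi in seq_len(nrow(bd))) {
    b <- bd$name[bi]
    absPow <- matrix(NA_real_, n, nroi)
    for (i in seq_len(n)) {
      w <- tensors[[b]][i, , , , drop = TRUE]
      dim(w) <- dim(tensors[[b]])[2:4]
      absPow[i, ] <- rowMeans(windowBandPower(w, rate, bd$low[bi], bd$high[bi]))
    }
    relPow <- ifelse(denom > 0, absPow / denom, 0)
    block <- matrix(NA_real_, 2L * nroi, n)
    nm <- character(2L * nroi)
    for (r in seq_len(nroi)) {
      block[2 * r - 1L, ] <- absPow[, r]
      block[2 * r, ]      <- relPow[, r]
      nm[2 * r - 1L] <- paste0("pow.", b, ".r", r, ".abs")
      nm[2 * r]      <- paste0("pow.", b, ".r", r, ".rel")
    }
    rownames(block) <- nm
    vals <- rbind(vals, block)
    info <- rbind(info, data.frame(
      family = "power", band = b, roi = rep(seq_len(nroi), each = 2),
      measure = rep(c("abs", "rel"), nroi), stringsAsFactors = FALSE))
  }
  FeatureSet(vals, info, as.data.frame(obs@rowData),
             baseline = segment == "baseline")
}
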