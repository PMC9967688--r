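#' @include AllClasses.R AllGenerics.R filters.R
NULL

#' Hann taper of length n
#' @param n window length in samples.
#' @return numeric vector.
#' @export
hannWindow <- function(n) 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))

## Per-window mean per-bin Hann-periodogram power in [low, high) Hz.
## windows: roi x nwin x wlen.  Returns roi x nwin.
windowBandPower <- function(windows, rate, low, high) {
  nroi <- dim(windows)[1]; nwin <- dim(windows)[2]; wlen <- dim(windows)[3]
  taper <- hannWindow(wlen)
  scale <- 1 / (sum(taper^2) * rate)
  freq <- (seq_len(wlen) - 1L) * rate / wlen
  keep <- which(freq >= low & freq < high)
  out <- matrix(0, nroi, nwin)
  for (w in seq_len(nwin)) {
    seg <- t(matrix(windows[, w, ], nroi, wlen)) * taper
    X <- stats::mvfft(seg)
    P <- (Mod(X[keep, , drop = FALSE])^2) * scale
    out[, w] <- colMeans(P)
  }
  out
}

## Upper-triangle ROI pairs in row-major order (1,2),(1,3),...,(2,3),...
roiPairs <- function(nroi) {
  if (nroi < 2L) return(matrix(integer(0), 0L, 2L))
  p <- t(utils::combn(nroi, 2L))
  storage.mode(p) <- "integer"
  p
}

#' Welch-style averaged spectra of one observation
#'
#' Computes Hann-tapered periodogram auto- and cross-spectra per 3 s
#' window and averages them across the window ensemble.  The frequency
#' grid has resolution rate / window-samples (1/3 Hz at the defaults).
#' With a single window the coherence estimator degenerates to 1
#' identically, so at least two windows are required.
#'
#' @param windows array ROIs x windows x window-samples (one observation
#'   of one band, or broadband).
#' @param rate sampling rate, Hz.
#' @return a \linkS4class{SpectralEstimate} covering frequencies up to
#'   the Nyquist rate.
#' @export
estimateSpectra <- function(windows, rate) {
  nroi <- dim(windows)[1]; nwin <- dim(windows)[2]; wlen <- dim(windows)[3]
  if (is.na(nwin) || nwin < 2L)
    stop("need >= 2 windows for an ensemble spectral estimate; ",
         "check the windowing configuration")
  taper <- hannWindow(wlen)
  scale <- 1 / (sum(taper^2) * rate)
  freq <- (seq_len(wlen) - 1L) * rate / wlen
  keep <- which(freq <= rate / 2)
  pairs <- roiPairs(nroi)
  auto <- matrix(0, length(keep), nroi)
  cross <- matrix(0 + 0i, length(keep), nrow(pairs))
  for (w in seq_len(nwin)) {
    seg <- t(matrix(windows[, w, ], nroi, wlen)) * taper
    X <- stats::mvfft(seg)[keep, , drop = FALSE]
    auto <- auto + Mod(X)^2 * scale
    cross <- cross + X[, pairs[, 1], drop = FALSE] *
      Conj(X[, pairs[, 2], drop = FALSE]) * scale
  }
  new("SpectralEstimate",
      freq = freq[keep], auto = auto / nwin, cross = cross / nwin,
      pairs = pairs, ensembleSize = as.integer(nwin))
}

setMethod("show", "SpectralEstimate", function(object) {
  cat("SpectralEstimate:", ncol(object@auto), "ROIs,",
      length(object@freq), "bins up to", max(object@freq), "Hz,",
      object@ensembleSize, "averaged windows\n")
})

#' Band-averaged magnitude-squared coherence
#'
#' Evaluates the squared magnitude of the ensemble-averaged
#' cross-spectrum over the product of the ensemble-averaged
#' auto-spectra, per frequency bin, and averages the bins with
#' low <= f < high.  Values lie in [0, 1]; bins where either
#' auto-spectrum is zero contribute 0.  A signal paired with itself has
#' coherence exactly 1.  With L independent windows the estimator has a
#' known positive bias of about 1/L for independent signals.
#'
#' @param spectra a \linkS4class{SpectralEstimate}.
#' @param pair integer length-2, ROI indices (order irrelevant; equal
#'   indices give self-coherence).
#' @param band band name (looked up in \code{\link{bandDefinitions}}) or
#'   numeric c(low, high) in Hz.
#' @return numeric scalar in [0, 1].
#' @export
msc <- function(spectra, pair, band) {
  edges <- bandEdges(band)
  keep <- which(spectra@freq >= edges[1] & spectra@freq < edges[2])
  if (!length(keep)) stop("band outside the analysed frequency range")
  i <- min(pair); j <- max(pair)
  den <- spectra@auto[keep, i] * spectra@auto[keep, j]
  if (i == j) {
    num <- spectra@auto[keep, i]^2
  } else {
    pidx <- which(spectra@pairs[, 1] == i & spectra@pairs[, 2] == j)
    num <- Mod(spectra@cross[keep, pidx])^2
  }
  g <- ifelse(den > 0, num / den, 0)
  mean(pmin(g, 1))
}

## Resolve a band argument into c(low, high).
bandEdges <- function(band) {
  if (is.character(band)) {
    bd <- bandDefinitions()
    row <- match(band, bd$name)
    if (is.na(row)) stop("unknown band name: ", band)
    c(bd$low[row], bd$high[row])
  } else as.numeric(band)
}
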