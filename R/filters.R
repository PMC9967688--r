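#' @include AllClasses.R
NULL

#' Canonical EEG frequency bands
#'
#' The five sub-bands used throughout the pipeline: delta 1-4, theta 4-8,
#' alpha 8-12, beta 12-30 and gamma 30-45 Hz, plus (separately) the
#' 0.5-45 Hz broadband range used for the initial filter and the
#' relative-power denominator.
#'
#' @return data.frame with columns \code{name}, \code{low}, \code{high}.
#' @examples
#' bandDefinitions()
#' @export
bandDefinitions <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "beta", "gamma"),
    low  = c(1, 4, 8, 12, 30),
    high = c(4, 8, 12, 30, 45),
    stringsAsFactors = FALSE
  )
}

#' Broadband edges (Hz) used before sub-band decomposition
#' @return numeric length-2 vector (low, high).
#' @export
broadbandEdges <- function() c(0.5, 45)

## Transition width (Hz) for a band's FIR design: 1 Hz, narrowed near a
## low edge so that a tone one octave below the band is still rejected.
## Kept narrow because the forward-backward application squares the
## response, deepening the crossover dip between adjacent bands.
firTransition <- function(low) min(1, low / 2)

#' Design a windowed-sinc bandpass FIR filter
#'
#' Hamming-windowed sinc design (via \code{signal::fir1}) with an odd tap
#' count chosen for a transition width of at most 1 Hz (narrower near low
#' band edges).  The filter is linear phase; the pipeline always applies
#' it forward-backward, so the effective response is the squared
#' magnitude and the net phase is zero.
#'
#' @param low,high band edges in Hz, 0 < low < high < rate/2.
#' @param rate sampling rate in Hz.
#' @param transition transition width in Hz; default depends on \code{low}.
#' @return numeric vector of filter taps.
#' @export
firBandpass <- function(low, high, rate, transition = firTransition(low)) {
  if (!(low > 0 && low < high && high < rate / 2))
    stop("invalid band edges: need 0 < low < high < rate/2")
  ntaps <- ceiling(3.3 * rate / transition)
  if (ntaps %% 2 == 0) ntaps <- ntaps + 1
  as.numeric(signal::fir1(ntaps - 1, c(low, high) / (rate / 2), type = "pass"))
}

## Squared-magnitude frequency response of taps h at FFT length nfft.
## Real and non-negative; multiplying a spectrum by it equals circular
## forward-backward filtering with h (exactly zero phase).
firPowerResponse <- function(h, nfft) {
  if (length(h) > nfft) stop("FFT length shorter than the filter")
  Mod(stats::fft(c(h, numeric(nfft - length(h)))))^2
}

## Smallest FFT-friendly length >= n: 2^a * 3^b * 5^c with b <= 2 and
## c <= 3 (lengths dominated by odd radices transform slowly in R).
goodFFTLength <- function(n) {
  best <- Inf
  p3 <- 1
  for (b in 0:2) {
    p5 <- 1
    for (c in 0:3) {
      base <- p3 * p5
      cand <- base * 2^max(0, ceiling(log2(n / base)))
      if (cand >= n && cand < best) best <- cand
      p5 <- p5 * 5
    }
    p3 <- p3 * 3
  }
  as.integer(best)
}

## Reflection-pad a samples x channels matrix at both ends.
reflectPad <- function(x, padLen) {
  n <- nrow(x)
  padLen <- min(padLen, n - 1L)
  head <- x[seq(padLen + 1L, 2L), , drop = FALSE]
  tail <- x[seq(n - 1L, n - padLen), , drop = FALSE]
  rbind(head, x, tail)
}

#' Apply several zero-phase FIR filters sharing one forward FFT
#'
#' Filters a samples x channels matrix with each filter in \code{filters}
#' (a list of tap vectors), using reflection padding against edge
#' transients and a single forward FFT whose spectrum is multiplied by
#' each filter's squared-magnitude response (forward-backward
#' application, zero phase).  Output lengths equal the input length.
#'
#' @param x numeric matrix, samples x channels (a vector is treated as
#'   one channel).
#' @param filters list of FIR tap vectors (see \code{\link{firBandpass}}).
#' @param pad logical, reflection-pad the signal (recommended).
#' @return list of filtered matrices, same shape as \code{x}.
#' @export
applyFilterBank <- function(x, filters, pad = TRUE) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, ncol = 1L)
  n <- nrow(x)
  padLen <- if (pad) min(max(lengths(filters)), n - 1L) else 0L
  xp <- if (padLen > 0) reflectPad(x, padLen) else x
  off <- nrow(xp) - n - padLen  # actual head pad (== padLen)
  nfft <- goodFFTLength(nrow(xp) + max(lengths(filters)))
  xp <- rbind(xp, matrix(0, nfft - nrow(xp), ncol(x)))
  F <- stats::mvfft(xp)
  lapply(filters, function(h) {
    resp <- firPowerResponse(h, nfft)
    y <- Re(stats::mvfft(F * resp, inverse = TRUE)) / nfft
    y <- y[padLen + seq_len(n), , drop = FALSE]
    if (vec) drop(y) else y
  })
}

#' Zero-phase bandpass filter an ROI x samples signal matrix
#'
#' Forward-backward windowed-sinc FIR filtering; output length equals
#' input length, pure tones inside the passband are preserved and tones
#' at least one octave outside are suppressed.
#'
#' @param signal numeric matrix, ROIs x samples (or a single vector).
#' @param low,high band edges in Hz.
#' @param rate sampling rate in Hz.
#' @return filtered matrix (or vector), same shape as the input.
#' @examples
#' rate <- 500; t <- seq(0, 3, by = 1 / rate)
#' x <- sin(2 * pi * 10 * t)
#' y <- bandpass(x, 8, 12, rate)   # alpha keeps a 10 Hz tone
#' @export
bandpass <- function(signal, low, high, rate) {
  h <- firBandpass(low, high, rate)
  vec <- is.null(dim(signal))
  x <- if (vec) matrix(signal, ncol = 1L) else t(signal)
  y <- applyFilterBank(x, list(h))[[1L]]
  if (vec) drop(y) else t(y)
}
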