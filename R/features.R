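## Feature extraction: per-band differential entropy (DE) for EEG
## windows and mel-frequency cepstral coefficients (MFCC) for audio
## windows. These are the continuous features that DBSCAN later
## discretizes into the token dictionaries.

#' Default EEG analysis bands
#'
#' Theta (4-8), alpha (8-13), beta (13-30) and gamma (30-45) Hz — the
#' standard affect-EEG bands, all inside the 4-45 Hz filter.
#'
#' @return named list of `c(low, high)` Hz pairs.
#' @export
defaultBands <- function() {
  list(theta = c(4, 8), alpha = c(8, 13), beta = c(13, 30),
       gamma = c(30, 45))
}

## One-sided periodogram band variance: by Parseval, the variance of the
## band-limited component is the sum of the power-spectrum mass over the
## band's frequency bins (DC excluded).
.bandVariance <- function(x, rateHz, bands) {
  W <- length(x)
  X <- stats::fft(x)
  power <- Mod(X)^2 / W^2                  # two-sided, per bin
  freq <- (seq_len(W) - 1) * rateHz / W
  half <- 2:(floor(W / 2) + 1L)            # positive frequencies
  vapply(bands, function(b) {
    sel <- half[freq[half] > b[1] & freq[half] <= b[2]]
    v <- sum(power[sel])
    ## double all bins except an exact Nyquist bin (its conjugate is itself)
    nyquistBin <- if (W %% 2 == 0) W / 2 + 1L else -1L
    2 * v - sum(power[sel[sel == nyquistBin]])
  }, numeric(1))
}

#' Differential entropy of band-limited EEG
#'
#' For each channel and band, the signal's band-limited variance
#' \eqn{\sigma^2} is measured from the periodogram and the Gaussian
#' closed form \eqn{\tfrac12 \ln(2\pi e \sigma^2)} is returned — the
#' standard DE feature of EEG emotion analysis. Zero-variance bands are
#' floored (with a warning) instead of returning `-Inf`.
#'
#' @param window channels x samples numeric matrix (one analysis window).
#' @param rateHz sampling rate in Hz.
#' @param bandEdges list of `c(low, high)` Hz pairs; default
#'   [defaultBands()].
#' @param windowIndex 1-based index recorded in the result.
#' @param varFloor variance floor substituted for empty bands.
#' @return a [DEFeatureFrame-class] (channels x bands, nats).
#' @export
#' @examples
#' w <- matrix(sin(2 * pi * 10 * (0:511) / 128), 1)  # alpha sinusoid
#' differentialEntropy(w, 128)
differentialEntropy <- function(window, rateHz, bandEdges = defaultBands(),
                                windowIndex = 1L, varFloor = 1e-12) {
  window <- as.matrix(window)
  if (ncol(window) < rateHz) {
    stop("window must contain at least one second of data", call. = FALSE)
  }
  nyq <- rateHz / 2
  for (b in bandEdges) {
    if (!(b[1] >= 0 && b[1] < b[2] && b[2] <= nyq + 1e-9)) {
      stop("band edges must lie within (0, Nyquist]", call. = FALSE)
    }
  }
  vars <- matrix(unlist(lapply(seq_len(nrow(window)), function(i) {
    .bandVariance(window[i, ], rateHz, bandEdges)
  })), nrow = nrow(window), byrow = TRUE)
  if (any(vars < varFloor)) {
    warning("zero-variance band(s); differential entropy floored")
    vars <- pmax(vars, varFloor)
  }
  de <- 0.5 * log(2 * pi * exp(1) * vars)
  dimnames(de) <- list(rownames(window), names(bandEdges))
  new("DEFeatureFrame", values = de, bandEdges = unname(bandEdges),
      windowIndex = as.integer(windowIndex))
}

#' Flatten a DE frame to a vector (row-major)
#'
#' Channel-major order: element (channel c, band b) (0-based) lands at
#' index `c * B + b`, so channel 1's first band is at 0-based index B.
#' [unflattenDE()] is the inverse.
#'
#' @param frame a [DEFeatureFrame-class].
#' @return numeric vector of length channels x bands.
#' @export
flattenDE <- function(frame) {
  stopifnot(is(frame, "DEFeatureFrame"))
  as.vector(t(frame@values))
}

#' @rdname flattenDE
#' @param x flattened vector.
#' @param nChannels channel count of the original frame.
#' @export
unflattenDE <- function(x, nChannels) {
  matrix(x, nrow = nChannels, byrow = TRUE)
}

## mel scale (HTK convention)
.hzToMel <- function(f) 2595 * log10(1 + f / 700)
.melToHz <- function(m) 700 * (10 ^ (m / 2595) - 1)

#' Triangular mel filterbank
#'
#' @param nMels number of filters.
#' @param nFft FFT length.
#' @param rateHz sampling rate.
#' @param fMin,fMax frequency range in Hz.
#' @return nMels x (nFft/2 + 1) filter matrix.
#' @keywords internal
melFilterbank <- function(nMels, nFft, rateHz, fMin = 0,
                          fMax = rateHz / 2) {
  melPts <- seq(.hzToMel(fMin), .hzToMel(fMax), length.out = nMels + 2L)
  hzPts <- .melToHz(melPts)
  bins <- floor((nFft + 1) * hzPts / rateHz)
  fb <- matrix(0, nrow = nMels, ncol = nFft %/% 2L + 1L)
  for (m in seq_len(nMels)) {
    lo <- bins[m]; ce <- bins[m + 1L]; hi <- bins[m + 2L]
    if (ce > lo) {
      k <- lo:ce
      fb[m, k + 1L] <- (k - lo) / (ce - lo)
    }
    if (hi > ce) {
      k <- ce:hi
      fb[m, k + 1L] <- pmin(fb[m, k + 1L] + (hi - k) / (hi - ce), 1)
    }
  }
  fb
}

## orthonormal DCT-II matrix (nCoef x n)
.dctMatrix <- function(nCoef, n) {
  m <- outer(0:(nCoef - 1L), 0:(n - 1L),
             function(k, j) cos(pi * k * (j + 0.5) / n))
  m <- m * sqrt(2 / n)
  m[1, ] <- m[1, ] / sqrt(2)
  m
}

#' Mel-frequency cepstral coefficients of an audio window
#'
#' Standard chain: framing (Hamming window), power spectrum, triangular
#' mel filterbank, log (floored, so silence yields finite values), and
#' orthonormal DCT-II. Frame count is
#' `floor((length - frame) / hop) + 1`.
#'
#' @param window numeric sample vector (one analysis window).
#' @param rateHz sampling rate in Hz.
#' @param nCoef number of cepstral coefficients (default 20).
#' @param frameS,hopS analysis frame length and hop in seconds
#'   (defaults 25 ms / 10 ms).
#' @param nMels mel filterbank size (default 26).
#' @param logFloor floor applied inside the log.
#' @return an [MFCCFeatures-class] (frames x nCoef).
#' @export
mfcc <- function(window, rateHz, nCoef = 20, frameS = 0.025, hopS = 0.010,
                 nMels = 26, logFloor = 1e-10) {
  x <- as.numeric(window)
  frameLen <- round(frameS * rateHz)
  hopLen <- round(hopS * rateHz)
  if (length(x) < frameLen) {
    stop("window shorter than one analysis frame", call. = FALSE)
  }
  nFrames <- floor((length(x) - frameLen) / hopLen) + 1L
  starts <- (seq_len(nFrames) - 1L) * hopLen + 1L
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(frameLen - 1L)) / (frameLen - 1L))
  frames <- vapply(starts, function(s) x[s:(s + frameLen - 1L)] * ham,
                   numeric(frameLen))
  nFft <- 2 ^ ceiling(log2(frameLen))
  padded <- rbind(frames, matrix(0, nFft - frameLen, nFrames))
  spec <- stats::mvfft(padded)
  power <- Mod(spec[seq_len(nFft %/% 2L + 1L), , drop = FALSE])^2 / nFft
  fb <- melFilterbank(nMels, nFft, rateHz)
  melPower <- fb %*% power                     # nMels x nFrames
  logMel <- log(pmax(melPower, logFloor))
  coef <- .dctMatrix(nCoef, nMels) %*% logMel  # nCoef x nFrames
  new("MFCCFeatures", values = t(coef), frameS = frameS, hopS = hopS,
      rateHz = rateHz, nMels = as.integer(nMels))
}

#' Per-window feature matrices for a segmented trial
#'
#' EEG: one flattened DE vector per window (channels x bands). Audio:
#' the mean MFCC vector over the window's frames, i.e. one feature
#' vector per window for each modality, so both token sequences share
#' the trial's window grid.
#'
#' @param seg a [SegmentedTrial-class].
#' @param rateHz EEG sampling rate.
#' @param audioRateHz audio sampling rate.
#' @param bandEdges DE bands, default [defaultBands()].
#' @param nCoef,frameS,hopS,nMels MFCC settings (see [mfcc()]).
#' @return list with `eeg` (windows x channels*bands) and `audio`
#'   (windows x nCoef) matrices plus the settings used.
#' @export
trialFeatures <- function(seg, rateHz, audioRateHz,
                          bandEdges = defaultBands(), nCoef = 20,
                          frameS = 0.025, hopS = 0.010, nMels = 26) {
  stopifnot(is(seg, "SegmentedTrial"))
  eeg <- t(vapply(seq_along(seg@eegWindows), function(i) {
    flattenDE(differentialEntropy(seg@eegWindows[[i]], rateHz,
                                  bandEdges, windowIndex = i))
  }, numeric(nrow(seg@eegWindows[[1]]) * length(bandEdges))))
  audio <- t(vapply(seg@audioWindows, function(w) {
    colMeans(mfcc(w, audioRateHz, nCoef = nCoef, frameS = frameS,
                  hopS = hopS, nMels = nMels)@values)
  }, numeric(nCoef)))
  list(eeg = eeg, audio = audio,
       meta = list(bandEdges = bandEdges, rateHz = rateHz,
                   audioRateHz = audioRateHz, nCoef = nCoef,
                   frameS = frameS, hopS = hopS, nMels = nMels))
}
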