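## EEG/audio preprocessing: band-pass filtering, decimation, baseline
## correction, peak normalization and segmentation into the fixed 4-s
## analysis windows used throughout the pipeline.

#' DEAP 32-channel montage (Twente ordering)
#'
#' Ordered channel names of the standard 32-channel music-video affect
#' corpus layout, used as the default synthetic montage and for
#' channel-subset selection.
#'
#' @return character vector of 32 channel names.
#' @export
deapChannels <- function() {
  c("Fp1", "AF3", "F7", "F3", "FC1", "FC5", "T7", "C3",
    "CP1", "CP5", "P7", "P3", "Pz", "PO3", "O1", "Oz",
    "O2", "PO4", "P4", "P8", "CP6", "CP2", "C4", "T8",
    "FC6", "FC2", "F4", "F8", "AF4", "Fp2", "Fz", "Cz")
}

#' Channel subsets used by published EEG-music baselines
#'
#' Named list of the channel selections reported for the comparison
#' systems (6-channel, 29-channel and 5-channel configurations). The
#' 29-channel list is reproduced as published; note that PO7/PO8 are not
#' part of the 32-channel DEAP montage, so [selectChannels()] rejects
#' that subset on a DEAP-layout recording unless those names are dropped.
#'
#' @return named list of character vectors.
#' @export
channelSubsets <- function() {
  list(
    tiraboschi = c("FC5", "FC6", "CP5", "CP6", "PO3", "PO4"),
    miyamoto = c("Fp1", "Fp2", "AF3", "AF4", "F7", "F8", "F3", "Fz", "F4",
                 "FC5", "FC6", "T7", "T8", "C3", "Cz", "C4", "CP5", "CP6",
                 "P7", "P8", "P3", "Pz", "P4", "PO7", "PO8", "PO3", "PO4",
                 "O1", "O2"),
    inoue = c("AF3", "AF4", "T7", "T8", "Pz"))
}

#' Zero-phase band-pass filter an EEG recording
#'
#' Fourth-order Butterworth filter applied forward and backward
#' (zero-phase) to each channel. The default band is 4-45 Hz, the
#' standard affect-EEG analysis band.
#'
#' @param rec an [EEGRecording-class].
#' @param lowHz,highHz band edges in Hz; must satisfy
#'   `0 < lowHz < highHz < rateHz/2`.
#' @param order Butterworth order (applied twice via filtfilt).
#' @return the filtered [EEGRecording-class] (same shape).
#' @export
bandpassFilter <- function(rec, lowHz = 4, highHz = 45, order = 4) {
  stopifnot(is(rec, "EEGRecording"))
  nyq <- rec@rateHz / 2
  if (!(lowHz > 0 && lowHz < highHz && highHz < nyq)) {
    stop(sprintf("invalid band: need 0 < %g < %g < Nyquist (%g Hz)",
                 lowHz, highHz, nyq), call. = FALSE)
  }
  bf <- signal::butter(order, c(lowHz, highHz) / nyq, type = "pass")
  out <- t(apply(rec@data, 1L, function(x) signal::filtfilt(bf, x)))
  EEGRecording(out, rec@rateHz, rec@channelNames, rec@baselineS)
}

#' Downsample an EEG recording
#'
#' Anti-aliased decimation (FIR low-pass, zero-phase) by an integer
#' factor. `targetHz = rateHz` is the identity; upsampling is not
#' supported.
#'
#' @param rec an [EEGRecording-class].
#' @param targetHz target rate; must divide `rateHz`.
#' @return the decimated [EEGRecording-class].
#' @export
downsampleEEG <- function(rec, targetHz) {
  stopifnot(is(rec, "EEGRecording"))
  if (targetHz > rec@rateHz) {
    stop("upsampling not supported: targetHz > rateHz", call. = FALSE)
  }
  if (abs(targetHz - rec@rateHz) < 1e-9) return(rec)
  q <- rec@rateHz / targetHz
  if (abs(q - round(q)) > 1e-9) {
    stop("only integer decimation factors supported; got rate ratio ",
         format(q), call. = FALSE)
  }
  q <- as.integer(round(q))
  out <- t(apply(rec@data, 1L, function(x) {
    signal::decimate(x, q, ftype = "fir")
  }))
  EEGRecording(out, targetHz, rec@channelNames, rec@baselineS)
}

#' Remove the pre-stimulus baseline
#'
#' Drops the first `baselineS` seconds and subtracts each channel's mean
#' over that baseline from the remaining stimulus samples.
#'
#' @param rec an [EEGRecording-class] with `baselineS > 0`.
#' @return an [EEGRecording-class] with `baselineS = 0`.
#' @export
removeBaseline <- function(rec) {
  stopifnot(is(rec, "EEGRecording"))
  if (rec@baselineS <= 0) {
    stop("invalid trial: recording has no baseline to remove", call. = FALSE)
  }
  nBase <- round(rec@baselineS * rec@rateHz)
  if (nBase >= ncol(rec@data)) {
    stop("invalid trial: recording shorter than its baseline", call. = FALSE)
  }
  baseMean <- rowMeans(rec@data[, seq_len(nBase), drop = FALSE])
  stim <- rec@data[, (nBase + 1L):ncol(rec@data), drop = FALSE] - baseMean
  EEGRecording(stim, rec@rateHz, rec@channelNames, baselineS = 0)
}

#' Peak-normalize an audio track
#'
#' Scales samples so the maximum absolute amplitude is 1 (silent input is
#' returned unchanged), removing level differences before MFCC.
#'
#' @param audio an [AudioTrack-class].
#' @return the normalized [AudioTrack-class].
#' @export
peakNormalize <- function(audio) {
  stopifnot(is(audio, "AudioTrack"))
  peak <- max(abs(audio@data))
  if (peak > 0) audio@data <- audio@data / peak
  audio
}

#' Segment an aligned EEG/audio trial into fixed windows
#'
#' Cuts both modalities into consecutive non-overlapping `windowS`-second
#' windows (half-open intervals `[t, t + windowS)`); a trailing partial
#' window is dropped. EEG and audio window i span the same time
#' interval. The EEG must be baseline-free (use [removeBaseline()]
#' first) and both signals must cover the same stimulus duration.
#'
#' @param eeg an [EEGRecording-class] with `baselineS = 0`.
#' @param audio an [AudioTrack-class].
#' @param windowS window length in seconds (default 4).
#' @param trialId,subjectId identifiers carried into the result.
#' @return a [SegmentedTrial-class].
#' @export
segmentWindows <- function(eeg, audio, windowS = 4, trialId = "t01",
                           subjectId = "s01") {
  stopifnot(is(eeg, "EEGRecording"), is(audio, "AudioTrack"))
  if (eeg@baselineS > 0) {
    stop("EEG still contains baseline; call removeBaseline() first",
         call. = FALSE)
  }
  durE <- ncol(eeg@data) / eeg@rateHz
  durA <- length(audio@data) / audio@rateHz
  if (abs(durE - durA) > 1 / min(eeg@rateHz, audio@rateHz) + 1e-9) {
    stop(sprintf("EEG (%.3f s) and audio (%.3f s) durations differ",
                 durE, durA), call. = FALSE)
  }
  n <- floor(min(durE, durA) / windowS)
  if (n < 1L) {
    stop("empty trial: duration shorter than one window", call. = FALSE)
  }
  wE <- round(windowS * eeg@rateHz)
  wA <- round(windowS * audio@rateHz)
  eegWindows <- lapply(seq_len(n), function(i) {
    eeg@data[, ((i - 1L) * wE + 1L):(i * wE), drop = FALSE]
  })
  audioWindows <- lapply(seq_len(n), function(i) {
    audio@data[((i - 1L) * wA + 1L):(i * wA)]
  })
  new("SegmentedTrial", eegWindows = eegWindows,
      audioWindows = audioWindows, windowS = windowS,
      trialId = trialId, subjectId = subjectId)
}

#' Select and reorder EEG channels
#'
#' @param rec an [EEGRecording-class].
#' @param names channels to keep, in the requested order.
#' @return the subset [EEGRecording-class].
#' @export
selectChannels <- function(rec, names) {
  stopifnot(is(rec, "EEGRecording"))
  missing <- setdiff(names, rec@channelNames)
  if (length(missing)) {
    stop("channel(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  idx <- match(names, rec@channelNames)
  EEGRecording(rec@data[idx, , drop = FALSE], rec@rateHz,
               rec@channelNames[idx], rec@baselineS)
}

#' Standard preprocessing for one trial
#'
#' Band-pass filter (4-45 Hz), optional decimation to `targetHz`,
#' baseline removal, audio peak normalization and 4-s segmentation —
#' the default preparation applied before feature extraction.
#'
#' @param trial a trial entry (`eeg`, `audio`, ids) as produced by
#'   [genDataset()] / [readFixture()].
#' @param lowHz,highHz filter band.
#' @param targetHz EEG rate after decimation (defaults to the input rate).
#' @param windowS analysis window in seconds.
#' @param channels optional channel subset.
#' @return a [SegmentedTrial-class].
#' @export
preprocessTrial <- function(trial, lowHz = 4, highHz = 45,
                            targetHz = NULL, windowS = 4,
                            channels = NULL) {
  eeg <- trial$eeg
  if (!is.null(channels)) eeg <- selectChannels(eeg, channels)
  eeg <- bandpassFilter(eeg, lowHz, highHz)
  if (!is.null(targetHz)) eeg <- downsampleEEG(eeg, targetHz)
  if (eeg@baselineS > 0) eeg <- removeBaseline(eeg)
  audio <- peakNormalize(trial$audio)
  segmentWindows(eeg, audio, windowS,
                 trialId = if (is.null(trial$trialId)) "t01" else trial$trialId,
                 subjectId = if (is.null(trial$subjectId)) "s01" else
                   trial$subjectId)
}
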