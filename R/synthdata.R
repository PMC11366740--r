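## Synthetic coupled EEG/audio generator. A hidden first-order Markov
## chain of K "emotional states" (one state per analysis frame) drives
## both modalities: each state has a band-limited EEG oscillation
## template and a harmonic audio chord template, so the EEG -> audio-token
## mapping downstream is learnable by construction. The trial layout
## mirrors music-video affect corpora: 32-channel EEG at 128 Hz with a
## 3 s pre-stimulus baseline followed by a 60 s stimulus, paired with a
## 60 s mono audio track.

#' Synthetic-data configuration
#'
#' Defaults emulate the DEAP corpus shape: 32 subjects x 40 trials of
#' 32-channel 128 Hz EEG (3 s baseline + 60 s stimulus) with a 60 s mono
#' audio track. Audio is generated at 8 kHz: the synthetic chords live
#' well below 4 kHz, and nothing in the pipeline needs more bandwidth.
#'
#' @param nSubjects,nTrials corpus size.
#' @param nChannels EEG channel count.
#' @param eegRateHz,audioRateHz sampling rates in Hz.
#' @param trialS stimulus duration in seconds.
#' @param baselineS pre-stimulus baseline duration in seconds.
#' @param K number of latent emotional states.
#' @param stayProb Markov probability of keeping the current state
#'   between consecutive frames.
#' @param frameS seconds per latent frame (matched to the 4 s analysis
#'   window).
#' @param noiseSd additive white-noise standard deviation on the EEG
#'   (template oscillations have unit-order amplitude); audio noise is
#'   scaled down by 20x relative to this value.
#' @param seed integer seed controlling templates and trial randomness.
#' @return a validated `synthConfig` list.
#' @export
#' @examples
#' cfg <- synthConfig(nSubjects = 2, nTrials = 1, trialS = 12)
#' lat <- genLatentStates(cfg)
#' states(lat)
synthConfig <- function(nSubjects = 32, nTrials = 40, nChannels = 32,
                        eegRateHz = 128, audioRateHz = 8000, trialS = 60,
                        baselineS = 3, K = 4, stayProb = 0.9, frameS = 4,
                        noiseSd = 0.3, seed = 1) {
  .assertCount(nSubjects, "nSubjects")
  .assertCount(nTrials, "nTrials")
  .assertCount(nChannels, "nChannels")
  .assertScalarNum(eegRateHz, "eegRateHz", lower = 1e-9)
  .assertScalarNum(audioRateHz, "audioRateHz", lower = 1e-9)
  .assertScalarNum(trialS, "trialS", lower = 1e-9)
  .assertScalarNum(baselineS, "baselineS", lower = 0)
  if (!is.numeric(K) || length(K) != 1L || K < 1 || K != round(K)) {
    stop("invalid config: K must be an integer >= 1", call. = FALSE)
  }
  .assertScalarNum(stayProb, "stayProb", lower = 0, upper = 1)
  .assertScalarNum(frameS, "frameS", lower = 1e-9)
  .assertScalarNum(noiseSd, "noiseSd", lower = 0)
  cfg <- list(nSubjects = as.integer(nSubjects), nTrials = as.integer(nTrials),
              nChannels = as.integer(nChannels), eegRateHz = eegRateHz,
              audioRateHz = audioRateHz, trialS = trialS,
              baselineS = baselineS, K = as.integer(K), stayProb = stayProb,
              frameS = frameS, noiseSd = noiseSd, seed = as.integer(seed))
  class(cfg) <- c("synthConfig", "list")
  cfg
}

#' Generate a latent emotional-state sequence
#'
#' First-order Markov chain over `{0..K-1}`: uniform initial state, stay
#' probability `stayProb`, otherwise a uniform jump to one of the other
#' states. One state per `frameS`-second frame, covering `trialS`.
#'
#' @param cfg a [synthConfig()].
#' @param seed integer seed (defaults to the config seed).
#' @return a [LatentStateSequence-class].
#' @export
genLatentStates <- function(cfg, seed = cfg$seed) {
  if (!inherits(cfg, "synthConfig")) cfg <- do.call(synthConfig, cfg)
  nFrames <- as.integer(ceiling(cfg$trialS / cfg$frameS))
  states <- withSeed(seed, {
    s <- integer(nFrames)
    s[1] <- sample.int(cfg$K, 1L) - 1L
    if (nFrames > 1L) {
      for (t in 2:nFrames) {
        if (cfg$K == 1L || stats::runif(1) < cfg$stayProb) {
          s[t] <- s[t - 1]
        } else {
          others <- setdiff(0:(cfg$K - 1L), s[t - 1])
          s[t] <- others[sample.int(length(others), 1L)]
        }
      }
    }
    s
  })
  new("LatentStateSequence", states = states, K = cfg$K,
      stayProb = cfg$stayProb, frameS = cfg$frameS)
}

## Per-state emission templates, deterministic given the config seed.
## EEG: one oscillation frequency per state spread over 6-38 Hz (inside
## the 4-45 Hz analysis band), with per-channel amplitudes and phases.
## Audio: one chord fundamental per state with two alternating harmonic
## voicings (a two-frame metric pattern), giving 2K distinct audio
## frame classes while the EEG carries the K-state information.
.stateTemplates <- function(cfg) {
  withSeed(deriveSeed(cfg$seed, "templates"), {
    K <- cfg$K
    eegFreqs <- if (K == 1L) 10 else seq(6, 38, length.out = K)
    amps <- matrix(stats::runif(cfg$nChannels * K, 0.6, 1.4),
                   nrow = cfg$nChannels)
    phases <- matrix(stats::runif(cfg$nChannels * K, 0, 2 * pi),
                     nrow = cfg$nChannels)
    dcOffset <- stats::runif(cfg$nChannels, -2, 2)
    audioF0 <- 180 * 2 ^ ((seq_len(K) - 1) / 5)
    voicings <- list(c(1, 0.6, 0.4, 0.2), c(0.3, 1, 0.2, 0.8))
    list(eegFreqs = eegFreqs, amps = amps, phases = phases,
         dcOffset = dcOffset, audioF0 = audioF0, voicings = voicings)
  })
}

#' Generate one coupled EEG/audio trial
#'
#' Both modalities are driven by the same latent state sequence. EEG is
#' the per-state oscillation template plus white noise and a per-channel
#' DC offset (shared with the baseline, so baseline correction is
#' meaningful); audio is the per-state chord template, whose harmonic
#' voicing alternates between even and odd frames, plus low-level noise.
#'
#' @param cfg a [synthConfig()].
#' @param latent a [LatentStateSequence-class] covering `trialS`.
#' @param seed integer noise seed (defaults to the config seed).
#' @return list with elements `eeg` ([EEGRecording-class], baseline
#'   included) and `audio` ([AudioTrack-class], stimulus only).
#' @export
genCoupledPair <- function(cfg, latent, seed = cfg$seed) {
  if (!inherits(cfg, "synthConfig")) cfg <- do.call(synthConfig, cfg)
  if (length(latent@states) * latent@frameS < cfg$trialS - 1e-9) {
    stop("invalid config: latent sequence does not cover trialS",
         call. = FALSE)
  }
  if (latent@K != cfg$K) {
    stop("invalid config: latent K differs from cfg K", call. = FALSE)
  }
  tpl <- .stateTemplates(cfg)
  nBase <- round(cfg$baselineS * cfg$eegRateHz)
  nStim <- round(cfg$trialS * cfg$eegRateHz)
  nAudio <- round(cfg$trialS * cfg$audioRateHz)
  tEEG <- (seq_len(nStim) - 1) / cfg$eegRateHz
  frameOfEEG <- pmin(length(latent@states),
                     1L + as.integer(tEEG %/% latent@frameS))
  stateOfEEG <- latent@states[frameOfEEG] + 1L
  tAud <- (seq_len(nAudio) - 1) / cfg$audioRateHz
  frameOfAud <- pmin(length(latent@states),
                     1L + as.integer(tAud %/% latent@frameS))
  stateOfAud <- latent@states[frameOfAud] + 1L
  meterOfAud <- (frameOfAud - 1L) %% 2L

  withSeed(seed, {
    eeg <- matrix(0, nrow = cfg$nChannels, ncol = nBase + nStim)
    for (ch in seq_len(cfg$nChannels)) {
      osc <- tpl$amps[ch, stateOfEEG] *
        sin(2 * pi * tpl$eegFreqs[stateOfEEG] * tEEG + tpl$phases[ch, stateOfEEG])
      eeg[ch, ] <- tpl$dcOffset[ch] + c(numeric(nBase), osc)
    }
    if (cfg$noiseSd > 0) {
      eeg <- eeg + matrix(stats::rnorm(length(eeg), sd = cfg$noiseSd),
                          nrow = nrow(eeg))
    }
    f0 <- tpl$audioF0[stateOfAud]
    audio <- numeric(nAudio)
    for (h in 1:4) {
      w <- ifelse(meterOfAud == 0L, tpl$voicings[[1]][h], tpl$voicings[[2]][h])
      audio <- audio + w * sin(2 * pi * h * f0 * tAud)
    }
    audio <- audio / 4
    if (cfg$noiseSd > 0) {
      audio <- audio + stats::rnorm(nAudio, sd = cfg$noiseSd / 20)
    }
    chNames <- if (cfg$nChannels <= 32L) {
      deapChannels()[seq_len(cfg$nChannels)]
    } else {
      paste0("Ch", seq_len(cfg$nChannels))
    }
    list(eeg = EEGRecording(eeg, cfg$eegRateHz, channelNames = chNames,
                            baselineS = cfg$baselineS),
         audio = AudioTrack(audio, cfg$audioRateHz),
         latent = latent)
  })
}

#' Generate a full synthetic corpus
#'
#' One latent sequence and coupled pair per subject x trial, with
#' per-trial seeds derived from the config seed.
#'
#' @param cfg a [synthConfig()].
#' @return list of trial entries, each with `subjectId`, `trialId`,
#'   `eeg`, `audio`, `latent`.
#' @export
genDataset <- function(cfg) {
  if (!inherits(cfg, "synthConfig")) cfg <- do.call(synthConfig, cfg)
  out <- vector("list", cfg$nSubjects * cfg$nTrials)
  k <- 0L
  for (s in seq_len(cfg$nSubjects)) {
    for (tr in seq_len(cfg$nTrials)) {
      tag <- sprintf("s%02d/t%02d", s, tr)
      latent <- genLatentStates(cfg, seed = deriveSeed(cfg$seed,
                                                      paste0("latent/", tag)))
      pair <- genCoupledPair(cfg, latent,
                             seed = deriveSeed(cfg$seed, paste0("noise/", tag)))
      k <- k + 1L
      out[[k]] <- list(subjectId = sprintf("s%02d", s),
                       trialId = sprintf("t%02d", tr),
                       eeg = pair$eeg, audio = pair$audio, latent = latent)
    }
  }
  out
}

#' Write a synthetic corpus to disk
#'
#' EEG goes to NPY matrices with JSON sidecars (rate, channel names,
#' baseline duration), audio to 16-bit PCM WAV, and a manifest JSON lists
#' every trial with its files, rates and latent state path.
#'
#' @param dataset output of [genDataset()] (or a single-trial list from
#'   [genCoupledPair()] with `subjectId`/`trialId` added).
#' @param dir output directory (created if needed).
#' @return path of the manifest file, invisibly.
#' @export
writeFixture <- function(dataset, dir) {
  if (!is.null(dataset$eeg)) dataset <- list(dataset)  # single trial
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create fixture directory: ", dir)
  }
  entries <- lapply(dataset, function(tr) {
    sid <- if (is.null(tr$subjectId)) "s01" else tr$subjectId
    tid <- if (is.null(tr$trialId)) "t01" else tr$trialId
    stem <- paste0(sid, "_", tid)
    eegFile <- paste0(stem, "_eeg.npy")
    wavFile <- paste0(stem, "_audio.wav")
    writeNpy(tr$eeg@data, file.path(dir, eegFile))
    jsonlite::write_json(
      list(rate_hz = tr$eeg@rateHz, channel_names = tr$eeg@channelNames,
           baseline_s = tr$eeg@baselineS),
      file.path(dir, paste0(stem, "_eeg.json")), auto_unbox = TRUE,
      digits = NA)
    writeWav(tr$audio, file.path(dir, wavFile))
    list(subject_id = sid, trial_id = tid, eeg = eegFile,
         eeg_meta = paste0(stem, "_eeg.json"), audio = wavFile,
         eeg_rate_hz = tr$eeg@rateHz, audio_rate_hz = tr$audio@rateHz,
         latent_states = as.integer(tr$latent@states),
         latent_K = tr$latent@K, latent_stay_prob = tr$latent@stayProb,
         latent_frame_s = tr$latent@frameS)
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(list(format_version = 1L, n_trials = length(entries),
                            trials = entries),
                       manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Read a fixture directory written by [writeFixture()]
#'
#' @param dir fixture directory containing `manifest.json`.
#' @return list of trial entries as in [genDataset()].
#' @export
readFixture <- function(dir) {
  manifest <- file.path(dir, "manifest.json")
  if (!file.exists(manifest)) stop("no manifest.json in ", dir)
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  lapply(seq_len(m$n_trials), function(i) {
    tr <- if (is.data.frame(m$trials)) as.list(m$trials[i, ]) else m$trials[[i]]
    meta <- jsonlite::read_json(file.path(dir, tr$eeg_meta[[1]]),
                                simplifyVector = TRUE)
    states <- as.integer(unlist(tr$latent_states))
    list(subjectId = tr$subject_id[[1]], trialId = tr$trial_id[[1]],
         eeg = EEGRecording(readNpy(file.path(dir, tr$eeg[[1]])),
                            meta$rate_hz, meta$channel_names,
                            meta$baseline_s),
         audio = readWav(file.path(dir, tr$audio[[1]])),
         latent = new("LatentStateSequence", states = states,
                      K = as.integer(tr$latent_K[[1]]),
                      stayProb = as.numeric(tr$latent_stay_prob[[1]]),
                      frameS = as.numeric(tr$latent_frame_s[[1]])))
  })
}
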