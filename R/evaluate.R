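## Evaluation: Hits@k ranking of predicted audio tokens, subject-wise
## train/test splitting, the ablation harness (clustering on/off,
## backbone swap, depth sweep) and mel-domain audio reconstruction.

#' Hits@k of reference IDs under model scores
#'
#' For each evaluated position the reference ID's rank is 1 plus the
#' number of candidates scored strictly higher, plus the number of
#' equally-scored candidates with a lower ID (deterministic,
#' slightly pessimistic tie handling). `hits[k]` is the fraction of
#' positions with rank <= k.
#'
#' @param probs L x V row-score matrix (rows need not be normalized).
#' @param referenceIds 0-based reference IDs, length L.
#' @param positions 1-based positions to evaluate (default: all).
#' @param kValues k cutoffs (default 1, 3, 5, 10, 20).
#' @return a [HitsResult-class].
#' @export
#' @examples
#' p <- matrix(c(0.7, 0.2, 0.1, 0.1, 0.8, 0.1), 2, byrow = TRUE)
#' hits(hitsAtK(p, c(0L, 0L), kValues = c(1, 2)))
hitsAtK <- function(probs, referenceIds, positions = seq_len(nrow(probs)),
                    kValues = c(1, 3, 5, 10, 20)) {
  probs <- as.matrix(probs)
  if (!length(positions)) {
    stop("undefined metric: no positions to evaluate", call. = FALSE)
  }
  if (any(positions < 1L | positions > nrow(probs))) {
    stop("positions out of range", call. = FALSE)
  }
  refs <- referenceIds[positions]
  if (any(refs < 0L | refs >= ncol(probs))) {
    stop("reference ID outside the vocabulary", call. = FALSE)
  }
  rk <- vapply(seq_along(positions), function(i) {
    row <- probs[positions[i], ]
    ref <- refs[i] + 1L
    1L + sum(row > row[ref]) +
      sum(row[seq_len(ref - 1L)] == row[ref])
  }, integer(1))
  kValues <- as.integer(sort(kValues))
  h <- vapply(kValues, function(k) mean(rk <= k), numeric(1))
  names(h) <- paste0("k", kValues)
  new("HitsResult", kValues = kValues, hits = h,
      n = length(rk), ranks = rk)
}

#' Subject-wise train/test split
#'
#' Seeded shuffle of the subject IDs, then the first
#' `round(testFraction * n)` go to the test side — an 8:2 split by
#' default, with no subject appearing on both sides.
#'
#' @param subjectIds character vector of subject IDs.
#' @param testFraction held-out fraction (default 0.2).
#' @param seed integer seed.
#' @return list with `trainSubjects`, `testSubjects`, `testFraction`,
#'   `seed` (class `"splitSpec"`).
#' @export
splitSubjects <- function(subjectIds, testFraction = 0.2, seed = 1) {
  subjectIds <- unique(as.character(subjectIds))
  n <- length(subjectIds)
  if (n < 5L) {
    stop("invalid split: need >= 5 subjects for a non-empty test set",
         call. = FALSE)
  }
  .assertScalarNum(testFraction, "testFraction", 0, 1)
  nTest <- max(1L, round(testFraction * n))
  if (nTest >= n) stop("invalid split: no training subjects left",
                       call. = FALSE)
  shuffled <- withSeed(seed, sample(subjectIds))
  structure(list(trainSubjects = sort(shuffled[-seq_len(nTest)]),
                 testSubjects = sort(shuffled[seq_len(nTest)]),
                 testFraction = testFraction, seed = as.integer(seed)),
            class = c("splitSpec", "list"))
}

#' Ablation specification
#'
#' @param useEEGClustering,useAudioClustering use the DBSCAN dictionary
#'   for the modality; when FALSE, dictionary IDs are replaced by
#'   uniform-quantile binning of every feature dimension (joint bin
#'   codes; unseen codes map to the unknown ID).
#' @param backbone `"transformer"`, `"lstm"` or `"cnn"`.
#' @param dLayers encoder/decoder depth.
#' @param binsPerDim quantile bins per feature dimension in the binning
#'   arm (2 = median split).
#' @return classed list.
#' @export
ablationSpec <- function(useEEGClustering = TRUE, useAudioClustering = TRUE,
                         backbone = c("transformer", "lstm", "cnn"),
                         dLayers = 2, binsPerDim = 2) {
  backbone <- match.arg(backbone)
  structure(list(useEEGClustering = isTRUE(useEEGClustering),
                 useAudioClustering = isTRUE(useAudioClustering),
                 backbone = backbone, dLayers = .assertCount(dLayers,
                                                             "dLayers"),
                 binsPerDim = .assertCount(binsPerDim, "binsPerDim",
                                           min = 2L)),
            class = c("ablationSpec", "list"))
}

## Per-dimension quantile-binning codec: the clustering-off ablation arm
## still needs discrete targets, so every feature dimension is binned at
## its training quantiles (median split by default) and the joint bin
## code of a frame is its token. The vocabulary is the set of distinct
## codes observed in training (ordered by frequency, ties by first
## occurrence); unseen codes map to the reserved unknown ID. In high
## dimensions this vocabulary fragments badly — which is exactly the
## contrast with density clustering the ablation is meant to expose.
.makeBinningCodec <- function(trainFrames, binsPerDim = 2) {
  B <- max(2L, as.integer(binsPerDim))
  qs <- apply(trainFrames, 2L, stats::quantile,
              probs = seq_len(B - 1L) / B, names = FALSE)
  qs <- matrix(qs, nrow = B - 1L)
  codeOf <- function(frames) {
    frames <- .asFrameMatrix(frames)
    bins <- vapply(seq_len(ncol(frames)), function(j) {
      findInterval(frames[, j], qs[, j])
    }, integer(nrow(frames)))
    if (nrow(frames) == 1L) bins <- matrix(bins, nrow = 1L)
    apply(bins, 1L, paste, collapse = ".")
  }
  trainCodes <- codeOf(trainFrames)
  tab <- table(trainCodes)
  firstSeen <- vapply(names(tab), function(cd)
    which(trainCodes == cd)[1], integer(1))
  vocabCodes <- names(tab)[order(-as.integer(tab), firstSeen)]
  vocab <- length(vocabCodes)
  list(vocab = vocab + 1L, unkId = vocab,
       encode = function(frames) {
         codes <- codeOf(frames)
         ids <- match(codes, vocabCodes) - 1L
         ids[is.na(ids)] <- vocab
         new("DiscreteSequence", ids = as.integer(ids),
             sourceFrames = seq_along(codes))
       })
}

## Prepare per-trial features from a raw dataset (genDataset/readFixture
## entries): preprocess + segment, then extract DE and window-mean MFCC.
.segmentAll <- function(data, lowHz = 4, highHz = 45, windowS = 4,
                        targetHz = NULL) {
  lapply(data, function(tr) {
    seg <- preprocessTrial(tr, lowHz = lowHz, highHz = highHz,
                           targetHz = targetHz, windowS = windowS)
    list(subjectId = seg@subjectId, trialId = seg@trialId, seg = seg,
         eegRateHz = if (is.null(targetHz)) tr$eeg@rateHz else targetHz,
         audioRateHz = tr$audio@rateHz, latent = tr$latent)
  })
}

.featurizeAll <- function(segTrials, bandEdges = defaultBands(),
                          nCoef = 20) {
  lapply(segTrials, function(tr) {
    fe <- trialFeatures(tr$seg, rateHz = tr$eegRateHz,
                        audioRateHz = tr$audioRateHz,
                        bandEdges = bandEdges, nCoef = nCoef)
    c(tr, list(eegFeat = fe$eeg, audioFeat = fe$audio, meta = fe$meta))
  })
}

.prepareTrials <- function(data, lowHz = 4, highHz = 45, windowS = 4,
                           bandEdges = defaultBands(), nCoef = 20) {
  .featurizeAll(.segmentAll(data, lowHz, highHz, windowS),
                bandEdges = bandEdges, nCoef = nCoef)
}

#' Run a full train/evaluate experiment
#'
#' End-to-end harness: preprocess and featurize every trial, split
#' subjects 8:2, learn the EEG/audio dictionaries on training frames
#' (or the binning codec for ablation arms), assemble token pairs,
#' train the model, and score held-out subjects with Hits@k under two
#' framings: masked positions (several seeded mask draws per test
#' trial) and full-sequence generation (every position masked).
#'
#' @param data a fixture directory path, or a dataset list from
#'   [genDataset()] / [readFixture()].
#' @param ablation an [ablationSpec()].
#' @param cfg a [modelConfig()]; `dLayers`/`backbone` are overridden by
#'   the ablation spec.
#' @param seed master seed for split, model init, masking.
#' @param epochs training epochs.
#' @param kValues Hits@k cutoffs.
#' @param nMaskDraws mask draws per test trial in the masked framing.
#' @param eegDictParams,audioDictParams optional [dbscanParams()]
#'   overrides (heuristic estimate when NULL).
#' @param windowS analysis window seconds.
#' @param outDir if non-NULL, write `report.json` and a `report.csv`
#'   row there.
#' @return report list (invisibly also written to `outDir`).
#' @export
runExperiment <- function(data, ablation = ablationSpec(),
                          cfg = modelConfig(dLayers = 2), seed = 1,
                          epochs = 10, kValues = c(1, 3, 5, 10, 20),
                          nMaskDraws = 10, eegDictParams = NULL,
                          audioDictParams = NULL, windowS = 4,
                          outDir = NULL) {
  if (is.character(data)) data <- readFixture(data)
  if (!length(data)) stop("no data: empty dataset", call. = FALSE)
  trials <- .prepareTrials(data, windowS = windowS)
  subjects <- unique(vapply(trials, `[[`, character(1), "subjectId"))
  split <- splitSubjects(subjects, seed = deriveSeed(seed, "split"))
  isTrain <- vapply(trials, function(tr)
    tr$subjectId %in% split$trainSubjects, logical(1))
  if (!any(isTrain) || all(isTrain)) {
    stop("degenerate split: need both train and test trials",
         call. = FALSE)
  }
  eegTrain <- do.call(rbind, lapply(trials[isTrain], `[[`, "eegFeat"))
  audTrain <- do.call(rbind, lapply(trials[isTrain], `[[`, "audioFeat"))

  ## discretizers per modality: DBSCAN dictionary or binning codec
  if (ablation$useEEGClustering) {
    eegDict <- learnDictionary(eegTrain, "eeg", params = eegDictParams)
    encE <- function(fr) encodeSequence(fr, eegDict)
    vocabE <- nClusters(eegDict) + 1L
  } else {
    eegCodec <- .makeBinningCodec(eegTrain, ablation$binsPerDim)
    encE <- eegCodec$encode
    vocabE <- eegCodec$vocab
    eegDict <- NULL
  }
  if (ablation$useAudioClustering) {
    audioDict <- learnDictionary(audTrain, "audio",
                                 params = audioDictParams,
                                 meta = c(trials[[1]]$meta,
                                          list(windowS = windowS)))
    encA <- function(fr) encodeSequence(fr, audioDict)
    vocabA <- nClusters(audioDict) + 1L
  } else {
    audCodec <- .makeBinningCodec(audTrain, ablation$binsPerDim)
    encA <- audCodec$encode
    vocabA <- audCodec$vocab
    audioDict <- NULL
  }

  mcfg <- modelConfig(dLayers = ablation$dLayers, nHeads = cfg$nHeads,
                      dModel = cfg$dModel, dFf = cfg$dFf,
                      dropout = cfg$dropout, alpha = cfg$alpha,
                      maskRatio = cfg$maskRatio, lr = cfg$lr,
                      batchPairs = cfg$batchPairs,
                      backbone = ablation$backbone,
                      seed = deriveSeed(seed, "model"))
  cnnSeed <- deriveSeed(seed, "frontend")
  pairs <- lapply(trials, function(tr) {
    list(eegContent = cnnContentFeatures(tr$seg@eegWindows, "eeg",
                                         mcfg$dModel, cnnSeed),
         eegIds = encE(tr$eegFeat)@ids,
         audioContent = cnnContentFeatures(tr$seg@audioWindows, "audio",
                                           mcfg$dModel, cnnSeed),
         audioIds = encA(tr$audioFeat)@ids,
         subjectId = tr$subjectId, trialId = tr$trialId)
  })
  model <- buildModel(mcfg, vocabE, vocabA)
  model <- fitModel(model, pairs[isTrain], epochs = epochs)

  ## held-out evaluation, masked framing
  testPairs <- pairs[!isTrain]
  refAll <- c(); probAll <- NULL
  for (i in seq_along(testPairs)) {
    p <- testPairs[[i]]
    La <- nrow(p$audioContent)
    nMask <- max(1L, round(mcfg$maskRatio * La))
    for (dr in seq_len(nMaskDraws)) {
      ms <- withSeed(deriveSeed(seed, sprintf("evalmask/%d/%d", i, dr)),
                     sort(sample.int(La, nMask)))
      probs <- .predictProbs(model, p$eegContent, p$eegIds, La,
                             maskSet = ms, audioContent = p$audioContent,
                             audioIds = p$audioIds)
      probAll <- rbind(probAll, probs[ms, , drop = FALSE])
      refAll <- c(refAll, p$audioIds[ms])
    }
  }
  hitsMasked <- hitsAtK(probAll, refAll, kValues = kValues)

  ## full-sequence generation framing
  refGen <- c(); probGen <- NULL
  for (p in testPairs) {
    La <- nrow(p$audioContent)
    probs <- .predictProbs(model, p$eegContent, p$eegIds, La,
                           maskSet = seq_len(La))
    probGen <- rbind(probGen, probs)
    refGen <- c(refGen, p$audioIds)
  }
  hitsGenerate <- hitsAtK(probGen, refGen, kValues = kValues)

  report <- list(
    seed = seed,
    configHash = stableHash(list(model = unclass(mcfg),
                                 ablation = unclass(ablation))),
    ablation = unclass(ablation),
    model = unclass(mcfg),
    split = unclass(split),
    vocab = list(eeg = vocabE, audio = vocabA),
    nTrainPairs = sum(vapply(pairs[isTrain], function(p)
      nrow(p$audioContent), numeric(1))),
    hitsMasked = list(k = hitsMasked@kValues,
                      hits = unname(hitsMasked@hits), n = hitsMasked@n),
    hitsGenerate = list(k = hitsGenerate@kValues,
                        hits = unname(hitsGenerate@hits),
                        n = hitsGenerate@n),
    finalLoss = utils::tail(lossHistory(model), 1L))
  attr(report, "model") <- model
  attr(report, "audioDict") <- audioDict
  attr(report, "eegDict") <- eegDict
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    row <- data.frame(seed = seed, backbone = ablation$backbone,
                      dLayers = ablation$dLayers,
                      eegClust = ablation$useEEGClustering,
                      audioClust = ablation$useAudioClustering,
                      t(stats::setNames(unname(hitsMasked@hits),
                                        paste0("hitsMasked", kValues))),
                      n = hitsMasked@n)
    utils::write.csv(row, file.path(outDir, "report.csv"),
                     row.names = FALSE)
  }
  invisible(report)
}

## STFT helpers for reconstruction ---------------------------------------
.stft <- function(x, frameLen, hop, nFft) {
  nFrames <- floor((length(x) - frameLen) / hop) + 1L
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(frameLen - 1L)) / (frameLen - 1L))
  frames <- vapply(seq_len(nFrames), function(i) {
    x[((i - 1L) * hop + 1L):((i - 1L) * hop + frameLen)] * ham
  }, numeric(frameLen))
  stats::mvfft(rbind(frames, matrix(0, nFft - frameLen, nFrames)))
}
.istft <- function(X, frameLen, hop, nSamples) {
  nFft <- nrow(X)
  nFrames <- ncol(X)
  ham <- 0.54 - 0.46 * cos(2 * pi * (0:(frameLen - 1L)) / (frameLen - 1L))
  y <- numeric(nSamples)
  wsum <- numeric(nSamples)
  frames <- Re(stats::mvfft(X, inverse = TRUE)) / nFft
  for (i in seq_len(nFrames)) {
    idx <- ((i - 1L) * hop + 1L):((i - 1L) * hop + frameLen)
    keep <- idx <= nSamples
    y[idx[keep]] <- y[idx[keep]] + frames[seq_len(frameLen), i][keep] *
      ham[keep]
    wsum[idx[keep]] <- wsum[idx[keep]] + ham[keep]^2
  }
  y / pmax(wsum, 1e-8)
}

#' Reconstruct a waveform from predicted audio token IDs
#'
#' Each ID's centroid MFCC vector is inverted back to a mel power
#' envelope (inverse DCT, exponential), lifted to a linear magnitude
#' spectrum via the least-norm filterbank inverse, tiled over the
#' token's analysis window, and rendered to audio by iterative phase
#' reconstruction (Griffin-Lim, seeded random initial phase). Unknown
#' IDs render as silence.
#'
#' @param ids a [DiscreteSequence-class] of audio dictionary IDs.
#' @param dict the audio [FeatureDictionary-class] (its `meta` must
#'   carry the MFCC settings, as written by [runExperiment()] or
#'   [trialFeatures()]).
#' @param rateHz output sampling rate.
#' @param nIter Griffin-Lim iterations (default 32).
#' @param seed phase-initialization seed.
#' @return an [AudioTrack-class].
#' @export
reconstructAudio <- function(ids, dict, rateHz, nIter = 32, seed = 1) {
  stopifnot(is(ids, "DiscreteSequence"), is(dict, "FeatureDictionary"))
  if (dict@modality != "audio") {
    stop("modality error: reconstruction needs an audio dictionary",
         call. = FALSE)
  }
  meta <- dict@meta
  frameS <- if (is.null(meta$frameS)) 0.025 else meta$frameS
  hopS <- if (is.null(meta$hopS)) 0.010 else meta$hopS
  nMels <- if (is.null(meta$nMels)) 26L else as.integer(meta$nMels)
  windowS <- if (is.null(meta$windowS)) 4 else meta$windowS
  frameLen <- round(frameS * rateHz)
  hop <- round(hopS * rateHz)
  nFft <- 2L^as.integer(ceiling(log2(frameLen)))
  nBins <- nFft %/% 2L + 1L
  fb <- melFilterbank(nMels, nFft, rateHz)
  fbInv <- t(fb) %*% solve(fb %*% t(fb) + 1e-8 * diag(nMels))
  nCoef <- ncol(dict@centroids)
  D <- .dctMatrix(nCoef, nMels)
  winSamples <- round(windowS * rateHz)
  framesPerWin <- floor((winSamples - frameLen) / hop) + 1L
  mags <- lapply(ids@ids, function(id) {
    if (id == dict@unkId) {
      matrix(0, nBins, framesPerWin)
    } else {
      logMel <- as.numeric(crossprod(D, dict@centroids[id + 1L, ]))
      linPow <- pmax(as.numeric(fbInv %*% exp(logMel)), 0)
      matrix(sqrt(linPow * nFft), nBins, framesPerWin)
    }
  })
  S <- do.call(cbind, mags)                       # nBins x totalFrames
  nSamples <- length(ids@ids) * winSamples
  if (max(S) <= 0) return(AudioTrack(numeric(nSamples), rateHz))
  Sfull <- rbind(S, S[(nBins - 1L):2L, , drop = FALSE][
    seq_len(nFft - nBins), , drop = FALSE])
  phase <- withSeed(seed,
                    matrix(stats::runif(length(Sfull), 0, 2 * pi),
                           nrow(Sfull)))
  ## conjugate symmetry of the initial phase keeps the signal real
  X <- Sfull * exp(1i * phase)
  for (it in seq_len(nIter)) {
    x <- .istft(X, frameLen, hop, nSamples)
    Xn <- .stft(x, frameLen, hop, nFft)
    ang <- Arg(Xn)
    nf <- min(ncol(Xn), ncol(Sfull))
    X <- Sfull[, seq_len(nf), drop = FALSE] *
      exp(1i * ang[, seq_len(nf), drop = FALSE])
  }
  x <- .istft(X, frameLen, hop, nSamples)
  peak <- max(abs(x))
  if (peak > 0) x <- x / peak
  AudioTrack(x, rateHz)
}
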