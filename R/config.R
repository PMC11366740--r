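## Pipeline configuration (YAML-friendly), validation with exhaustive
## error reporting, the staged pipeline runner, and provenance-stamped
## run manifests.

.defaultProvenance <- function() {
  ## which defaults restate the study conditions vs. package decisions
  list(
    reported = c("preproc.lowHz", "preproc.highHz", "preproc.windowS",
                 "synth.eegRateHz", "synth.nChannels", "synth.trialS",
                 "synth.baselineS", "model.dLayers",
                 "evaluate.kValues", "evaluate.testFraction"),
    decision = c("synth.K", "synth.stayProb", "synth.noiseSd",
                 "synth.audioRateHz", "features.nCoef", "features.bands",
                 "discretize.noiseFactor", "model.alpha",
                 "model.maskRatio", "model.dModel", "model.lr",
                 "model.batchPairs", "evaluate.nMaskDraws"))
}

#' Default pipeline configuration
#'
#' @param seed global seed fanned out to per-stage seeds.
#' @return nested config list (class `"pipelineConfig"`).
#' @export
defaultConfig <- function(seed = 1) {
  cfg <- list(
    seed = as.integer(seed),
    outputDir = "neuromelody-run",
    synth = list(nSubjects = 7L, nTrials = 2L, nChannels = 32L,
                 eegRateHz = 128, audioRateHz = 8000, trialS = 60,
                 baselineS = 3, K = 4L, stayProb = 0.9, frameS = 4,
                 noiseSd = 0.3),
    preproc = list(lowHz = 4, highHz = 45, windowS = 4,
                   targetHz = NULL),
    features = list(nCoef = 20L, bands = defaultBands()),
    discretize = list(eegEps = NULL, eegMinPts = NULL, audioEps = NULL,
                      audioMinPts = NULL, noiseFactor = 1.5),
    model = list(dLayers = 2L, nHeads = 4L, dModel = 64L, dFf = 128L,
                 dropout = 0, alpha = 0.1, maskRatio = 0.3, lr = 1e-3,
                 batchPairs = 60L, backbone = "transformer"),
    evaluate = list(kValues = c(1L, 3L, 5L, 10L, 20L),
                    testFraction = 0.2, nMaskDraws = 10L, epochs = 10L))
  cfg$provenance <- .defaultProvenance()
  class(cfg) <- c("pipelineConfig", "list")
  cfg
}

## deep-merge user values over defaults
.mergeConfig <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- .mergeConfig(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Validate a pipeline configuration
#'
#' Fills defaults ([defaultConfig()]), then checks field and cross-field
#' constraints, reporting every violation at once. Cross-field rules:
#' `dModel` even and divisible by `nHeads`; every DE band inside the
#' filter band; filter band below the EEG Nyquist.
#'
#' @param raw NULL (pure defaults), a nested list, or a YAML file path.
#' @param seed seed used when the document does not set one.
#' @return validated `pipelineConfig`.
#' @export
validateConfig <- function(raw = NULL, seed = 1) {
  if (is.character(raw) && length(raw) == 1L) {
    if (!file.exists(raw)) stop("config file not found: ", raw,
                                call. = FALSE)
    raw <- yaml::read_yaml(raw)
  }
  cfg <- defaultConfig(seed)
  if (!is.null(raw)) cfg <- .mergeConfig(cfg, raw)
  errs <- character()
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)

  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed),
      "seed: must be an integer")
  with(cfg$synth, {
    chk(nSubjects >= 1, "synth.nSubjects: must be >= 1")
    chk(nTrials >= 1, "synth.nTrials: must be >= 1")
    chk(nChannels >= 1, "synth.nChannels: must be >= 1")
    chk(eegRateHz > 0, "synth.eegRateHz: must be > 0")
    chk(audioRateHz > 0, "synth.audioRateHz: must be > 0")
    chk(baselineS >= 0, "synth.baselineS: must be >= 0")
    chk(K >= 1, "synth.K: must be >= 1")
    chk(stayProb >= 0 && stayProb <= 1,
        "synth.stayProb: must lie in [0, 1]")
  })
  with(cfg$preproc, {
    chk(lowHz > 0 && lowHz < highHz,
        "preproc: need 0 < lowHz < highHz")
    chk(windowS > 0, "preproc.windowS: must be > 0")
  })
  rate <- if (is.null(cfg$preproc$targetHz)) cfg$synth$eegRateHz else
    cfg$preproc$targetHz
  chk(cfg$preproc$highHz < rate / 2,
      sprintf("preproc.highHz: %g must be < EEG Nyquist %g",
              cfg$preproc$highHz, rate / 2))
  for (bn in names(cfg$features$bands)) {
    b <- cfg$features$bands[[bn]]
    chk(b[1] >= cfg$preproc$lowHz - 1e-9 &&
          b[2] <= cfg$preproc$highHz + 1e-9,
        sprintf("features.bands.%s: [%g, %g] outside filter band [%g, %g]",
                bn, b[1], b[2], cfg$preproc$lowHz, cfg$preproc$highHz))
  }
  with(cfg$model, {
    chk(dModel %% 2 == 0,
        "model.dModel: must be even (sin/cos positional pairs)")
    chk(dModel %% nHeads == 0,
        "model.dModel: must be divisible by model.nHeads")
    chk(dLayers >= 1, "model.dLayers: must be >= 1")
    chk(alpha >= 0 && alpha <= 1, "model.alpha: must lie in [0, 1]")
    chk(maskRatio >= 0 && maskRatio <= 1,
        "model.maskRatio: must lie in [0, 1]")
    chk(dropout >= 0 && dropout <= 1,
        "model.dropout: must lie in [0, 1]")
    chk(backbone %in% c("transformer", "lstm", "cnn"),
        "model.backbone: must be transformer, lstm or cnn")
  })
  with(cfg$evaluate, {
    chk(testFraction > 0 && testFraction < 1,
        "evaluate.testFraction: must lie in (0, 1)")
    chk(all(kValues >= 1), "evaluate.kValues: must be >= 1")
    chk(epochs >= 1, "evaluate.epochs: must be >= 1")
  })
  if (length(errs)) {
    stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "),
         call. = FALSE)
  }
  cfg
}

## lightweight content digest for manifests (size + byte sum + FNV of
## the first 4 KiB): deterministic, cheap on multi-MB fixtures
.fileDigest <- function(path) {
  n <- file.info(path)$size
  con <- file(path, "rb")
  on.exit(close(con))
  head <- as.integer(readBin(con, raw(), n = min(n, 1024)))
  total <- sum(head)
  while (TRUE) {
    chunk <- readBin(con, integer(), n = 65536, size = 1, signed = FALSE)
    if (!length(chunk)) break
    total <- (total + sum(chunk * seq_along(chunk))) %% 4294967296
  }
  fnv1a(paste(n, total, paste(head[seq_len(min(64, length(head)))],
                              collapse = ",")))
}

.pipelineStages <- c("synth", "preproc", "features", "dict", "train",
                     "evaluate", "reconstruct")

#' Run the staged pipeline
#'
#' Executes the requested stages in order — synthetic-data generation,
#' preprocessing, feature extraction, dictionary learning, model
#' training, held-out evaluation, audio reconstruction — each stage
#' consuming the previous stage's in-memory output and writing its
#' artifacts under `cfg$outputDir`. A run manifest (config hash, stage
#' list, output-file digests, timestamps) is written and returned.
#'
#' @param cfg a validated [validateConfig()] configuration.
#' @param stages ordered subset of
#'   `c("synth","preproc","features","dict","train","evaluate","reconstruct")`.
#' @return the manifest list, invisibly.
#' @export
runPipeline <- function(cfg = validateConfig(),
                        stages = .pipelineStages) {
  if (!inherits(cfg, "pipelineConfig")) cfg <- validateConfig(cfg)
  stages <- match.arg(stages, .pipelineStages, several.ok = TRUE)
  outDir <- cfg$outputDir
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  state <- new.env(parent = emptyenv())
  files <- character()
  ranStages <- list()
  need <- function(what, stage) {
    if (!exists(what, envir = state)) {
      stop(sprintf("dependency error: stage '%s' requires output of '%s'",
                   stage, what), call. = FALSE)
    }
    get(what, envir = state)
  }
  for (st in stages) {
    t0 <- Sys.time()
    if (st == "synth") {
      scfg <- do.call(synthConfig, c(cfg$synth,
                                     list(seed = deriveSeed(cfg$seed,
                                                            "synth"))))
      dataset <- genDataset(scfg)
      fixDir <- file.path(outDir, "fixtures")
      manifest <- writeFixture(dataset, fixDir)
      files <- c(files, manifest)
      assign("synth", dataset, envir = state)
    } else if (st == "preproc") {
      dataset <- need("synth", st)
      assign("preproc",
             .segmentAll(dataset, lowHz = cfg$preproc$lowHz,
                         highHz = cfg$preproc$highHz,
                         windowS = cfg$preproc$windowS,
                         targetHz = cfg$preproc$targetHz),
             envir = state)
    } else if (st == "features") {
      seg <- need("preproc", st)
      assign("features",
             .featurizeAll(seg, bandEdges = cfg$features$bands,
                           nCoef = cfg$features$nCoef),
             envir = state)
    } else if (st == "dict") {
      trials <- need("features", st)
      subjects <- unique(vapply(trials, `[[`, character(1), "subjectId"))
      split <- splitSubjects(subjects,
                             testFraction = cfg$evaluate$testFraction,
                             seed = deriveSeed(cfg$seed, "split"))
      isTrain <- vapply(trials, function(tr)
        tr$subjectId %in% split$trainSubjects, logical(1))
      eegTrain <- do.call(rbind, lapply(trials[isTrain], `[[`, "eegFeat"))
      audTrain <- do.call(rbind, lapply(trials[isTrain], `[[`,
                                        "audioFeat"))
      dp <- cfg$discretize
      eegParams <- if (!is.null(dp$eegEps)) {
        dbscanParams(dp$eegEps,
                     if (is.null(dp$eegMinPts))
                       estimateDbscanParams(eegTrain)$minPts else
                         dp$eegMinPts,
                     noiseFactor = dp$noiseFactor)
      } else {
        NULL
      }
      audParams <- if (!is.null(dp$audioEps)) {
        dbscanParams(dp$audioEps,
                     if (is.null(dp$audioMinPts))
                       estimateDbscanParams(audTrain)$minPts else
                         dp$audioMinPts,
                     noiseFactor = dp$noiseFactor)
      } else {
        NULL
      }
      eegDict <- learnDictionary(eegTrain, "eeg", params = eegParams)
      audioDict <- learnDictionary(audTrain, "audio", params = audParams,
                                   meta = c(trials[[1]]$meta,
                                            list(windowS =
                                                   cfg$preproc$windowS)))
      f1 <- file.path(outDir, "dict_eeg.json")
      f2 <- file.path(outDir, "dict_audio.json")
      saveDictionary(eegDict, f1)
      saveDictionary(audioDict, f2)
      files <- c(files, f1, f2)
      assign("dict", list(eegDict = eegDict, audioDict = audioDict,
                          split = split, isTrain = isTrain),
             envir = state)
    } else if (st == "train") {
      trials <- need("features", st)
      dict <- need("dict", st)
      mcfg <- do.call(modelConfig,
                      c(cfg$model, list(seed = deriveSeed(cfg$seed,
                                                          "model"))))
      cnnSeed <- deriveSeed(cfg$seed, "frontend")
      pairs <- lapply(trials, function(tr) {
        list(eegContent = cnnContentFeatures(tr$seg@eegWindows, "eeg",
                                             mcfg$dModel, cnnSeed),
             eegIds = encodeSequence(tr$eegFeat, dict$eegDict)@ids,
             audioContent = cnnContentFeatures(tr$seg@audioWindows,
                                               "audio", mcfg$dModel,
                                               cnnSeed),
             audioIds = encodeSequence(tr$audioFeat, dict$audioDict)@ids,
             subjectId = tr$subjectId, trialId = tr$trialId)
      })
      model <- buildModel(mcfg, nClusters(dict$eegDict) + 1L,
                          nClusters(dict$audioDict) + 1L)
      model <- fitModel(model, pairs[dict$isTrain],
                        epochs = cfg$evaluate$epochs)
      f <- file.path(outDir, "training_log.csv")
      utils::write.csv(lossHistory(model), f, row.names = FALSE)
      files <- c(files, f)
      assign("train", list(model = model, pairs = pairs, mcfg = mcfg),
             envir = state)
    } else if (st == "evaluate") {
      trained <- need("train", st)
      dict <- need("dict", st)
      testPairs <- trained$pairs[!dict$isTrain]
      refAll <- c(); probAll <- NULL
      for (i in seq_along(testPairs)) {
        p <- testPairs[[i]]
        La <- nrow(p$audioContent)
        nMask <- max(1L, round(trained$mcfg$maskRatio * La))
        for (dr in seq_len(cfg$evaluate$nMaskDraws)) {
          ms <- withSeed(deriveSeed(cfg$seed,
                                    sprintf("evalmask/%d/%d", i, dr)),
                         sort(sample.int(La, nMask)))
          pr <- .predictProbs(trained$model, p$eegContent, p$eegIds, La,
                              maskSet = ms,
                              audioContent = p$audioContent,
                              audioIds = p$audioIds)
          probAll <- rbind(probAll, pr[ms, , drop = FALSE])
          refAll <- c(refAll, p$audioIds[ms])
        }
      }
      hr <- hitsAtK(probAll, refAll, kValues = cfg$evaluate$kValues)
      f <- file.path(outDir, "evaluation.json")
      jsonlite::write_json(list(k = hr@kValues, hits = unname(hr@hits),
                                n = hr@n),
                           f, auto_unbox = TRUE, digits = NA)
      files <- c(files, f)
      assign("evaluate", hr, envir = state)
    } else if (st == "reconstruct") {
      trained <- need("train", st)
      dict <- need("dict", st)
      testPairs <- trained$pairs[!dict$isTrain]
      p <- testPairs[[1]]
      ids <- generateIds(trained$model, p$eegContent, p$eegIds,
                         nrow(p$audioContent))
      wav <- reconstructAudio(ids, dict$audioDict,
                              rateHz = cfg$synth$audioRateHz,
                              seed = deriveSeed(cfg$seed, "phase"))
      f <- file.path(outDir, "reconstructed.wav")
      writeWav(wav, f)
      files <- c(files, f)
      assign("reconstruct", ids, envir = state)
    }
    ranStages[[st]] <- list(stage = st,
                            startedAt = format(t0, "%Y-%m-%dT%H:%M:%S"),
                            seconds = as.numeric(difftime(Sys.time(), t0,
                                                          units = "secs")))
  }
  cfgNoProv <- unclass(cfg)
  cfgNoProv$provenance <- NULL
  cfgNoProv$outputDir <- NULL   # identity of a run, not its location
  manifest <- list(configHash = stableHash(cfgNoProv),
                   packageVersion = as.character(
                     utils::packageVersion("NeuroMelody")),
                   seed = cfg$seed,
                   stages = unname(ranStages),
                   files = lapply(stats::setNames(files, basename(files)),
                                  .fileDigest))
  jsonlite::write_json(manifest, file.path(outDir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
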