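test_that("hits@k counts ranks exactly as the indicator average", {
  ## reference always top-ranked
  p <- matrix(c(0.7, 0.2, 0.1,
                0.6, 0.3, 0.1), 2, byrow = TRUE)
  hr <- hitsAtK(p, c(0L, 0L), kValues = c(1, 2))
  expect_equal(unname(hits(hr)), c(1, 1))

  ## engineered ranks 1, 5, 30 -> hits@10 = 2/3
  V <- 40L
  probs <- matrix(0, 3, V)
  probs[1, ] <- c(1, rep(0, V - 1))
  probs[2, 1:5] <- c(0.9, 0.8, 0.7, 0.6, 0.5)
  probs[3, ] <- seq(V, 1) / V
  refs <- c(0L, 4L, 29L)
  hr2 <- hitsAtK(probs, refs, kValues = c(1, 10, 40))
  expect_equal(ranks(hr2), c(1L, 5L, 30L))
  expect_equal(unname(hits(hr2)), c(1 / 3, 2 / 3, 1))

  ## ties break toward the lower index (pessimistic for the reference)
  tied <- matrix(0.25, 1, 4)
  expect_equal(ranks(hitsAtK(tied, 2L, kValues = 1)), 3L)

  ## exhaustive-count oracle on random instances
  withSeed(31, {
    for (rep in 1:20) {
      L <- sample(5:40, 1); V <- sample(3:20, 1)
      pr <- matrix(runif(L * V), L)
      refs <- sample(0:(V - 1L), L, TRUE)
      hr <- hitsAtK(pr, refs, kValues = 1:V)
      oracleRank <- vapply(1:L, function(i) {
        ord <- order(-pr[i, ], seq_len(V))
        which(ord == refs[i] + 1L)
      }, integer(1))
      expect_identical(ranks(hr), as.integer(oracleRank))
      expect_true(all(diff(hits(hr)) >= 0))
      expect_equal(unname(hits(hr))[V], 1)
    }
  })

  expect_error(hitsAtK(p, c(0L, 0L), positions = integer()),
               "undefined metric")
  expect_error(hitsAtK(p, c(0L, 5L)), "vocabulary")
})

test_that("subject split is a seeded 8:2 partition", {
  ids <- sprintf("s%02d", 1:32)
  sp <- splitSubjects(ids, seed = 4)
  expect_equal(length(sp$testSubjects), 6)   # round(0.2 * 32)
  expect_equal(length(sp$trainSubjects), 26)
  expect_identical(sp, splitSubjects(ids, seed = 4))
  for (seed in 1:50) {
    s <- splitSubjects(ids, seed = seed)
    expect_length(intersect(s$trainSubjects, s$testSubjects), 0)
    expect_setequal(c(s$trainSubjects, s$testSubjects), ids)
  }
  expect_error(splitSubjects(sprintf("s%d", 1:4)), "invalid split")
})

test_that("quantile binning codec is total, seeded by data, and fragments", {
  X <- withSeed(8, matrix(rnorm(60 * 8), 60))
  codec <- NeuroMelody:::.makeBinningCodec(X, binsPerDim = 2)
  ids <- codec$encode(X)@ids
  expect_true(all(ids >= 0L & ids < codec$vocab))
  expect_false(any(ids == codec$unkId))  # training codes are in-vocab
  ## a frame with an unobserved joint bin code maps to unk: 60 frames
  ## cannot cover all 2^8 codes, so some sign pattern is unseen
  seen <- apply(sweep(X, 2, apply(X, 2, median)) > 0, 1, paste,
                collapse = "")
  all02 <- vapply(0:255, function(v)
    paste(as.integer(intToBits(v))[1:8], collapse = ""), character(1))
  missing <- setdiff(all02, unique(seen))[1]
  far <- matrix(100 * (2 * as.integer(strsplit(missing, "")[[1]]) - 1),
                1)
  expect_equal(codec$encode(far)@ids, codec$unkId)
  ## high-dimensional continuous frames fragment into many codes
  expect_gt(codec$vocab, 20)
})

test_that("audio reconstruction renders tokens as their spectra", {
  ## dictionary with two synthetic tone classes
  rate <- 8000
  mk <- function(f0) {
    t <- (0:(4 * rate - 1)) / rate
    colMeans(mfcc(sin(2 * pi * f0 * t), rate)@values)
  }
  frames <- rbind(t(replicate(10, mk(300) + rnorm(20, sd = 0.01))),
                  t(replicate(10, mk(1200) + rnorm(20, sd = 0.01))))
  dict <- learnDictionary(frames, "audio",
                          params = dbscanParams(2, 3),
                          meta = list(nCoef = 20, nMels = 26,
                                      frameS = 0.025, hopS = 0.010,
                                      windowS = 4))
  expect_equal(nClusters(dict), 2L)
  ids <- encodeSequence(rbind(mk(300), mk(1200)), dict)
  wav <- reconstructAudio(ids, dict, rate, seed = 3)
  expect_equal(length(signalData(wav)), 2 * 4 * rate)

  ## dominant mel band of each reconstructed window matches the source
  fb <- NeuroMelody:::melFilterbank(26, 256, rate)
  melPeak <- function(x) {
    sp <- Mod(fft(x))^2
    half <- sp[1:129]
    which.max(fb %*% half)
  }
  x <- signalData(wav)
  w1 <- x[1:(4 * rate)]; w2 <- x[(4 * rate + 1):(8 * rate)]
  t <- (0:(4 * rate - 1)) / rate
  expect_lte(abs(melPeak(w1[1:256]) - melPeak(sin(2 * pi * 300 * t)[1:256])), 1)
  expect_lte(abs(melPeak(w2[1:256]) - melPeak(sin(2 * pi * 1200 * t)[1:256])), 1)

  ## determinism given the seed
  wav2 <- reconstructAudio(ids, dict, rate, seed = 3)
  expect_identical(signalData(wav), signalData(wav2))

  ## all-unk renders silence of the contracted duration
  unkSeq <- new("DiscreteSequence", ids = rep(unkId(dict), 3L),
                sourceFrames = 1:3)
  silent <- reconstructAudio(unkSeq, dict, rate)
  expect_true(all(signalData(silent) == 0))
  expect_equal(length(signalData(silent)), 3 * 4 * rate)

  eegDict <- dict
  eegDict@modality <- "eeg"
  expect_error(reconstructAudio(ids, eegDict, rate), "modality")
})

test_that("experiment harness is deterministic and writes reports", {
  data <- tinyDataset()
  out1 <- file.path(tempdir(), "rep1")
  rep1 <- runExperiment(data, ablationSpec(dLayers = 1), seed = 3,
                        epochs = 2, nMaskDraws = 2, outDir = out1)
  rep2 <- runExperiment(data, ablationSpec(dLayers = 1), seed = 3,
                        epochs = 2, nMaskDraws = 2)
  expect_equal(rep1$hitsMasked, rep2$hitsMasked)
  expect_equal(rep1$hitsGenerate, rep2$hitsGenerate)
  expect_equal(rep1$configHash, rep2$configHash)
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "report.csv")))
  expect_true(all(diff(rep1$hitsMasked$hits) >= 0))

  ## depth sweep: one report per depth
  reps <- lapply(c(1, 2), function(d)
    runExperiment(data, ablationSpec(dLayers = d), seed = 3,
                  epochs = 1, nMaskDraws = 1))
  expect_equal(vapply(reps, function(r) r$ablation$dLayers, numeric(1)),
               c(1, 2))
})
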