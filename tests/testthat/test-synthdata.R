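test_that("latent Markov chain respects its transition structure", {
  cfg <- synthConfig(nSubjects = 1, nTrials = 1, trialS = 40, K = 1,
                     seed = 3)
  expect_true(all(states(genLatentStates(cfg)) == 0L))
  expect_identical(states(genLatentStates(cfg, seed = 1)),
                   states(genLatentStates(cfg, seed = 2)))

  ## absorbing chain: stayProb = 1 keeps the initial state forever
  cfgAbs <- synthConfig(nSubjects = 1, nTrials = 1, trialS = 40, K = 4,
                        stayProb = 1, seed = 5)
  st <- states(genLatentStates(cfgAbs))
  expect_true(all(st == st[1]))

  ## empirical stay fraction within 3 Monte-Carlo SDs of stayProb
  cfgLong <- synthConfig(nSubjects = 1, nTrials = 1,
                         trialS = 10000 * 4, K = 4, stayProb = 0.9,
                         seed = 7)
  st <- states(genLatentStates(cfgLong))
  nTrans <- length(st) - 1
  stay <- mean(st[-1] == st[-length(st)])
  sd3 <- 3 * sqrt(0.9 * 0.1 / nTrans)
  expect_lt(abs(stay - 0.9), sd3)

  expect_error(synthConfig(K = 0), "K")
})

test_that("coupled pairs are deterministic, DEAP-shaped, and coupled", {
  cfg <- tinyConfig()
  lat <- genLatentStates(cfg, seed = 9)
  p1 <- genCoupledPair(cfg, lat, seed = 4)
  p2 <- genCoupledPair(cfg, lat, seed = 4)
  expect_identical(p1$eeg@data, p2$eeg@data)
  expect_identical(p1$audio@data, p2$audio@data)

  ## shape: channels x round((baseline + trial) * rate)
  expect_equal(dim(p1$eeg@data),
               c(cfg$nChannels,
                 round((cfg$baselineS + cfg$trialS) * cfg$eegRateHz)))
  expect_equal(length(p1$audio@data), round(cfg$trialS * cfg$audioRateHz))
  expect_identical(channelNames(p1$eeg)[1:4], c("Fp1", "AF3", "F7", "F3"))

  ## noiseless single state: EEG spectrum concentrated at the template
  ## frequency (10 Hz for K = 1)
  cfg1 <- synthConfig(nSubjects = 1, nTrials = 1, trialS = 8,
                      baselineS = 0, K = 1, noiseSd = 0, seed = 2)
  pr <- genCoupledPair(cfg1, genLatentStates(cfg1))
  x <- pr$eeg@data[1, ] - mean(pr$eeg@data[1, ])
  spec <- Mod(fft(x))^2
  freq <- (seq_along(x) - 1) * cfg1$eegRateHz / length(x)
  peak <- freq[which.max(spec[2:(length(x) / 2)]) + 1]
  expect_lt(abs(peak - 10), 0.5)

  ## mismatch: latent too short for the trial
  latShort <- genLatentStates(synthConfig(nSubjects = 1, nTrials = 1,
                                          trialS = 8, K = 3, seed = 2))
  expect_error(genCoupledPair(cfg, latShort), "cover")
})

test_that("per-frame band-power classifier recovers the latent states", {
  ## K = 2 with well-separated template bands, noiseless
  cfg <- synthConfig(nSubjects = 1, nTrials = 1, trialS = 60,
                     baselineS = 0, K = 2, noiseSd = 0, seed = 6)
  lat <- genLatentStates(cfg, seed = 31)
  pr <- genCoupledPair(cfg, lat, seed = 1)
  ## oracle: argmax of band power around each state's template frequency
  ## (6 and 38 Hz for K = 2)
  w <- round(cfg$frameS * cfg$eegRateHz)
  nF <- length(states(lat))
  pred <- vapply(seq_len(nF), function(t) {
    seg <- pr$eeg@data[, ((t - 1) * w + 1):(t * w), drop = FALSE]
    pow <- function(f0) {
      ## noiseless off-template bands hit the variance floor by design
      de <- suppressWarnings(
        differentialEntropy(seg, cfg$eegRateHz,
                            list(c(f0 - 2, f0 + 2))))
      mean(de@values)
    }
    which.max(c(pow(6), pow(38))) - 1L
  }, integer(1))
  expect_gt(mean(pred == states(lat)), 0.95)
})

test_that("latent/EEG coupling weakens monotonically with noise", {
  ## plug-in mutual information between latent states and the
  ## band-power argmax over state template bands, three noise levels
  miAt <- function(noiseSd) {
    cfg <- synthConfig(nSubjects = 1, nTrials = 1, trialS = 120,
                       baselineS = 0, K = 2, noiseSd = noiseSd, seed = 8)
    lat <- genLatentStates(cfg, seed = 21)
    pr <- genCoupledPair(cfg, lat, seed = 3)
    w <- round(cfg$frameS * cfg$eegRateHz)
    pred <- vapply(seq_along(states(lat)), function(t) {
      seg <- pr$eeg@data[1:4, ((t - 1) * w + 1):(t * w), drop = FALSE]
      de1 <- mean(differentialEntropy(seg, 128, list(c(4, 8)))@values)
      de2 <- mean(differentialEntropy(seg, 128, list(c(36, 40)))@values)
      as.integer(de2 > de1)
    }, integer(1))
    tab <- table(factor(pred, 0:1), factor(states(lat), 0:1)) /
      length(pred)
    mi <- 0
    for (i in 1:2) for (j in 1:2) {
      if (tab[i, j] > 0) {
        mi <- mi + tab[i, j] *
          log(tab[i, j] / (sum(tab[i, ]) * sum(tab[, j])))
      }
    }
    mi
  }
  mis <- vapply(c(0.05, 1, 6), miAt, numeric(1))
  expect_gt(mis[1], 0)
  expect_true(all(diff(mis) <= 1e-12))
})

test_that("fixtures round-trip through NPY/WAV/manifest", {
  dir <- file.path(tempdir(), "fix-test")
  unlink(dir, recursive = TRUE)
  data <- tinyDataset()
  manifest <- writeFixture(data, dir)
  expect_true(file.exists(manifest))
  m <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  expect_equal(m$n_trials, length(data))

  back <- readFixture(dir)
  expect_equal(length(back), length(data))
  ## EEG numeric round-trip is exact (float64 NPY)
  expect_equal(back[[1]]$eeg@data, data[[1]]$eeg@data,
               ignore_attr = TRUE)
  expect_identical(channelNames(back[[1]]$eeg),
                   channelNames(data[[1]]$eeg))
  ## WAV round-trip within 16-bit quantization of the clipped signal
  expect_lt(max(abs(back[[2]]$audio@data -
                      pmax(-1, pmin(1, data[[2]]$audio@data)))), 1e-4)
  expect_equal(rateHz(back[[2]]$audio), data[[2]]$audio@rateHz)
  expect_identical(states(back[[3]]$latent), states(data[[3]]$latent))
})

test_that("NPY files interoperate across writers and fail on truncation", {
  m <- matrix(rnorm(15), 3)
  path <- tempfile(fileext = ".npy")
  writeNpy(m, path)
  expect_equal(readNpy(path), m, ignore_attr = TRUE)
  ## truncated file is rejected
  raw <- readBin(path, raw(), n = file.info(path)$size)
  writeBin(raw[1:100], path)
  expect_error(readNpy(path), "truncated")
})
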