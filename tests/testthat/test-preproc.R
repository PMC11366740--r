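mkRec <- function(x, rate = 128, baseline = 0) {
  EEGRecording(matrix(x, nrow = 1), rate, baselineS = baseline)
}

test_that("band-pass filter keeps the pass band and kills the stop band", {
  t <- (0:(128 * 8 - 1)) / 128
  rms <- function(x) sqrt(mean(x^2))
  trim <- 128  # discard one second of edges

  stopBand <- bandpassFilter(mkRec(sin(2 * pi * 2 * t)), 4, 45)
  expect_lt(rms(signalData(stopBand)[1, trim:(1024 - trim)]),
            0.05 * rms(sin(2 * pi * 2 * t)))

  passBand <- bandpassFilter(mkRec(sin(2 * pi * 10 * t)), 4, 45)
  expect_lt(abs(rms(signalData(passBand)[1, trim:(1024 - trim)]) /
                  rms(sin(2 * pi * 10 * t)) - 1), 0.05)

  ## white noise: out-of-band power down >= 20 dB relative to pass band
  x <- withSeed(1, rnorm(128 * 30))
  filt <- signalData(bandpassFilter(mkRec(x), 4, 45))[1, ]
  spec <- Mod(fft(filt))^2
  freq <- (seq_along(filt) - 1) * 128 / length(filt)
  inBand <- freq > 8 & freq < 40
  outBand <- (freq > 0.1 & freq < 2) | (freq > 55 & freq <= 64)
  expect_gt(10 * log10(mean(spec[inBand]) / mean(spec[outBand])), 20)

  expect_error(bandpassFilter(mkRec(x), 4, 70), "Nyquist")
  ## linearity: f(a x) = a f(x)
  f1 <- signalData(bandpassFilter(mkRec(x), 4, 45))
  f3 <- signalData(bandpassFilter(mkRec(3 * x), 4, 45))
  expect_equal(f3, 3 * f1, tolerance = 1e-10)
})

test_that("decimation preserves duration, rate and in-band content", {
  t <- (0:(512 * 60 - 1)) / 512
  rec <- mkRec(sin(2 * pi * 8 * t), rate = 512)
  dn <- downsampleEEG(rec, 128)
  expect_equal(rateHz(dn), 128)
  expect_equal(ncol(signalData(dn)), 60 * 128)

  ## 8 Hz sinusoid survives 512 -> 128 Hz with amplitude within 5%
  y <- signalData(dn)[1, (2 * 128):(58 * 128)]
  tt <- seq_along(y)
  fit <- lm(y ~ sin(2 * pi * 8 * tt / 128) + cos(2 * pi * 8 * tt / 128))
  amp <- sqrt(sum(coef(fit)[2:3]^2))
  expect_lt(abs(amp - 1), 0.05)

  expect_identical(downsampleEEG(rec, 512), rec)  # identity
  expect_error(downsampleEEG(rec, 1024), "upsampling")
})

test_that("baseline removal drops and centers exactly", {
  ## 63 s at 128 Hz = 3 s baseline + 60 s stimulus
  n <- 63 * 128
  rec <- EEGRecording(matrix(rnorm(2 * n) + 5, nrow = 2), 128,
                      baselineS = 3)
  out <- removeBaseline(rec)
  expect_equal(ncol(signalData(out)), 60 * 128)
  expect_equal(baselineS(out), 0)

  ## constant channel becomes all zeros
  recC <- EEGRecording(matrix(7, 1, 10 * 128), 128, baselineS = 3)
  expect_true(all(signalData(removeBaseline(recC)) == 0))

  expect_error(removeBaseline(mkRec(rnorm(128), baseline = 0)),
               "baseline")
})

test_that("segmentation partitions the stimulus into aligned windows", {
  mkPair <- function(sec) {
    list(eeg = EEGRecording(matrix(rnorm(2 * sec * 128), 2), 128),
         audio = AudioTrack(rnorm(sec * 1000), 1000))
  }
  p <- mkPair(60)
  seg <- segmentWindows(p$eeg, p$audio, 4)
  expect_equal(length(seg@eegWindows), 15)
  expect_equal(length(seg@audioWindows), 15)
  expect_equal(dim(seg@eegWindows[[1]]), c(2, 512))
  expect_equal(length(seg@audioWindows[[1]]), 4000)

  ## trailing partial second dropped; a 61 s pair still yields 15
  p61 <- mkPair(61)
  expect_equal(length(segmentWindows(p61$eeg, p61$audio, 4)@eegWindows),
               15)
  ## single full-trial window
  seg1 <- segmentWindows(p$eeg, p$audio, 60)
  expect_equal(length(seg1@eegWindows), 1)
  expect_equal(seg1@eegWindows[[1]], signalData(p$eeg))

  ## concatenating the windows reproduces the first 60 s exactly
  expect_equal(do.call(cbind, seg@eegWindows), signalData(p$eeg))

  expect_error(segmentWindows(p$eeg, p$audio, 120), "window")
  ## duration mismatch
  expect_error(segmentWindows(p$eeg, AudioTrack(rnorm(30000), 1000), 4),
               "durations differ")
})

test_that("channel selection subsets, reorders and reports offenders", {
  rec <- EEGRecording(matrix(rnorm(32 * 128), 32), 128,
                      channelNames = deapChannels())
  ## full montage list is the identity permutation
  same <- selectChannels(rec, deapChannels())
  expect_identical(signalData(same), signalData(rec))

  one <- selectChannels(rec, "Fp1")
  expect_equal(signalData(one), signalData(rec)[1, , drop = FALSE])

  sub <- selectChannels(rec, channelSubsets()$tiraboschi)
  expect_identical(channelNames(sub), channelSubsets()$tiraboschi)

  expect_error(selectChannels(rec, c("Fp1", "XX")), "XX")
})
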