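test_that("differential entropy matches the Gaussian closed form", {
  ## band-limited variance of a unit sinusoid is 1/2: a 10 Hz tone at
  ## 128 Hz lands exactly on an FFT bin of a 4 s window
  t <- (0:511) / 128
  de <- suppressWarnings(
    differentialEntropy(matrix(sin(2 * pi * 10 * t), 1), 128))
  expect_equal(unname(de@values[1, 2]),
               0.5 * log(2 * pi * exp(1) * 0.5), tolerance = 1e-6)

  ## variance 1 in a band gives DE = 0.5 ln(2 pi e) ~ 1.4189
  deA <- suppressWarnings(
    differentialEntropy(matrix(sqrt(2) * sin(2 * pi * 10 * t), 1), 128))
  expect_equal(unname(deA@values[1, 2]), 0.5 * log(2 * pi * exp(1)),
               tolerance = 1e-6)

  ## scaling the signal by 2 adds ln 2 to every (non-floored) band
  x <- matrix(rnorm(2 * 512), 2)
  d1 <- differentialEntropy(x, 128)
  d2 <- differentialEntropy(2 * x, 128)
  expect_equal(d2@values, d1@values + log(2), tolerance = 1e-9)

  ## translation invariance: a DC shift changes nothing (DC excluded)
  d3 <- differentialEntropy(x + 5, 128)
  expect_equal(d3@values, d1@values, tolerance = 1e-9)

  ## zero-variance guard: flat signal floors with a warning
  expect_warning(differentialEntropy(matrix(1, 1, 512), 128), "floored")

  expect_error(differentialEntropy(matrix(rnorm(64), 1), 128), "second")
  expect_error(differentialEntropy(x, 128, list(c(10, 70))), "Nyquist")
})

test_that("DE flattening is row-major with a documented inverse", {
  v <- matrix(1:6, nrow = 2, byrow = TRUE)  # 2 channels x 3 bands
  frame <- new("DEFeatureFrame", values = v * 1.0,
               bandEdges = list(c(4, 8), c(8, 13), c(13, 30)),
               windowIndex = 1L)
  flat <- flattenDE(frame)
  expect_equal(length(flat), 6)
  ## element (channel 1, band 0) lands at 0-based index B = 3
  expect_equal(flat[4], v[2, 1])
  expect_equal(unflattenDE(flat, 2), v * 1.0)
})

test_that("MFCC follows the standard frame/mel/DCT contract", {
  x <- withSeed(4, rnorm(32000))  # 4 s at 8 kHz
  m <- mfcc(x, 8000)
  ## closed-form frame count: floor((4 - 0.025)/0.010) + 1 = 398
  expect_equal(nrow(m@values), 398)
  expect_equal(ncol(m@values), 20)

  ## determinism
  expect_identical(m@values, mfcc(x, 8000)@values)

  ## amplitude scaling shifts c0 but barely moves higher coefficients
  m10 <- mfcc(10 * x, 8000)
  d <- colMeans(abs(m10@values - m@values))
  expect_gt(d[1], 10 * max(d[-1]))

  ## silence stays finite via the log floor
  expect_true(all(is.finite(mfcc(numeric(4000), 8000)@values)))

  ## frame-count closed form across window/hop combinations
  for (cmb in list(c(2, 0.025, 0.010), c(1, 0.030, 0.015),
                   c(0.5, 0.020, 0.020))) {
    mm <- mfcc(rnorm(cmb[1] * 8000), 8000, frameS = cmb[2],
               hopS = cmb[3])
    expect_equal(nrow(mm@values),
                 floor((cmb[1] - cmb[2]) / cmb[3]) + 1)
  }

  expect_error(mfcc(numeric(10), 8000), "frame")
})

test_that("trial features share the window grid across modalities", {
  data <- tinyDataset()
  cfg <- tinyConfig()
  seg <- preprocessTrial(data[[1]])
  fe <- trialFeatures(seg, cfg$eegRateHz, cfg$audioRateHz)
  nWin <- floor(cfg$trialS / 4)
  expect_equal(nrow(fe$eeg), nWin)
  expect_equal(nrow(fe$audio), nWin)
  expect_equal(ncol(fe$eeg), cfg$nChannels * 4)
  expect_equal(ncol(fe$audio), 20)
  expect_true(all(is.finite(fe$eeg)) && all(is.finite(fe$audio)))
})
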