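tinyModelPair <- function(d = 8L, Le = 4L, La = 5L, vE = 4L, vA = 5L,
                          seed = 1) {
  withSeed(seed, list(
    eegContent = matrix(rnorm(Le * d), Le),
    eegIds = sample(0:(vE - 2L), Le, TRUE),
    audioContent = matrix(rnorm(La * d), La),
    audioIds = sample(0:(vA - 2L), La, TRUE)))
}

test_that("analytic gradients match finite differences on every backbone", {
  for (backbone in c("transformer", "lstm", "cnn")) {
    cfg <- modelConfig(dLayers = 2, nHeads = 2, dModel = 8, dFf = 16,
                       backbone = backbone, seed = 7)
    model <- buildModel(cfg, 4L, 5L)
    params <- model@params
    pair <- tinyModelPair()
    maskSet <- c(2L, 4L)
    pe <- positionalEncoding(5, 8)
    lossOf <- function(params) {
      inp <- NeuroMelody:::.pairInputs(params, pair, maskSet, pe)
      fwd <- NeuroMelody:::.coreForward(params, cfg, inp$encX, inp$decY)
      probs <- NeuroMelody:::.softmaxRows(
        NeuroMelody:::.linF(fwd$dec, params$head$W, params$head$b))
      NeuroMelody:::.seqLoss(probs, pair$audioIds, maskSet, cfg$alpha)
    }
    ls <- lossOf(params)
    inp <- NeuroMelody:::.pairInputs(params, pair, maskSet, pe)
    fwd <- NeuroMelody:::.coreForward(params, cfg, inp$encX, inp$decY)
    hb <- NeuroMelody:::.linB(fwd$dec, params$head$W, ls$dLogits)
    back <- NeuroMelody:::.coreBackward(params, cfg, fwd, hb$dX)
    g <- back$grads
    g$head <- list(W = hb$dW, b = hb$db)

    paths <- switch(backbone,
      transformer = list(list("enc", 1L, "attn", "Wq"),
                         list("enc", 2L, "ffn", "W1"),
                         list("dec", 1L, "cross", "Wk"),
                         list("dec", 2L, "ln3", "g"),
                         list("align", "W"), list("head", "W")),
      lstm = list(list("enc", "Wx"), list("dec", "Wh"),
                  list("ctx", "W"), list("head", "W")),
      cnn = list(list("enc", 1L, "conv", "W0"),
                 list("dec", 2L, "conv", "Wm1"),
                 list("ctx", "W"), list("head", "W")))
    assignAt <- function(plist, path, val) {
      if (length(path) == 1L) {
        plist[[path[[1]]]] <- val
        return(plist)
      }
      plist[[path[[1]]]] <- assignAt(plist[[path[[1]]]], path[-1], val)
      plist
    }
    for (path in paths) {
      P <- params; G <- g
      for (k in path) { P <- P[[k]]; G <- G[[k]] }
      idx <- withSeed(42, sample(length(P), min(4, length(P))))
      num <- numGrad(function(x) {
        lossOf(assignAt(params, path, x))$fl
      }, P, idx)
      rel <- abs(num - G[idx]) / pmax(1e-8, abs(num) + abs(G[idx]))
      expect_lt(max(rel), 1e-4)
    }
  }
})

test_that("encoder output has the contracted shape and attention rows sum to 1", {
  cfg <- modelConfig(dLayers = 2, nHeads = 4, dModel = 16, dFf = 32,
                     seed = 3)
  model <- buildModel(cfg, 4L, 5L)
  for (L in c(1L, 7L)) {
    X <- matrix(rnorm(L * 16), L)
    out <- encode(model, X, returnAttention = TRUE)
    expect_equal(dim(out$hidden), c(L, 16L))
    for (layer in out$attention) for (P in layer) {
      expect_equal(rowSums(P), rep(1, L), tolerance = 1e-5)
    }
  }
  ## positional encoding breaks permutation equivariance
  L <- 5L
  content <- matrix(rnorm(L * 16), L)
  pe <- positionalEncoding(L, 16)
  perm <- c(3L, 1L, 5L, 2L, 4L)
  h1 <- encode(model, content + pe)
  h2 <- encode(model, content[perm, ] + pe)
  expect_false(isTRUE(all.equal(h1[perm, ], h2, tolerance = 1e-6)))
  expect_error(encode(model, matrix(0, 2, 8)), "dModel")
})

test_that("masking selects the contracted number of seeded positions", {
  L <- 100L
  tok <- new("TokenSequence", tokens = matrix(rnorm(L * 8), L),
             ids = new("DiscreteSequence", ids = rep(0L, L),
                       sourceFrames = 1:L),
             modality = "audio")
  mb <- applyMask(tok, 0.15, seed = 5)
  expect_equal(length(maskSet(mb)), 15L)
  expect_identical(maskSet(mb), maskSet(applyMask(tok, 0.15, seed = 5)))
  expect_false(identical(maskSet(mb), maskSet(applyMask(tok, 0.15, 6))))

  expect_equal(length(maskSet(applyMask(tok, 0, 1))), 0L)
  expect_identical(applyMask(tok, 0, 1)@tokens, tok@tokens)
  expect_equal(length(maskSet(applyMask(tok, 1, 1))), 100L)
})

test_that("decoder output is a proper distribution driven by the encoder", {
  cfg <- modelConfig(dLayers = 2, nHeads = 2, dModel = 16, dFf = 32,
                     seed = 9)
  model <- buildModel(cfg, 4L, 6L)
  La <- 7L
  tok <- new("TokenSequence", tokens = matrix(rnorm(La * 16), La),
             ids = new("DiscreteSequence",
                       ids = sample(0:4, La, TRUE),
                       sourceFrames = 1:La),
             modality = "audio")
  mb <- applyMask(tok, 0.3, seed = 2)
  H <- encode(model, matrix(rnorm(4 * 16), 4))
  out <- decode(model, mb, H)
  expect_s4_class(out, "DecoderOutput")
  expect_equal(nrow(out@probs), La)
  expect_equal(ncol(out@probs), 6L)
  expect_equal(rowSums(out@probs), rep(1, La), tolerance = 1e-5)
  expect_equal(out@predictedIds,
               as.integer(max.col(out@probs, ties.method = "first") - 1L))

  ## zeroed encoder output makes the decoder ignore the EEG entirely
  Z <- matrix(0, 4, 16)
  o1 <- decode(model, mb, Z)
  o2 <- decode(model, mb, matrix(0, 4, 16))
  expect_equal(o1@probs, o2@probs)
})

test_that("losses hit their closed forms and compose affinely", {
  V <- 32L; L <- 10L
  refs <- sample(0:(V - 1L), L, TRUE)
  mb <- new("MaskedBatch", tokens = matrix(0, L, 4),
            maskSet = c(2L, 5L, 7L), referenceIds = refs)
  uniform <- new("DecoderOutput", hidden = matrix(0, L, 4),
                 logits = matrix(0, L, V),
                 probs = matrix(1 / V, L, V),
                 predictedIds = rep(0L, L))
  expect_equal(maskedLoss(uniform, mb), log(32), tolerance = 1e-6)
  expect_equal(unmaskedLoss(uniform, mb), log(32), tolerance = 1e-6)

  perfect <- matrix(1e-12, L, V)
  perfect[cbind(1:L, refs + 1L)] <- 1
  perfect <- perfect / rowSums(perfect)
  perfOut <- new("DecoderOutput", hidden = matrix(0, L, 4),
                 logits = matrix(0, L, V), probs = perfect,
                 predictedIds = refs)
  expect_equal(maskedLoss(perfOut, mb), 0, tolerance = 1e-9)
  expect_equal(unmaskedLoss(perfOut, mb), 0, tolerance = 1e-9)

  ## moving mass toward the reference strictly lowers the loss
  better <- matrix((1 - 0.5) / (V - 1), L, V)
  better[cbind(1:L, refs + 1L)] <- 0.5
  betterOut <- new("DecoderOutput", hidden = matrix(0, L, 4),
                   logits = matrix(0, L, V), probs = better,
                   predictedIds = refs)
  expect_lt(maskedLoss(betterOut, mb), maskedLoss(uniform, mb))

  for (alpha in withSeed(1, runif(20))) {
    flm <- runif(1, 0, 3); flu <- runif(1, 0, 3)
    cl <- compositeLoss(flm, flu, alpha)
    expect_equal(cl$total, (1 - alpha) * flm + alpha * flu,
                 tolerance = 1e-9)
  }
  expect_equal(compositeLoss(2, 4, 0)$total, 2)
  expect_equal(compositeLoss(2, 4, 1)$total, 4)
  expect_equal(compositeLoss(2, 4, 0.5)$total, 3)
  expect_error(compositeLoss(1, 1, 1.2), "alpha")

  empty <- new("MaskedBatch", tokens = matrix(0, L, 4),
               maskSet = integer(), referenceIds = refs)
  expect_error(maskedLoss(uniform, empty), "undefined")
  full <- new("MaskedBatch", tokens = matrix(0, L, 4),
              maskSet = 1:L, referenceIds = refs)
  expect_error(unmaskedLoss(uniform, full), "undefined")
})

test_that("training makes progress, is seeded, and can memorize one pair", {
  cfg <- modelConfig(dLayers = 1, nHeads = 2, dModel = 16, dFf = 32,
                     maskRatio = 0.3, seed = 3)
  pairs <- lapply(1:4, function(i)
    tinyModelPair(d = 16L, Le = 8L, La = 8L, seed = i))
  m0 <- buildModel(cfg, 4L, 5L)
  m1 <- fitModel(m0, pairs, epochs = 5)
  h <- lossHistory(m1)
  expect_lt(h$fl[5], h$fl[1])
  expect_true(m1@trained)

  ## seeded runs are bit-identical
  m1b <- fitModel(buildModel(cfg, 4L, 5L), pairs, epochs = 5)
  expect_identical(lossHistory(m1b), h)
  expect_identical(m1b@params$head$W, m1@params$head$W)

  ## zero learning rate performs no update (per-epoch losses still vary
  ## because masks are re-drawn dynamically)
  cfg0 <- modelConfig(dLayers = 1, nHeads = 2, dModel = 16, dFf = 32,
                      maskRatio = 0.3, lr = 0, seed = 3)
  init <- buildModel(cfg0, 4L, 5L)
  mFlat <- fitModel(init, pairs, epochs = 4)
  expect_identical(mFlat@params, init@params)

  ## memorization: overfitting one pair drives masked top-1 to 1.0
  one <- tinyModelPair(d = 16L, Le = 10L, La = 10L, seed = 2)
  mOv <- fitModel(buildModel(cfg, 4L, 5L), list(one), epochs = 60)
  probs <- NeuroMelody:::.predictProbs(mOv, one$eegContent, one$eegIds,
                                       10L, maskSet = c(1L, 4L, 9L),
                                       audioContent = one$audioContent,
                                       audioIds = one$audioIds)
  pred <- max.col(probs, ties.method = "first") - 1L
  expect_equal(pred[c(1, 4, 9)], one$audioIds[c(1, 4, 9)])
})

test_that("LSTM and CNN ablation backbones also train", {
  pairs <- lapply(1:3, function(i)
    tinyModelPair(d = 16L, Le = 6L, La = 6L, seed = i))
  for (backbone in c("lstm", "cnn")) {
    cfg <- modelConfig(dLayers = 1, nHeads = 2, dModel = 16, dFf = 32,
                       backbone = backbone, maskRatio = 0.3, seed = 5)
    m <- fitModel(buildModel(cfg, 4L, 5L), pairs, epochs = 8)
    h <- lossHistory(m)
    expect_lt(h$fl[8], h$fl[1])
  }
})

test_that("generation is deterministic argmax of the contracted length", {
  cfg <- modelConfig(dLayers = 1, nHeads = 2, dModel = 16, dFf = 32,
                     seed = 3)
  pair <- tinyModelPair(d = 16L, Le = 8L, La = 8L, seed = 4)
  m <- fitModel(buildModel(cfg, 4L, 5L), list(pair), epochs = 2)
  g1 <- generateIds(m, pair$eegContent, pair$eegIds, 8L)
  g2 <- generateIds(m, pair$eegContent, pair$eegIds, 8L)
  expect_identical(g1@ids, g2@ids)
  expect_equal(length(g1@ids), 8L)
  expect_true(all(g1@ids >= 0L & g1@ids < 5L))
  expect_warning(generateIds(buildModel(cfg, 4L, 5L), pair$eegContent,
                             pair$eegIds, 8L), "trained")
})
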