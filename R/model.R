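## Public model API: configuration, masking, encoder/decoder execution,
## the composite masked/unmasked loss, training, and generation.

#' Model configuration
#'
#' @param dLayers encoder and decoder layer count. The default 12
#'   follows the depth at which the mapping performs best in a layer
#'   sweep; desk-scale experiments use 2.
#' @param nHeads attention heads; must divide `dModel`.
#' @param dModel even token dimension (default 64, desk scale).
#' @param dFf feed-forward hidden width.
#' @param dropout dropout rate applied to sublayer outputs during
#'   training (default 0 for exact reproducibility).
#' @param alpha composite-loss weight: `FL = (1 - alpha) * FLm + alpha *
#'   FLu`, i.e. small `alpha` emphasizes the masked positions.
#' @param maskRatio fraction of audio positions masked during training.
#' @param maskDraws independent mask draws per sequence within each
#'   training epoch (dynamic masking: the same pair is processed under
#'   several different masks, which densifies the masked-prediction
#'   signal without adding data).
#' @param lr Adam learning rate (linearly warmed up over the first
#'   `warmupSteps` optimizer steps; gradients are clipped to global
#'   norm `clipNorm`).
#' @param warmupSteps linear learning-rate warmup steps.
#' @param clipNorm global gradient-norm clip.
#' @param headLrMult learning-rate multiplier for the linear
#'   classification head (the readout is well-conditioned and benefits
#'   from faster steps at the short training schedules used here).
#' @param batchPairs optimizer batch size counted in window pairs
#'   (token positions); rounded to whole trial sequences.
#' @param backbone `"transformer"` (the method), or `"lstm"` / `"cnn"`
#'   ablation backbones.
#' @param seed weight-initialization and masking seed.
#' @return a validated config list.
#' @export
modelConfig <- function(dLayers = 12, nHeads = 4, dModel = 64, dFf = 128,
                        dropout = 0, alpha = 0.1, maskRatio = 0.3,
                        maskDraws = 8,
                        lr = 1e-3, warmupSteps = 20, clipNorm = 1,
                        headLrMult = 10, batchPairs = 60,
                        backbone = c("transformer", "lstm", "cnn"),
                        seed = 1) {
  backbone <- match.arg(backbone)
  .assertCount(dLayers, "dLayers")
  .assertCount(nHeads, "nHeads")
  .assertCount(dModel, "dModel", min = 2L)
  .assertCount(dFf, "dFf")
  if (dModel %% 2 != 0) {
    stop("invalid config: dModel must be even", call. = FALSE)
  }
  if (dModel %% nHeads != 0) {
    stop("invalid config: dModel must be divisible by nHeads",
         call. = FALSE)
  }
  .assertScalarNum(dropout, "dropout", 0, 1)
  .assertScalarNum(alpha, "alpha", 0, 1)
  .assertScalarNum(maskRatio, "maskRatio", 0, 1)
  .assertCount(maskDraws, "maskDraws")
  .assertScalarNum(lr, "lr", lower = 0)
  .assertCount(warmupSteps, "warmupSteps", min = 0L)
  .assertScalarNum(clipNorm, "clipNorm", lower = 1e-9)
  .assertScalarNum(headLrMult, "headLrMult", lower = 1e-9)
  .assertCount(batchPairs, "batchPairs")
  cfg <- list(dLayers = as.integer(dLayers), nHeads = as.integer(nHeads),
              dModel = as.integer(dModel), dFf = as.integer(dFf),
              dropout = dropout, alpha = alpha, maskRatio = maskRatio,
              maskDraws = as.integer(maskDraws),
              lr = lr, warmupSteps = as.integer(warmupSteps),
              clipNorm = clipNorm, headLrMult = headLrMult,
              batchPairs = as.integer(batchPairs),
              backbone = backbone, seed = as.integer(seed))
  class(cfg) <- c("modelConfig", "list")
  cfg
}

#' Build an untrained model
#'
#' @param cfg a [modelConfig()].
#' @param vocabEEG,vocabAudio vocabulary sizes including the unknown ID
#'   (i.e. dictionary entries + 1).
#' @return a [TransformerModel-class].
#' @export
buildModel <- function(cfg, vocabEEG, vocabAudio) {
  if (!inherits(cfg, "modelConfig")) cfg <- do.call(modelConfig, cfg)
  vocabEEG <- .assertCount(vocabEEG, "vocabEEG", min = 2L)
  vocabAudio <- .assertCount(vocabAudio, "vocabAudio", min = 2L)
  new("TransformerModel", params = .initParams(cfg, vocabEEG, vocabAudio),
      cfg = unclass(cfg), vocabEEG = vocabEEG, vocabAudio = vocabAudio,
      history = data.frame(epoch = integer(), flm = numeric(),
                           flu = numeric(), fl = numeric()),
      trained = FALSE)
}

#' Run the encoder over an EEG token sequence
#'
#' @param model a [TransformerModel-class].
#' @param eegTokens a [TokenSequence-class] (or L x dModel matrix) of
#'   assembled EEG tokens.
#' @param returnAttention also return the per-layer, per-head attention
#'   matrices (transformer backbone only).
#' @return L x dModel hidden matrix; with `returnAttention = TRUE`, a
#'   list `(hidden, attention)`.
#' @export
encode <- function(model, eegTokens, returnAttention = FALSE) {
  stopifnot(is(model, "TransformerModel"))
  X <- if (is(eegTokens, "TokenSequence")) eegTokens@tokens else
    as.matrix(eegTokens)
  cfg <- model@cfg
  if (ncol(X) != cfg$dModel) {
    stop("invalid config: token dimension != dModel", call. = FALSE)
  }
  if (cfg$backbone == "transformer") {
    att <- list()
    H <- X
    for (l in seq_len(cfg$dLayers)) {
      cache <- .encLayerF(H, model@params$enc[[l]], cfg)
      H <- cache$Y
      if (returnAttention) {
        att[[l]] <- lapply(cache$att$heads, `[[`, "P")
      }
    }
    H <- .lnF(H, model@params$encLn$g, model@params$encLn$b)$Y
    if (returnAttention) list(hidden = H, attention = att) else H
  } else if (cfg$backbone == "lstm") {
    .lstmF(X, model@params$enc)$H
  } else {
    H <- X
    for (l in seq_len(cfg$dLayers)) H <- .cnnBlockF(H, model@params$enc[[l]])$Y
    H
  }
}

#' Randomly mask audio token positions
#'
#' Chooses `round(maskRatio * L)` positions without replacement
#' (seeded). The returned batch keeps the original token rows and the
#' reference IDs; the decoder substitutes its learned mask embedding
#' (plus positional encoding) at the masked rows when it runs.
#'
#' @param audioTokens a [TokenSequence-class] (or L x d matrix).
#' @param maskRatio fraction of positions to mask.
#' @param seed integer seed.
#' @param referenceIds 0-based true IDs (taken from the TokenSequence
#'   when omitted).
#' @return a [MaskedBatch-class].
#' @export
applyMask <- function(audioTokens, maskRatio, seed = 1,
                      referenceIds = NULL) {
  .assertScalarNum(maskRatio, "maskRatio", 0, 1)
  X <- if (is(audioTokens, "TokenSequence")) audioTokens@tokens else
    as.matrix(audioTokens)
  if (is.null(referenceIds)) {
    if (!is(audioTokens, "TokenSequence")) {
      stop("referenceIds required when tokens are a bare matrix",
           call. = FALSE)
    }
    referenceIds <- audioTokens@ids@ids
  }
  L <- nrow(X)
  nMask <- round(maskRatio * L)
  maskSet <- if (nMask > 0) {
    withSeed(seed, sort(sample.int(L, nMask)))
  } else {
    integer()
  }
  new("MaskedBatch", tokens = X, maskSet = as.integer(maskSet),
      referenceIds = as.integer(referenceIds))
}

## decoder input rows: masked positions -> mask embedding + PE
.decoderInput <- function(model, masked) {
  d <- model@cfg$dModel
  Y <- masked@tokens
  if (length(masked@maskSet)) {
    pe <- positionalEncoding(nrow(Y), d)
    Y[masked@maskSet, ] <- matrix(model@params$maskEmb,
                                  length(masked@maskSet), d,
                                  byrow = TRUE) +
      pe[masked@maskSet, , drop = FALSE]
  }
  Y
}

#' Run the decoder over a masked audio batch
#'
#' Decoder self-attention is bidirectional (masked-prediction
#' infilling, not autoregressive generation); cross-attention reads the
#' encoder output; a linear head scores the audio vocabulary and a
#' softmax yields per-position probabilities.
#'
#' @param model a [TransformerModel-class].
#' @param masked a [MaskedBatch-class].
#' @param encOut encoder hidden matrix from [encode()].
#' @return a [DecoderOutput-class].
#' @export
decode <- function(model, masked, encOut) {
  stopifnot(is(model, "TransformerModel"), is(masked, "MaskedBatch"))
  if (nrow(masked@tokens) < 1L) stop("empty decoder input", call. = FALSE)
  cfg <- model@cfg
  Y <- .decoderInput(model, masked)
  H <- if (is.list(encOut)) encOut$hidden else as.matrix(encOut)
  out <- .coreForward(model@params, cfg, encX = NULL, decY = Y,
                      encH = H)
  logits <- .linF(out$dec, model@params$head$W, model@params$head$b)
  probs <- .softmaxRows(logits)
  new("DecoderOutput", hidden = out$dec, logits = logits, probs = probs,
      predictedIds = as.integer(max.col(probs, ties.method = "first") - 1L))
}

#' Masked-portion loss
#'
#' Mean negative log probability of the reference dictionary ID over the
#' masked positions.
#'
#' @param out a [DecoderOutput-class].
#' @param masked the [MaskedBatch-class] it was computed from.
#' @return non-negative scalar.
#' @export
maskedLoss <- function(out, masked) {
  if (!length(masked@maskSet)) {
    stop("undefined loss: mask set is empty", call. = FALSE)
  }
  idx <- cbind(masked@maskSet, masked@referenceIds[masked@maskSet] + 1L)
  mean(-log(pmax(out@probs[idx], 1e-300)))
}

#' Unmasked-portion loss
#'
#' Same negative log-likelihood form as [maskedLoss()], over the
#' complement of the mask set.
#'
#' @inheritParams maskedLoss
#' @return non-negative scalar.
#' @export
unmaskedLoss <- function(out, masked) {
  keep <- setdiff(seq_len(nrow(out@probs)), masked@maskSet)
  if (!length(keep)) {
    stop("undefined loss: every position is masked", call. = FALSE)
  }
  idx <- cbind(keep, masked@referenceIds[keep] + 1L)
  mean(-log(pmax(out@probs[idx], 1e-300)))
}

#' Composite loss
#'
#' `FL = (1 - alpha) * FLm + alpha * FLu`.
#'
#' @param flm masked loss.
#' @param flu unmasked loss.
#' @param alpha balance weight in [0, 1].
#' @return list with `total`, `masked`, `unmasked`, `alpha`.
#' @export
compositeLoss <- function(flm, flu, alpha) {
  .assertScalarNum(alpha, "alpha", 0, 1)
  if (flm < 0 || flu < 0) stop("losses must be >= 0", call. = FALSE)
  structure(list(total = (1 - alpha) * flm + alpha * flu, masked = flm,
                 unmasked = flu, alpha = alpha), class = "lossValue")
}

#' @export
print.lossValue <- function(x, ...) {
  cat(sprintf("FL = %.6f  [(1-%.2f)*FLm %.6f + %.2f*FLu %.6f]\n",
              x$total, x$alpha, x$masked, x$alpha, x$unmasked))
  invisible(x)
}

## loss + gradient on logits for one sequence ----------------------------
.seqLoss <- function(probs, refIds, maskSet, alpha) {
  L <- nrow(probs)
  keep <- setdiff(seq_len(L), maskSet)
  flm <- if (length(maskSet)) {
    mean(-log(pmax(probs[cbind(maskSet, refIds[maskSet] + 1L)], 1e-300)))
  } else {
    NA_real_
  }
  flu <- if (length(keep)) {
    mean(-log(pmax(probs[cbind(keep, refIds[keep] + 1L)], 1e-300)))
  } else {
    NA_real_
  }
  fl <- (1 - alpha) * (if (is.na(flm)) 0 else flm) +
    alpha * (if (is.na(flu)) 0 else flu)
  dLogits <- probs
  dLogits[cbind(seq_len(L), refIds + 1L)] <-
    dLogits[cbind(seq_len(L), refIds + 1L)] - 1
  w <- numeric(L)
  if (length(maskSet)) w[maskSet] <- (1 - alpha) / length(maskSet)
  if (length(keep)) w[keep] <- alpha / length(keep)
  list(flm = flm, flu = flu, fl = fl, dLogits = dLogits * w)
}

## assemble encoder/decoder inputs for one training pair -----------------
.pairInputs <- function(params, pair, maskSet, pe) {
  Le <- nrow(pair$eegContent)
  La <- nrow(pair$audioContent)
  encX <- pair$eegContent +
    params$embE[pair$eegIds + 1L, , drop = FALSE] +
    pe[seq_len(Le), , drop = FALSE]
  decY <- pair$audioContent +
    params$embA[pair$audioIds + 1L, , drop = FALSE] +
    pe[seq_len(La), , drop = FALSE]
  if (length(maskSet)) {
    decY[maskSet, ] <- matrix(params$maskEmb, length(maskSet),
                              ncol(decY), byrow = TRUE) +
      pe[maskSet, , drop = FALSE]
  }
  list(encX = encX, decY = decY)
}

#' Train the model on paired token sequences
#'
#' Gradient optimization (Adam) of the composite loss
#' `FL = (1 - alpha) * FLm + alpha * FLu` with per-epoch random audio
#' masking. Each training pair is one trial: matched EEG/audio content
#' features and dictionary IDs on the shared window grid.
#'
#' @param model a [TransformerModel-class] from [buildModel()].
#' @param pairs list of pairs, each a list with `eegContent`
#'   (L x dModel), `eegIds` (0-based), `audioContent`, `audioIds`.
#' @param epochs training epochs.
#' @param verbose print per-epoch losses.
#' @return the trained model, with `lossHistory()` filled in.
#' @export
fitModel <- function(model, pairs, epochs = 10, verbose = FALSE) {
  stopifnot(is(model, "TransformerModel"), length(pairs) >= 1L)
  cfg <- model@cfg
  params <- model@params
  maxL <- max(vapply(pairs, function(p)
    max(nrow(p$eegContent), nrow(p$audioContent)), numeric(1)))
  pe <- positionalEncoding(maxL, cfg$dModel)
  seqPerStep <- max(1L, round(cfg$batchPairs /
                                stats::median(vapply(pairs, function(p)
                                  nrow(p$audioContent), numeric(1)))))
  state <- .adamInit(params)
  hist <- data.frame(epoch = integer(), flm = numeric(), flu = numeric(),
                     fl = numeric())
  for (ep in seq_len(epochs)) {
    ord <- withSeed(deriveSeed(cfg$seed, paste0("shuffle", ep)),
                    sample.int(length(pairs)))
    acc <- NULL
    nAcc <- 0L
    epFlm <- c(); epFlu <- c(); epFl <- c()
    for (kk in seq_len(length(ord) * cfg$maskDraws)) {
      k <- ((kk - 1L) %% length(ord)) + 1L
      draw <- ((kk - 1L) %/% length(ord)) + 1L
      pair <- pairs[[ord[k]]]
      La <- nrow(pair$audioContent)
      nMask <- round(cfg$maskRatio * La)
      maskSet <- if (nMask > 0) {
        withSeed(deriveSeed(cfg$seed, sprintf("mask/%d/%d/%d", ep,
                                              ord[k], draw)),
                 sort(sample.int(La, nMask)))
      } else {
        integer()
      }
      inp <- .pairInputs(params, pair, maskSet, pe)
      if (cfg$dropout > 0) {
        set.seed(deriveSeed(cfg$seed, sprintf("drop/%d/%d", ep, ord[k])))
      }
      fwd <- .coreForward(params, cfg, inp$encX, inp$decY,
                          training = TRUE)
      logits <- .linF(fwd$dec, params$head$W, params$head$b)
      probs <- .softmaxRows(logits)
      ls <- .seqLoss(probs, pair$audioIds, maskSet, cfg$alpha)
      if (!is.finite(ls$fl)) {
        stop(sprintf(
          "NaN/Inf loss at epoch %d, pair %d (flm=%g, flu=%g); aborting",
          ep, ord[k], ls$flm, ls$flu), call. = FALSE)
      }
      epFlm <- c(epFlm, ls$flm); epFlu <- c(epFlu, ls$flu)
      epFl <- c(epFl, ls$fl)
      ## backward
      hb <- .linB(fwd$dec, params$head$W, ls$dLogits)
      back <- .coreBackward(params, cfg, fwd, hb$dX)
      g <- back$grads
      g$head <- list(W = hb$dW, b = hb$db)
      ## embedding/mask-embedding grads from the input rows
      g$embE <- matrix(0, nrow(params$embE), cfg$dModel)
      eAcc <- rowsum(back$dEncX, group = pair$eegIds)
      g$embE[as.integer(rownames(eAcc)) + 1L, ] <- eAcc
      g$embA <- matrix(0, nrow(params$embA), cfg$dModel)
      keep <- setdiff(seq_len(La), maskSet)
      if (length(keep)) {
        aAcc <- rowsum(back$dDecY[keep, , drop = FALSE],
                       group = pair$audioIds[keep])
        g$embA[as.integer(rownames(aAcc)) + 1L, ] <- aAcc
      }
      g$maskEmb <- if (length(maskSet)) {
        colSums(back$dDecY[maskSet, , drop = FALSE])
      } else {
        numeric(cfg$dModel)
      }
      acc <- if (is.null(acc)) g else .treeAdd(acc, g)
      nAcc <- nAcc + 1L
      if (nAcc >= seqPerStep || kk == length(ord) * cfg$maskDraws) {
        warm <- if (cfg$warmupSteps > 0) {
          min(1, (state$t + 1L) / cfg$warmupSteps)
        } else {
          1
        }
        upd <- .adamStep(params,
                         .treeClip(.treeScale(acc, 1 / nAcc),
                                   cfg$clipNorm),
                         state, cfg$lr * warm,
                         lrScale = list(head = cfg$headLrMult))
        params <- upd$params
        state <- upd$state
        acc <- NULL
        nAcc <- 0L
      }
    }
    hist <- rbind(hist, data.frame(epoch = ep,
                                   flm = mean(epFlm, na.rm = TRUE),
                                   flu = mean(epFlu, na.rm = TRUE),
                                   fl = mean(epFl)))
    if (verbose) {
      message(sprintf("epoch %3d  FLm %.4f  FLu %.4f  FL %.4f", ep,
                      hist$flm[ep], hist$flu[ep], hist$fl[ep]))
    }
  }
  model@params <- params
  model@history <- hist
  model@trained <- TRUE
  model
}

#' Predict audio token IDs from EEG tokens
#'
#' Runs the decoder with every audio position masked (pure generation:
#' only the EEG conditioning and position information are available)
#' and returns the argmax dictionary IDs.
#'
#' @param model a trained [TransformerModel-class].
#' @param eegContent L_e x dModel EEG content features.
#' @param eegIds 0-based EEG dictionary IDs.
#' @param LAudio number of audio positions to generate.
#' @return a [DiscreteSequence-class] of predicted audio IDs.
#' @export
generateIds <- function(model, eegContent, eegIds, LAudio) {
  stopifnot(is(model, "TransformerModel"))
  if (!model@trained) {
    warning("model has not been trained; predictions are random")
  }
  out <- .predictProbs(model, eegContent, eegIds, LAudio,
                       maskSet = seq_len(LAudio),
                       audioContent = NULL, audioIds = NULL)
  new("DiscreteSequence",
      ids = as.integer(max.col(out, ties.method = "first") - 1L),
      sourceFrames = seq_len(LAudio))
}

## probability matrix for one pair under an arbitrary mask ---------------
.predictProbs <- function(model, eegContent, eegIds, LAudio, maskSet,
                          audioContent = NULL, audioIds = NULL) {
  cfg <- model@cfg
  params <- model@params
  Le <- nrow(eegContent)
  pe <- positionalEncoding(max(Le, LAudio), cfg$dModel)
  if (is.null(audioContent)) {
    audioContent <- matrix(0, LAudio, cfg$dModel)
    audioIds <- rep(0L, LAudio)
  }
  pair <- list(eegContent = eegContent, eegIds = eegIds,
               audioContent = audioContent, audioIds = audioIds)
  inp <- .pairInputs(params, pair, maskSet, pe)
  fwd <- .coreForward(params, cfg, inp$encX, inp$decY)
  .softmaxRows(.linF(fwd$dec, params$head$W, params$head$b))
}
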