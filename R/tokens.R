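## Token assembly: sinusoidal positional encoding, a small convolutional
## content-feature frontend, and the additive composition
## token = content + ID embedding + positional encoding.

#' Sinusoidal positional encoding
#'
#' Row `pos` (0-based), even column `2i` holds
#' `sin(pos / 10000^(2i/dModel))` and odd column `2i+1` the cosine of
#' the same argument, so each sin/cos pair shares its angular frequency
#' and wavelengths span 2*pi to 10000*2*pi.
#'
#' @param L number of positions (rows; positions 0..L-1).
#' @param dModel even embedding dimension.
#' @return L x dModel matrix with entries in [-1, 1].
#' @export
#' @examples
#' pe <- positionalEncoding(4, 8)
#' rowSums(pe^2)  # = dModel/2 for every row
positionalEncoding <- function(L, dModel) {
  .assertCount(L, "L")
  if (dModel %% 2 != 0 || dModel < 2) {
    stop("invalid config: dModel must be even (sin/cos pairs)",
         call. = FALSE)
  }
  pos <- 0:(L - 1)
  i <- 0:(dModel / 2 - 1)
  ang <- outer(pos, 10000 ^ (2 * i / dModel), "/")
  pe <- matrix(0, nrow = L, ncol = dModel)
  pe[, 2 * i + 1] <- sin(ang)
  pe[, 2 * i + 2] <- cos(ang)
  pe
}

.gelu <- function(x) x * stats::pnorm(x)

.layerNormRows <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  v <- rowMeans((X - mu)^2)
  (X - mu) / sqrt(v + eps)
}

## 1-D strided convolution via patch extraction.
## X: C_in x T; W: C_out x (C_in * k); returns C_out x T_out.
.conv1d <- function(X, W, k, stride) {
  Tlen <- ncol(X)
  nOut <- floor((Tlen - k) / stride) + 1L
  if (nOut < 1L) stop("input shorter than kernel", call. = FALSE)
  starts <- (seq_len(nOut) - 1L) * stride
  idx <- outer(seq_len(k), starts, "+")          # k x nOut sample indices
  patches <- do.call(rbind, lapply(seq_len(nrow(X)), function(c) {
    matrix(X[c, idx], nrow = k)
  }))                                            # (C_in*k) x nOut
  W %*% patches
}

## Deterministic frontend weights for a given seed and geometry.
.frontendWeights <- function(cIn, dModel, seed) {
  chans <- c(cIn, 16L, 32L, dModel)
  kernels <- c(7L, 5L, 3L)
  lapply(1:3, function(l) {
    fanIn <- chans[l] * kernels[l]
    w <- .rnorm1(chans[l + 1L] * fanIn, deriveSeed(seed, paste0("cnn", l)),
                 sd = sqrt(2 / fanIn))
    matrix(w, nrow = chans[l + 1L])
  })
}

#' Convolutional content features for token frames
#'
#' A fixed (seeded, bias-free) 3-layer 1-D convolution stack — kernels
#' 7/5/3 with GELU between layers — reduces each raw analysis window to
#' one `dModel` content vector, followed by a parameter-free layer
#' normalization. The EEG frontend consumes channels x samples windows;
#' the audio frontend consumes waveform windows. Weights are random but
#' deterministic given `seed`: the frontend acts as a fixed random
#' feature map, while the trainable ID embeddings carry the discrete
#' dictionary information (see [fitModel()]).
#'
#' @param windows list of windows: channels x W matrices (EEG) or
#'   numeric vectors (audio).
#' @param modality `"eeg"` or `"audio"`.
#' @param dModel output dimension.
#' @param seed weight seed.
#' @return L x dModel matrix, one row per window.
#' @export
cnnContentFeatures <- function(windows, modality = c("eeg", "audio"),
                               dModel = 64, seed = 1) {
  modality <- match.arg(modality)
  if (!length(windows)) stop("no windows given", call. = FALSE)
  toMat <- function(w) if (is.matrix(w)) w else matrix(w, nrow = 1L)
  first <- toMat(windows[[1]])
  cIn <- nrow(first)
  strides <- if (modality == "eeg") c(4L, 4L, 4L) else c(8L, 8L, 8L)
  Wts <- .frontendWeights(cIn, dModel, seed)
  kernels <- c(7L, 5L, 3L)
  out <- t(vapply(windows, function(w) {
    X <- toMat(w)
    if (nrow(X) != cIn) stop("inconsistent window shape", call. = FALSE)
    for (l in 1:3) {
      X <- .conv1d(X, Wts[[l]], kernels[l], strides[l])
      if (l < 3L) X <- .gelu(X)
    }
    rowMeans(X)
  }, numeric(dModel)))
  if (dModel == 1L) out <- matrix(out, ncol = 1L)
  .layerNormRows(out)
}

#' Assemble a token sequence
#'
#' `token_pos = content_pos + embedding[id_pos] + PE_pos`: the additive
#' transformer recipe. The embedding table must have one row per
#' dictionary entry plus one for the unknown ID.
#'
#' @param content L x dModel content-feature matrix (see
#'   [cnnContentFeatures()]).
#' @param ids a [DiscreteSequence-class] (or 0-based integer vector).
#' @param pe positional encoding matrix with at least L rows (see
#'   [positionalEncoding()]).
#' @param embedding (V+1) x dModel table; row `id + 1` is used.
#' @param modality `"eeg"` or `"audio"`.
#' @return a [TokenSequence-class].
#' @export
assembleTokens <- function(content, ids, pe, embedding,
                           modality = c("eeg", "audio")) {
  modality <- match.arg(modality)
  idv <- if (is(ids, "DiscreteSequence")) ids@ids else as.integer(ids)
  L <- nrow(content)
  if (length(idv) != L) stop("length(ids) must equal nrow(content)",
                             call. = FALSE)
  if (any(idv < 0L) || any(idv >= nrow(embedding))) {
    stop("invalid id: outside the embedding table range", call. = FALSE)
  }
  if (ncol(content) != ncol(pe) || ncol(content) != ncol(embedding)) {
    stop("dModel mismatch between content, pe and embedding",
         call. = FALSE)
  }
  if (nrow(pe) < L) stop("positional encoding shorter than sequence",
                         call. = FALSE)
  tokens <- content + embedding[idv + 1L, , drop = FALSE] +
    pe[seq_len(L), , drop = FALSE]
  seqIds <- if (is(ids, "DiscreteSequence")) ids else
    new("DiscreteSequence", ids = idv, sourceFrames = seq_len(L))
  new("TokenSequence", tokens = tokens, ids = seqIds, modality = modality)
}
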