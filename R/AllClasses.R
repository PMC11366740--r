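#' @include AllGenerics.R
NULL

## Central S4 containers for the EEG -> audio-token pipeline.
## Conventions: dictionary IDs are 0-based (cluster 0 is the largest
## cluster; the reserved unknown/noise ID equals the cluster count);
## positions, frame indices and mask sets are 1-based R indices.

#' EEGRecording: a multichannel EEG trial
#'
#' Raw or preprocessed EEG for one trial: a channels x samples matrix in
#' microvolts, with sampling rate, ordered channel names and the duration
#' of the pre-stimulus baseline still present at the start of the data.
#'
#' @slot data numeric matrix, channels x samples.
#' @slot rateHz sampling rate in Hz.
#' @slot channelNames character vector, one per row of `data`.
#' @slot baselineS seconds of baseline at the start of `data` (0 after
#'   baseline removal).
#' @export
setClass("EEGRecording",
  representation(data = "matrix", rateHz = "numeric",
                 channelNames = "character", baselineS = "numeric"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@data) < 1L || ncol(object@data) < 1L)
      msg <- c(msg, "data must have >= 1 channel and >= 1 sample")
    if (length(object@channelNames) != nrow(object@data))
      msg <- c(msg, "length(channelNames) must equal nrow(data)")
    if (length(object@rateHz) != 1L || object@rateHz <= 0)
      msg <- c(msg, "rateHz must be a positive scalar")
    if (length(object@baselineS) != 1L || object@baselineS < 0)
      msg <- c(msg, "baselineS must be a non-negative scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct an EEGRecording
#'
#' @param data channels x samples numeric matrix.
#' @param rateHz sampling rate in Hz.
#' @param channelNames channel names; defaults to Ch1..ChN.
#' @param baselineS seconds of baseline data at the start.
#' @return an [EEGRecording-class] object.
#' @export
#' @examples
#' rec <- EEGRecording(matrix(rnorm(256), 2), rateHz = 128)
#' rateHz(rec)
EEGRecording <- function(data, rateHz, channelNames = NULL, baselineS = 0) {
  data <- as.matrix(data)
  if (is.null(channelNames)) channelNames <- paste0("Ch", seq_len(nrow(data)))
  new("EEGRecording", data = data, rateHz = as.numeric(rateHz),
      channelNames = as.character(channelNames),
      baselineS = as.numeric(baselineS))
}

#' AudioTrack: a mono audio signal
#'
#' @slot data numeric vector of samples (normalized amplitude in [-1, 1]
#'   after preprocessing).
#' @slot rateHz sampling rate in Hz.
#' @export
setClass("AudioTrack",
  representation(data = "numeric", rateHz = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@data) < 1L) msg <- c(msg, "data must be non-empty")
    if (length(object@rateHz) != 1L || object@rateHz <= 0)
      msg <- c(msg, "rateHz must be a positive scalar")
    if (length(msg)) msg else TRUE
  })

#' Construct an AudioTrack
#' @param data numeric sample vector.
#' @param rateHz sampling rate in Hz.
#' @return an [AudioTrack-class] object.
#' @export
AudioTrack <- function(data, rateHz) {
  new("AudioTrack", data = as.numeric(data), rateHz = as.numeric(rateHz))
}

#' LatentStateSequence: shared emotional-state sequence
#'
#' The hidden Markov state path that drives both the synthetic EEG and the
#' synthetic audio of a trial, one state per analysis frame.
#'
#' @slot states integer vector of states in `{0..K-1}`, one per frame.
#' @slot K number of emotional states.
#' @slot stayProb probability of staying in the current state.
#' @slot frameS seconds per frame.
#' @export
setClass("LatentStateSequence",
  representation(states = "integer", K = "integer", stayProb = "numeric",
                 frameS = "numeric"),
  validity = function(object) {
    msg <- character()
    if (length(object@states) < 1L) msg <- c(msg, "need >= 1 frame")
    if (any(object@states < 0L | object@states >= object@K))
      msg <- c(msg, "states must lie in {0..K-1}")
    if (object@stayProb < 0 || object@stayProb > 1)
      msg <- c(msg, "stayProb must lie in [0, 1]")
    if (object@frameS <= 0) msg <- c(msg, "frameS must be positive")
    if (length(msg)) msg else TRUE
  })

#' SegmentedTrial: aligned fixed-length EEG/audio windows
#'
#' @slot eegWindows list of channels x W matrices.
#' @slot audioWindows list of length-Wa numeric vectors.
#' @slot windowS window length in seconds.
#' @slot trialId,subjectId identifiers.
#' @export
setClass("SegmentedTrial",
  representation(eegWindows = "list", audioWindows = "list",
                 windowS = "numeric", trialId = "character",
                 subjectId = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@eegWindows) != length(object@audioWindows))
      msg <- c(msg, "EEG and audio window counts must match")
    if (length(object@eegWindows)) {
      dims <- vapply(object@eegWindows, dim, integer(2))
      if (any(dims != dims[, 1]))
        msg <- c(msg, "all EEG windows must share one shape")
    }
    if (length(msg)) msg else TRUE
  })

#' DEFeatureFrame: per-window differential-entropy features
#'
#' @slot values channels x bands matrix of differential entropies (nats).
#' @slot bandEdges list of `c(low, high)` Hz pairs, one per column.
#' @slot windowIndex 1-based index of the source window.
#' @export
setClass("DEFeatureFrame",
  representation(values = "matrix", bandEdges = "list",
                 windowIndex = "integer"),
  validity = function(object) {
    msg <- character()
    if (ncol(object@values) != length(object@bandEdges))
      msg <- c(msg, "ncol(values) must equal length(bandEdges)")
    if (any(!is.finite(object@values)))
      msg <- c(msg, "values must be finite")
    if (length(msg)) msg else TRUE
  })

#' MFCCFeatures: framewise mel-frequency cepstral coefficients
#'
#' @slot values frames x coefficients matrix.
#' @slot frameS,hopS analysis frame length and hop in seconds.
#' @slot rateHz source audio rate.
#' @slot nMels mel filterbank size used.
#' @export
setClass("MFCCFeatures",
  representation(values = "matrix", frameS = "numeric", hopS = "numeric",
                 rateHz = "numeric", nMels = "integer"),
  validity = function(object) {
    if (ncol(object@values) < 1L) "need >= 1 coefficient" else TRUE
  })

#' ClusterAssignment: DBSCAN labels
#'
#' @slot labels integer per frame; -1 marks noise, clusters are 0-based in
#'   discovery order.
#' @slot nClusters number of clusters.
#' @export
setClass("ClusterAssignment",
  representation(labels = "integer", nClusters = "integer"),
  validity = function(object) {
    ok <- object@labels >= -1L & object@labels < object@nClusters
    if (!all(ok)) "labels must lie in {-1, 0..nClusters-1}" else TRUE
  })

#' FeatureDictionary: discrete vocabulary for one modality
#'
#' One entry per DBSCAN cluster, ordered by descending cluster size (ties
#' by first-seen frame). Centroids are stored in the original feature
#' space; `center`/`scale` record the z-scoring under which clustering
#' distances (and encoding distances) are measured.
#'
#' @slot centroids entries x dim matrix (original feature units).
#' @slot representatives list of matrices of representative member
#'   features per entry (interpretability metadata).
#' @slot sizes integer cluster sizes.
#' @slot modality `"eeg"` or `"audio"`.
#' @slot params list with `eps`, `minPts`, `metric`, `noiseFactor`.
#' @slot center,scale z-scoring vectors applied before distances.
#' @slot unkId reserved 0-based ID for unmatched/noise frames (= entry
#'   count, i.e. one past the last cluster ID).
#' @slot meta modality-specific metadata (band edges or MFCC settings),
#'   needed e.g. for audio reconstruction.
#' @export
setClass("FeatureDictionary",
  representation(centroids = "matrix", representatives = "list",
                 sizes = "integer", modality = "character",
                 params = "list", center = "numeric", scale = "numeric",
                 unkId = "integer", meta = "list"),
  validity = function(object) {
    msg <- character()
    if (!object@modality %in% c("eeg", "audio"))
      msg <- c(msg, "modality must be 'eeg' or 'audio'")
    if (nrow(object@centroids) >= 1L &&
        anyDuplicated(round(object@centroids, 12L)))
      msg <- c(msg, "centroids must be distinct")
    if (object@unkId != nrow(object@centroids))
      msg <- c(msg, "unkId must equal the entry count")
    if (length(msg)) msg else TRUE
  })

#' DiscreteSequence: dictionary IDs for a frame sequence
#'
#' @slot ids integer vector of 0-based dictionary IDs; the dictionary's
#'   `unkId` marks unmatched frames.
#' @slot sourceFrames 1-based indices of the source frames.
#' @export
setClass("DiscreteSequence",
  representation(ids = "integer", sourceFrames = "integer"),
  validity = function(object) {
    if (length(object@ids) != length(object@sourceFrames))
      "ids and sourceFrames must have equal length" else TRUE
  })

#' TokenSequence: model-ready token matrix
#'
#' Each row is content features + dictionary-ID embedding + sinusoidal
#' positional encoding for one frame.
#'
#' @slot tokens L x d_model matrix.
#' @slot ids the underlying [DiscreteSequence-class].
#' @slot modality `"eeg"` or `"audio"`.
#' @export
setClass("TokenSequence",
  representation(tokens = "matrix", ids = "DiscreteSequence",
                 modality = "character"),
  validity = function(object) {
    msg <- character()
    if (nrow(object@tokens) != length(object@ids@ids))
      msg <- c(msg, "nrow(tokens) must equal length(ids)")
    if (any(!is.finite(object@tokens))) msg <- c(msg, "tokens must be finite")
    if (length(msg)) msg else TRUE
  })

#' MaskedBatch: audio token sequence with masked positions
#'
#' `tokens` holds the pre-substitution token rows; the decoder replaces
#' rows in `maskSet` by its learned mask embedding plus positional
#' encoding at run time (the mask embedding is a model parameter).
#'
#' @slot tokens L x d_model matrix.
#' @slot maskSet 1-based masked positions.
#' @slot referenceIds true 0-based dictionary IDs at all positions.
#' @export
setClass("MaskedBatch",
  representation(tokens = "matrix", maskSet = "integer",
                 referenceIds = "integer"),
  validity = function(object) {
    msg <- character()
    L <- nrow(object@tokens)
    if (length(object@referenceIds) != L)
      msg <- c(msg, "referenceIds must cover every position")
    if (length(object@maskSet) &&
        (any(object@maskSet < 1L) || any(object@maskSet > L) ||
         anyDuplicated(object@maskSet)))
      msg <- c(msg, "maskSet must be distinct positions in 1..L")
    if (length(msg)) msg else TRUE
  })

#' DecoderOutput: decoder hidden states and token predictions
#'
#' @slot hidden L x d_model decoder states.
#' @slot logits L x V score matrix over the audio vocabulary (clusters
#'   plus the unknown ID).
#' @slot probs row-stochastic softmax of `logits`.
#' @slot predictedIds 0-based argmax IDs per position.
#' @export
setClass("DecoderOutput",
  representation(hidden = "matrix", logits = "matrix", probs = "matrix",
                 predictedIds = "integer"),
  validity = function(object) {
    rs <- rowSums(object@probs)
    if (any(abs(rs - 1) > 1e-5)) "probs rows must sum to 1" else TRUE
  })

#' TransformerModel: the EEG-to-audio-token sequence model
#'
#' Encoder-decoder network with learned ID embeddings, a learned mask
#' embedding, and a linear classification head over the audio vocabulary.
#' The backbone is a transformer by default; LSTM and CNN backbones are
#' available for ablation comparisons.
#'
#' @slot params named list of weight matrices/vectors.
#' @slot cfg the model configuration list (see [modelConfig()]).
#' @slot vocabEEG,vocabAudio vocabulary sizes (clusters + 1 for unk).
#' @slot history data.frame with per-epoch losses (epoch, flm, flu, fl).
#' @slot trained logical; FALSE until [fitModel()] has run.
#' @export
setClass("TransformerModel",
  representation(params = "list", cfg = "list", vocabEEG = "integer",
                 vocabAudio = "integer", history = "data.frame",
                 trained = "logical"))

#' HitsResult: Hits@k ranking metrics
#'
#' @slot kValues the evaluated k cutoffs.
#' @slot hits named numeric, proportion of positions whose reference ID
#'   ranks within the top k.
#' @slot n number of evaluated positions.
#' @slot ranks per-position rank of the reference ID (1 = best).
#' @export
setClass("HitsResult",
  representation(kValues = "integer", hits = "numeric", n = "integer",
                 ranks = "integer"),
  validity = function(object) {
    msg <- character()
    if (length(object@hits) != length(object@kValues))
      msg <- c(msg, "one hits value per k")
    if (is.unsorted(object@hits[order(object@kValues)]))
      msg <- c(msg, "hits must be non-decreasing in k")
    if (object@n != length(object@ranks))
      msg <- c(msg, "n must equal length(ranks)")
    if (length(msg)) msg else TRUE
  })

## accessors ----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("rateHz", "EEGRecording", function(x) x@rateHz)
#' @rdname accessors
#' @export
setMethod("rateHz", "AudioTrack", function(x) x@rateHz)
#' @rdname accessors
#' @export
setMethod("channelNames", "EEGRecording", function(x) x@channelNames)
#' @rdname accessors
#' @export
setMethod("baselineS", "EEGRecording", function(x) x@baselineS)
#' @rdname accessors
#' @export
setMethod("signalData", "EEGRecording", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("signalData", "AudioTrack", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("nClusters", "ClusterAssignment", function(x) x@nClusters)
#' @rdname accessors
#' @export
setMethod("nClusters", "FeatureDictionary", function(x) nrow(x@centroids))
#' @rdname accessors
#' @export
setMethod("centroids", "FeatureDictionary", function(x) x@centroids)
#' @rdname accessors
#' @export
setMethod("unkId", "FeatureDictionary", function(x) x@unkId)
#' @rdname accessors
#' @export
setMethod("modality", "FeatureDictionary", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("modality", "TokenSequence", function(x) x@modality)
#' @rdname accessors
#' @export
setMethod("tokenIds", "DiscreteSequence", function(x) x@ids)
#' @rdname accessors
#' @export
setMethod("tokenIds", "TokenSequence", function(x) x@ids@ids)
#' @rdname accessors
#' @export
setMethod("tokenMatrix", "TokenSequence", function(x) x@tokens)
#' @rdname accessors
#' @export
setMethod("maskSet", "MaskedBatch", function(x) x@maskSet)
#' @rdname accessors
#' @export
setMethod("referenceIds", "MaskedBatch", function(x) x@referenceIds)
#' @rdname accessors
#' @export
setMethod("hits", "HitsResult", function(x) x@hits)
#' @rdname accessors
#' @export
setMethod("ranks", "HitsResult", function(x) x@ranks)
#' @rdname accessors
#' @export
setMethod("states", "LatentStateSequence", function(x) x@states)
#' @rdname accessors
#' @export
setMethod("lossHistory", "TransformerModel", function(x) x@history)

## show methods --------------------------------------------------------------

setMethod("show", "EEGRecording", function(object) {
  cat(sprintf("EEGRecording: %d channels x %d samples @ %g Hz (%.1f s",
              nrow(object@data), ncol(object@data), object@rateHz,
              ncol(object@data) / object@rateHz))
  if (object@baselineS > 0) cat(sprintf(", incl. %g s baseline", object@baselineS))
  cat(")\n  channels:", paste(utils::head(object@channelNames, 8L),
                              collapse = " "),
      if (length(object@channelNames) > 8L) "..." else "", "\n")
})

setMethod("show", "AudioTrack", function(object) {
  cat(sprintf("AudioTrack: %d samples @ %g Hz (%.1f s)\n",
              length(object@data), object@rateHz,
              length(object@data) / object@rateHz))
})

setMethod("show", "LatentStateSequence", function(object) {
  cat(sprintf("LatentStateSequence: %d frames, K=%d, stay=%.2f, %g s/frame\n",
              length(object@states), object@K, object@stayProb,
              object@frameS))
})

setMethod("show", "SegmentedTrial", function(object) {
  cat(sprintf("SegmentedTrial %s/%s: %d windows of %g s\n",
              object@subjectId, object@trialId,
              length(object@eegWindows), object@windowS))
})

setMethod("show", "FeatureDictionary", function(object) {
  cat(sprintf(
    "FeatureDictionary (%s): %d entries (dim %d), unk id %d, eps=%.4g, minPts=%d\n",
    object@modality, nrow(object@centroids), ncol(object@centroids),
    object@unkId, object@params$eps, object@params$minPts))
})

setMethod("show", "TransformerModel", function(object) {
  cat(sprintf(
    "TransformerModel (%s backbone): %d layers, d_model=%d, heads=%d\n",
    object@cfg$backbone, object@cfg$dLayers, object@cfg$dModel,
    object@cfg$nHeads))
  cat(sprintf("  vocab: EEG %d, audio %d; %s\n", object@vocabEEG,
              object@vocabAudio,
              if (object@trained) {
                sprintf("trained %d epochs (final FL %.4f)",
                        nrow(object@history),
                        object@history$fl[nrow(object@history)])
              } else "untrained"))
})

setMethod("show", "HitsResult", function(object) {
  cat("HitsResult (n =", object@n, "positions)\n")
  for (i in seq_along(object@kValues)) {
    cat(sprintf("  Hits@%-3d %.4f\n", object@kValues[i], object@hits[i]))
  }
})
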