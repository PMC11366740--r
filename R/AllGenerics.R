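#' @import methods
NULL

#' Accessors for NeuroMelody data objects
#'
#' Slot accessors for the S4 containers used across the pipeline.
#'
#' @param x an object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("rateHz", function(x) standardGeneric("rateHz"))

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))

#' @rdname accessors
#' @export
setGeneric("baselineS", function(x) standardGeneric("baselineS"))

#' @rdname accessors
#' @export
setGeneric("signalData", function(x) standardGeneric("signalData"))

#' @rdname accessors
#' @export
setGeneric("nClusters", function(x) standardGeneric("nClusters"))

#' @rdname accessors
#' @export
setGeneric("centroids", function(x) standardGeneric("centroids"))

#' @rdname accessors
#' @export
setGeneric("unkId", function(x) standardGeneric("unkId"))

#' @rdname accessors
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' @rdname accessors
#' @export
setGeneric("tokenIds", function(x) standardGeneric("tokenIds"))

#' @rdname accessors
#' @export
setGeneric("tokenMatrix", function(x) standardGeneric("tokenMatrix"))

#' @rdname accessors
#' @export
setGeneric("maskSet", function(x) standardGeneric("maskSet"))

#' @rdname accessors
#' @export
setGeneric("referenceIds", function(x) standardGeneric("referenceIds"))

#' @rdname accessors
#' @export
setGeneric("hits", function(x) standardGeneric("hits"))

#' @rdname accessors
#' @export
setGeneric("ranks", function(x) standardGeneric("ranks"))

#' @rdname accessors
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))
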