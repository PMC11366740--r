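## DBSCAN discretization: cluster feature frames, build the ordered
## feature dictionary (one entry per cluster: centroid + representative
## members), and encode new frames as discrete dictionary IDs with a
## reserved unknown ID for frames far from every centroid.
##
## Distances are Euclidean on z-scored features (DE and MFCC dimensions
## have very different scales); the dictionary stores the z-scoring so
## encoding uses the same geometry as clustering.

#' DBSCAN parameters
#'
#' @param eps neighborhood radius (in z-scored feature units).
#' @param minPts minimum neighborhood size (including the point itself)
#'   for a core point.
#' @param metric distance metric; only `"euclidean"` is implemented.
#' @param noiseFactor encoding-time noise threshold: frames farther than
#'   `eps * noiseFactor` from every centroid map to the unknown ID.
#' @return a validated parameter list.
#' @export
dbscanParams <- function(eps, minPts, metric = "euclidean",
                         noiseFactor = 1.5) {
  .assertScalarNum(eps, "eps", lower = 1e-12)
  minPts <- .assertCount(minPts, "minPts")
  if (!identical(metric, "euclidean")) {
    stop("only the euclidean metric is implemented", call. = FALSE)
  }
  .assertScalarNum(noiseFactor, "noiseFactor", lower = 0)
  list(eps = as.numeric(eps), minPts = minPts, metric = metric,
       noiseFactor = noiseFactor)
}

## frames: n x dim matrix (rows = frames). Full pairwise distance matrix;
## the dictionary operates on hundreds of frames, so O(n^2) is fine.
.distMatrix <- function(frames) {
  as.matrix(stats::dist(frames, method = "euclidean"))
}

.zscore <- function(frames, center = NULL, scale = NULL) {
  if (is.null(center)) center <- colMeans(frames)
  if (is.null(scale)) {
    scale <- apply(frames, 2L, stats::sd)
    scale[!is.finite(scale) | scale < 1e-12] <- 1
  }
  list(z = sweep(sweep(frames, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

.asFrameMatrix <- function(frames) {
  if (is.list(frames)) frames <- do.call(rbind, frames)
  frames <- as.matrix(frames)
  if (nrow(frames) < 1L) stop("empty frame list", call. = FALSE)
  frames
}

#' Epsilon-neighborhood of a frame
#'
#' Indices `q` with `dist(frame_i, frame_q) <= eps`, including `i`
#' itself. Distances are computed on the frames as given (no z-scoring
#' here; callers that want the clustering geometry should pass z-scored
#' frames).
#'
#' @param frames n x dim matrix (or list of equal-length vectors).
#' @param i 1-based query index.
#' @param params a [dbscanParams()].
#' @return integer vector of 1-based neighbor indices.
#' @export
epsilonNeighborhood <- function(frames, i, params) {
  frames <- .asFrameMatrix(frames)
  if (i < 1L || i > nrow(frames)) stop("invalid index i", call. = FALSE)
  d <- sqrt(colSums((t(frames) - frames[i, ])^2))
  which(d <= params$eps + 1e-12)
}

#' DBSCAN clustering of feature frames
#'
#' Density-based clustering: a frame whose eps-neighborhood holds at
#' least `minPts` frames is a core point; clusters are the maximal
#' density-connected sets grown from core points; non-core frames inside
#' a core's neighborhood are border points and join the cluster of the
#' nearest core (ties to the lower index — a deterministic refinement of
#' the classic order-dependent rule); everything else is noise (-1).
#'
#' @param frames n x dim matrix (or list of vectors), one frame per row.
#' @param params a [dbscanParams()].
#' @param zscore standardize features before distances (default TRUE;
#'   set FALSE if frames are already in the target geometry).
#' @return a [ClusterAssignment-class]; cluster labels are 0-based in
#'   discovery order.
#' @export
dbscanCluster <- function(frames, params, zscore = TRUE) {
  frames <- .asFrameMatrix(frames)
  z <- if (zscore) .zscore(frames)$z else frames
  n <- nrow(z)
  D <- .distMatrix(z)
  nbr <- lapply(seq_len(n), function(i) which(D[i, ] <= params$eps + 1e-12))
  core <- vapply(nbr, length, integer(1)) >= params$minPts
  labels <- rep(NA_integer_, n)
  cl <- -1L
  for (i in seq_len(n)) {
    if (!core[i] || !is.na(labels[i])) next
    cl <- cl + 1L
    ## expand the density-connected component of core points from i
    queue <- i
    labels[i] <- cl
    while (length(queue)) {
      p <- queue[1]
      queue <- queue[-1]
      for (q in nbr[[p]]) {
        if (core[q] && is.na(labels[q])) {
          labels[q] <- cl
          queue <- c(queue, q)
        }
      }
    }
  }
  ## border points: non-core within eps of some core -> nearest core's
  ## cluster (ties to lower core index); remaining non-core are noise
  for (i in which(!core)) {
    cores <- nbr[[i]][core[nbr[[i]]]]
    if (length(cores)) {
      best <- cores[order(D[i, cores], cores)][1]
      labels[i] <- labels[best]
    } else {
      labels[i] <- -1L
    }
  }
  new("ClusterAssignment", labels = labels, nClusters = cl + 1L)
}

#' Heuristic DBSCAN parameter estimate
#'
#' k-distance knee heuristic: sort every frame's distance to its k-th
#' nearest neighbor and pick the point of maximum deviation from the
#' straight line joining the curve's ends. `minPts` defaults to
#' `max(4, min(2 * dim, floor(n / 20)))` — the classic `2 * dim` rule
#' capped so that high-dimensional DE features (dim ~ channels x bands)
#' remain clusterable with a few hundred frames.
#'
#' @param frames n x dim matrix (or list of vectors).
#' @param minPts optional override.
#' @param zscore standardize first (default TRUE, matching
#'   [dbscanCluster()]).
#' @return a [dbscanParams()].
#' @export
estimateDbscanParams <- function(frames, minPts = NULL, zscore = TRUE) {
  frames <- .asFrameMatrix(frames)
  n <- nrow(frames)
  if (is.null(minPts)) {
    minPts <- max(4L, min(2L * ncol(frames), floor(n / 25)))
  }
  minPts <- max(2L, min(as.integer(minPts), n - 1L))
  z <- if (zscore) .zscore(frames)$z else frames
  D <- .distMatrix(z)
  kdist <- sort(vapply(seq_len(n), function(i) {
    sort(D[i, -i], partial = minPts)[minPts]
  }, numeric(1)))
  ## knee: max absolute deviation from the chord of the sorted curve
  ## (for the typical convex flat-then-jump curve this lands at the top
  ## of the flat within-cluster region, just before the jump)
  xs <- seq_along(kdist)
  chord <- kdist[1] + (kdist[n] - kdist[1]) * (xs - 1) / (n - 1)
  knee <- which.max(abs(kdist - chord))
  eps <- kdist[knee]
  if (!is.finite(eps) || eps <= 0) eps <- stats::median(kdist) + 1e-6
  dbscanParams(eps = eps, minPts = minPts)
}

#' Build a feature dictionary from a clustering
#'
#' One entry per cluster, ordered by descending cluster size (ties
#' broken by the cluster's first-seen frame index). Each entry stores
#' the member centroid (original feature units) and the `nRep` members
#' nearest the centroid as representative features. The reserved
#' unknown ID equals the entry count.
#'
#' @param frames the frames that were clustered (n x dim matrix or list).
#' @param assign the [ClusterAssignment-class] produced from `frames`.
#' @param modality `"eeg"` or `"audio"`.
#' @param params the [dbscanParams()] used (stored for encoding).
#' @param nRep representative members per entry (default 5).
#' @param meta modality metadata list (band edges / MFCC settings).
#' @param zscore must match the `zscore` used in [dbscanCluster()].
#' @return a [FeatureDictionary-class].
#' @export
buildDictionary <- function(frames, assign, modality = c("eeg", "audio"),
                            params, nRep = 5, meta = list(),
                            zscore = TRUE) {
  modality <- match.arg(modality)
  frames <- .asFrameMatrix(frames)
  if (length(assign@labels) != nrow(frames)) {
    stop("assignment does not match the frame count", call. = FALSE)
  }
  if (assign@nClusters < 1L) {
    stop("empty dictionary: DBSCAN found no clusters; decrease minPts or ",
         "increase eps", call. = FALSE)
  }
  zs <- if (zscore) .zscore(frames) else
    list(center = rep(0, ncol(frames)), scale = rep(1, ncol(frames)))
  info <- lapply(0:(assign@nClusters - 1L), function(cl) {
    members <- which(assign@labels == cl)
    list(cl = cl, size = length(members), first = min(members),
         members = members)
  })
  ord <- order(-vapply(info, `[[`, integer(1), "size"),
               vapply(info, `[[`, integer(1), "first"))
  info <- info[ord]
  cent <- t(vapply(info, function(e) {
    colMeans(frames[e$members, , drop = FALSE])
  }, numeric(ncol(frames))))
  reps <- lapply(seq_along(info), function(k) {
    e <- info[[k]]
    d <- sqrt(colSums((t(frames[e$members, , drop = FALSE]) - cent[k, ])^2))
    take <- e$members[order(d, e$members)][seq_len(min(nRep, e$size))]
    frames[take, , drop = FALSE]
  })
  new("FeatureDictionary", centroids = cent, representatives = reps,
      sizes = vapply(info, `[[`, integer(1), "size"), modality = modality,
      params = params, center = as.numeric(zs$center),
      scale = as.numeric(zs$scale), unkId = length(info),
      meta = meta)
}

#' Cluster frames and build a dictionary in one step
#'
#' @inheritParams buildDictionary
#' @param params optional [dbscanParams()]; estimated via
#'   [estimateDbscanParams()] when omitted.
#' @return a [FeatureDictionary-class].
#' @export
learnDictionary <- function(frames, modality = c("eeg", "audio"),
                            params = NULL, nRep = 5, meta = list()) {
  modality <- match.arg(modality)
  frames <- .asFrameMatrix(frames)
  if (is.null(params)) params <- estimateDbscanParams(frames)
  assign <- dbscanCluster(frames, params)
  buildDictionary(frames, assign, modality, params, nRep = nRep,
                  meta = meta)
}

#' Encode frames as dictionary IDs
#'
#' Nearest-centroid assignment in the dictionary's z-scored geometry;
#' ties go to the lower entry ID. Frames farther than
#' `eps * noiseFactor` from every centroid receive the reserved unknown
#' ID.
#'
#' @param frames n x dim matrix (or list of vectors).
#' @param dict a [FeatureDictionary-class].
#' @return a [DiscreteSequence-class] of 0-based IDs.
#' @export
encodeSequence <- function(frames, dict) {
  frames <- .asFrameMatrix(frames)
  if (ncol(frames) != ncol(dict@centroids)) {
    stop("frame dimension does not match dictionary centroids",
         call. = FALSE)
  }
  if (nrow(dict@centroids) < 1L) stop("empty dictionary", call. = FALSE)
  z <- .zscore(frames, dict@center, dict@scale)$z
  zc <- .zscore(dict@centroids, dict@center, dict@scale)$z
  thresh <- dict@params$eps * dict@params$noiseFactor
  ids <- vapply(seq_len(nrow(z)), function(i) {
    d <- sqrt(colSums((t(zc) - z[i, ])^2))
    best <- which.min(d)                   # lowest index on ties
    if (d[best] > thresh + 1e-12) dict@unkId else as.integer(best - 1L)
  }, integer(1))
  new("DiscreteSequence", ids = ids, sourceFrames = seq_len(nrow(z)))
}

#' Save / load a feature dictionary
#'
#' JSON serialization (versioned) with full numeric precision; the
#' round-trip preserves entries, ordering, parameters and metadata.
#'
#' @param dict a [FeatureDictionary-class].
#' @param path file path.
#' @return `path` (save) or the [FeatureDictionary-class] (load).
#' @export
saveDictionary <- function(dict, path) {
  stopifnot(is(dict, "FeatureDictionary"))
  obj <- list(format = "NeuroMelody-dictionary", version = 1L,
              modality = dict@modality, params = dict@params,
              center = dict@center, scale = dict@scale,
              unk_id = dict@unkId, sizes = dict@sizes,
              centroids = dict@centroids,
              representatives = dict@representatives, meta = dict@meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname saveDictionary
#' @export
loadDictionary <- function(path) {
  obj <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("format error: cannot parse dictionary file: ",
                         conditionMessage(e), call. = FALSE)
                  })
  if (!identical(obj$format, "NeuroMelody-dictionary") ||
      !identical(as.integer(obj$version), 1L)) {
    stop("format error: not a version-1 dictionary file", call. = FALSE)
  }
  cent <- if (is.matrix(obj$centroids)) obj$centroids else
    matrix(as.numeric(obj$centroids), nrow = length(obj$sizes),
           byrow = TRUE)
  reps <- lapply(obj$representatives, function(r) {
    if (is.matrix(r)) r else matrix(as.numeric(r), nrow = 1L)
  })
  new("FeatureDictionary", centroids = cent, representatives = reps,
      sizes = as.integer(obj$sizes), modality = obj$modality,
      params = dbscanParams(obj$params$eps, obj$params$minPts,
                            obj$params$metric, obj$params$noiseFactor),
      center = as.numeric(obj$center), scale = as.numeric(obj$scale),
      unkId = as.integer(obj$unk_id),
      meta = if (is.null(obj$meta)) list() else obj$meta)
}
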