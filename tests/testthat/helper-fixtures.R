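## Shared fixtures and independent oracles, built in code at test time.

.cache <- new.env(parent = emptyenv())

## small coupled corpus for unit tests: 5 subjects x 1 trial, 24 s
tinyDataset <- function() {
  if (is.null(.cache$tiny)) {
    cfg <- synthConfig(nSubjects = 5, nTrials = 1, trialS = 24,
                       baselineS = 3, K = 3, noiseSd = 0.1, seed = 42)
    .cache$tinyCfg <- cfg
    .cache$tiny <- genDataset(cfg)
  }
  .cache$tiny
}
tinyConfig <- function() {
  tinyDataset()
  .cache$tinyCfg
}

## study-scale corpus for the end-to-end checks: 7 subjects x 2 trials
## of 60 s (~210 window pairs), K = 4 states, low noise
studyDataset <- function() {
  if (is.null(.cache$study)) {
    cfg <- synthConfig(nSubjects = 7, nTrials = 2, K = 4, noiseSd = 0.1,
                       seed = 11)
    .cache$study <- genDataset(cfg)
  }
  .cache$study
}

## full and clustering-off experiment runs over 5 seeds, shared by the
## parameter-recovery and ablation-direction checks
studyExperiments <- function() {
  if (is.null(.cache$exp)) {
    data <- studyDataset()
    runs <- lapply(1:5, function(sd) {
      list(full = runExperiment(data, ablationSpec(dLayers = 2),
                                seed = sd, epochs = 10),
           ablated = runExperiment(
             data,
             ablationSpec(useEEGClustering = FALSE,
                          useAudioClustering = FALSE, dLayers = 2),
             seed = sd, epochs = 10))
    })
    .cache$exp <- runs
  }
  .cache$exp
}

## independent brute-force DBSCAN reference: core points from pairwise
## distance counts, clusters as connected components of the core-core
## eps-graph (igraph), border points to the nearest core (ties to the
## lower index) — the same deterministic border rule the implementation
## documents.
bruteDbscan <- function(X, eps, minPts) {
  X <- as.matrix(X)
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  nb <- D <= eps + 1e-12
  core <- rowSums(nb) >= minPts
  labels <- rep(-1L, n)
  if (any(core)) {
    coreIdx <- which(core)
    A <- nb[coreIdx, coreIdx, drop = FALSE]
    diag(A) <- FALSE
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    comp <- igraph::components(g)$membership
    labels[coreIdx] <- as.integer(comp) - 1L
    for (i in which(!core)) {
      cand <- coreIdx[nb[i, coreIdx]]
      if (length(cand)) {
        best <- cand[order(D[i, cand], cand)][1]
        labels[i] <- labels[best]
      }
    }
  }
  labels
}

## canonical renumbering: clusters labeled by order of first appearance,
## noise kept at -1; two labelings agree up to renumbering iff their
## canonical forms are identical
canonicalLabels <- function(labels) {
  out <- labels
  nxt <- 0L
  seen <- c()
  for (i in seq_along(labels)) {
    l <- labels[i]
    if (l < 0L) next
    key <- as.character(l)
    if (is.null(seen[key]) || is.na(seen[key])) {
      seen[key] <- nxt
      nxt <- nxt + 1L
    }
    out[i] <- seen[key]
  }
  out
}

## numeric gradient of a scalar function at selected coordinates
numGrad <- function(f, x, idx, eps = 1e-6) {
  vapply(idx, function(i) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}
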