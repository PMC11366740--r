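test_that("epsilon neighborhoods come from plain pairwise distances", {
  pts <- matrix(c(0, 1, 10), ncol = 1)
  par <- dbscanParams(eps = 2, minPts = 2)
  expect_equal(epsilonNeighborhood(pts, 1, par), c(1L, 2L))
  ## isolation: eps below every pairwise distance
  expect_equal(epsilonNeighborhood(pts, 3, dbscanParams(0.5, 2)), 3L)
  ## coincident points: everything is in everyone's neighborhood
  same <- matrix(1, 5, 2)
  expect_equal(epsilonNeighborhood(same, 2, dbscanParams(1e-6, 2)), 1:5)
  expect_error(epsilonNeighborhood(matrix(0, 0, 1), 1, par), "empty")
})

test_that("dbscan handles blobs, noise, and the MinPts = 1 degeneracy", {
  blob <- function(cx, cy, n, seed) {
    withSeed(seed, cbind(cx + rnorm(n, sd = 0.1), cy + rnorm(n, sd = 0.1)))
  }
  X <- rbind(blob(0, 0, 20, 1), blob(10, 10, 20, 2))
  asg <- dbscanCluster(X, dbscanParams(eps = 0.5, minPts = 4),
                       zscore = FALSE)
  expect_equal(nClusters(asg), 2L)
  expect_false(any(asg@labels == -1L))
  expect_equal(length(unique(asg@labels[1:20])), 1)
  expect_equal(length(unique(asg@labels[21:40])), 1)

  ## a far outlier is noise
  Xo <- rbind(X, c(500, 500))
  asgO <- dbscanCluster(Xo, dbscanParams(0.5, 4), zscore = FALSE)
  expect_equal(asgO@labels[41], -1L)

  ## MinPts = 1: every point is core; clusters = eps-connected components
  line <- matrix(c(0, 1, 2, 10, 11), ncol = 1)
  asgL <- dbscanCluster(line, dbscanParams(1.5, 1), zscore = FALSE)
  expect_equal(nClusters(asgL), 2L)
  expect_false(any(asgL@labels == -1L))
})

test_that("dbscan matches the brute-force reference on random instances", {
  skip_if_not_installed("igraph")
  withSeed(2024, {
    for (rep in 1:40) {
      n <- sample(20:120, 1)
      d <- sample(2:8, 1)
      k <- sample(2:4, 1)
      centers <- matrix(rnorm(k * d, sd = 4), k)
      X <- centers[sample(k, n, TRUE), , drop = FALSE] +
        matrix(rnorm(n * d, sd = 0.5), n)
      eps <- runif(1, 0.5, 2)
      minPts <- sample(2:8, 1)
      mine <- dbscanCluster(X, dbscanParams(eps, minPts),
                            zscore = FALSE)@labels
      ref <- bruteDbscan(X, eps, minPts)
      expect_identical(canonicalLabels(mine), canonicalLabels(ref))
    }
  })
})

test_that("noise fraction is monotone non-increasing in eps", {
  X <- withSeed(5, matrix(rnorm(80 * 3), 80))
  fr <- vapply(c(0.5, 1, 1.5, 2, 3), function(e) {
    mean(dbscanCluster(X, dbscanParams(e, 5), zscore = FALSE)@labels ==
           -1L)
  }, numeric(1))
  expect_true(all(diff(fr) <= 1e-12))
})

test_that("dictionaries order entries by size and store centroid geometry", {
  X <- rbind(matrix(c(0, 0, 2, 0), 2, byrow = TRUE),
             matrix(rep(c(50, 50), 30), ncol = 2, byrow = TRUE) +
               withSeed(1, matrix(rnorm(60, sd = 0.01), 30)))
  par <- dbscanParams(eps = 3, minPts = 2)
  asg <- dbscanCluster(X, par, zscore = FALSE)
  dict <- buildDictionary(X, asg, "eeg", par, nRep = 3, zscore = FALSE)
  expect_equal(nClusters(dict), 2L)
  ## entry 0 is the size-30 cluster; centroid of the pair is its mean
  expect_equal(dict@sizes, c(30L, 2L))
  expect_equal(unname(centroids(dict)[2, ]), c(1, 0))
  ## representatives are the nRep members closest to the centroid
  d <- sqrt(colSums((t(X[3:32, ]) - centroids(dict)[1, ])^2))
  expect_equal(dict@representatives[[1]],
               X[3:32, , drop = FALSE][order(d, 3:32)[1:3], ])
  expect_equal(unkId(dict), 2L)

  ## all-noise clustering cannot make a dictionary
  lone <- matrix(seq(0, 1000, by = 100), ncol = 1)
  asgN <- dbscanCluster(lone, dbscanParams(1, 3), zscore = FALSE)
  expect_error(buildDictionary(lone, asgN, "eeg", dbscanParams(1, 3)),
               "empty dictionary")
})

test_that("encoding is nearest-centroid with a noise threshold", {
  X <- rbind(matrix(rep(c(0, 0), 20), ncol = 2, byrow = TRUE),
             matrix(rep(c(10, 0), 10), ncol = 2, byrow = TRUE)) +
    withSeed(3, matrix(rnorm(60, sd = 0.05), 30))
  dict <- learnDictionary(X, "audio", params = dbscanParams(1, 3))
  expect_equal(nClusters(dict), 2L)

  ## encoding the centroids returns 0..n-1 in order (idempotence)
  expect_equal(encodeSequence(centroids(dict), dict)@ids, c(0L, 1L))

  ## far frame maps to unk
  far <- matrix(c(0, 500), 1)
  expect_equal(encodeSequence(far, dict)@ids, unkId(dict))

  ## random frames match a brute-force nearest-centroid scan
  Fr <- withSeed(9, matrix(rnorm(40, sd = 3), 20))
  ids <- encodeSequence(Fr, dict)@ids
  z <- sweep(sweep(Fr, 2, dict@center), 2, dict@scale, "/")
  zc <- sweep(sweep(centroids(dict), 2, dict@center), 2, dict@scale, "/")
  brute <- vapply(seq_len(nrow(z)), function(i) {
    d <- sqrt(colSums((t(zc) - z[i, ])^2))
    if (min(d) > dict@params$eps * dict@params$noiseFactor) unkId(dict)
    else as.integer(which.min(d) - 1L)
  }, integer(1))
  expect_identical(ids, brute)

  expect_error(encodeSequence(matrix(1, 1, 5), dict), "dimension")
})

test_that("dictionary files round-trip losslessly and reject corruption", {
  X <- withSeed(7, rbind(matrix(rnorm(40, 0, 0.1), 20),
                         matrix(rnorm(40, 8, 0.1), 20)))
  dict <- learnDictionary(X, "audio", params = dbscanParams(1, 4),
                          meta = list(nMels = 26L, windowS = 4))
  path <- tempfile(fileext = ".json")
  saveDictionary(dict, path)
  back <- loadDictionary(path)
  expect_equal(centroids(back), centroids(dict), tolerance = 1e-12)
  expect_identical(back@sizes, dict@sizes)
  expect_identical(back@modality, dict@modality)
  expect_equal(back@params, dict@params)
  expect_equal(back@meta$nMels, 26)
  ## identical encodings after the round-trip (order preserved)
  Fr <- withSeed(2, matrix(rnorm(20, 4, 3), 10))
  expect_identical(encodeSequence(Fr, back)@ids,
                   encodeSequence(Fr, dict)@ids)

  writeLines(substr(paste(readLines(path), collapse = ""), 1, 50), path)
  expect_error(loadDictionary(path), "format error")
})

test_that("the eps heuristic recovers the planted clusters", {
  X <- withSeed(12, rbind(matrix(rnorm(200, 0, 0.2), 100),
                          matrix(rnorm(200, 6, 0.2), 100)))
  par <- estimateDbscanParams(X)
  asg <- dbscanCluster(X, par)
  expect_equal(nClusters(asg), 2L)
  ## a small fringe of boundary points may stay noise
  expect_lt(mean(asg@labels == -1L), 0.1)
  ## each planted blob maps to one cluster
  expect_equal(length(unique(asg@labels[1:100][asg@labels[1:100] >= 0])),
               1L)
  expect_equal(length(unique(asg@labels[101:200][asg@labels[101:200] >= 0])),
               1L)
})
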