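# Independent oracle implementations used to cross-check the pipeline.
# These deliberately use naive loops and textbook formulas, never the
# package's own code paths.

# nearest-centroid classification by exhaustive pairwise distances
bruteNearestCentroid <- function(supportX, supportY, queryX) {
  classes <- sort(unique(supportY))
  centroids <- lapply(classes, function(k) {
    rows <- which(supportY == k)
    acc <- numeric(ncol(supportX))
    for (r in rows) acc <- acc + supportX[r, ]
    acc / length(rows)
  })
  apply(queryX, 1, function(q) {
    d <- vapply(centroids, function(ck) sqrt(sum((q - ck)^2)), numeric(1))
    classes[which(d == min(d))[1]]
  })
}

# brute-force 2-D cross-correlation peak offset between two equally sized
# images, searched over integer shifts in [-maxShift, maxShift]
xcorrPeakOffset <- function(a, b, maxShift) {
  best <- c(NA, NA)
  bestVal <- -Inf
  n <- nrow(a)
  for (dy in -maxShift:maxShift) {
    for (dx in -maxShift:maxShift) {
      ia <- max(1, 1 + dy):min(n, n + dy)
      ja <- max(1, 1 + dx):min(n, n + dx)
      ib <- ia - dy
      jb <- ja - dx
      va <- a[ia, ja] - mean(a[ia, ja])
      vb <- b[ib, jb] - mean(b[ib, jb])
      v <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
      if (v > bestVal) {
        bestVal <- v
        best <- c(dy, dx)
      }
    }
  }
  best
}

# textbook Pearson correlation
pearsonTextbook <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sum((x - mx) * (y - my)) / sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# well-separated Gaussian class clusters in feature space: inter-class
# centroid distance `separation` times the intra-class spread
makeSeparatedFeatures <- function(nPerClass, K, d, separation = 100,
                                  seed = 1) {
  withr::with_seed(seed, {
    centers <- matrix(rnorm(K * d), K)
    centers <- centers / sqrt(rowSums(centers^2)) * separation
    X <- do.call(rbind, lapply(seq_len(K), function(k) {
      matrix(rnorm(nPerClass * d), nPerClass) + # unit intra-class spread
        matrix(centers[k, ], nPerClass, d, byrow = TRUE)
    }))
    list(features = X, labels = rep(seq_len(K) - 1L, each = nPerClass))
  })
}

smallSpec <- function(...) {
  args <- list(imageSize = 32L, nClasses = 2L, signalAmplitude = 0.5,
               noiseSigma = 0.05, seed = 11L)
  args[names(list(...))] <- list(...)
  do.call(syntheticSpec, args)
}
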