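#' Sample one K-way N-shot episode
#'
#' Samples K classes without replacement, then per class N + NQ feature rows
#' without replacement, split into disjoint support and query sets. Uses the
#' current RNG state (callers such as [evaluateFewshot()] seed it per
#' episode), so identical RNG state gives identical episodes.
#'
#' @param features n x d feature matrix.
#' @param labels integer class labels, length n.
#' @param K number of classes ("ways").
#' @param N support examples per class ("shots").
#' @param NQ query examples per class (default 15).
#' @return an [Episode-class].
#' @export
sampleEpisode <- function(features, labels, K, N, NQ = 15L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels))
  classes <- sort(unique(labels))
  if (length(classes) < K)
    stop("dataset has ", length(classes), " classes, need K = ", K)
  counts <- table(labels)
  deficient <- names(counts)[counts < N + NQ]
  if (length(deficient))
    stop("class ", deficient[1], " has ", counts[deficient[1]],
         " images, need N + NQ = ", N + NQ)

  pick <- sort(classes[sample.int(length(classes), K)])
  sIdx <- integer(0); qIdx <- integer(0)
  for (k in pick) {
    rows <- which(labels == k)
    sel <- rows[sample.int(length(rows), N + NQ)]
    sIdx <- c(sIdx, sel[seq_len(N)])
    qIdx <- c(qIdx, sel[N + seq_len(NQ)])
  }
  new("Episode",
    supportFeatures = features[sIdx, , drop = FALSE],
    supportLabels = as.integer(labels[sIdx]),
    queryFeatures = features[qIdx, , drop = FALSE],
    queryLabels = as.integer(labels[qIdx]),
    classIds = as.integer(pick)
  )
}

#' Compute class prototypes (support centroids)
#'
#' The prototype of class k is the arithmetic mean of its N support feature
#' vectors.
#'
#' @param episode an [Episode-class].
#' @return a [PrototypeSet-class] with one prototype per episode class.
#' @export
computePrototypes <- function(episode) {
  stopifnot(is(episode, "Episode"))
  cls <- sort(unique(episode@classIds))
  protos <- matrix(0, length(cls), ncol(episode@supportFeatures))
  for (i in seq_along(cls)) {
    rows <- episode@supportLabels == cls[i]
    if (!any(rows)) stop("class ", cls[i], " has no support examples")
    protos[i, ] <- colMeans(episode@supportFeatures[rows, , drop = FALSE])
  }
  new("PrototypeSet", prototypes = protos, classIds = cls)
}

#' Classify queries by nearest prototype
#'
#' Each query is assigned the class of the prototype at minimum (squared)
#' Euclidean distance; exact ties are broken toward the lowest class id.
#'
#' @param prototypes a [PrototypeSet-class].
#' @param queryFeatures m x d matrix.
#' @return integer vector of predicted class ids, length m.
#' @export
classifyQueries <- function(prototypes, queryFeatures) {
  stopifnot(is(prototypes, "PrototypeSet"))
  P <- prototypes@prototypes
  if (ncol(P) != ncol(queryFeatures))
    stop("feature dimension mismatch: prototypes d = ", ncol(P),
         ", queries d = ", ncol(queryFeatures))
  ord <- order(prototypes@classIds)
  P <- P[ord, , drop = FALSE]
  ids <- prototypes@classIds[ord]
  # squared distances via the expansion |q|^2 - 2 q.p + |p|^2
  d2 <- outer(rowSums(queryFeatures^2), rowSums(P^2), "+") -
    2 * queryFeatures %*% t(P)
  ids[max.col(-d2, ties.method = "first")]
}

#' Episodic few-shot evaluation with prototypical networks
#'
#' Features are computed once for the whole dataset and reused across
#' episodes. Episode e is sampled under a child seed derived from
#' `(seed, e)`, so results are reproducible and independent of evaluation
#' order. Reports the mean episode accuracy with a normal-approximation 95%
#' confidence half-width (`1.96 * sd / sqrt(nEpisodes)`).
#'
#' @param x a [FeatureExtractor-class] (with `dataset` a
#'   [LabeledImageSet-class]), or a precomputed n x d feature matrix (with
#'   `dataset` the label vector).
#' @param dataset images or labels, matching `x`.
#' @param K,N,NQ episode shape (K-way N-shot with NQ queries per class).
#' @param nEpisodes number of episodes (default 600).
#' @param seed integer seed.
#' @return an [EpisodicResult-class].
#' @examples
#' f <- matrix(rnorm(200 * 8), 200)
#' y <- rep(0:1, each = 100)
#' evaluateFewshot(f, y, K = 2, N = 20, nEpisodes = 20, seed = 1)
#' @export
evaluateFewshot <- function(x, dataset, K, N, NQ = 15L, nEpisodes = 600L,
                            seed = 1L) {
  if (is(x, "FeatureExtractor")) {
    emb <- embedDataset(x, dataset)
    features <- emb$features
    labels <- emb$labels
  } else {
    features <- x
    labels <- dataset
  }
  acc <- numeric(nEpisodes)
  for (e in seq_len(nEpisodes)) {
    ep <- withSeed(childSeed(seed, paste0("episode:", e)),
                   sampleEpisode(features, labels, K, N, NQ))
    pred <- classifyQueries(computePrototypes(ep), ep@queryFeatures)
    acc[e] <- mean(pred == ep@queryLabels)
  }
  new("EpisodicResult",
    perEpisodeAccuracy = acc,
    meanAccuracy = mean(acc),
    ci95Halfwidth = if (nEpisodes > 1)
      1.96 * stats::sd(acc) / sqrt(nEpisodes) else 0,
    K = as.integer(K), N = as.integer(N), NQ = as.integer(NQ),
    nEpisodes = as.integer(nEpisodes), seed = as.integer(seed)
  )
}
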