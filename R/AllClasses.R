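#' Synthetic dataset specification
#'
#' Describes a synthetic labeled-image dataset with a planted class signal:
#' each class carries a sinusoidal texture grating (orientation indexed by
#' class) of amplitude `signalAmplitude`, confined to `signalRegion`, on top
#' of a shared smooth polynomial background plus Gaussian pixel noise.
#'
#' @slot imageSize integer, pixels per side of the square image.
#' @slot nClasses integer, number of classes (>= 2).
#' @slot signalRegion integer vector `(top, left, height, width)` in pixel
#'   coordinates (1-based), fully inside the image bounds.
#' @slot signalAmplitude numeric >= 0, texture contrast of the class grating.
#' @slot noiseSigma numeric >= 0, standard deviation of additive Gaussian
#'   pixel noise (intensity units).
#' @slot channels integer, 1 (radiograph-like grayscale) or 3 (RGB).
#' @slot multiviewShift integer >= 0, maximum per-axis translation in pixels
#'   between two views of the same object.
#' @slot seed integer RNG seed; identical spec + seed gives byte-identical
#'   output.
#' @export
setClass("SyntheticSpec",
  representation(
    imageSize = "integer",
    nClasses = "integer",
    signalRegion = "integer",
    signalAmplitude = "numeric",
    noiseSigma = "numeric",
    channels = "integer",
    multiviewShift = "integer",
    seed = "integer"
  )
)

setValidity("SyntheticSpec", function(object) {
  msgs <- character()
  if (!isCount(object@imageSize, 1L)) msgs <- c(msgs, "imageSize must be a positive integer")
  if (!isCount(object@nClasses, 2L)) msgs <- c(msgs, "nClasses must be an integer >= 2")
  if (length(object@signalRegion) != 4L) {
    msgs <- c(msgs, "signalRegion must be (top, left, height, width)")
  } else {
    r <- object@signalRegion
    if (any(r[1:2] < 1L) || any(r[3:4] < 1L) ||
        r[1] + r[3] - 1L > object@imageSize ||
        r[2] + r[4] - 1L > object@imageSize) {
      msgs <- c(msgs, "signalRegion must lie fully inside the image bounds")
    }
  }
  if (!isSingleNumber(object@signalAmplitude) || object@signalAmplitude < 0)
    msgs <- c(msgs, "signalAmplitude must be >= 0")
  if (!isSingleNumber(object@noiseSigma) || object@noiseSigma < 0)
    msgs <- c(msgs, "noiseSigma must be >= 0")
  if (!object@channels %in% c(1L, 3L)) msgs <- c(msgs, "channels must be 1 or 3")
  if (!isCount(object@multiviewShift, 0L)) msgs <- c(msgs, "multiviewShift must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Labeled image collection
#'
#' An ordered collection of images (each an `H x W` or `H x W x 3` array of
#' intensities in `[0, 1]`) with integer class labels and optional group/view
#' identifiers linking multiple views of the same underlying object.
#'
#' @slot images list of numeric arrays with intensities in `[0, 1]`.
#' @slot label integer vector of 0-based class indices.
#' @slot groupId integer vector (NA when the image is not part of a
#'   multi-view group); equal within a view pair.
#' @slot viewId integer vector (NA or the view index within the group).
#' @slot nClasses integer, number of classes of the owning dataset.
#' @export
setClass("LabeledImageSet",
  representation(
    images = "list",
    label = "integer",
    groupId = "integer",
    viewId = "integer",
    nClasses = "integer"
  )
)

setValidity("LabeledImageSet", function(object) {
  n <- length(object@images)
  msgs <- character()
  if (length(object@label) != n || length(object@groupId) != n ||
      length(object@viewId) != n)
    msgs <- c(msgs, "label, groupId and viewId must match length(images)")
  if (n > 0) {
    rng <- range(vapply(object@images, function(im) range(im), numeric(2)))
    if (rng[1] < 0 || rng[2] > 1)
      msgs <- c(msgs, "all pixel intensities must lie in [0, 1]")
    if (any(object@label < 0L | object@label >= object@nClasses))
      msgs <- c(msgs, "labels must satisfy 0 <= label < nClasses")
  }
  if (length(msgs)) msgs else TRUE
})

#' Image preprocessing specification
#'
#' The preprocessing applied before feature extraction: channel stacking of
#' grayscale input to three channels, aspect-preserving bicubic resize of the
#' shorter side, center crop, then normalization.
#'
#' @slot resizeSide integer; shorter side after resize (NA skips resizing).
#' @slot cropSize integer; side of the center crop (NA skips cropping).
#' @slot interpolation character; only "bicubic" is supported.
#' @slot normalization one of "imagenet" (per-channel mean/sd standardization
#'   with ImageNet statistics), "histeq" (per-image histogram equalization to
#'   uniform on `[0, 1]`, applied before channel stacking), or "none".
#' @slot stackChannels logical; replicate single-channel input to three
#'   identical channels.
#' @export
setClass("PreprocessSpec",
  representation(
    resizeSide = "integer",
    cropSize = "integer",
    interpolation = "character",
    normalization = "character",
    stackChannels = "logical"
  )
)

setValidity("PreprocessSpec", function(object) {
  msgs <- character()
  if (!identical(object@interpolation, "bicubic"))
    msgs <- c(msgs, "interpolation must be 'bicubic'")
  if (!object@normalization %in% c("imagenet", "histeq", "none"))
    msgs <- c(msgs, "normalization must be one of 'imagenet', 'histeq', 'none'")
  if (!is.na(object@resizeSide) && !is.na(object@cropSize) &&
      object@cropSize > object@resizeSide)
    msgs <- c(msgs, "cropSize must be <= resizeSide")
  if (length(msgs)) msgs else TRUE
})

#' Feature extractor contract
#'
#' A deterministic map from a preprocessed image to a fixed-length feature
#' vector, together with its preprocessing specification. Third-party
#' backbones can be wrapped by supplying `embedFun`; the package's toy
#' extractors (see [makeToyExtractor()]) additionally expose their linear map
#' over flattened pixels in `linearMap`, which fast paths may exploit.
#'
#' @slot id character identifier.
#' @slot featureDim integer d >= 1; `embedFun` always returns a d-vector.
#' @slot preprocess a [PreprocessSpec-class].
#' @slot embedFun function(pixel array) -> numeric d-vector; pure.
#' @slot linearMap either NULL or a d x npix matrix such that
#'   `embedFun(px) == linearMap %*% as.numeric(px)` for images of `inputDim`.
#' @slot inputDim integer vector (H, W, C) the extractor expects after
#'   preprocessing, or NA when any size is accepted.
#' @slot trainable logical; whether the finetuning protocol is supported.
#' @export
setClass("FeatureExtractor",
  representation(
    id = "character",
    featureDim = "integer",
    preprocess = "PreprocessSpec",
    embedFun = "function",
    linearMap = "ANY",
    inputDim = "integer",
    trainable = "logical"
  )
)

setValidity("FeatureExtractor", function(object) {
  msgs <- character()
  if (!isCount(object@featureDim, 1L)) msgs <- c(msgs, "featureDim must be >= 1")
  if (!is.null(object@linearMap) &&
      (!is.matrix(object@linearMap) || nrow(object@linearMap) != object@featureDim))
    msgs <- c(msgs, "linearMap must be a featureDim x npix matrix or NULL")
  if (length(msgs)) msgs else TRUE
})

#' Trainable feature extractor
#'
#' Extends [FeatureExtractor-class] with explicit parameters and
#' forward/gradient functions so the finetuning protocol can refit all
#' parameters by gradient descent.
#'
#' @slot params named list of numeric parameter arrays.
#' @slot forwardFun function(params, px) -> list(feature, cache).
#' @slot gradFun function(params, px, cache, dFeature) -> named list of
#'   gradients matching `params`.
#' @export
setClass("TrainableExtractor",
  contains = "FeatureExtractor",
  representation(
    params = "list",
    forwardFun = "function",
    gradFun = "function"
  )
)

#' One few-shot episode
#'
#' A K-way N-shot task instance: per sampled class, N support and N_Q query
#' feature vectors drawn without replacement from one dataset (support and
#' query sets disjoint).
#'
#' @slot supportFeatures (K*N) x d matrix.
#' @slot supportLabels integer vector of class ids, length K*N.
#' @slot queryFeatures (K*N_Q) x d matrix.
#' @slot queryLabels integer vector, length K*N_Q.
#' @slot classIds the K sampled class ids.
#' @export
setClass("Episode",
  representation(
    supportFeatures = "matrix",
    supportLabels = "integer",
    queryFeatures = "matrix",
    queryLabels = "integer",
    classIds = "integer"
  )
)

setValidity("Episode", function(object) {
  msgs <- character()
  tabS <- table(object@supportLabels)
  tabQ <- table(object@queryLabels)
  if (!setequal(names(tabS), as.character(object@classIds)))
    msgs <- c(msgs, "support must cover exactly the episode classes")
  if (length(unique(tabS)) > 1L) msgs <- c(msgs, "unequal support counts per class")
  if (length(unique(tabQ)) > 1L) msgs <- c(msgs, "unequal query counts per class")
  if (length(msgs)) msgs else TRUE
})

#' Class prototypes of an episode
#'
#' @slot prototypes K x d matrix; row k is the centroid of class k's support
#'   features.
#' @slot classIds integer vector of length K.
#' @export
setClass("PrototypeSet",
  representation(prototypes = "matrix", classIds = "integer")
)

setValidity("PrototypeSet", function(object) {
  if (nrow(object@prototypes) != length(object@classIds))
    "one prototype per episode class required" else TRUE
})

#' Episodic few-shot evaluation result
#'
#' @slot perEpisodeAccuracy numeric vector in `[0, 1]`.
#' @slot meanAccuracy arithmetic mean of the per-episode accuracies.
#' @slot ci95Halfwidth 1.96 * sd / sqrt(n) over episode accuracies.
#' @slot K,N,NQ,nEpisodes,seed the episodic configuration.
#' @export
setClass("EpisodicResult",
  representation(
    perEpisodeAccuracy = "numeric",
    meanAccuracy = "numeric",
    ci95Halfwidth = "numeric",
    K = "integer", N = "integer", NQ = "integer",
    nEpisodes = "integer", seed = "integer"
  )
)

setValidity("EpisodicResult", function(object) {
  msgs <- character()
  if (abs(object@meanAccuracy - mean(object@perEpisodeAccuracy)) > 1e-12)
    msgs <- c(msgs, "meanAccuracy must equal mean(perEpisodeAccuracy)")
  if (object@ci95Halfwidth < 0) msgs <- c(msgs, "ci95Halfwidth must be >= 0")
  if (length(msgs)) msgs else TRUE
})

#' Linear-probe result
#'
#' @slot lambdaGrid the 45-value l2 grid (see [l2Grid()]).
#' @slot valAccuracy validation accuracy at each lambda.
#' @slot chosenLambda lambda maximizing validation accuracy (ties broken
#'   toward the smallest lambda).
#' @slot testAccuracy top-1 accuracy on the test split after refitting on
#'   train + validation at `chosenLambda`.
#' @slot weights K x (d + 1) coefficient matrix (intercept first column).
#' @slot notes character vector of recorded fit warnings.
#' @export
setClass("LinearProbeResult",
  representation(
    lambdaGrid = "numeric",
    valAccuracy = "numeric",
    chosenLambda = "numeric",
    testAccuracy = "numeric",
    weights = "matrix",
    notes = "character"
  )
)

#' Finetuning protocol configuration
#'
#' Defaults mirror the evaluation protocol: at most 5000 SGD steps with
#' Nesterov momentum 0.9, learning rate 1e-2, weight decay 1e-8, batch size
#' 64, validation accuracy checked every 200 steps with early-stopping
#' patience 3, random-resized-crop + horizontal-flip augmentation.
#'
#' @slot maxSteps,evalEvery,batchSize,earlyStopPatience integers.
#' @slot learningRate,momentum,weightDecay numerics.
#' @slot augment logical; apply training augmentations.
#' @export
setClass("FinetuneConfig",
  representation(
    maxSteps = "integer",
    learningRate = "numeric",
    momentum = "numeric",
    weightDecay = "numeric",
    batchSize = "integer",
    earlyStopPatience = "integer",
    evalEvery = "integer",
    augment = "logical"
  )
)

setValidity("FinetuneConfig", function(object) {
  msgs <- character()
  if (object@maxSteps < 0L) msgs <- c(msgs, "maxSteps must be >= 0")
  if (object@learningRate <= 0) msgs <- c(msgs, "learningRate must be positive")
  if (object@batchSize < 1L) msgs <- c(msgs, "batchSize must be positive")
  if (object@earlyStopPatience < 1L) msgs <- c(msgs, "earlyStopPatience must be positive")
  if (object@evalEvery < 1L) msgs <- c(msgs, "evalEvery must be positive")
  if (object@maxSteps > 0L && object@evalEvery > object@maxSteps)
    msgs <- c(msgs, "evalEvery must be <= maxSteps")
  if (length(msgs)) msgs else TRUE
})

#' Occlusion saliency map
#'
#' Per-pixel mean feature-perturbation (RRSE) under a sliding occlusion mask,
#' cropped so that every retained pixel was occluded the same number of
#' times.
#'
#' @slot attention cropTo x cropTo matrix of nonnegative mean RRSE values.
#' @slot occlusionCounts matching matrix of per-pixel occlusion counts
#'   (uniform after the crop: maskSize^2).
#' @slot imageId,extractorId character identifiers.
#' @slot maskSize,resizeTo,cropTo the occlusion geometry.
#' @export
setClass("SaliencyMap",
  representation(
    attention = "matrix",
    occlusionCounts = "matrix",
    imageId = "character",
    extractorId = "character",
    maskSize = "integer",
    resizeTo = "integer",
    cropTo = "integer"
  )
)

setValidity("SaliencyMap", function(object) {
  msgs <- character()
  if (any(object@attention < 0)) msgs <- c(msgs, "attention values must be >= 0")
  if (length(unique(as.integer(object@occlusionCounts))) != 1L)
    msgs <- c(msgs, "occlusion counts must be uniform after the crop")
  if (length(msgs)) msgs else TRUE
})

#' Feature distribution moments for invariance scoring
#'
#' Mean feature, (ridged) feature covariance and the lower-triangular
#' Cholesky factor L of its inverse (`solve(sigma) = L %*% t(L)`), estimated
#' from at most 1000 images of a dataset.
#'
#' @slot meanFeature numeric d-vector.
#' @slot sigma d x d covariance matrix (after ridge).
#' @slot L lower-triangular d x d matrix with `L %*% t(L)` reproducing
#'   `solve(sigma)` to 1e-8 relative Frobenius error.
#' @slot nImages number of images used (<= 1000).
#' @slot ridge the ridge epsilon added to the covariance diagonal.
#' @export
setClass("InvarianceMoments",
  representation(
    meanFeature = "numeric",
    sigma = "matrix",
    L = "matrix",
    nImages = "integer",
    ridge = "numeric"
  )
)

setValidity("InvarianceMoments", function(object) {
  msgs <- character()
  if (object@nImages > 1000L) msgs <- c(msgs, "nImages must be <= 1000")
  prec <- object@L %*% t(object@L)
  target <- solve(object@sigma)
  rel <- norm(prec - target, "F") / max(norm(target, "F"), .Machine$double.eps)
  if (rel > 1e-8)
    msgs <- c(msgs, "L %*% t(L) must reproduce solve(sigma) to 1e-8 relative error")
  if (length(msgs)) msgs else TRUE
})

#' Parameterized image transformation family
#'
#' @slot name character family name ("hflip", "rotation", "hue", ...).
#' @slot params list of parameter values theta.
#' @slot applyFun deterministic function(image, theta) -> image.
#' @export
setClass("TransformFamily",
  representation(name = "character", params = "list", applyFun = "function")
)

setValidity("TransformFamily", function(object) {
  if (length(object@params) < 1L) "params must be nonempty" else TRUE
})

#' Invariance score result
#'
#' @slot score mean whitened cosine similarity in `[-1, 1]`.
#' @slot family transformation family name (or "multiview").
#' @slot nEval number of images (or pairs) averaged over.
#' @slot nSkipped terms skipped because of a zero-norm whitened feature.
#' @slot notes character annotations (e.g. hue on stacked grayscale is a
#'   no-op).
#' @export
setClass("InvarianceResult",
  representation(
    score = "numeric",
    family = "character",
    nEval = "integer",
    nSkipped = "integer",
    notes = "character"
  )
)

setValidity("InvarianceResult", function(object) {
  if (abs(object@score) > 1 + 1e-9) "score must lie in [-1, 1]" else TRUE
})

#' Cross-model score table
#'
#' Rows are models, columns are tasks; cells hold a metric (accuracy,
#' diffusion, invariance), optionally with a matching uncertainty matrix.
#'
#' @slot values numeric matrix with model rownames and task colnames.
#' @slot uncertainty NULL or a matching matrix of CI half-widths.
#' @export
setClass("ScoreTable",
  representation(values = "matrix", uncertainty = "ANY")
)

setValidity("ScoreTable", function(object) {
  msgs <- character()
  if (is.null(rownames(object@values)) || is.null(colnames(object@values)))
    msgs <- c(msgs, "values must have model rownames and task colnames")
  if (anyDuplicated(rownames(object@values)) || anyDuplicated(colnames(object@values)))
    msgs <- c(msgs, "duplicated (model, task) cells are not allowed")
  if (!is.null(object@uncertainty) &&
      !identical(dim(object@uncertainty), dim(object@values)))
    msgs <- c(msgs, "uncertainty must match dim(values)")
  if (length(msgs)) msgs else TRUE
})
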