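#' @rdname LabeledImageSet-class
#' @param x,object a `LabeledImageSet`.
#' @export
setMethod("length", "LabeledImageSet", function(x) length(x@images))

#' Accessors for LabeledImageSet
#'
#' `images()` returns the list of pixel arrays, `imageLabels()` the 0-based
#' class labels, `groupIds()`/`viewIds()` the multi-view bookkeeping and
#' `nClasses()` the class count of the owning dataset.
#'
#' @param x a [LabeledImageSet-class].
#' @return the corresponding slot value.
#' @export
setGeneric("images", function(x) standardGeneric("images"))

#' @rdname images
#' @export
setMethod("images", "LabeledImageSet", function(x) x@images)

#' @rdname images
#' @export
setGeneric("imageLabels", function(x) standardGeneric("imageLabels"))

#' @rdname images
#' @export
setMethod("imageLabels", "LabeledImageSet", function(x) x@label)

#' @rdname images
#' @export
setGeneric("groupIds", function(x) standardGeneric("groupIds"))

#' @rdname images
#' @export
setMethod("groupIds", "LabeledImageSet", function(x) x@groupId)

#' @rdname images
#' @export
setGeneric("viewIds", function(x) standardGeneric("viewIds"))

#' @rdname images
#' @export
setMethod("viewIds", "LabeledImageSet", function(x) x@viewId)

#' @rdname images
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' @rdname images
#' @export
setMethod("nClasses", "LabeledImageSet", function(x) x@nClasses)

#' @rdname LabeledImageSet-class
#' @param i index vector.
#' @export
setMethod("[", "LabeledImageSet", function(x, i) {
  new("LabeledImageSet",
    images = x@images[i],
    label = x@label[i],
    groupId = x@groupId[i],
    viewId = x@viewId[i],
    nClasses = x@nClasses
  )
})

setMethod("show", "LabeledImageSet", function(object) {
  n <- length(object)
  dims <- if (n > 0) paste(dim(object@images[[1]]), collapse = " x ") else "?"
  cat("LabeledImageSet with", n, "images (", dims, "),",
      object@nClasses, "classes\n")
  if (n > 0) {
    cat("  class counts:", paste(table(object@label), collapse = ", "), "\n")
    if (any(!is.na(object@groupId)))
      cat("  multi-view groups:", length(unique(stats::na.omit(object@groupId))), "\n")
  }
})

setMethod("show", "SyntheticSpec", function(object) {
  cat("SyntheticSpec:", object@imageSize, "x", object@imageSize,
      "px,", object@nClasses, "classes,", object@channels, "channel(s)\n")
  cat("  signal region (t,l,h,w):", paste(object@signalRegion, collapse = ","),
      " amplitude:", object@signalAmplitude,
      " noise sd:", object@noiseSigma, "\n")
  cat("  multiview shift:", object@multiviewShift, " seed:", object@seed, "\n")
})

setMethod("show", "FeatureExtractor", function(object) {
  cat("FeatureExtractor '", object@id, "': d = ", object@featureDim,
      if (object@trainable) " (trainable)" else "", "\n", sep = "")
  cat("  normalization:", object@preprocess@normalization, "\n")
})

setMethod("show", "EpisodicResult", function(object) {
  cat(sprintf("EpisodicResult: %d-way %d-shot, %d episodes\n",
              object@K, object@N, object@nEpisodes))
  cat(sprintf("  accuracy %.4f +/- %.4f (95%% CI)\n",
              object@meanAccuracy, object@ci95Halfwidth))
})

setMethod("show", "LinearProbeResult", function(object) {
  cat(sprintf("LinearProbeResult: test accuracy %.4f at lambda %.3g\n",
              object@testAccuracy, object@chosenLambda))
})

setMethod("show", "SaliencyMap", function(object) {
  cat(sprintf("SaliencyMap %d x %d (mask %d, resize %d) for '%s' / '%s'\n",
              nrow(object@attention), ncol(object@attention),
              object@maskSize, object@resizeTo,
              object@imageId, object@extractorId))
  cat(sprintf("  attentive diffusion: %.4f\n", attentiveDiffusion(object)))
})

setMethod("show", "InvarianceResult", function(object) {
  cat(sprintf("InvarianceResult[%s]: score %.4f over %d samples",
              object@family, object@score, object@nEval))
  if (object@nSkipped > 0) cat(sprintf(" (%d skipped)", object@nSkipped))
  cat("\n")
  if (length(object@notes)) cat("  note:", object@notes, "\n")
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@values), "models x",
      ncol(object@values), "tasks\n")
  print(round(object@values, 4))
})

#' Attentive diffusion of a saliency map
#'
#' The fraction of map pixels with attention strictly above the map mean.
#' Values near 1 indicate a broad focus; values near 0 a concentrated focus.
#' A constant map has diffusion 0 (no pixel is strictly above the mean).
#'
#' @param x a [SaliencyMap-class] or a numeric matrix of attention values.
#' @return a single number in `[0, 1]`.
#' @examples
#' attentiveDiffusion(matrix(c(1, 1, 0, 0), 2))
#' @export
setGeneric("attentiveDiffusion", function(x) standardGeneric("attentiveDiffusion"))

#' @rdname attentiveDiffusion
#' @export
setMethod("attentiveDiffusion", "SaliencyMap", function(x) {
  attentiveDiffusion(x@attention)
})

#' @rdname attentiveDiffusion
#' @export
setMethod("attentiveDiffusion", "matrix", function(x) {
  stopifnot(length(x) > 0)
  mean(x > mean(x))
})

#' Embed a single preprocessed image
#'
#' Applies the extractor's embedding to an already-preprocessed pixel array.
#' For most use go through [embedDataset()], which also applies the
#' extractor's preprocessing.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param px a pixel array.
#' @return numeric vector of length `featureDim(extractor)`.
#' @export
setGeneric("embedImage", function(extractor, px) standardGeneric("embedImage"))

#' @rdname embedImage
#' @export
setMethod("embedImage", "FeatureExtractor", function(extractor, px) {
  f <- extractor@embedFun(px)
  if (length(f) != extractor@featureDim)
    stop("extractor '", extractor@id, "' returned a feature of length ",
         length(f), ", expected ", extractor@featureDim)
  as.numeric(f)
})

#' @rdname embedImage
#' @export
setMethod("embedImage", "TrainableExtractor", function(extractor, px) {
  f <- extractor@forwardFun(extractor@params, px)$feature
  if (length(f) != extractor@featureDim)
    stop("trainable extractor returned wrong feature length")
  as.numeric(f)
})

#' @rdname images
#' @export
setGeneric("featureDim", function(x) standardGeneric("featureDim"))

#' @rdname images
#' @export
setMethod("featureDim", "FeatureExtractor", function(x) x@featureDim)

#' Extract the invariance (or diffusion) score value
#'
#' @param x an [InvarianceResult-class].
#' @return numeric scalar.
#' @export
setGeneric("score", function(x) standardGeneric("score"))

#' @rdname score
#' @export
setMethod("score", "InvarianceResult", function(x) x@score)
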