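#' ImageNet channel statistics used for "imagenet" normalization
#' @keywords internal
.imagenetMean <- c(0.485, 0.456, 0.406)
.imagenetSd <- c(0.229, 0.224, 0.225)

#' Create a preprocessing specification
#'
#' Defaults follow the standard evaluation convention: aspect-preserving
#' bicubic resize of the shorter side to 224 pixels, a 224 x 224 center
#' crop, and per-channel standardization with ImageNet statistics.
#'
#' @param resizeSide shorter side after resize (NA to skip resizing).
#' @param cropSize center-crop side (NA to skip cropping).
#' @param normalization "imagenet", "histeq" or "none".
#' @param stackChannels replicate single-channel input to three identical
#'   channels (TRUE for backbone-style extractors; the package's toy
#'   extractors use FALSE so their analytic oracles stay exact).
#' @return a [PreprocessSpec-class].
#' @export
preprocessSpec <- function(resizeSide = 224L, cropSize = 224L,
                           normalization = "imagenet", stackChannels = TRUE) {
  new("PreprocessSpec",
    resizeSide = as.integer(resizeSide),
    cropSize = as.integer(cropSize),
    interpolation = "bicubic",
    normalization = normalization,
    stackChannels = isTRUE(stackChannels)
  )
}

# Catmull-Rom cubic convolution kernel (a = -0.5), the classical bicubic
# resampling kernel.
.cubicKernel <- function(t) {
  a <- -0.5
  at <- abs(t)
  w <- numeric(length(t))
  i1 <- at <= 1
  i2 <- at > 1 & at < 2
  w[i1] <- (a + 2) * at[i1]^3 - (a + 3) * at[i1]^2 + 1
  w[i2] <- a * at[i2]^3 - 5 * a * at[i2]^2 + 8 * a * at[i2] - 4 * a
  w
}

# nOut x nIn interpolation weight matrix for 1-D bicubic resampling with
# center-aligned coordinates (src = (i + 0.5) * nIn/nOut - 0.5) and edge
# clamping. Exact identity when nOut == nIn.
.bicubicWeights <- function(nIn, nOut) {
  scale <- nIn / nOut
  src <- (seq_len(nOut) - 0.5) * scale - 0.5 # 0-based source coordinate
  base <- floor(src)
  frac <- src - base
  W <- matrix(0, nOut, nIn)
  for (k in -1:2) {
    idx <- pmin(pmax(base + k, 0), nIn - 1) + 1
    w <- .cubicKernel(frac - k)
    W[cbind(seq_len(nOut), idx)] <- W[cbind(seq_len(nOut), idx)] + w
  }
  # normalize rows (clamping at edges can make weights sum slightly off 1)
  W / rowSums(W)
}

#' Bicubic image resize
#'
#' Separable cubic-convolution (Catmull-Rom) resampling of an `H x W` or
#' `H x W x C` array to `outH x outW`.
#'
#' @param px numeric array.
#' @param outH,outW output dimensions.
#' @return resized array of the same channel structure.
#' @export
resizeBicubic <- function(px, outH, outW) {
  d <- dim(px)
  Wr <- .bicubicWeights(d[1], outH)
  Wc <- .bicubicWeights(d[2], outW)
  if (length(d) == 2L) {
    Wr %*% px %*% t(Wc)
  } else {
    out <- array(0, c(outH, outW, d[3]))
    for (c in seq_len(d[3])) out[, , c] <- Wr %*% px[, , c] %*% t(Wc)
    out
  }
}

# Per-image histogram equalization to (approximately) uniform on [0, 1]
# using midpoint-adjusted average ranks; a constant image maps to 0.5.
.histEqualize <- function(x) {
  n <- length(x)
  array((rank(x, ties.method = "average") - 0.5) / n, dim(x))
}

.centerCrop <- function(px, size) {
  d <- dim(px)
  r0 <- (d[1] - size) %/% 2L
  c0 <- (d[2] - size) %/% 2L
  if (length(d) == 2L) {
    px[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size)]
  } else {
    px[(r0 + 1):(r0 + size), (c0 + 1):(c0 + size), , drop = FALSE]
  }
}

#' Preprocess an image for feature extraction
#'
#' Applies, in order: replication of single-channel input to three identical
#' channels (exactly preserving per-pixel intensity), aspect-preserving
#' bicubic resize of the shorter side to `resizeSide`, a `cropSize` center
#' crop, and normalization last.
#'
#' @param px an `H x W` or `H x W x 3` array with intensities in `[0, 1]`.
#' @param spec a [PreprocessSpec-class].
#' @return preprocessed array (`H x W x 3`, or `H x W` when the spec's
#'   `stackChannels` is FALSE and the input is single-channel).
#' @export
preprocessImage <- function(px, spec = preprocessSpec()) {
  if (length(px) == 0L) stop("image is empty")
  if (min(px) < 0 || max(px) > 1)
    stop("image intensities must lie in [0, 1]")
  if (is.null(dim(px))) stop("image must be a matrix or array")

  if (length(dim(px)) == 2L && spec@stackChannels) {
    px <- array(rep(px, 3L), c(dim(px), 3L))
  }

  if (!is.na(spec@resizeSide)) {
    h <- dim(px)[1]; w <- dim(px)[2]
    short <- min(h, w)
    sc <- spec@resizeSide / short
    outH <- if (h <= w) spec@resizeSide else as.integer(round(h * sc))
    outW <- if (h <= w) as.integer(round(w * sc)) else spec@resizeSide
    px <- resizeBicubic(px, outH, outW)
    px <- clip01(px) # cubic kernels can overshoot [0, 1]
  }

  if (!is.na(spec@cropSize)) {
    h <- dim(px)[1]; w <- dim(px)[2]
    if (h < spec@cropSize)
      stop("image height ", h, " is smaller than crop size ", spec@cropSize)
    if (w < spec@cropSize)
      stop("image width ", w, " is smaller than crop size ", spec@cropSize)
    px <- .centerCrop(px, spec@cropSize)
  }

  switch(spec@normalization,
    imagenet = {
      if (length(dim(px)) != 3L)
        stop("imagenet normalization requires a 3-channel image")
      for (c in 1:3) px[, , c] <- (px[, , c] - .imagenetMean[c]) / .imagenetSd[c]
      px
    },
    histeq = {
      if (length(dim(px)) == 2L) .histEqualize(px)
      else {
        for (c in seq_len(dim(px)[3])) px[, , c] <- .histEqualize(px[, , c])
        px
      }
    },
    none = px
  )
}
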