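#' Root relative squared error between feature vectors
#'
#' `sqrt( sum_j (fOcc_j - fOrig_j)^2 / sum_j (fOrig_j - mean(fOrig))^2 )`:
#' the perturbation of the occluded feature relative to the spread of the
#' original feature's components. Scale-invariant (scaling both vectors by
#' c > 0 leaves it unchanged) and zero iff the vectors are equal.
#'
#' @param fOrig original feature vector (must not be constant).
#' @param fOcc occluded-image feature vector of the same length.
#' @return a nonnegative number.
#' @examples
#' rrse(c(0, 2), c(1, 3)) # 1
#' @export
rrse <- function(fOrig, fOcc) {
  if (length(fOrig) != length(fOcc))
    stop("feature vectors must have equal length")
  den <- sum((fOrig - mean(fOrig))^2)
  if (den == 0)
    stop("degenerate feature: the original feature vector is constant, ",
         "RRSE denominator is zero")
  sqrt(sum((fOcc - fOrig)^2) / den)
}

# 2-D windowed sum: out[i, j] = sum of z[a, b] over a in [i-m+1, i],
# b in [j-m+1, j] (indices clipped to z's extent), for an outH x outW output
# grid. Direct shift-and-add (m adds per axis) rather than integral images:
# windows of exact zeros sum to exactly zero, which the attention-locality
# guarantees rely on.
.boxSum2d <- function(z, m, outH, outW) {
  Z <- matrix(0, outH, outW)
  Z[seq_len(nrow(z)), seq_len(ncol(z))] <- z
  A <- matrix(0, outH, outW)
  for (k in 0:(m - 1L)) {
    A[(k + 1L):outH, ] <- A[(k + 1L):outH, ] + Z[seq_len(outH - k), ]
  }
  B <- matrix(0, outH, outW)
  for (k in 0:(m - 1L)) {
    B[, (k + 1L):outW] <- B[, (k + 1L):outW] + A[, seq_len(outW - k)]
  }
  B
}

# per-axis occlusion count for pixel index i on a side of length R with
# P = R - m + 1 mask positions
.axisCounts <- function(R, m) {
  P <- R - m + 1L
  i <- seq_len(R)
  pmin(i, P) - pmax(1L, i - m + 1L) + 1L
}

#' Occlusion-based saliency map
#'
#' The image is resized (square, bicubic) to `resizeTo`, channel-stacked and
#' normalized per the extractor's preprocessing spec, and embedded once. A
#' `maskSize x maskSize` occluding patch (fill value `fill`, i.e. zero in
#' normalized space) is slid over every position fully inside the image
#' (stride 1, `(resizeTo - maskSize + 1)^2` positions). For each position the
#' RRSE between the original and occluded features is added to the attention
#' accumulator of every occluded pixel; accumulators are divided by the
#' per-pixel occlusion counts and the map is center-cropped to
#' `cropTo x cropTo`, inside which every pixel was occluded exactly
#' `maskSize^2` times.
#'
#' For extractors exposing a linear pixel map the per-position RRSE is
#' computed exactly in closed form (occluding pixels subtracts their linear
#' contribution), avoiding re-embedding; the result is identical to the
#' generic path.
#'
#' @param extractor a [FeatureExtractor-class].
#' @param image an `H x W` or `H x W x 3` pixel array in `[0, 1]`.
#' @param maskSize occluding patch side (default 10).
#' @param resizeTo working image side (default 242).
#' @param cropTo retained map side (default 224); must satisfy
#'   `cropTo <= resizeTo - 2 * (maskSize - 1)` so retained occlusion counts
#'   are uniform.
#' @param fill occlusion fill value in normalized space (default 0).
#' @param imageId identifier recorded in the map.
#' @param forceGeneric always embed every masked copy, even for linear
#'   extractors (used to validate the closed-form path).
#' @return a [SaliencyMap-class].
#' @export
occlusionSaliency <- function(extractor, image, maskSize = 10L,
                              resizeTo = 242L, cropTo = 224L, fill = 0,
                              imageId = "image", forceGeneric = FALSE) {
  stopifnot(is(extractor, "FeatureExtractor"))
  maskSize <- as.integer(maskSize)
  resizeTo <- as.integer(resizeTo)
  cropTo <- as.integer(cropTo)
  if (cropTo > resizeTo - 2L * (maskSize - 1L))
    stop("cropTo must be <= resizeTo - 2 * (maskSize - 1) so that every ",
         "retained pixel is occluded the same number of times")

  spec <- extractor@preprocess
  px <- clip01(resizeBicubic(image, resizeTo, resizeTo))
  if (length(dim(px)) == 2L && spec@stackChannels)
    px <- array(rep(px, 3L), c(dim(px), 3L))
  normSpec <- preprocessSpec(resizeSide = NA, cropSize = NA,
                             normalization = spec@normalization,
                             stackChannels = FALSE)
  base <- preprocessImage(px, normSpec)

  fOrig <- embedImage(extractor, base)
  den <- sum((fOrig - mean(fOrig))^2)
  if (den == 0)
    stop("degenerate extractor '", extractor@id,
         "': constant feature on this image (RRSE denominator is zero)")

  R <- resizeTo
  P <- R - maskSize + 1L
  nch <- if (length(dim(base)) == 3L) dim(base)[3] else 1L
  M <- extractor@linearMap

  if (!is.null(M) && !forceGeneric && ncol(M) == length(base)) {
    # closed form: occluding window w changes the feature by
    # delta = M[, w] %*% (fill - v[w]); accumulate per-pixel products and
    # box-sum them per feature dimension.
    v <- as.numeric(base)
    d <- nrow(M)
    D2 <- matrix(0, P, P) # squared feature change per mask position
    Dsum <- vector("list", d)
    for (f in seq_len(d)) {
      contrib <- matrix(0, R, R)
      for (c in seq_len(nch) - 1L) {
        idx <- c * R * R + seq_len(R * R)
        contrib <- contrib + matrix(M[f, idx] * (fill - v[idx]), R, R)
      }
      # sum of contrib over the window anchored at (a, b)..(a+m-1, b+m-1):
      # equals .boxSum2d of contrib evaluated at (a+m-1, b+m-1)
      full <- .boxSum2d(contrib, maskSize, R, R)
      Df <- full[maskSize:R, maskSize:R]
      D2 <- D2 + Df^2
    }
    rrseMat <- sqrt(D2 / den)
  } else {
    rrseMat <- matrix(0, P, P)
    for (a in seq_len(P)) {
      rows <- a:(a + maskSize - 1L)
      for (b in seq_len(P)) {
        cols <- b:(b + maskSize - 1L)
        occ <- base
        if (nch > 1L) occ[rows, cols, ] <- fill else occ[rows, cols] <- fill
        fOcc <- tryCatch(embedImage(extractor, occ),
                         error = function(e) stop("embedding failed at mask ",
                                                  "position (", a, ", ", b,
                                                  "): ", conditionMessage(e)))
        rrseMat[a, b] <- sqrt(sum((fOcc - fOrig)^2) / den)
      }
    }
  }

  attSum <- .boxSum2d(rrseMat, maskSize, R, R)
  cnt <- .axisCounts(R, maskSize)
  counts <- outer(cnt, cnt)
  attention <- attSum / counts

  off <- (R - cropTo) %/% 2L
  keep <- (off + 1L):(off + cropTo)
  new("SaliencyMap",
    attention = attention[keep, keep],
    occlusionCounts = counts[keep, keep],
    imageId = imageId,
    extractorId = extractor@id,
    maskSize = maskSize,
    resizeTo = resizeTo,
    cropTo = cropTo
  )
}
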