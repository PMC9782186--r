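#' The l2 regularization grid for the linear probe
#'
#' 45 logarithmically spaced values between 1e-6 and 1e5, endpoints
#' included (a geometric sequence with constant ratio `(1e5/1e-6)^(1/44)`).
#'
#' @return numeric vector of length 45, increasing.
#' @examples
#' range(l2Grid())
#' @export
l2Grid <- function() {
  10^seq(-6, 5, length.out = 45L)
}

.probeAccuracy <- function(pred, truth) mean(as.character(pred) == as.character(truth))

#' Fit a linear probe on frozen features
#'
#' Fits an l2-regularized multinomial logistic regression
#' (`P(y = c_i | x) = exp(w_i . x) / sum_k exp(w_k . x)`, via glmnet ridge
#' with an intercept) on the training features for every value of the
#' 45-value grid, selects the regularization constant maximizing validation
#' accuracy (ties broken toward the smallest lambda), refits on
#' train + validation at the chosen constant, and reports top-1 test
#' accuracy. No data augmentation is involved; features are used as given
#' (not re-standardized).
#'
#' @param trainX,valX,testX feature matrices with equal column counts.
#' @param trainY,valY,testY label vectors.
#' @param lambdaGrid regularization constants (default [l2Grid()]).
#' @return a [LinearProbeResult-class].
#' @export
fitLinearProbe <- function(trainX, trainY, valX, valY, testX, testY,
                           lambdaGrid = l2Grid()) {
  stopifnot(ncol(trainX) == ncol(valX), ncol(valX) == ncol(testX))
  if (length(unique(trainY)) < 2L)
    stop("training split contains a single class; probe requires >= 2")
  classes <- sort(unique(c(trainY, valY, testY)))
  lev <- as.character(classes)
  grid <- sort(lambdaGrid, decreasing = TRUE)
  notes <- character(0)

  fitGlmnet <- function(X, y) {
    withCallingHandlers(
      glmnet::glmnet(X, factor(as.character(y), levels = lev),
                     family = "multinomial", alpha = 0, lambda = grid,
                     standardize = FALSE, thresh = 1e-10, maxit = 1e6),
      warning = function(w) {
        notes <<- c(notes, conditionMessage(w))
        invokeRestart("muffleWarning")
      }
    )
  }

  fit <- fitGlmnet(trainX, trainY)
  predVal <- predict(fit, valX, s = grid, type = "class")
  valAcc <- apply(predVal, 2, .probeAccuracy, truth = valY)
  # order valAcc back onto the increasing grid
  inc <- order(grid) # positions of increasing lambdas within `grid`
  valAccInc <- as.numeric(valAcc[inc])
  lambdaInc <- grid[inc]
  chosen <- lambdaInc[which.max(valAccInc)] # which.max -> first max = smallest lambda

  refit <- fitGlmnet(rbind(trainX, valX), c(trainY, valY))
  predTest <- predict(refit, testX, s = chosen, type = "class")
  testAcc <- .probeAccuracy(predTest, testY)

  co <- stats::coef(refit, s = chosen)
  weights <- t(vapply(co, function(m) as.numeric(m), numeric(ncol(trainX) + 1L)))
  rownames(weights) <- lev
  colnames(weights) <- c("(Intercept)", paste0("f", seq_len(ncol(trainX))))

  new("LinearProbeResult",
    lambdaGrid = lambdaInc,
    valAccuracy = valAccInc,
    chosenLambda = chosen,
    testAccuracy = testAcc,
    weights = weights,
    notes = unique(notes)
  )
}

#' Create a finetuning configuration
#'
#' Defaults: at most 5000 SGD steps (Nesterov momentum 0.9), learning rate
#' 1e-2, weight decay 1e-8, batch size 64, validation accuracy checked every
#' 200 steps, early-stopping patience 3 consecutive non-improving checks,
#' random-resized-crop and horizontal-flip augmentation during training.
#'
#' @param maxSteps,learningRate,momentum,weightDecay,batchSize numeric
#'   protocol parameters.
#' @param earlyStopPatience,evalEvery early-stopping schedule.
#' @param augment logical, apply training augmentations.
#' @return a [FinetuneConfig-class].
#' @export
finetuneConfig <- function(maxSteps = 5000L, learningRate = 1e-2,
                           momentum = 0.9, weightDecay = 1e-8,
                           batchSize = 64L, earlyStopPatience = 3L,
                           evalEvery = 200L, augment = TRUE) {
  new("FinetuneConfig",
    maxSteps = as.integer(maxSteps),
    learningRate = learningRate,
    momentum = momentum,
    weightDecay = weightDecay,
    batchSize = as.integer(batchSize),
    earlyStopPatience = as.integer(earlyStopPatience),
    evalEvery = as.integer(evalEvery),
    augment = isTRUE(augment)
  )
}

.randomHFlip <- function(x) {
  if (stats::runif(1) < 0.5) x[, rev(seq_len(ncol(x))), drop = FALSE] else x
}

.randomResizedCrop <- function(x, minScale = 0.7) {
  h <- nrow(x); w <- ncol(x)
  s <- stats::runif(1, minScale, 1)
  ch <- max(2L, as.integer(round(h * s)))
  cw <- max(2L, as.integer(round(w * s)))
  top <- sample.int(h - ch + 1L, 1L)
  left <- sample.int(w - cw + 1L, 1L)
  clip01(resizeBicubic(x[top:(top + ch - 1L), left:(left + cw - 1L)], h, w))
}

.augmentImage <- function(x) .randomResizedCrop(.randomHFlip(x))

# forward pass through extractor + linear head for one raw image
.headLogits <- function(extractor, head, px) {
  pre <- preprocessImage(px, extractor@preprocess)
  feat <- extractor@forwardFun(extractor@params, pre)$feature
  as.numeric(head$W %*% feat + head$b)
}

.splitAccuracy <- function(extractor, head, split, classes) {
  preds <- vapply(images(split), function(px) {
    classes[which.max(.headLogits(extractor, head, px))]
  }, numeric(1))
  mean(preds == imageLabels(split))
}

#' Finetune a trainable extractor with the stated protocol
#'
#' Refits all extractor parameters together with an attached linear
#' classification head by SGD with Nesterov momentum, minimizing softmax
#' cross-entropy. Validation accuracy is checked every `evalEvery` steps;
#' training halts at `maxSteps` or when validation accuracy has failed to
#' improve for `earlyStopPatience` consecutive checks, and the
#' best-validation checkpoint is evaluated on the test split. With
#' `maxSteps = 0` the initial model is evaluated and the log is empty.
#'
#' @param extractor a [TrainableExtractor-class].
#' @param train,val,test [LabeledImageSet-class] splits.
#' @param config a [FinetuneConfig-class].
#' @param seed integer seed (head initialization, batch order,
#'   augmentation).
#' @param valAccuracyFn optional `function(step)` returning the validation
#'   metric, overriding the computed validation accuracy. Used for
#'   diagnostics of the early-stopping schedule.
#' @return a list with `testAccuracy`, `log` (data.frame of step /
#'   valAccuracy at every check), `stoppedAt` (last training step),
#'   `extractor` (best-checkpoint extractor) and `head`.
#' @export
finetune <- function(extractor, train, val, test, config = finetuneConfig(),
                     seed = 1L, valAccuracyFn = NULL) {
  if (!is(extractor, "TrainableExtractor") || !extractor@trainable)
    stop("finetuning requires a trainable extractor")
  validObject(config)
  classes <- sort(unique(imageLabels(train)))
  K <- length(classes)
  d <- extractor@featureDim

  head <- withSeed(childSeed(seed, "head"),
                   list(W = matrix(stats::rnorm(K * d, sd = 0.01), K, d),
                        b = numeric(K)))
  params <- extractor@params

  log <- data.frame(step = integer(0), valAccuracy = numeric(0))
  best <- -Inf
  bestParams <- params
  bestHead <- head
  bad <- 0L
  stoppedAt <- 0L

  if (config@maxSteps > 0L) {
    vel <- list(params = lapply(params, function(p) p * 0),
                W = head$W * 0, b = head$b * 0)
    trainImgs <- images(train)
    trainLab <- imageLabels(train)
    mu <- config@momentum
    lr <- config@learningRate
    wd <- config@weightDecay

    withSeed(childSeed(seed, "finetune"), {
      for (step in seq_len(config@maxSteps)) {
        idx <- sample.int(length(trainImgs),
                          min(config@batchSize, length(trainImgs)))
        gParams <- lapply(params, function(p) p * 0)
        gW <- head$W * 0
        gb <- head$b * 0
        for (i in idx) {
          px <- trainImgs[[i]]
          if (config@augment) {
            x2 <- if (length(dim(px)) == 3L) px[, , 1] else px
            px <- .augmentImage(x2)
          }
          pre <- preprocessImage(px, extractor@preprocess)
          fw <- extractor@forwardFun(params, pre)
          logits <- as.numeric(head$W %*% fw$feature + head$b)
          p <- exp(logits - max(logits))
          p <- p / sum(p)
          y <- match(trainLab[i], classes)
          dlog <- p
          dlog[y] <- dlog[y] - 1
          gW <- gW + outer(dlog, fw$feature)
          gb <- gb + dlog
          dFeat <- as.numeric(t(head$W) %*% dlog)
          gp <- extractor@gradFun(params, pre, fw$cache, dFeat)
          for (nm in names(gParams)) gParams[[nm]] <- gParams[[nm]] + gp[[nm]]
        }
        nb <- length(idx)
        gW <- gW / nb + wd * head$W
        gb <- gb / nb + wd * head$b
        for (nm in names(gParams))
          gParams[[nm]] <- gParams[[nm]] / nb + wd * params[[nm]]

        # Nesterov momentum: v <- mu v + g ; p <- p - lr (g + mu v)
        vel$W <- mu * vel$W + gW
        head$W <- head$W - lr * (gW + mu * vel$W)
        vel$b <- mu * vel$b + gb
        head$b <- head$b - lr * (gb + mu * vel$b)
        for (nm in names(params)) {
          vel$params[[nm]] <- mu * vel$params[[nm]] + gParams[[nm]]
          params[[nm]] <- params[[nm]] - lr * (gParams[[nm]] + mu * vel$params[[nm]])
        }

        if (step %% config@evalEvery == 0L) {
          exCur <- extractor
          exCur@params <- params
          acc <- if (is.null(valAccuracyFn)) {
            .splitAccuracy(exCur, head, val, classes)
          } else {
            valAccuracyFn(step)
          }
          log <- rbind(log, data.frame(step = step, valAccuracy = acc))
          if (acc > best) {
            best <- acc
            bestParams <- params
            bestHead <- head
            bad <- 0L
          } else {
            bad <- bad + 1L
          }
          if (bad >= config@earlyStopPatience) {
            stoppedAt <- step
            break
          }
        }
        stoppedAt <- step
      }
    })
  }

  bestExtractor <- extractor
  bestExtractor@params <- if (is.finite(best)) bestParams else params
  bestHeadOut <- if (is.finite(best)) bestHead else head
  testAcc <- .splitAccuracy(bestExtractor, bestHeadOut, test, classes)

  list(
    testAccuracy = testAcc,
    log = log,
    stoppedAt = as.integer(stoppedAt),
    extractor = bestExtractor,
    head = bestHeadOut
  )
}
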