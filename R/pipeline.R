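#' Default demonstration pipeline configuration
#'
#' A compact, fully synthetic end-to-end configuration: a two-class planted
#' -texture dataset, one global and one region-restricted toy extractor, and
#' modest evaluation sizes (200 episodes, a reduced saliency geometry) so the
#' whole run completes in a couple of minutes on one CPU.
#'
#' @param seed global seed.
#' @param outDir output directory.
#' @return a config list accepted by [runPipeline()].
#' @export
demoConfig <- function(seed = 1L, outDir = tempfile("transferscope_demo")) {
  list(
    seed = as.integer(seed),
    outDir = outDir,
    synthetic = list(imageSize = 64L, nClasses = 2L, nPerClass = 40L,
                     signalAmplitude = 0.5, noiseSigma = 0.05),
    extractors = list(
      list(name = "global", kind = "random_projection", featureDim = 32L),
      list(name = "focused", kind = "region_restricted", featureDim = 32L,
           region = c(25L, 25L, 16L, 16L)),
      # texture-sensitive features; excluded from the saliency stage, which
      # re-embeds tens of thousands of occluded copies
      list(name = "texture_cnn", kind = "tiny_cnn", featureDim = 8L,
           stages = c("fewshot", "linear", "invariance"))
    ),
    fewshot = list(K = 2L, N = 20L, NQ = 15L, episodes = 200L),
    saliency = list(maskSize = 5L, resizeTo = 121L, cropTo = 113L),
    invariance = list(nEval = 50L),
    stages = c("synth", "fewshot", "linear", "saliency", "invariance",
               "report")
  )
}

# stratified split into train/val/test index lists
.stratifiedSplit <- function(labels, props = c(0.7, 0.15, 0.15), seed = 1L) {
  idx <- list(train = integer(0), val = integer(0), test = integer(0))
  withSeed(childSeed(seed, "split"), {
    for (k in unique(labels)) {
      rows <- sample(which(labels == k))
      n <- length(rows)
      nTrain <- round(props[1] * n)
      nVal <- round(props[2] * n)
      idx$train <- c(idx$train, rows[seq_len(nTrain)])
      idx$val <- c(idx$val, rows[nTrain + seq_len(nVal)])
      idx$test <- c(idx$test, rows[(nTrain + nVal + 1):n])
    }
  })
  idx
}

.buildExtractor <- function(def, imageSize) {
  kinds <- c("random_projection", "region_restricted", "flip_invariant",
             "tiny_cnn")
  if (is.null(def$kind) || !def$kind %in% kinds)
    stop("unknown extractor kind '", def$kind, "' for extractor '",
         def$name, "'")
  makeToyExtractor(def$kind,
                   featureDim = def$featureDim,
                   seed = if (is.null(def$seed)) 1L else def$seed,
                   inputSize = c(imageSize, imageSize),
                   region = if (is.null(def$region)) NULL
                            else as.integer(unlist(def$region)))
}

.writeStageJson <- function(outDir, file, results, config, extra = list()) {
  payload <- c(list(
    results = results,
    seed = config$seed,
    configHash = objectHash(config[setdiff(names(config), "outDir")]),
    packageVersion = as.character(utils::packageVersion("transferscope"))
  ), extra)
  jsonlite::write_json(payload, file.path(outDir, file), auto_unbox = TRUE,
                       digits = NA)
}

#' Run the evaluation pipeline from a configuration
#'
#' Executes the requested stages in dependency order — synthesize (or load),
#' embed, evaluate (few-shot, linear probe), analyze (saliency, invariance)
#' and report — writing one JSON result file per stage and extractor into
#' `config$outDir`. Every output embeds the seed, a hash of the
#' configuration and the package version. The run is fully deterministic
#' under a fixed seed. Any stage failure aborts with the stage name;
#' already-written results are preserved.
#'
#' @param config a config list (see [demoConfig()]) or the path to a YAML
#'   file with the same structure.
#' @param stages optional subset of stages to run (default
#'   `config$stages`).
#' @return invisibly, a list with the output directory, per-stage key
#'   numbers and (when the report stage runs) the aggregated
#'   [ScoreTable-class] list.
#' @export
runPipeline <- function(config, stages = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$seed), !is.null(config$outDir))
  seed <- as.integer(config$seed)
  outDir <- config$outDir
  if (is.null(stages)) stages <- config$stages
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)

  syn <- config$synthetic
  imageSize <- if (is.null(syn$imageSize)) 64L else as.integer(syn$imageSize)

  # validate extractor definitions before any compute
  extractors <- list()
  extractorDefs <- list()
  for (def in config$extractors) {
    if (is.null(def$name)) stop("every extractor needs a name")
    extractors[[def$name]] <- .buildExtractor(def, imageSize)
    extractorDefs[[def$name]] <- def
  }
  if (!length(extractors)) stop("config defines no extractors")

  runStage <- function(name, fun) {
    tryCatch(fun(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
  }

  # extractors participating in a stage (an extractor definition may opt in
  # to a subset of stages)
  stageExtractors <- function(stage) {
    names(extractors)[vapply(names(extractors), function(nm) {
      st <- extractorDefs[[nm]]$stages
      is.null(st) || stage %in% st
    }, logical(1))]
  }

  out <- list(outDir = outDir)

  spec <- syntheticSpec(
    imageSize = imageSize,
    nClasses = if (is.null(syn$nClasses)) 2L else as.integer(syn$nClasses),
    signalAmplitude = if (is.null(syn$signalAmplitude)) 0.5 else syn$signalAmplitude,
    noiseSigma = if (is.null(syn$noiseSigma)) 0.05 else syn$noiseSigma,
    seed = seed
  )
  nPerClass <- if (is.null(syn$nPerClass)) 40L else as.integer(syn$nPerClass)
  dataset <- generateDataset(spec, nPerClass)

  if ("synth" %in% stages) {
    runStage("synth", function() {
      writeImageSet(dataset, file.path(outDir, "synthetic"))
      out$manifest <<- file.path(outDir, "synthetic", "manifest.csv")
    })
  }

  emb <- lapply(extractors, embedDataset, x = dataset)

  if ("fewshot" %in% stages) {
    runStage("fewshot", function() {
      fs <- config$fewshot
      res <- list()
      for (nm in stageExtractors("fewshot")) {
        r <- evaluateFewshot(emb[[nm]]$features, emb[[nm]]$labels,
                             K = fs$K, N = fs$N, NQ = fs$NQ,
                             nEpisodes = fs$episodes, seed = seed)
        res[[nm]] <- list(model = nm, task = "synthetic",
                          metric = "fewshot_accuracy",
                          value = r@meanAccuracy, ci = r@ci95Halfwidth)
      }
      .writeStageJson(outDir, "fewshot.json", unname(res), config)
      out$fewshot <<- vapply(res, function(x) x$value, numeric(1))
    })
  }

  if ("linear" %in% stages) {
    runStage("linear", function() {
      res <- list()
      for (nm in stageExtractors("linear")) {
        sp <- .stratifiedSplit(emb[[nm]]$labels, seed = seed)
        pr <- fitLinearProbe(
          emb[[nm]]$features[sp$train, , drop = FALSE], emb[[nm]]$labels[sp$train],
          emb[[nm]]$features[sp$val, , drop = FALSE], emb[[nm]]$labels[sp$val],
          emb[[nm]]$features[sp$test, , drop = FALSE], emb[[nm]]$labels[sp$test]
        )
        res[[nm]] <- list(model = nm, task = "synthetic",
                          metric = "linear_accuracy",
                          value = pr@testAccuracy,
                          chosenLambda = pr@chosenLambda)
      }
      .writeStageJson(outDir, "linear.json", unname(res), config)
      out$linear <<- vapply(res, function(x) x$value, numeric(1))
    })
  }

  if ("saliency" %in% stages) {
    runStage("saliency", function() {
      sal <- config$saliency
      res <- list()
      for (nm in stageExtractors("saliency")) {
        # rebuild the extractor for the saliency working size
        exSal <- .buildExtractor(extractorDefs[[nm]], sal$resizeTo)
        m <- occlusionSaliency(exSal, images(dataset)[[1]],
                               maskSize = sal$maskSize,
                               resizeTo = sal$resizeTo, cropTo = sal$cropTo,
                               imageId = "synthetic_img_1")
        res[[nm]] <- list(model = nm, task = "synthetic",
                          metric = "attentive_diffusion",
                          value = attentiveDiffusion(m),
                          countsChecksum = sum(m@occlusionCounts))
      }
      .writeStageJson(outDir, "saliency.json", unname(res), config)
      out$diffusion <<- vapply(res, function(x) x$value, numeric(1))
    })
  }

  if ("invariance" %in% stages) {
    runStage("invariance", function() {
      inv <- config$invariance
      nEval <- if (is.null(inv$nEval)) 100L else as.integer(inv$nEval)
      res <- list()
      for (nm in stageExtractors("invariance")) {
        mom <- estimateMoments(extractors[[nm]], dataset, seed = seed)
        r <- invarianceScore(extractors[[nm]], dataset, flipFamily(), mom,
                             nEval = nEval, seed = seed)
        res[[nm]] <- list(model = nm, task = "synthetic",
                          metric = "flip_invariance", value = r@score)
      }
      .writeStageJson(outDir, "invariance.json", unname(res), config)
      out$invariance <<- vapply(res, function(x) x$value, numeric(1))
    })
  }

  if ("report" %in% stages) {
    runStage("report", function() {
      out$tables <<- aggregateRun(outDir, file.path(outDir, "report"))
    })
  }

  invisible(out)
}

#' Run the end-to-end synthetic demonstration
#'
#' Runs synth, few-shot, linear probe, saliency, invariance and report on
#' the built-in synthetic configuration. Deterministic under a fixed seed.
#'
#' @param outDir output directory.
#' @param seed global seed.
#' @return invisibly, the [runPipeline()] result list.
#' @export
runDemo <- function(outDir = tempfile("transferscope_demo"), seed = 1L) {
  runPipeline(demoConfig(seed = seed, outDir = outDir))
}

#' Command-line interface dispatcher
#'
#' Thin argument parser behind the `transferscope` command-line script
#' (`inst/cli/transferscope.R`). Subcommands: `demo` (built-in synthetic
#' end-to-end run), `run` (all configured stages), and the single-stage
#' commands `synth`, `fewshot`, `linear`, `saliency`, `invariance`,
#' `report`, each driven by `--config cfg.yaml`. Options: `--config PATH`,
#' `--out DIR`, `--seed INT`.
#'
#' @param args character vector (e.g. `commandArgs(trailingOnly = TRUE)`).
#' @return invisibly, the pipeline result.
#' @export
runCli <- function(args) {
  if (length(args) == 0L)
    stop("usage: transferscope <demo|run|synth|fewshot|linear|saliency|",
         "invariance|report> [--config cfg.yaml] [--out DIR] [--seed INT]")
  cmd <- args[1]
  opts <- list(config = NULL, out = NULL, seed = 1L)
  i <- 2L
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opts)) stop("unknown option --", key)
    if (i + 1L > length(args)) stop("missing value for --", key)
    opts[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  seed <- as.integer(opts$seed)

  if (cmd == "demo") {
    outDir <- if (is.null(opts$out)) tempfile("transferscope_demo") else opts$out
    return(invisible(runDemo(outDir, seed = seed)))
  }
  stagesByCmd <- list(
    run = NULL,
    synth = "synth", fewshot = "fewshot", linear = "linear",
    saliency = "saliency", invariance = "invariance", report = "report"
  )
  if (!cmd %in% names(stagesByCmd))
    stop("unknown subcommand '", cmd, "'")
  if (is.null(opts$config))
    stop("subcommand '", cmd, "' requires --config")
  config <- yaml::read_yaml(opts$config)
  config$seed <- seed
  if (!is.null(opts$out)) config$outDir <- opts$out
  invisible(runPipeline(config, stages = stagesByCmd[[cmd]]))
}
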