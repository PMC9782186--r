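#' Construct a cross-model score table
#'
#' @param values numeric matrix, rows = models, columns = tasks (dimnames
#'   required).
#' @param uncertainty optional matching matrix of CI half-widths.
#' @return a [ScoreTable-class].
#' @export
scoreTable <- function(values, uncertainty = NULL) {
  new("ScoreTable", values = values, uncertainty = uncertainty)
}

#' Min-max scale scores across models
#'
#' Rescales one task's scores across models to `[0, 1]`: the best model maps
#' to 1 and the worst to 0, via `(x - min) / (max - min)`. When all models
#' score the same (max = min) every cell maps to 0.5 by convention (flagged
#' in the result's `"degenerate"` attribute). Affine transforms of a column
#' leave the scaled values unchanged.
#'
#' @param x numeric vector of one task's scores across >= 2 models, or a
#'   [ScoreTable-class] (scaled column by column).
#' @return scaled vector (or ScoreTable).
#' @export
minmaxScaleAcrossModels <- function(x) {
  if (is(x, "ScoreTable")) {
    scaled <- apply(x@values, 2, minmaxScaleAcrossModels)
    dimnames(scaled) <- dimnames(x@values)
    return(scoreTable(scaled))
  }
  if (length(x) < 2L)
    stop("scaling across models requires at least 2 models")
  rng <- range(x)
  if (rng[1] == rng[2]) {
    out <- rep(0.5, length(x))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Linear fit with Pearson correlation and optional reduced chi-squared
#'
#' Ordinary least squares of y on x (weighted by `1 / sigma^2` when
#' uncertainties are supplied), the Pearson correlation coefficient r, a
#' two-sided p value from the t distribution with n - 2 degrees of freedom,
#' and — only when `sigma` is given — the reduced chi-squared
#' `sum(((y - yhat) / sigma)^2) / (n - 2)` of the fit.
#'
#' @param x,y numeric vectors, length n >= 3.
#' @param sigma optional per-point uncertainties (> 0).
#' @return list with `slope`, `intercept`, `r`, `pValue`, `reducedChi2`
#'   (NA when `sigma` is absent) and `n`.
#' @examples
#' pearsonFit(1:10, 2 * (1:10) + 1, sigma = rep(0.5, 10))
#' @export
pearsonFit <- function(x, y, sigma = NULL) {
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("pearsonFit requires equal-length x and y with n >= 3")
  if (stats::var(x) == 0) stop("x has zero variance; no fit possible")
  if (!is.null(sigma) && (length(sigma) != n || any(sigma <= 0)))
    stop("sigma must be positive and match length(x)")

  fit <- if (is.null(sigma)) {
    stats::lm(y ~ x)
  } else {
    stats::lm(y ~ x, weights = 1 / sigma^2)
  }
  co <- stats::coef(fit)
  r <- stats::cor(x, y)
  tstat <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  chi2 <- if (is.null(sigma)) {
    NA_real_
  } else {
    sum(((y - stats::fitted(fit)) / sigma)^2) / (n - 2)
  }
  list(slope = unname(co[2]), intercept = unname(co[1]),
       r = r, pValue = p, reducedChi2 = chi2, n = n)
}

#' Aggregate stage results from a directory into score tables
#'
#' Reads every `*.json` result file (schema: objects with `model`, `task`,
#' `metric`, `value`, optional `ci`), builds one [ScoreTable-class] per
#' metric, and optionally renders CSV and JSON reports.
#'
#' @param resultsDir directory of result JSON files.
#' @param outDir optional output directory for `report_<metric>.csv` tables
#'   and a combined `report.json`.
#' @return named list of [ScoreTable-class], one per metric.
#' @export
aggregateRun <- function(resultsDir, outDir = NULL) {
  files <- list.files(resultsDir, pattern = "\\.json$", full.names = TRUE)
  rows <- list()
  bad <- character(0)
  for (f in files) {
    rec <- tryCatch(jsonlite::read_json(f), error = function(e) NULL)
    entries <- if (!is.null(rec) && !is.null(rec$results)) rec$results
               else list(rec)
    for (e in entries) {
      if (is.null(e) || is.null(e$model) || is.null(e$task) ||
          is.null(e$metric) || is.null(e$value)) {
        bad <- c(bad, f)
        next
      }
      rows[[length(rows) + 1L]] <- data.frame(
        model = e$model, task = e$task, metric = e$metric,
        value = as.numeric(e$value),
        ci = if (is.null(e$ci)) NA_real_ else as.numeric(e$ci)
      )
    }
  }
  bad <- unique(bad)
  if (length(bad))
    stop("result files violate the schema: ", paste(basename(bad), collapse = ", "))
  if (!length(rows)) stop("no result entries found in ", resultsDir)
  df <- do.call(rbind, rows)

  tables <- list()
  for (m in unique(df$metric)) {
    sub <- df[df$metric == m, ]
    if (anyDuplicated(sub[c("model", "task")]))
      stop("duplicated (model, task) cell for metric ", m)
    models <- sort(unique(sub$model))
    tasks <- sort(unique(sub$task))
    vals <- matrix(NA_real_, length(models), length(tasks),
                   dimnames = list(models, tasks))
    unc <- vals
    vals[cbind(match(sub$model, models), match(sub$task, tasks))] <- sub$value
    unc[cbind(match(sub$model, models), match(sub$task, tasks))] <- sub$ci
    tables[[m]] <- scoreTable(vals, if (all(is.na(unc))) NULL else unc)
  }

  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    for (m in names(tables)) {
      utils::write.csv(tables[[m]]@values,
                       file.path(outDir, paste0("report_", m, ".csv")))
    }
    jsonlite::write_json(
      lapply(tables, function(t) as.data.frame(t@values)),
      file.path(outDir, "report.json"), auto_unbox = TRUE, digits = NA
    )
  }
  tables
}

#' Scaled group means across model classes
#'
#' Applies the cross-model min-max scaling per task, then averages over each
#' model class, and finally over tasks — in that order. The `sd` column is
#' the 1-sigma variation across the individual models being averaged (0 for
#' a group of one model).
#'
#' @param table a [ScoreTable-class].
#' @param groups named character vector: model id -> group label (e.g.
#'   supervised / self-supervised / domain-specific).
#' @return data.frame with columns `group`, `mean`, `sd`, `nModels`.
#' @export
scaledGroupMeans <- function(table, groups) {
  stopifnot(is(table, "ScoreTable"))
  scaled <- minmaxScaleAcrossModels(table)@values
  models <- rownames(scaled)
  missing <- setdiff(models, names(groups))
  if (length(missing))
    stop("no group assigned for model(s): ", paste(missing, collapse = ", "))
  perModel <- rowMeans(scaled, na.rm = TRUE) # average over tasks
  g <- factor(groups[models])
  data.frame(
    group = levels(g),
    mean = as.numeric(tapply(perModel, g, mean)),
    sd = as.numeric(tapply(perModel, g, function(v)
      if (length(v) > 1) stats::sd(v) else 0)),
    nModels = as.integer(table(g))
  )
}
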