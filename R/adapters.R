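#' Read an image manifest CSV
#'
#' A manifest has one row per image with columns `filepath` and `label`
#' (plus optional `group_id`, `view_id`). Column names are configurable for
#' heterogeneous real-world manifests.
#'
#' @param path CSV path.
#' @param filepathCol,labelCol column names holding paths and labels.
#' @return a data.frame with normalized column names `filepath`, `label`
#'   (and any remaining columns unchanged).
#' @export
readImageManifest <- function(path, filepathCol = "filepath",
                              labelCol = "label") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!filepathCol %in% names(df))
    stop("manifest is missing the filepath column '", filepathCol, "'")
  if (!labelCol %in% names(df))
    stop("manifest is missing the label column '", labelCol, "'")
  names(df)[names(df) == filepathCol] <- "filepath"
  names(df)[names(df) == labelCol] <- "label"
  if (anyDuplicated(df$filepath))
    stop("manifest filepaths must be unique")
  df
}

#' Write a (converted) manifest CSV
#'
#' @param df a manifest data.frame.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeManifest <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Load images referenced by a manifest into a LabeledImageSet
#'
#' @param manifestPath manifest CSV path; image paths are resolved relative
#'   to the manifest's directory.
#' @param nClasses total class count (default: `max(label) + 1`).
#' @return a [LabeledImageSet-class].
#' @export
loadImageSet <- function(manifestPath, nClasses = NULL) {
  df <- readImageManifest(manifestPath)
  base <- dirname(manifestPath)
  imgs <- lapply(df$filepath, function(f) {
    px <- png::readPNG(file.path(base, f))
    if (length(dim(px)) == 3L && dim(px)[3] == 4L) px <- px[, , 1:3] # drop alpha
    px
  })
  lab <- as.integer(df$label)
  new("LabeledImageSet",
    images = imgs,
    label = lab,
    groupId = if ("group_id" %in% names(df)) as.integer(df$group_id)
              else rep(NA_integer_, nrow(df)),
    viewId = if ("view_id" %in% names(df)) as.integer(df$view_id)
             else rep(NA_integer_, nrow(df)),
    nClasses = if (is.null(nClasses)) max(lab) + 1L else as.integer(nClasses)
  )
}

.asIndicator <- function(x) {
  if (is.logical(x)) as.integer(x) else as.integer(x != 0)
}

#' Many-to-one label binarization
#'
#' Converts multi-label records to binary labels for one target pathology:
#' positive (1) iff the target indicator is set; all other pathologies and
#' the absence of findings are negative (0), regardless of co-occurring
#' pathologies. The target is caller-supplied (e.g. the most common
#' pathology of the dataset), never auto-detected.
#'
#' @param records data.frame with one 0/1 (or logical) column per pathology.
#' @param target name of the target pathology column.
#' @return integer vector of 0/1 labels.
#' @export
binarizeManyToOne <- function(records, target) {
  if (!target %in% names(records))
    stop("target pathology '", target, "' is not a column of the records")
  .asIndicator(records[[target]])
}

#' Abnormal-vs-normal binarization of textual labels
#'
#' Labels are trimmed and case-folded before matching; any abnormal X-ray is
#' positive (1), normal is negative (0).
#'
#' @param labels character vector of "normal"/"abnormal" (any case,
#'   surrounding whitespace tolerated).
#' @return integer vector of 0/1 labels.
#' @export
binarizeAbnormal <- function(labels) {
  norm <- tolower(trimws(as.character(labels)))
  bad <- setdiff(unique(norm), c("normal", "abnormal"))
  if (length(bad))
    stop("unrecognized label value(s): ", paste(bad, collapse = ", "))
  as.integer(norm == "abnormal")
}

#' Merge classes under an explicit map
#'
#' Remaps each observed label through `mergeMap` (e.g. combining normal and
#' high-myopia into one negative class while pathological myopia stays
#' positive). Every observed label must be covered.
#'
#' @param labels vector of labels.
#' @param mergeMap named vector or list: `observed label -> new label`.
#' @return vector of remapped labels (integer when the targets are numeric).
#' @export
mergeClasses <- function(labels, mergeMap) {
  mergeMap <- unlist(mergeMap)
  key <- as.character(labels)
  missing <- setdiff(unique(key), names(mergeMap))
  if (length(missing))
    stop("mergeMap does not cover label(s): ", paste(missing, collapse = ", "))
  out <- mergeMap[key]
  names(out) <- NULL
  if (is.numeric(out)) as.integer(out) else out
}

#' Ordinal encoding of categorical labels
#'
#' Maps each label to its 0-based index in an ordered category list.
#'
#' @param labels vector of categorical labels.
#' @param orderedCategories categories from lowest to highest grade.
#' @return integer vector of indices `0 .. length(orderedCategories) - 1`.
#' @export
ordinalize <- function(labels, orderedCategories) {
  pos <- match(as.character(labels), as.character(orderedCategories))
  if (anyNA(pos)) {
    bad <- unique(labels[is.na(pos)])
    stop("unknown categor", if (length(bad) > 1) "ies: " else "y: ",
         paste(bad, collapse = ", "))
  }
  as.integer(pos - 1L)
}

#' Filter multi-label records to single-pathology multiclass labels
#'
#' Keeps only records with exactly one positive pathology indicator and
#' labels each by that pathology's 0-based column index, enabling multiclass
#' classification from multi-label annotations. The number of dropped rows
#' is reported via `message()`.
#'
#' @param records data.frame of pathology indicator columns (a `no_finding`
#'   column, if present, is ignored for counting).
#' @param pathologyNames indicator columns to use (default: all columns
#'   except `no_finding`).
#' @return the retained records with an added integer `label` column; zero
#'   rows (with a warning) when no record qualifies.
#' @export
filterSinglePathology <- function(records, pathologyNames = NULL) {
  if (is.null(pathologyNames))
    pathologyNames <- setdiff(names(records), "no_finding")
  ind <- vapply(records[pathologyNames], .asIndicator, integer(nrow(records)))
  ind <- matrix(ind, nrow = nrow(records))
  pos <- rowSums(ind)
  keep <- pos == 1L
  message(sum(!keep), " record(s) dropped (zero or multiple pathologies)")
  out <- records[keep, , drop = FALSE]
  out$label <- if (any(keep)) max.col(ind[keep, , drop = FALSE]) - 1L else integer(0)
  if (!any(keep)) warning("no single-pathology records retained")
  out
}
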