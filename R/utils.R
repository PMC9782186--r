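#' @keywords internal
"_PACKAGE"

#' @import methods
NULL

# Deterministic child seed from (seed, tag). Uses a 31-multiplier polynomial
# hash over the tag modulo the Mersenne prime 2^31 - 1; intermediate products
# stay below 2^53 so double arithmetic is exact.
childSeed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- abs(as.numeric(seed)) %% 2147483647
  for (code in utf8ToInt(as.character(tag))) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under set.seed(seed) without disturbing the caller's RNG
# stream.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

# Flatten an image array (H x W or H x W x C) to a numeric vector in a fixed
# (column-major, channel-last) order.
flattenImage <- function(px) {
  as.numeric(px)
}

isSingleNumber <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

isCount <- function(x, min = 0L) {
  isSingleNumber(x) && x >= min && x == as.integer(x)
}

# md5 of an R object via its canonical JSON serialization written to a
# temporary file (tools::md5sum works on files).
objectHash <- function(x) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf), add = TRUE)
  jsonlite::write_json(x, tf, auto_unbox = TRUE, digits = NA, force = TRUE)
  unname(tools::md5sum(tf))
}
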