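#' @keywords internal
"_PACKAGE"

# Numerically stable log(sum(exp(x))) along rows of a matrix.
# Returns a vector of length nrow(x).
rowLogSumExp <- function(x) {
  m <- apply(x, 1L, max)
  m + log(rowSums(exp(x - m)))
}

logSumExp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Derive a child seed from a master seed and a stream name
#'
#' One master seed fans out to independent named streams (data generation,
#' model initialization, k-means, batching, ...) so that consistency
#' experiments can vary a single stream while holding the others fixed.
#' The derivation is a small deterministic string hash folded into the
#' master seed, kept below 2^31.
#'
#' @param seed integer master seed.
#' @param stream character stream name, e.g. `"data"`, `"model"`, `"kmeans"`.
#' @return a single integer usable with [set.seed()].
#' @export
#' @examples
#' deriveSeed(1L, "data")
#' deriveSeed(1L, "model")
deriveSeed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (cc in utf8ToInt(stream)) h <- (h * 131 + cc) %% 1000000007
  as.integer((abs(as.numeric(seed)) * 48271 + h) %% 2147483647)
}

# run expr with a temporary RNG state seeded from (seed, stream),
# restoring the caller's RNG state afterwards
withStream <- function(seed, stream, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(deriveSeed(seed, stream))
  expr
}

assertMatrix <- function(x, what = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", what), call. = FALSE)
  }
  if (any(!is.finite(x))) {
    stop(sprintf("'%s' contains non-finite values", what), call. = FALSE)
  }
  invisible(x)
}
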