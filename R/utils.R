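#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

#' Derive a reproducible sub-seed from a master seed and a stage tag
#'
#' A single pipeline seed fans out deterministically to per-stage seeds so
#' that re-running one stage reproduces its randomness without replaying the
#' whole pipeline.  The derivation hashes the tag into the seed and keeps the
#' result inside the 32-bit integer range.
#'
#' @param seed master integer seed.
#' @param tag character stage tag.
#' @return an integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% (2^31 - 1))
}

## run `expr` under a local RNG state seeded with `seed`; the caller's RNG
## stream is untouched.  `seed = NULL` uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

stop_bad <- function(...) stop(sprintf(...), call. = FALSE)

check_finite_matrix <- function(x, what = "points") {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop_bad("%s must be a numeric matrix", what)
  }
  if (any(!is.finite(x))) stop_bad("%s contains non-finite values", what)
  invisible(x)
}

## bounding-box diagonal of an n x 2 point matrix
bbox_diagonal <- function(points) {
  rng_x <- range(points[, 1L])
  rng_y <- range(points[, 2L])
  sqrt(diff(rng_x)^2 + diff(rng_y)^2)
}
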