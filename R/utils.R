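#' @importFrom methods new is validObject slot show
#' @importFrom stats median quantile rnorm runif sd setNames phyper t.test
#' @importFrom utils head read.delim write.table combn
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom IRanges CharacterList
#' @importFrom Rcpp evalCpp
#' @useDynLib perturbGRN, .registration = TRUE
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`.
## The caller's RNG stream is restored afterwards so that seeded package
## functions never perturb the session's randomness.
withSeed <- function(seed, expr) {
  if (is.null(seed) || is.na(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Deterministically expand one seed into `n` child seeds (all < 2^31).
deriveSeeds <- function(seed, n) {
  withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.assertFiniteMatrix <- function(x, name = deparse(substitute(x))) {
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  if (!all(is.finite(x)))
    stop(sprintf("'%s' contains non-finite values", name), call. = FALSE)
  invisible(x)
}

.assertSquare <- function(x, name = deparse(substitute(x))) {
  .assertFiniteMatrix(x, name)
  if (nrow(x) != ncol(x))
    stop(sprintf("'%s' must be square (got %d x %d)", name, nrow(x), ncol(x)),
         call. = FALSE)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

softThreshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)

## Entries below this magnitude are treated as absent links after any refit.
.ZERO_TOL <- 1e-12
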