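#' @keywords internal
#' @importFrom e1071 svm
#' @importFrom randomForest randomForest
#' @importFrom stats predict coef
#' @importFrom graphics plot
"_PACKAGE"

## Evaluate `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards. All randomness in the package flows through
## this so cohorts, fits and splits are reproducible from a single integer.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% .Machine$integer.max))
  }
  force(expr)
}

## Derived per-unit seed: keeps streams independent across sessions / folds
## while staying inside 32-bit integer range.
derive_seed <- function(seed, ordinal) {
  as.integer((as.numeric(seed) + as.numeric(ordinal)) %% .Machine$integer.max)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

## Numbers are serialized with %.17g so that a write/read round trip is
## bit-exact for doubles.
format_num <- function(x) formatC(x, format = "g", digits = 17)

sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) {
  x[x < 0] <- 0
  x
}

col_sds <- function(m) {
  if (nrow(m) < 2L) return(numeric(ncol(m)))
  apply(m, 2L, stats::sd)
}
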