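#' @useDynLib reposcreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom randomForest randomForest
#' @importFrom e1071 svm
#' @importFrom xgboost xgb.train
#' @importFrom limma squeezeVar
#' @importFrom jsonlite toJSON
#' @importFrom data.table as.data.table
NULL

# Deterministic 32-bit-range hash of an integer vector (polynomial rolling hash
# mod the Mersenne prime 2^31 - 1).  All intermediates stay below 2^53 so the
# computation is exact in doubles on every platform.
hash_ints <- function(v) {
  h <- 17
  p <- 2147483647
  for (x in v) {
    h <- (h * 31 + (x %% p)) %% p
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards. Used so that every stochastic operation in the
# package is reproducible from an explicit seed argument.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from one master seed, kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) * 7919 + 104729 * seq_len(n)) %% 2147483629
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
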