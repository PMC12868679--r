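#' @useDynLib spatmet, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats kmeans density dnorm median quantile sd var rexp runif
#'   rbinom rnorm setNames pchisq qnorm p.adjust wilcox.test complete.cases
#'   cor predict coef aggregate rbeta
#' @importFrom utils read.csv write.csv head modifyList
NULL

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (has_seed) old <- get(".Random.seed", envir = globalenv())
    set.seed(seed)
    on.exit({
      if (has_seed) assign(".Random.seed", old, envir = globalenv())
      else rm(".Random.seed", envir = globalenv())
    })
  }
  force(expr)
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

msg <- function(..., verbose = TRUE) {
  if (isTRUE(verbose)) message(sprintf(...))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)
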