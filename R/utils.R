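## internal helpers shared across modules

# Evaluate an expression with a temporary RNG state, restoring the caller's
# stream afterwards.  All user-facing randomness goes through this.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive independent sub-seeds from a master seed by fixed positions in a
# seeded integer stream, so components (presence draws, background draws,
# latent labels, optimizer starts, ...) are separately reproducible.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clip01 <- function(x, eps) pmin(pmax(x, eps), 1 - eps)

# coerce covariate input (vector for d = 1, matrix/data.frame otherwise)
as_points <- function(x, d) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (d != 1L) {
      stop("expected a matrix with ", d, " columns, got a plain vector")
    }
    x <- matrix(as.numeric(x), ncol = 1L)
  }
  storage.mode(x) <- "double"
  if (ncol(x) != d) {
    stop("covariate matrix has ", ncol(x), " columns; model expects ", d)
  }
  if (anyNA(x) || any(!is.finite(x))) stop("non-finite covariate values")
  x
}

`%||%` <- function(a, b) if (is.null(a)) b else a
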