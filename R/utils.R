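`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's random-number state afterwards so that library
#' internals never perturb user-level reproducibility.
#' @noRd
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Deterministic derived seeds, kept inside 32-bit integer range.
deriveSeed <- function(seed, ...) {
  off <- c(...)
  s <- as.double(seed) %% 2147483647
  for (o in off) {
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s) + 1L
}

# Stratified fold assignment: each class spread as evenly as possible.
stratifiedFolds <- function(y, k, seed) {
  stopifnot(k >= 2)
  fold <- integer(length(y))
  withSeed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

oneHot <- function(y, K) {
  out <- matrix(0, length(y), K)
  out[cbind(seq_along(y), y)] <- 1
  out
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

rowArgmax <- function(p) apply(p, 1L, which.max)
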