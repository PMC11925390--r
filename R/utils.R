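#' @importFrom stats cor p.adjust predict rbinom runif sd wilcox.test
#' @importFrom utils head read.csv write.csv packageVersion
NULL

## Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
## the caller's stream afterwards so seeded helpers do not perturb each other.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a stage seed from a master seed
#'
#' Deterministically maps a master seed and a stage label to a positive
#' integer below 2^31, so every pipeline stage gets its own reproducible
#' random stream.
#'
#' @param master integer master seed.
#' @param stage character stage label.
#' @return a single integer seed.
#' @export
deriveSeed <- function(master, stage) {
  stopifnot(length(master) == 1L, is.finite(master))
  h <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729) %% 2147483629 + 1)
}

## Models enter the attribution and faithfulness code either as fitted
## ActivityModel objects or as plain scoring functions X -> numeric
## (useful for closed-form oracles in tests and examples).
scoreFun <- function(model) {
  if (is.function(model)) model else function(X) predictScore(model, X)
}

## Binary-matrix guard used by kernels, generators and value functions.
assertBinaryMatrix <- function(X, what = "matrix") {
  if (!is.matrix(X)) stop(what, " must be a matrix")
  if (!all(X %in% c(0, 1))) stop(what, " must contain only 0/1 entries")
  invisible(TRUE)
}

checkProbability <- function(p, what) {
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop(what, " must be a probability in [0, 1]")
  invisible(TRUE)
}

## popcount for non-negative integer masks (used by the coalition enumerator)
bitCount <- function(masks, nbits) {
  counts <- integer(length(masks))
  for (b in seq_len(nbits) - 1L)
    counts <- counts + as.integer(bitwAnd(masks, bitwShiftL(1L, b)) != 0L)
  counts
}

## mask -> logical coalition matrix (rows = masks, cols = players)
masksToMatrix <- function(masks, nbits) {
  out <- matrix(FALSE, length(masks), nbits)
  for (b in seq_len(nbits))
    out[, b] <- bitwAnd(masks, bitwShiftL(1L, b - 1L)) != 0L
  out
}
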