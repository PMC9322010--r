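# Internal helpers: condensed-pair indexing and deterministic seed fan-out.

# Index of pair (i, j), i < j, in a condensed vector laid out in
# stats::dist order (lower triangle, column-wise) for n items.
.pairIndex <- function(i, j, n) {
  stopifnot(all(i < j))
  n * (i - 1) - i * (i - 1) / 2 + j - i
}

# Two-column matrix of all (i, j), i < j, in dist order.
.pairGrid <- function(n) {
  i <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  j <- sequence((n - 1L):1L) + i
  cbind(i = i, j = j)
}

# Deterministically derive `n` independent sub-seeds from a master seed,
# kept below 2^31 so they are valid R integers.
.seedStream <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards so package functions do not disturb the
# user's random stream.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()))
  set.seed(as.integer(seed))
  expr
}

# Condensed vector -> square symmetric matrix with labels.
.squareForm <- function(x, labels, diag_value = 0) {
  n <- length(labels)
  m <- matrix(diag_value, n, n, dimnames = list(labels, labels))
  pg <- .pairGrid(n)
  m[pg] <- x
  m[pg[, c(2, 1), drop = FALSE]] <- x
  m
}
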