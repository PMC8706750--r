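# internal helpers shared across modules

# row-major pixel coordinates: p = (r - 1) * C + c
.pixelCoords <- function(dims) {
  R <- dims[1L]; C <- dims[2L]
  list(r = rep(seq_len(R), each = C), c = rep.int(seq_len(C), R))
}

.pixelIndex <- function(r, c, C) (r - 1L) * C + c

# matrix (R x C) -> vector in row-major pixel order, and back
.flattenRowMajor <- function(m) as.vector(t(m))

.unflattenRowMajor <- function(v, dims) {
  matrix(v, nrow = dims[1L], ncol = dims[2L], byrow = TRUE)
}

# run expr with a temporarily seeded RNG, restoring global state after;
# seed = NULL leaves the RNG alone
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# counter-based seed splitting: all randomness in a composite operation
# flows from one user seed; keeps derived seeds in 32-bit integer range
.splitSeed <- function(seed, counter) {
  if (is.null(seed)) return(NULL)
  as.integer((as.double(seed) * 7919 + 104729 * counter) %% 2147483629)
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)
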