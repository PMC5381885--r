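# Radical-inverse Halton sequence on [0,1]^dim (deterministic low-discrepancy
# points used for reproducible multi-start optimisation).
halton_points <- function(n, dim) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29)
  if (dim > length(primes)) stop("too many dimensions for halton_points()")
  radical_inverse <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) {
      f <- f / b
      r <- r + f * (i %% b)
      i <- i %/% b
    }
    r
  }
  out <- matrix(0, n, dim)
  for (j in seq_len(dim))
    out[, j] <- vapply(seq_len(n), radical_inverse, numeric(1), b = primes[j])
  out
}

# Evaluate `expr` with the RNG seeded by `seed`, restoring the caller's RNG
# state afterwards so no global state leaks. seed = NULL runs unseeded.
with_local_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
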