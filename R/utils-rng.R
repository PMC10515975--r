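# Run code under a fixed seed without disturbing the caller's RNG stream.
.with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Dirichlet sampler (gamma normalisation); rows are draws.
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  x[x == 0] <- .Machine$double.xmin   # guard degenerate gamma draws at tiny alpha
  x / rowSums(x)
}
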