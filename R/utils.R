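`%||%` <- function(a, b) if (is.null(a)) b else a

# Run `expr` under a temporary RNG state seeded with `seed` (NULL = use the
# current stream).  Restores .Random.seed afterwards so generators with an
# explicit seed never perturb the caller's stream.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Normalize rows of an n x 3 matrix to unit length.
unitize <- function(v) {
  if (is.null(dim(v))) v <- matrix(v, nrow = 1)
  v / sqrt(rowSums(v^2))
}

vec_norm <- function(v) sqrt(sum(v^2))

# Separable Gaussian blur of a matrix; sigma in pixels.  Kernel is
# renormalized at the borders (no padding artefacts).
.gauss_blur <- function(m, sigma) {
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-half, half))^2 / (2 * sigma^2))
  blur1 <- function(x) {
    n <- length(x)
    out <- numeric(n)
    for (i in seq_len(n)) {
      j <- max(1, i - half):min(n, i + half)
      w <- k[j - i + half + 1]
      out[i] <- sum(x[j] * w) / sum(w)
    }
    out
  }
  m <- apply(m, 2L, blur1)
  t(apply(m, 1L, blur1))
}
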