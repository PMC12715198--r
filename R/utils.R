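## Internal helpers: seeded RNG streams and matrix utilities.

## Derive a child seed from a master seed and a stream label, so that each
## logical draw (genotypes, design, phenotype, ...) has its own reproducible
## stream. Deterministic, stays below 2^31.
streamSeed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 69621 + h) %% 2147483629 + 1)
}

## Evaluate expr under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Symmetric square root of a PSD matrix, clamping tiny negative eigenvalues.
symSqrt <- function(M, tol = 1e-10) {
  e <- eigen(M, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  if (min(e$values) < -tol * max(abs(e$values), 1))
    stop("matrix is not positive semi-definite")
  e$vectors %*% (sqrt(lam) * t(e$vectors))
}

## Force exact symmetry (guards against floating-point asymmetry).
symmetrize <- function(M) (M + t(M)) / 2
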