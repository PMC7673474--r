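# Internal helpers shared across modules.

# Deterministic sub-seed for a pipeline stage: mixes the global seed with a
# stage tag so adding stages never shifts the randomness of existing ones.
# Kept within the 32-bit integer range.
stageSeed <- function(seed, tag) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(seed) * 48271 + h * 7919) %% 2147483647)
}

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

# n uniform points on the unit sphere.
runifSphere <- function(n) {
  m <- matrix(stats::rnorm(3 * n), ncol = 3)
  m / sqrt(rowSums(m^2))
}

# Shannon entropy (bits) of a vector of counts or probabilities.
entropyBits <- function(p) {
  p <- p / sum(p)
  p <- p[p > 0]
  -sum(p * log2(p))
}

# Uniform random rotation matrix via Shoemake's unit-quaternion sampling.
randomRotation <- function() {
  u <- stats::runif(3)
  q <- c(sqrt(1 - u[1]) * sin(2 * pi * u[2]),
         sqrt(1 - u[1]) * cos(2 * pi * u[2]),
         sqrt(u[1]) * sin(2 * pi * u[3]),
         sqrt(u[1]) * cos(2 * pi * u[3]))
  w <- q[4]; x <- q[1]; y <- q[2]; z <- q[3]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
    2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
    2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Index pairs of the strict upper triangle, in column-major order matching
# upper.tri() extraction.
upperPairs <- function(n) {
  ut <- upper.tri(matrix(0, n, n))
  cbind(i = row(ut)[ut], j = col(ut)[ut])
}
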