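#' Derive a named RNG substream seed
#'
#' Deterministically maps a master seed plus a stage label to a fresh
#' 31-bit seed, so every randomized stage (sampling, initialization,
#' batching, ...) draws from its own stream and adding a stage never shifts
#' another stage's draws.
#'
#' @param seed master integer seed.
#' @param label character stage name.
#' @return An integer in `[0, 2^31 - 1)`.
#' @export
substream_seed <- function(seed, label) {
  codes <- utf8ToInt(label)
  h <- 0
  for (k in codes) h <- (h * 131 + k) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  expr
}

#' Sample points uniformly on a sphere
#'
#' Uniform draw on the sphere of radius `r` around the origin in `d`
#' dimensions (Gaussian draws scaled to the radius).
#'
#' @param n number of points.
#' @param d ambient dimension.
#' @param r sphere radius.
#' @return n x d matrix.
#' @export
sample_sphere <- function(n, d, r = 1) {
  g <- matrix(stats::rnorm(n * d), n, d)
  nr <- sqrt(rowSums(g^2))
  nr[nr == 0] <- 1
  g / nr * r
}
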