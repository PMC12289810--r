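# Independent oracles and fixture generators used across the suite.

# Dual LP for the flat metric solved with boot::simplex on the union support:
# maximize sum c_k f_k over f in [-1,1]^K subject to |f_k - f_l| <= d_kl.
# Independent of the package's transportation-problem route.
lp_flat_oracle <- function(mu, nu) {
  P <- rbind(mu$points, nu$points)
  key <- apply(P, 1, paste, collapse = "\r")
  cs <- tapply(c(mu$weights, -nu$weights), factor(key, levels = unique(key)), sum)
  Pu <- P[!duplicated(key), , drop = FALSE]
  K <- nrow(Pu)
  D <- pairwise_distances(Pu, Pu)
  A <- NULL; b <- NULL
  if (K > 1) {
    for (k in 1:(K - 1)) for (l in (k + 1):K) {
      row <- rep(0, K); row[k] <- 1; row[l] <- -1
      A <- rbind(A, row, -row); b <- c(b, D[k, l], D[k, l])
    }
  }
  A <- rbind(A, diag(K)); b <- c(b, rep(2, K)) # x = f + 1 in [0, 2]
  r <- boot::simplex(a = as.numeric(cs), A1 = A, b1 = b, maxi = TRUE)
  unname(r$value - sum(cs))
}

# W1 dual (no box constraint) via boot::simplex; masses must be equal.
lp_w1_oracle <- function(mu, nu, box = 1e3) {
  P <- rbind(mu$points, nu$points)
  key <- apply(P, 1, paste, collapse = "\r")
  cs <- tapply(c(mu$weights, -nu$weights), factor(key, levels = unique(key)), sum)
  Pu <- P[!duplicated(key), , drop = FALSE]
  K <- nrow(Pu)
  D <- pairwise_distances(Pu, Pu)
  A <- NULL; b <- NULL
  for (k in 1:(K - 1)) for (l in (k + 1):K) {
    row <- rep(0, K); row[k] <- 1; row[l] <- -1
    A <- rbind(A, row, -row); b <- c(b, D[k, l], D[k, l])
  }
  A <- rbind(A, diag(K)); b <- c(b, rep(2 * box, K)) # x = f + box, inert box
  r <- boot::simplex(a = as.numeric(cs), A1 = A, b1 = b, maxi = TRUE)
  unname(r$value - sum(cs))
}

random_measure <- function(n, d, mass_range = c(0.1, 3), sd = 2) {
  discrete_measure(matrix(stats::rnorm(n * d, sd = sd), n, d),
                   stats::runif(n, mass_range[1], mass_range[2]))
}

empty_measure <- function(d) {
  discrete_measure(matrix(numeric(0), 0, d), numeric(0))
}

# short training budget for tests that only need a converged small instance
fast_opt <- function(epochs = 400) optimizer_config(epochs = epochs)
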