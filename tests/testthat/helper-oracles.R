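# Independent oracles and small fixture builders used across the suite.

# Central finite difference of block_nll, entry by entry.
fd_gradient <- function(block, theta, h = 1e-6) {
  g <- matrix(0, nrow(theta), ncol(theta))
  for (i in seq_len(nrow(theta))) {
    for (j in seq_len(ncol(theta))) {
      up <- dn <- theta
      up[i, j] <- theta[i, j] + h
      dn[i, j] <- theta[i, j] - h
      g[i, j] <- (block_nll(block, up) - block_nll(block, dn)) / (2 * h)
    }
  }
  g
}

# Random valid block of a given type, with optional missingness.
random_block <- function(type, p = 4, n = 5, missing = 0, seed = 1) {
  withr::with_seed(seed, {
    x <- switch(type,
      gaussian = matrix(rnorm(p * n), p, n),
      binary   = matrix(rbinom(p * n, 1, 0.5), p, n),
      poisson  = matrix(rpois(p * n, 2), p, n))
    mask <- NULL
    if (missing > 0) {
      mask <- matrix(runif(p * n) >= missing, p, n)
      if (!any(mask)) mask[1, 1] <- TRUE
    }
    omics_block(x, type, name = paste0("rand_", type), mask = mask)
  })
}

random_theta <- function(p = 4, n = 5, lim = 3, seed = 1) {
  withr::with_seed(seed, matrix(runif(p * n, -lim, lim), p, n))
}

# Nuclear-norm proximal operator written out longhand: full SVD, soft
# threshold on the diagonal, explicit reconstruction.
prox_nuclear_oracle <- function(M, mu) {
  sv <- svd(M)
  d <- diag(pmax(sv$d - mu, 0), nrow = length(sv$d))
  sv$u %*% d %*% t(sv$v)
}

# Silhouette by direct double loop over the pairwise distance matrix.
brute_silhouette <- function(coords, labels) {
  D <- as.matrix(dist(t(coords)))
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(D[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Small simulation used where the full default would be slow.
small_spec <- function(seed = 1, ...) {
  simulation_spec(n_samples = 45,
                  block_specs = list(methylation = c(60, "gaussian"),
                                     mutation = c(30, "binary"),
                                     expression = c(40, "poisson")),
                  seed = seed, ...)
}
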