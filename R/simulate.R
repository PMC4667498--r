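#' Specification of a synthetic multi-omics dataset
#'
#' Describes a planted-structure simulation: samples fall into clusters whose
#' centers live in an r-dimensional latent space, a low-rank parameter matrix
#' is built as loadings times latent factors, and each block observes that
#' matrix through its own noise model (additive gaussian noise, Bernoulli
#' draws with logit link, Poisson draws with log link). The generator mirrors
#' the model's own data-generating assumption — entries independent given a
#' low-rank parameter matrix — so it exercises the estimator under conditions
#' where its assumptions hold.
#'
#' @param n_samples Number of samples.
#' @param block_specs Named list; each element is `c(n_features, type)` with
#'   type one of `"gaussian"`, `"binary"`, `"poisson"`. The default mimics a
#'   typical integration of a continuous assay, a mutation panel and a count
#'   assay.
#' @param true_rank Rank r of the planted parameter matrix.
#' @param n_clusters Number of planted sample clusters.
#' @param separation Distance between cluster centers in the latent space.
#'   With the default `latent_sd` of 0.5 a separation of 4 places centers 8
#'   within-cluster standard deviations apart, so planted clusters are
#'   recoverable essentially without error.
#' @param latent_sd Within-cluster standard deviation of the sample factors
#'   around their cluster center.
#' @param noise_scale Standard deviation of the additive noise in gaussian
#'   blocks.
#' @param theta_scale Standard deviation of the feature loadings.
#' @param missing_rate Fraction of entries masked as missing, uniformly at
#'   random.
#' @param seed Integer RNG seed; stored so a dataset can be reproduced
#'   exactly.
#' @return A list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_samples = 90,
                            block_specs = list(
                              methylation = c(200, "gaussian"),
                              mutation = c(100, "binary"),
                              expression = c(150, "poisson")),
                            true_rank = 2, n_clusters = 3, separation = 4,
                            latent_sd = 0.5, noise_scale = 1, theta_scale = 1,
                            missing_rate = 0, seed = 1) {
  stopifnot(n_samples >= 2, true_rank >= 1, n_clusters >= 1, separation >= 0,
            latent_sd > 0, noise_scale >= 0, theta_scale > 0,
            missing_rate >= 0, missing_rate < 1)
  if (is.null(names(block_specs)))
    names(block_specs) <- paste0("block", seq_along(block_specs))
  for (bs in block_specs) {
    if (length(bs) != 2 || is.na(as.numeric(bs[1])) ||
        !bs[2] %in% c("gaussian", "binary", "poisson"))
      stop("each block spec must be c(n_features, type)")
  }
  structure(list(n_samples = n_samples, block_specs = block_specs,
                 true_rank = true_rank, n_clusters = n_clusters,
                 separation = separation, latent_sd = latent_sd,
                 noise_scale = noise_scale,
                 theta_scale = theta_scale, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Plant a low-rank parameter matrix with clustered sample factors
#'
#' Draws cluster centers separated by `spec$separation` in the r-dimensional
#' latent space (vertices of a regular simplex under a random rotation when
#' they fit in r dimensions, rescaled random centers otherwise), sample
#' factors as center plus `latent_sd` gaussian noise, and per-block feature
#' loadings as scaled gaussians. The planted parameter matrix is loadings
#' times factors transposed, hence of rank at most r exactly. Binary block
#' rows are rescaled so that 99% of entries give success probabilities within
#' \[0.05, 0.95\]; Poisson block rows are rescaled so that every rate lies in
#' \[1/3, 3\], which keeps the Poisson curvature inside the stable region of
#' the fixed-step solver (see the package vignette).
#'
#' @param spec A [simulation_spec()].
#' @return A list with `theta` (stacked parameter matrix), `labels` (true
#'   cluster per sample), `factors` (n x r latent factors), `centers`,
#'   `block_rows` (row indices per block) and `spec`.
#' @export
make_low_rank_theta <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, make_theta_core(spec))
}

make_theta_core <- function(spec) {
  n <- spec$n_samples
  r <- spec$true_rank
  k <- spec$n_clusters
  centers <- cluster_centers(k, r, spec$separation)
  labels <- rep(seq_len(k), length.out = n)
  factors <- centers[labels, , drop = FALSE] +
    matrix(stats::rnorm(n * r, sd = spec$latent_sd), n, r)

  theta_list <- list()
  block_rows <- list()
  row0 <- 0L
  for (bn in names(spec$block_specs)) {
    bs <- spec$block_specs[[bn]]
    p <- as.integer(bs[1]); type <- bs[2]
    load <- matrix(stats::rnorm(p * r, sd = spec$theta_scale), p, r)
    th <- load %*% t(factors)
    if (type != "gaussian") {
      # binary: 99% of |theta| within logit(0.95), so sigma(theta) mostly in
      # [.05, .95]; poisson: hard cap max|theta| at ln 3 so every rate is in
      # [1/3, 3] and the delta = 0.5 gradient iteration stays contractive
      cap <- if (type == "binary") stats::qlogis(0.95) else log(3)
      ref <- if (type == "binary")
        stats::quantile(abs(th), 0.99, names = FALSE) else max(abs(th))
      if (ref <= 0) stop("infeasible scaling for block '", bn,
                         "': planted parameters are all zero")
      th <- th * (cap / ref)
    }
    rownames(th) <- paste0(bn, "_f", seq_len(p))
    theta_list[[bn]] <- th
    block_rows[[bn]] <- (row0 + 1L):(row0 + p)
    row0 <- row0 + p
  }
  theta <- do.call(rbind, theta_list)
  colnames(theta) <- paste0("s", seq_len(n))
  list(theta = theta, labels = labels, factors = factors, centers = centers,
       block_rows = block_rows, spec = spec)
}

# k cluster centers in r dimensions with pairwise distance = separation when a
# regular simplex fits (k - 1 <= r); otherwise random directions rescaled so
# the minimum pairwise distance equals the separation.
cluster_centers <- function(k, r, separation) {
  if (k == 1 || separation == 0) return(matrix(0, k, r))
  if (k - 1 <= r) {
    # regular simplex with unit pairwise distances: rows of I_k / sqrt(2),
    # centered, then expressed in their (k-1)-dimensional span
    v <- scale(diag(k) / sqrt(2), center = TRUE, scale = FALSE)
    v <- (v %*% svd(v)$v)[, seq_len(k - 1), drop = FALSE]
    cent <- matrix(0, k, r)
    cent[, seq_len(k - 1)] <- v
    rot <- qr.Q(qr(matrix(stats::rnorm(r * r), r, r)))
    cent <- cent %*% rot
  } else {
    cent <- matrix(stats::rnorm(k * r), k, r)
    dmin <- min(stats::dist(cent))
    if (dmin <= 0) stop("degenerate random centers; change the seed")
    cent <- cent / dmin
  }
  cent * separation
}

#' Observe a planted parameter matrix through the per-type noise models
#'
#' Gaussian rows give \eqn{X = \Theta +} `noise_scale` \eqn{\cdot N(0,1)};
#' binary rows draw Bernoulli with success probability
#' \eqn{\sigma(\Theta)}; Poisson rows draw counts with rate \eqn{e^\Theta}.
#' An optional missingness rate masks entries uniformly at random.
#'
#' @param planted Output of [make_low_rank_theta()].
#' @param spec The same [simulation_spec()]; a derived seed keeps the draws
#'   reproducible yet distinct from the parameter draws.
#' @return A named list of [omics_block()] objects.
#' @export
sample_observations <- function(planted, spec = planted$spec) {
  withr::with_seed((spec$seed + 104729L) %% .Machine$integer.max,
                   sample_observations_core(planted, spec))
}

sample_observations_core <- function(planted, spec) {
  blocks <- list()
  for (bn in names(spec$block_specs)) {
    type <- spec$block_specs[[bn]][2]
    th <- planted$theta[planted$block_rows[[bn]], , drop = FALSE]
    p <- nrow(th); n <- ncol(th)
    x <- switch(type,
      gaussian = th + matrix(stats::rnorm(p * n, sd = spec$noise_scale), p, n),
      binary   = matrix(stats::rbinom(p * n, 1, stats::plogis(th)), p, n),
      poisson  = matrix(stats::rpois(p * n, exp(th)), p, n))
    dimnames(x) <- dimnames(th)
    mask <- NULL
    if (spec$missing_rate > 0) {
      mask <- matrix(stats::runif(p * n) >= spec$missing_rate, p, n)
      dimnames(mask) <- dimnames(th)
    }
    blocks[[bn]] <- omics_block(x, type, name = bn, mask = mask)
  }
  blocks
}

#' Generate a complete synthetic multi-omics dataset
#'
#' Convenience wrapper: plants the low-rank parameter matrix and samples the
#' observed blocks under one seed.
#'
#' @param spec A [simulation_spec()].
#' @return A list with `blocks`, `theta`, `labels`, `factors`, `block_rows`
#'   and `spec`.
#' @examples
#' sim <- simulate_multiomics(simulation_spec(seed = 7))
#' sapply(sim$blocks, dim)
#' table(sim$labels)
#' @export
simulate_multiomics <- function(spec = simulation_spec()) {
  planted <- make_low_rank_theta(spec)
  blocks <- sample_observations(planted, spec)
  c(list(blocks = blocks), planted)
}

#' Family of datasets with growing feature counts and fixed structure
#'
#' Builds datasets whose gaussian/binary/poisson feature counts scale with
#' `sizes` (in the proportion 1 : 0.5 : 0.75 of the leading size) while the
#' latent factors, cluster labels and seed stay fixed, for scaling and
#' stability checks.
#'
#' @param sizes Positive integer vector of gaussian-block feature counts.
#' @param seed Integer seed shared by every member.
#' @param ... Further arguments forwarded to [simulation_spec()].
#' @return A named list of [simulate_multiomics()] results, one per size.
#' @export
make_benchmark_suite <- function(sizes, seed = 1, ...) {
  stopifnot(all(sizes >= 4))
  out <- lapply(sizes, function(s) {
    spec <- simulation_spec(
      block_specs = list(methylation = c(s, "gaussian"),
                         mutation = c(max(2, round(s / 2)), "binary"),
                         expression = c(max(2, round(0.75 * s)), "poisson")),
      seed = seed, ...)
    simulate_multiomics(spec)
  })
  names(out) <- paste0("p", sizes)
  out
}
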