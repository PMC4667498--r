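#' Reduce samples to their low-dimensional coordinates
#'
#' Decomposes the fitted parameter matrix \eqn{\Theta = U \Sigma V^T} and
#' returns the r leading components of \eqn{\Sigma V^T}: an r-vector of
#' coordinates per sample on the top singular directions, the low-dimensional
#' representation in which samples are clustered. Each coordinate row's
#' largest-magnitude entry is made non-negative so that the (arbitrary) SVD
#' signs are reproducible.
#'
#' @param fit An [lra_fit()] object, or a plain numeric matrix \eqn{\Theta}.
#' @param rank Number of components to return; defaults to the fit's rank.
#' @return An object of class `"lra_reduction"`: a list with `coords`
#'   (rank x n_samples matrix, rows ordered by descending singular value),
#'   `sample_ids`, `rank` and `singular_values`. If the matrix has fewer
#'   non-zero singular values than `rank`, trailing coordinate rows are zero
#'   and a warning is raised.
#' @export
reduce_dims <- function(fit, rank = NULL) {
  theta <- if (inherits(fit, "lra_fit")) fit$theta else as.matrix(fit)
  if (is.null(rank))
    rank <- if (inherits(fit, "lra_fit")) fit$rank else min(dim(theta))
  n <- ncol(theta)
  sv <- svd(theta, nu = 0, nv = rank)
  d <- sv$d[seq_len(rank)]
  nonzero <- d > max(sv$d[1], .Machine$double.eps) * 1e-12
  if (!all(nonzero)) {
    warning("only ", sum(nonzero), " non-zero singular values for rank ",
            rank, "; trailing coordinate rows are zero", call. = FALSE)
    d[!nonzero] <- 0
  }
  coords <- d * t(sv$v) # (Sigma V^T), r x n
  for (i in seq_len(nrow(coords))) {
    j <- which.max(abs(coords[i, ]))
    if (length(j) && coords[i, j] < 0) coords[i, ] <- -coords[i, ]
  }
  sids <- colnames(theta)
  if (is.null(sids)) sids <- paste0("s", seq_len(n))
  dimnames(coords) <- list(paste0("dim", seq_len(rank)), sids)
  structure(list(coords = coords, sample_ids = sids, rank = rank,
                 singular_values = d),
            class = "lra_reduction")
}

#' @export
print.lra_reduction <- function(x, ...) {
  cat(sprintf("reduced representation: %d samples in %d dimensions\n",
              ncol(x$coords), x$rank))
  invisible(x)
}

#' Cluster samples in the reduced subspace with k-means
#'
#' Runs Lloyd's k-means with k-means++ seeding, keeping the best of
#' `restarts` random initializations (lowest total within-cluster sum of
#' squares), and scores the partition with the mean silhouette value.
#' Deterministic for a given seed.
#'
#' @param rep An [reduce_dims()] result, or a coordinates matrix with samples
#'   in columns.
#' @param k Number of clusters, `2 <= k <= n_samples`.
#' @param restarts Number of k-means++ initializations.
#' @param seed Integer RNG seed, recorded in the result.
#' @return An object of class `"lra_clusters"`: `labels` (named integer
#'   vector in 1..k), `k`, `centers`, `silhouette` (mean),
#'   `per_sample_silhouette`, `seed`, `restarts`.
#' @export
cluster_samples <- function(rep, k, restarts = 20, seed = 1) {
  coords <- if (inherits(rep, "lra_reduction")) rep$coords else as.matrix(rep)
  n <- ncol(coords)
  if (k < 2) stop("k must be at least 2")
  if (k > n) stop("k = ", k, " exceeds the number of samples (", n, ")")
  x <- t(coords) # samples in rows for stats::kmeans

  if (all(x == matrix(x[1, ], nrow(x), ncol(x), byrow = TRUE))) {
    warning("all samples coincide in the reduced space; ",
            "arbitrary partition returned with silhouette 0", call. = FALSE)
    labels <- rep(seq_len(k), length.out = n)
    names(labels) <- rownames(x)
    return(structure(list(labels = labels, k = k,
                          centers = x[seq_len(k), , drop = FALSE],
                          silhouette = 0,
                          per_sample_silhouette = rep(0, n),
                          seed = seed, restarts = restarts),
                     class = "lra_clusters"))
  }

  best <- withr::with_seed(seed, {
    best <- NULL
    attempts <- 0L
    tries <- 0L
    while (attempts < restarts && tries < 10L * restarts) {
      tries <- tries + 1L
      centers <- kmeanspp_centers(x, k)
      km <- tryCatch(
        stats::kmeans(x, centers = centers, iter.max = 100,
                      algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) {
          suppressWarnings(stats::kmeans(x, centers = centers, iter.max = 500,
                                         algorithm = "Lloyd"))
        })
      if (is.null(km) || any(km$size == 0)) next # re-initialize degenerate runs
      attempts <- attempts + 1L
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  if (is.null(best)) stop("k-means failed on every restart")

  labels <- as.integer(best$cluster)
  names(labels) <- rownames(x)
  sil <- silhouette_samples(coords, labels)
  structure(list(labels = labels, k = k, centers = best$centers,
                 silhouette = mean(sil), per_sample_silhouette = sil,
                 seed = seed, restarts = restarts),
            class = "lra_clusters")
}

#' @export
print.lra_clusters <- function(x, ...) {
  cat(sprintf("k-means clustering: k = %d, mean silhouette %.3f\n",
              x$k, x$silhouette))
  print(table(cluster = x$labels))
  invisible(x)
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[idx[1], ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    if (all(d2 == 0)) {
      idx[j + 1] <- sample.int(n, 1)
    } else {
      idx[j + 1] <- sample.int(n, 1, prob = d2)
    }
    dj <- rowSums((x - matrix(x[idx[j + 1], ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, dj)
  }
  x[idx, , drop = FALSE] + matrix(stats::runif(k * ncol(x), -1e-9, 1e-9),
                                  k, ncol(x)) # break exact duplicates
}

#' Mean silhouette value of a partition
#'
#' For each sample, the silhouette is \eqn{(b - a) / \max(a, b)} with a the
#' mean distance to its own cluster's other members and b the smallest mean
#' distance to another cluster; samples in singleton clusters score 0
#' (Rousseeuw's convention). Euclidean distance in the reduced space.
#' A larger mean silhouette indicates a better-separated clustering and is
#' the criterion used to choose the number of clusters.
#'
#' @param coords Coordinates matrix, samples in columns (or an
#'   [reduce_dims()] result).
#' @param labels Integer cluster assignment per sample, at least two distinct
#'   non-empty clusters.
#' @return Mean silhouette value in \[-1, 1\]. Degenerate geometry (all
#'   pairwise distances zero) is defined as 0 with a warning.
#' @export
silhouette_value <- function(coords, labels) {
  if (inherits(coords, "lra_reduction")) coords <- coords$coords
  mean(silhouette_samples(coords, labels))
}

silhouette_samples <- function(coords, labels) {
  labels <- as.integer(labels)
  if (length(labels) != ncol(coords))
    stop("labels length must equal the number of samples")
  if (length(unique(labels)) < 2)
    stop("silhouette requires at least two clusters")
  if (length(unique(labels)) == length(labels))
    return(rep(0, length(labels))) # every cluster a singleton: 0 by convention
  d <- stats::dist(t(coords))
  if (max(d) == 0) {
    warning("all samples coincide; silhouette defined as 0", call. = FALSE)
    return(rep(0, length(labels)))
  }
  sil <- cluster::silhouette(labels, d)
  widths <- sil[, "sil_width"]
  widths[is.na(widths)] <- 0
  widths
}

#' Silhouette curve over candidate cluster numbers
#'
#' Clusters the reduced representation at each candidate k and reports the
#' mean silhouette value; the recommended number of clusters is the k with
#' the largest value.
#'
#' @inheritParams cluster_samples
#' @param ks Integer vector of candidate cluster numbers, all at least 2.
#' @return A data.frame with columns `k` and `silhouette`, with attribute
#'   `"best_k"` (the argmax) and `"clusterings"` (the underlying
#'   [cluster_samples()] results, named by k).
#' @export
scan_clusters <- function(rep, ks = 2:6, restarts = 20, seed = 1) {
  if (any(ks < 2)) stop("all candidate cluster numbers must be at least 2")
  fits <- lapply(ks, function(k) cluster_samples(rep, k, restarts = restarts,
                                                 seed = seed))
  out <- data.frame(k = ks,
                    silhouette = vapply(fits, `[[`, numeric(1), "silhouette"))
  names(fits) <- ks
  attr(out, "best_k") <- ks[which.max(out$silhouette)]
  attr(out, "clusterings") <- fits
  out
}

#' Differential-feature signature of one cluster
#'
#' Ranks features of the input blocks by the strength of their difference
#' between the samples of one cluster and all remaining samples: a Wilcoxon
#' rank-sum test for gaussian and poisson features and a two-proportion
#' chi-squared test for binary features, with Benjamini-Hochberg adjustment
#' across all features of all blocks. This is a post-hoc description of the
#' clusters, not part of the model fit.
#'
#' @param blocks Blocks as supplied to [lra_fit()].
#' @param labels Cluster assignment per sample (as from [cluster_samples()]).
#' @param cluster The cluster id to contrast against the rest.
#' @return A data.frame sorted by adjusted p-value with columns `feature`,
#'   `block`, `type`, `statistic`, `effect` (difference of means / log odds
#'   ratio direction), `p_value`, `p_adjusted`, `constant` (flag for
#'   all-constant features, which get p = 1).
#' @export
signature_features <- function(blocks, labels, cluster) {
  blocks <- check_blocks(blocks)
  labels <- as.integer(labels)
  in_cl <- labels == cluster
  if (!any(in_cl) || all(in_cl))
    stop("cluster ", cluster, " or its complement is empty")

  rows <- list()
  for (b in blocks) {
    for (i in seq_len(nrow(b$data))) {
      o <- b$mask[i, ]
      x1 <- b$data[i, o & in_cl]
      x0 <- b$data[i, o & !in_cl]
      if (!length(x1) || !length(x0)) next
      constant <- length(unique(c(x1, x0))) < 2
      if (constant) {
        stat <- 0; p <- 1; eff <- 0
      } else if (b$type == "binary") {
        tab <- rbind(c(sum(x1), length(x1) - sum(x1)),
                     c(sum(x0), length(x0) - sum(x0)))
        ht <- suppressWarnings(stats::prop.test(tab))
        stat <- unname(ht$statistic); p <- ht$p.value
        eff <- log(((sum(x1) + 0.5) / (length(x1) - sum(x1) + 0.5)) /
                     ((sum(x0) + 0.5) / (length(x0) - sum(x0) + 0.5)))
      } else {
        ht <- suppressWarnings(stats::wilcox.test(x1, x0))
        stat <- unname(ht$statistic); p <- ht$p.value
        eff <- mean(x1) - mean(x0)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        feature = b$feature_ids[i], block = b$name, type = b$type,
        statistic = stat, effect = eff, p_value = p, constant = constant)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_adjusted, out$p_value), ]
  rownames(out) <- NULL
  out[, c("feature", "block", "type", "statistic", "effect",
          "p_value", "p_adjusted", "constant")]
}

#' Principal angles between two subspaces
#'
#' Canonical angles between the column spaces of two matrices, in radians;
#' all zero iff the subspaces coincide. Used to verify that the reduced
#' subspace of a gaussian-only fit matches the principal-component subspace.
#'
#' @param a,b Matrices whose columns span the subspaces (need not be
#'   orthonormal).
#' @return Numeric vector of angles in \[0, pi/2\], ascending.
#' @export
principal_angles <- function(a, b) {
  qa <- qr.Q(qr(as.matrix(a)))
  qb <- qr.Q(qr(as.matrix(b)))
  s <- svd(crossprod(qa, qb), nu = 0, nv = 0)$d
  acos(pmin(pmax(s, -1), 1))
}
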