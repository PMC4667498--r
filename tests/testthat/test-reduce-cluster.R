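test_that("reduction recovers the analytic SVD of a rank-1 outer product", {
  u <- c(1, 0, 0)
  v <- c(1, 1) / sqrt(2)
  theta <- 2 * tcrossprod(u, v)
  red <- reduce_dims(theta, rank = 1)
  expect_equal(unname(red$coords[1, ]), c(sqrt(2), sqrt(2)),
               tolerance = 1e-12)
  expect_equal(red$singular_values[1], 2, tolerance = 1e-12)
})

test_that("a zero parameter matrix reduces to zero coordinates, with warning", {
  expect_warning(red <- reduce_dims(matrix(0, 4, 3), rank = 2),
                 "non-zero singular values")
  expect_identical(unname(red$coords), matrix(0, 2, 3))
})

test_that("gaussian-only coordinates correlate with PCA scores", {
  set.seed(23)
  X <- matrix(rnorm(60 * 40), 60, 40) +
    tcrossprod(matrix(rnorm(60 * 2, sd = 4), 60, 2),
               matrix(rnorm(40 * 2), 40, 2))
  X <- t(scale(t(X), center = TRUE, scale = FALSE))
  fit <- lra_fit(omics_block(X, "gaussian"), rank = 2, tol = 1e-10,
                 max_iter = 500)
  red <- reduce_dims(fit)
  sv <- svd(X)
  scores <- sv$d[1:2] * t(sv$v[, 1:2]) # classical PCA scores, r x n
  for (i in 1:2)
    expect_gt(abs(cor(red$coords[i, ], scores[i, ])), 0.999)
})

test_that("k-means recovers two well-separated blobs exactly", {
  set.seed(5)
  truth <- rep(1:2, each = 50)
  coords <- rbind(rnorm(100, mean = c(-5, 5)[truth]),
                  rnorm(100))
  cl <- cluster_samples(coords, k = 2, seed = 9)
  expect_identical(ari(cl$labels, truth), 1)
  expect_gt(cl$silhouette, 0.5)
  # determinism: same seed, same input, identical labels
  cl2 <- cluster_samples(coords, k = 2, seed = 9)
  expect_identical(cl$labels, cl2$labels)
  expect_error(cluster_samples(coords, k = 101), "exceeds")
  expect_error(cluster_samples(coords, k = 1), "at least 2")
})

test_that("coincident samples cluster degenerately with silhouette zero", {
  coords <- matrix(1, 2, 10)
  expect_warning(cl <- cluster_samples(coords, k = 2), "coincide")
  expect_identical(cl$silhouette, 0)
  expect_identical(sort(unique(cl$labels)), 1:2)
})

test_that("silhouette agrees with the brute-force oracle", {
  for (seed in 1:12) {
    n <- withr::with_seed(seed, sample(10:50, 1))
    k <- withr::with_seed(seed + 1, sample(2:5, 1))
    coords <- withr::with_seed(seed + 2, matrix(rnorm(3 * n), 3, n))
    labels <- withr::with_seed(seed + 3,
                               c(seq_len(k), sample(k, n - k, replace = TRUE)))
    expect_equal(silhouette_value(coords, labels),
                 brute_silhouette(coords, labels), tolerance = 1e-10,
                 label = paste("silhouette seed", seed))
  }
})

test_that("silhouette reflects separation, noise and singleton conventions", {
  # two tight pairs around centers +-100: near-perfect separation
  coords <- matrix(c(-100.1, -99.9, 99.9, 100.1), 1, 4)
  expect_gt(silhouette_value(coords, c(1, 1, 2, 2)), 0.99)

  # random labels on one isotropic blob: no structure
  coords2 <- withr::with_seed(31, matrix(rnorm(2 * 200), 2, 200))
  labels2 <- withr::with_seed(32, sample(1:2, 200, replace = TRUE))
  expect_lt(abs(silhouette_value(coords2, labels2)), 0.1)

  # two singleton clusters score 0 by convention
  expect_identical(silhouette_value(matrix(c(0, 1), 1, 2), c(1, 2)), 0)

  expect_error(silhouette_value(matrix(rnorm(10), 2, 5), rep(1, 5)),
               "two clusters")
})

test_that("the silhouette scan selects the planted number of clusters", {
  set.seed(77)
  truth <- rep(1:3, each = 25)
  centers <- rbind(c(0, 0), c(8, 0), c(4, 7))
  coords <- t(centers[truth, ] + matrix(rnorm(150), 75, 2))
  sc <- scan_clusters(coords, ks = 2:6, seed = 3)
  expect_identical(attr(sc, "best_k"), 3L)
  s <- setNames(sc$silhouette, sc$k)
  expect_gt(s["3"], s["2"])
  expect_gt(s["3"], s["4"])

  one <- scan_clusters(coords, ks = 2, seed = 3)
  expect_identical(nrow(one), 1L)
})

test_that("signature tests rank planted differential features first", {
  set.seed(41)
  n <- 100
  labels <- rep(1:2, each = n / 2)
  g <- matrix(rnorm(20 * n), 20, n,
              dimnames = list(paste0("g", 1:20), paste0("s", 1:n)))
  g["g1", labels == 1] <- g["g1", labels == 1] + 5 # planted shift
  bg <- omics_block(g, "gaussian", name = "expr")

  bin <- matrix(0L, 3, n, dimnames = list(paste0("m", 1:3), paste0("s", 1:n)))
  bin["m1", labels == 1] <- 1L # mutation exclusive to cluster 1
  bin["m2", ] <- withr::with_seed(42, rbinom(n, 1, 0.3))
  bb <- omics_block(bin, "binary", name = "mut")

  tab <- signature_features(list(bg, bb), labels, cluster = 1)
  top2 <- tab$feature[1:2]
  expect_setequal(top2, c("g1", "m1"))
  expect_lt(tab$p_adjusted[tab$feature == "g1"], 1e-6)
  expect_gt(tab$effect[tab$feature == "g1"], 0)
  expect_gt(tab$effect[tab$feature == "m1"], 0) # positive log odds

  # features identical in distribution across groups are not significant
  null_p <- tab$p_adjusted[tab$feature %in% paste0("g", 2:20)]
  expect_true(all(null_p > 0.05))
  expect_gt(median(null_p), 0.5)

  # all-constant features are flagged with p = 1
  expect_true(tab$constant[tab$feature == "m3"])
  expect_identical(tab$p_value[tab$feature == "m3"], 1)

  expect_error(signature_features(list(bg), labels, cluster = 9), "empty")
})

test_that("signature statistics are invariant to cluster relabeling", {
  set.seed(51)
  labels <- rep(1:3, each = 20)
  x <- matrix(rnorm(10 * 60), 10, 60)
  x[1, labels == 2] <- x[1, labels == 2] + 3
  b <- omics_block(x, "gaussian")
  t1 <- signature_features(list(b), labels, cluster = 2)
  perm <- c(3, 1, 2)[labels] # cluster 2 becomes cluster 1
  t2 <- signature_features(list(b), perm, cluster = 1)
  expect_equal(t1$p_value, t2$p_value, tolerance = 1e-12)
  expect_equal(t1$statistic, t2$statistic, tolerance = 1e-12)
  expect_identical(t1$feature, t2$feature)
})
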