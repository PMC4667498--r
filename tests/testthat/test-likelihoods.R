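types <- c("gaussian", "binary", "poisson")

test_that("minus log-likelihood matches hand-computed values", {
  # gaussian: zero loss at theta = data
  x <- matrix(rnorm(6), 2, 3)
  b <- omics_block(x, "gaussian")
  expect_identical(block_nll(b, x), 0)

  # binary 1x1, X = 1, theta = 0: -ln(1/2)
  b1 <- omics_block(matrix(1, 1, 1), "binary")
  expect_equal(block_nll(b1, matrix(0, 1, 1)), log(2), tolerance = 1e-12)

  # poisson 1x1, X = 2, theta = 0: -(0 - e^0) = 1
  b2 <- omics_block(matrix(2, 1, 1), "poisson")
  expect_equal(block_nll(b2, matrix(0, 1, 1)), 1, tolerance = 1e-12)
})

test_that("nll rejects malformed inputs", {
  b <- omics_block(matrix(0, 2, 2), "gaussian")
  expect_error(block_nll(b, matrix(0, 2, 3)), "shape")
  expect_error(block_nll(b, matrix(c(0, 0, 0, NaN), 2, 2)), "non-finite")
  expect_error(block_nll_grad(b, matrix(Inf, 2, 2)), "non-finite")
})

test_that("analytic gradients match hand values and finite differences", {
  b1 <- omics_block(matrix(1, 1, 1), "binary")
  expect_equal(block_nll_grad(b1, matrix(0, 1, 1))[1, 1], -0.5,
               tolerance = 1e-12)
  b2 <- omics_block(matrix(0, 1, 1), "poisson")
  expect_equal(block_nll_grad(b2, matrix(0, 1, 1))[1, 1], 1, tolerance = 1e-12)
  bg <- omics_block(matrix(1:4, 2, 2), "gaussian")
  expect_identical(unname(block_nll_grad(bg, matrix(1:4, 2, 2))),
                   matrix(0, 2, 2))

  for (type in types) {
    for (seed in 1:6) {
      b <- random_block(type, seed = seed, missing = if (seed > 3) 0.3 else 0)
      th <- random_theta(seed = seed + 100)
      g <- block_nll_grad(b, th)
      fd <- fd_gradient(b, th)
      expect_equal(g, fd, tolerance = 1e-5, ignore_attr = TRUE,
                   label = paste("gradient", type, "seed", seed))
      expect_true(all(g[!b$mask] == 0))
    }
  }
})

test_that("saturated and null anchors take their closed-form values", {
  expect_identical(saturated_loglik(omics_block(matrix(rnorm(4), 2, 2),
                                                "gaussian")), 0)
  expect_identical(saturated_loglik(random_block("binary")), 0)
  expect_equal(saturated_loglik(omics_block(matrix(2, 1, 1), "poisson")),
               2 * log(2) - 2, tolerance = 1e-12)
  # X = 0 entries contribute 0 to the poisson saturated anchor
  expect_identical(saturated_loglik(omics_block(matrix(0, 2, 2), "poisson")), 0)

  expect_equal(null_loglik(omics_block(matrix(c(1, 2), 1, 2), "gaussian")),
               -2.5, tolerance = 1e-12)
  expect_equal(null_loglik(omics_block(matrix(c(0, 1, 1, 0), 2, 2), "binary")),
               -4 * log(2), tolerance = 1e-12)
  expect_equal(null_loglik(omics_block(matrix(1, 3, 2), "poisson")), -6,
               tolerance = 1e-12)
})

test_that("anchors bound the likelihood and agree with the nll at zero", {
  for (type in types) {
    for (seed in 1:4) {
      b <- random_block(type, seed = seed)
      zero <- matrix(0, 4, 5)
      expect_equal(-block_nll(b, zero), null_loglik(b), tolerance = 1e-12,
                   label = paste("null anchor", type))
      for (s2 in 1:3) {
        th <- random_theta(seed = 10 * seed + s2)
        expect_lte(-block_nll(b, th), saturated_loglik(b) + 1e-9)
      }
    }
  }
})

test_that("the minus log-likelihood is convex in theta", {
  for (type in types) {
    b <- random_block(type, seed = 3)
    for (seed in 1:10) {
      th1 <- random_theta(seed = seed)
      th2 <- random_theta(seed = seed + 50)
      t <- withr::with_seed(seed, runif(1))
      lhs <- block_nll(b, t * th1 + (1 - t) * th2)
      rhs <- t * block_nll(b, th1) + (1 - t) * block_nll(b, th2)
      expect_lte(lhs, rhs + 1e-9)
    }
  }
})

test_that("masked entries never influence value or gradient", {
  for (type in types) {
    b <- random_block(type, missing = 0.4, seed = 7)
    th <- random_theta(seed = 8)
    v0 <- block_nll(b, th)
    g0 <- block_nll_grad(b, th)
    # perturb the hidden entries arbitrarily
    x2 <- b$data
    x2[!b$mask] <- switch(type, gaussian = 99, binary = 1, poisson = 7)
    b2 <- omics_block(x2, type, name = b$name, mask = b$mask)
    expect_identical(block_nll(b2, th), v0)
    expect_identical(block_nll_grad(b2, th), g0)
  }
})

test_that("block validation enforces the data-type domains", {
  expect_error(omics_block(matrix(c(0, 1, 2, 1), 2, 2), "binary"),
               "outside \\{0, 1\\}")
  expect_error(omics_block(matrix(c(1, -1), 1, 2), "poisson"),
               "non-negative integers")
  expect_error(omics_block(matrix(c(1, 1.5), 1, 2), "poisson"),
               "non-negative integers")
  # NA entries are masked, not errors
  b <- omics_block(matrix(c(1, NA, 0, 1), 2, 2), "binary")
  expect_identical(sum(b$mask), 3L)
})

test_that("dummy coding one-hot-expands categorical features", {
  m <- matrix(c("A", "B", "A"), 1, 3,
              dimnames = list("site1", paste0("s", 1:3)))
  b <- dummy_encode(m, levels = c("A", "B"))
  expect_identical(b$type, "binary")
  expect_identical(unname(b$data), matrix(c(1, 0, 0, 1, 1, 0), 2, 3))
  expect_identical(b$feature_ids, c("site1:A", "site1:B"))

  # single level: one all-ones row
  b1 <- dummy_encode(matrix("A", 1, 3), levels = "A")
  expect_identical(unname(b1$data), matrix(1, 1, 3))

  # a masked input entry masks every derived row at that sample
  m2 <- matrix(c("A", NA, "B"), 1, 3)
  b2 <- dummy_encode(m2, levels = c("A", "B"))
  expect_identical(unname(b2$mask[, 2]), c(FALSE, FALSE))
  expect_identical(unname(b2$mask[, c(1, 3)]), matrix(TRUE, 2, 2))

  expect_error(dummy_encode(matrix("C", 1, 1), levels = c("A", "B")),
               "not among the declared levels")
})
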