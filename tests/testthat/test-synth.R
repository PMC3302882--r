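test_that("block correlation matrices have the stated exact structure", {
  expect_equal(block_correlation(5, rho = 0), diag(5), ignore_attr = TRUE)

  C <- block_correlation(c(3, 3), rho = 0.5)
  expected <- rbind(
    cbind(matrix(0.5, 3, 3), matrix(0, 3, 3)),
    cbind(matrix(0, 3, 3), matrix(0.5, 3, 3))
  )
  diag(expected) <- 1
  expect_equal(C, expected, ignore_attr = TRUE)

  nested <- block_correlation(list(c(4, 4), rep(2, 4)), rho = c(0.2, 0.6))
  expect_equal(nested[1, 2], 0.6) # inner block overrides
  expect_equal(nested[1, 3], 0.2)
  expect_equal(nested[1, 5], 0)
  labs <- attr(nested, "labels")
  expect_equal(names(labs), c("level1", "level2"))
  expect_equal(labs$level1, rep(1:2, each = 4))
})

test_that("the nested benchmark layout mirrors the three-level design", {
  C <- block_correlation(
    list(rep(64L, 4), rep(32L, 8), rep(16L, 16)),
    rho = c(0.3, 0.6, 0.9)
  )
  expect_equal(dim(C), c(256, 256))
  expect_equal(C[1, 2], 0.9) # same small block
  expect_equal(C[1, 17], 0.6) # same medium, different small
  expect_equal(C[1, 33], 0.3) # same large, different medium
  expect_equal(C[1, 65], 0) # different large blocks
  labs <- attr(C, "labels")
  expect_equal(vapply(labs, function(z) length(unique(z)), integer(1)),
    c(level1 = 4L, level2 = 8L, level3 = 16L),
    ignore_attr = TRUE
  )
})

test_that("invalid block layouts are rejected", {
  expect_error(block_correlation(list(c(4, 4), c(3, 5)), rho = c(0.2, 0.4)), "refine")
  expect_error(block_correlation(list(c(4, 4), rep(2, 4)), rho = c(0.6, 0.2)), "increase inward")
  expect_error(block_correlation(c(4, 4), rho = 1), "rho")
})

test_that("random correlations land off-block, symmetric, and PSD-repaired", {
  C0 <- block_correlation(c(4, 4), rho = 0.6)
  expect_equal(add_random_correlations(C0, 0, 0.6), C0)
  C <- add_random_correlations(C0, 5, magnitude = 0.6, seed = 3)
  labs <- attr(C, "labels")$level1
  off <- outer(labs, labs, "!=")
  # exactly 5 pairs carry the planted magnitude (PSD repair may leave
  # numerically tiny values elsewhere)
  expect_equal(sum(abs(C[off & upper.tri(C)]) > 0.3), 5)
  expect_lt(max(abs(C[off & upper.tri(C)][abs(C[off & upper.tri(C)]) <= 0.3])), 0.1)
  expect_true(isSymmetric(unclass(C)))
  expect_gte(min(eigen(C, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  expect_error(add_random_correlations(C0, 100, 0.6), "exceeds")
})

test_that("MVG samples reproduce the target correlation", {
  C <- block_correlation(c(4, 4), rho = 0.7)
  x <- mvg_sample(C, 10000, seed = 11)
  expect_equal(dim(x), c(8, 10000))
  S <- cor(t(x))
  labs <- attr(C, "labels")$level1
  intra <- S[outer(labs, labs, "==") & upper.tri(S)]
  inter <- S[outer(labs, labs, "!=") & upper.tri(S)]
  expect_lt(abs(mean(intra) - 0.7), 0.02)
  expect_lt(mean(abs(inter)), 3 / sqrt(10000) * 3)
  # identity target: off-diagonals are pure sampling noise
  z <- mvg_sample(diag(6), 10000, seed = 12)
  expect_lt(mean(abs(cor(t(z))[upper.tri(diag(6))])), 3 / sqrt(10000))
  # determinism
  expect_identical(mvg_sample(C, 50, seed = 4), mvg_sample(C, 50, seed = 4))
})

test_that("log-normal reference correlation recovers the target", {
  C <- block_correlation(c(2, 2), rho = 0.5)
  x <- lognormal_sample(C, 100000, seed = 21)
  S <- cor(t(x))
  expect_lt(abs(S[1, 2] - 0.5), 0.02) # Monte-Carlo check of the inversion
  expect_lt(abs(S[1, 3]), 0.02) # zero target stays zero
  expect_gt(min(x), 0) # log-normal margins are positive
})

test_that("noise families scale and tail out as documented", {
  C <- block_correlation(c(6, 6), rho = 0.5)
  x <- mvg_sample(C, 10000, seed = 31)
  expect_identical(add_noise(x, "normal", a = 0), x)
  expect_identical(add_noise(x, "none", a = 2), x)
  expect_error(add_noise(x, "powerlaw", a = 1, nu = 1.5), "nu > 2")

  y <- add_noise(x, "normal", a = 1, seed = 32)
  resid_var <- apply(y - x, 1, var)
  expect_true(all(abs(resid_var / apply(x, 1, var) - 1) < 0.05))

  # power-law magnitudes: survival function slope ~ -(nu - 1)
  nu <- 3.5
  z <- add_noise(x[1:2, , drop = FALSE], "powerlaw", a = 1, nu = nu, seed = 33)
  eps <- abs(as.vector(z - x[1:2, ]))
  tail <- sort(eps, decreasing = TRUE)[1:1500]
  fitc <- stats::coef(stats::lm(log(seq_along(tail)) ~ log(tail)))
  expect_lt(abs(-fitc[2] - (nu - 1)), 0.35)

  # centred log-normal noise has mean ~0 and the requested variance
  w <- add_noise(x, "lognormal", a = 0.5, seed = 34)
  resid <- (w - x) / (0.5 * apply(x, 1, sd))
  expect_lt(abs(mean(resid)), 0.05)
  expect_lt(abs(var(as.vector(resid)) - 1), 0.1)
})

test_that("rising noise shrinks the correlation gap monotonically", {
  gaps <- vapply(c(0, 0.5, 1, 2), function(a) {
    mean(vapply(1:3, function(s) {
      b <- flat_benchmark(
        seed = 100 + s, sizes = c(10, 10), rho = 0.8,
        n_singletons = 0, t_len = 400,
        noise = "normal", a = a
      )
      correlation_gap(cor(t(b$data)), b$labels$block)
    }, numeric(1)))
  }, numeric(1))
  expect_false(is.unsorted(rev(gaps)))
  expect_lt(gaps[4], gaps[1] / 2)
})

test_that("benchmark replicates are reproducible from their seed", {
  b1 <- nested_benchmark(seed = 9, t_len = 50)
  b2 <- nested_benchmark(seed = 9, t_len = 50)
  expect_identical(b1$data, b2$data)
  b3 <- nested_benchmark(seed = 10, t_len = 50)
  expect_false(identical(b1$data, b3$data))
})
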