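test_that("gaussian kernel matches its closed form and symmetry", {
  expect_identical(gaussian_kernel(c(1, 2), c(1, 2), 3), 1)
  expect_equal(gaussian_kernel(0, 1, 1), exp(-1))
  withr::with_seed(1, {
    for (i in 1:10) {
      x <- rnorm(3); y <- rnorm(3); s <- runif(1, 0.5, 3)
      expect_identical(gaussian_kernel(x, y, s), gaussian_kernel(y, x, s))
    }
  })
  expect_error(gaussian_kernel(1:2, 1:3, 1), "dimension")
  expect_error(gaussian_kernel(0, 1, -1), "positive")
})

test_that("median bandwidth: hand-enumerated cases and degenerate fallback", {
  expect_equal(median_bandwidth(c(0, 1)), 1)
  # pairs of {0,1,3}: squared distances 1, 4, 9 -> median 4 -> sqrt = 2
  expect_equal(median_bandwidth(c(0, 1, 3)), 2)
  expect_equal(median_bandwidth(rep(2.5, 6)), 1)
  expect_error(median_bandwidth(1), "at least 2")
})

test_that("median bandwidth is permutation invariant and scale equivariant", {
  withr::with_seed(42, {
    for (i in 1:10) {
      pts <- rnorm(7)
      expect_equal(median_bandwidth(sample(pts)), median_bandwidth(pts))
      c0 <- runif(1, 0.1, 10)
      expect_equal(median_bandwidth(c0 * pts), c0 * median_bandwidth(pts))
    }
  })
})

test_that("stationary Gram matrices have the kernel structure", {
  g <- gram_stationary(c(0, 1), kernel_spec(bandwidth = "fixed", sigma = 1))
  expect_equal(unclass(g), matrix(c(1, exp(-1), exp(-1), 1), 2),
               ignore_attr = TRUE)
  expect_true(all(gram_stationary(rep(3, 5)) == 1))  # constant series
  withr::with_seed(7, {
    x <- rnorm(10)
    g <- gram_stationary(x)
    expect_equal(unclass(g), t(unclass(g)), ignore_attr = TRUE)
    expect_true(all(diag(g) == 1))
    expect_true(all(g > 0 & g <= 1))
    expect_gte(min(eigen(g, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  })
})

test_that("realization Gram matrices use whole-path distances", {
  b <- rbind(c(0, 0), c(3, 4))  # Euclidean distance 5
  g <- gram_multireal(b, kernel_spec(bandwidth = "fixed", sigma = 5))
  expect_equal(g[1, 2], exp(-1))
  # identical realizations -> off-diagonal 1
  g2 <- gram_multireal(rbind(1:4, 1:4))
  expect_equal(g2[1, 2], 1)
  # relabeling: permuting rows permutes rows/columns of the Gram
  withr::with_seed(8, {
    b <- matrix(rnorm(12), 4)
    perm <- sample(4)
    ga <- gram_multireal(b)
    gb <- gram_multireal(b[perm, ])
    expect_equal(unclass(gb), unclass(ga)[perm, perm], ignore_attr = TRUE)
  })
  expect_error(gram_multireal(matrix(c(1, NA, 2, 3), 2)), "finite")
})

test_that("fixed-bandwidth spec validates sigma", {
  expect_error(kernel_spec(bandwidth = "fixed"), "sigma")
  expect_error(kernel_spec(bandwidth = "fixed", sigma = 0), "sigma")
  expect_equal(kernel_spec(bandwidth = "fixed", sigma = 2)$sigma, 2)
})
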