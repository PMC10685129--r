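test_that("generators are deterministic given a seed", {
  expect_identical(sim_ar_pairwise_coupled(T = 50, lambda = 1, seed = 3),
                   sim_ar_pairwise_coupled(T = 50, lambda = 1, seed = 3))
  expect_identical(sim_xor_gate(n = 10, T = 4, seed = 3),
                   sim_xor_gate(n = 10, T = 4, seed = 3))
  expect_identical(sim_rw_trend(n = 5, T = 6, seed = 3),
                   sim_rw_trend(n = 5, T = 6, seed = 3))
})

test_that("coupling enters only through lambda", {
  # same seed, different lambda: X and Y identical, Z differs
  a <- sim_ar_pairwise_coupled(T = 100, lambda = 0, seed = 9)
  b <- sim_ar_pairwise_coupled(T = 100, lambda = 1, seed = 9)
  expect_identical(a$series$X, b$series$X)
  expect_identical(a$series$Y, b$series$Y)
  expect_false(identical(a$series$Z, b$series$Z))
})

test_that("stationary AR moments match theory", {
  d <- sim_ar_pairwise_coupled(T = 1e5, lambda = 1, seed = 13)
  # AR(1/2) stationary variance = 1 / (1 - 1/4)
  expect_equal(var(d$series$X), 4 / 3, tolerance = 0.05)
  expect_lt(abs(cor(d$series$X, d$series$Y)), 0.05)
  expect_gt(cor(d$series$X, d$series$Z), 0.3)
  # uncoupled system: lag-1 autocorrelation matches a, no cross-correlation
  d3 <- sim_ar_independent(T = 1e5, a = 0.6, seed = 14)
  x <- d3$series$X
  expect_equal(cor(x[-1], x[-length(x)]), 0.6, tolerance = 0.03)
  expect_lt(abs(cor(d3$series$X, d3$series$Z)), 0.02)
})

test_that("sign-interaction coupling hides from pairwise correlation", {
  d <- sim_ar_three_way(T = 1e4, lambda = 2, seed = 15)
  expect_lt(abs(cor(d$series$X, d$series$Z)), 0.05)
  expect_lt(abs(cor(d$series$Y, d$series$Z)), 0.05)
  expect_gt(cor(d$series$X * d$series$Y, d$series$Z), 0.1)
})

test_that("unit-root trend model accumulates the deterministic drift", {
  d <- sim_rw_trend(n = 2000, T = 5, lambda = 0, trend = "linear", seed = 16)
  # E[X_t] = sum of 1..t -> 15 at t = 5
  expect_equal(mean(d$variables$X[, 5]), 15, tolerance = 0.2)
  # coupling shows up across realizations at the final time point
  d1 <- sim_rw_trend(n = 1000, T = 20, lambda = 1, seed = 17)
  expect_gt(cor(d1$variables$X[, 20], d1$variables$Z[, 20]), 0.5)
})

test_that("stationarity screen separates the AR and unit-root systems", {
  stat_series <- sim_ar_independent(T = 2000, a = 0.5, seed = 18)$series$X
  expect_true(dhsicts:::adf_looks_stationary(stat_series))
  rw <- sim_rw_trend(n = 2, T = 500, lambda = 0, trend = "oscillatory",
                     seed = 19)$variables$X[1, ]
  expect_false(dhsicts:::adf_looks_stationary(rw))
})

test_that("parity gate output obeys its construction", {
  x <- sim_xor_gate(n = 50, T = 10, seed = 20)
  vals <- unlist(lapply(x$variables, as.numeric))
  expect_true(all(vals %in% c(0, 1)))
  # forced parity: Z is exactly X xor Y xor W
  xf <- sim_xor_gate(n = 100, T = 10, seed = 21, invert_prob = 0)
  parity <- (xf$variables$X + xf$variables$Y + xf$variables$W) %% 2
  expect_identical(xf$variables$Z, parity)
  # literal inversion rate 1/2: Z matches the parity about half the time,
  # and its marginal is a fair coin
  xl <- sim_xor_gate(n = 300, T = 10, seed = 22)
  parl <- (xl$variables$X + xl$variables$Y + xl$variables$W) %% 2
  expect_equal(mean(xl$variables$Z == parl), 0.5, tolerance = 0.05)
  expect_equal(mean(xl$variables$Z), 0.5, tolerance = 0.05)
})

test_that("lambda = 0 decouples Z in every model family", {
  d <- sim_ar_three_way(T = 200, lambda = 0, seed = 23)
  di <- sim_ar_independent(T = 200, a = 0.5, seed = 23)
  # with lambda 0 the interaction model reduces to the uncoupled system
  # driven by the same innovations for X and Y
  expect_identical(d$series$X, di$series$X)
  dm <- sim_ar_trend_interaction(n = 30, T = 10, lambda = 0, seed = 24)
  dm1 <- sim_ar_trend_interaction(n = 30, T = 10, lambda = 3, seed = 24)
  expect_identical(dm$variables$X, dm1$variables$X)
  expect_false(identical(dm$variables$Z, dm1$variables$Z))
})
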