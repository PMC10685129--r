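test_that("cutoff lag tracks autocorrelation decay of the pooled series", {
  # white noise: lag-1 ACF near 0, below 0.2 immediately
  expect_identical(autocorr_cutoff_lag(white_noise_dataset(2000, seed = 5)), 1L)
  # AR(1) with a = 0.5: theoretical ACF 0.5^l -> first below 0.2 at lag 3
  d <- sim_ar_independent(T = 10000, a = 0.5, seed = 6)
  expect_identical(autocorr_cutoff_lag(d), 3L)
  # threshold above the attainable range -> lag 1
  expect_identical(autocorr_cutoff_lag(d, threshold = 1.1), 1L)
  # constant pooled series is an error
  con <- stationary_dataset(list(a = c(1, 2, 3, 4, 5), b = c(4, 3, 2, 1, 0)))
  expect_error(autocorr_cutoff_lag(con), "constant")
  # when no lag ever qualifies, fall back to floor(T/3) with a warning
  # (threshold below the attainable range forces the fallback path)
  slow <- white_noise_dataset(60, d = 2, seed = 9)
  expect_warning(h <- autocorr_cutoff_lag(slow, threshold = -1.5),
                 "never drops")
  expect_identical(h, 20L)
})

test_that("circular shift rotates by tau modulo the length", {
  x <- c(10, 20, 30, 40)
  expect_identical(circular_shift(x, 0), x)
  expect_identical(circular_shift(x, 4), x)
  expect_identical(circular_shift(x, 1), c(20, 30, 40, 10))
  expect_identical(circular_shift(x, 9), c(20, 30, 40, 10))
})

test_that("relabeled-Gram shifting null equals explicit recomputation", {
  d <- sim_ar_independent(T = 60, a = 0.3, seed = 7)
  grams <- dhsicts:::dataset_grams(d, kernel_spec())
  sig <- vapply(grams, attr, numeric(1), "sigma")
  nl <- shifting_null(d, S = 6, seed = 11)
  for (s in seq_len(6)) {
    shifted <- d$series
    for (j in 2:3)
      shifted[[j]] <- circular_shift(shifted[[j]], nl$plan[s, j - 1])
    g2 <- lapply(1:3, function(j)
      gram_stationary(shifted[[j]], kernel_spec(bandwidth = "fixed",
                                                sigma = sig[j])))
    expect_equal(nl$values[s], dhsic_statistic(g2)$raw, tolerance = 1e-12)
  }
  # all shifts obey the open interval (h, T)
  expect_true(all(nl$plan > nl$h & nl$plan < d$T))
})

test_that("shifting null handles edge cases", {
  d <- white_noise_dataset(30, seed = 2)
  expect_length(shifting_null(d, S = 0, seed = 1)$values, 0L)
  expect_error(shifting_null(d, S = 10, seed = 1, h = 29), "too short")
  # identical seed -> identical plan and values
  a <- shifting_null(d, S = 20, seed = 9)
  b <- shifting_null(d, S = 20, seed = 9)
  expect_identical(a$plan, b$plan)
  expect_identical(a$values, b$values)
})

test_that("white-noise observed statistic sits inside its shifting null", {
  # the observed quantile is ~uniform under joint independence; with S = 99
  # the interior probability is ~0.88 by discreteness, so the finite-sample
  # cutoff sits below the asymptotic 0.9
  hits <- vapply(1:50, function(r) {
    d <- white_noise_dataset(150, seed = 400 + r)
    grams <- dhsicts:::dataset_grams(d, kernel_spec())
    obs <- dhsic_statistic(grams)$raw
    nl <- shifting_null(d, S = 99, seed = 500 + r, grams = grams)
    q <- mean(nl$values < obs)
    q > 0.05 && q < 0.95
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("relabeled-Gram permutation null equals explicit recomputation", {
  d <- iid_multireal(n = 12, T = 4, d = 3, seed = 8)
  grams <- dhsicts:::dataset_grams(d, kernel_spec())
  sig <- vapply(grams, attr, numeric(1), "sigma")
  nl <- permutation_null(d, P = 6, seed = 21)
  for (p in seq_len(6)) {
    perm <- nl$plan[[p]]
    g2 <- lapply(1:3, function(j) {
      block <- if (j == 1L) d$variables[[j]] else
        d$variables[[j]][perm[, j - 1], , drop = FALSE]
      gram_multireal(block, kernel_spec(bandwidth = "fixed", sigma = sig[j]))
    })
    expect_equal(nl$values[p], dhsic_statistic(g2)$raw, tolerance = 1e-12)
  }
})

test_that("two realizations admit at most two distinct null values", {
  d <- iid_multireal(n = 2, T = 3, d = 2, seed = 3)
  nl <- permutation_null(d, P = 30, seed = 4)
  expect_lte(length(unique(round(nl$values, 14))), 2L)
  # the identity permutation reproduces the observed statistic
  obs <- dhsic_statistic(dhsicts:::dataset_grams(d, kernel_spec()))$raw
  expect_true(any(abs(nl$values - obs) < 1e-14))
})

test_that("Monte Carlo p-value uses the add-one tie-conservative rule", {
  expect_equal(mc_pvalue(3, c(1, 2, 3, 4)), 0.6)  # two values >= 3
  expect_equal(mc_pvalue(10, rep(0, 999)), 1 / 1000)
  expect_equal(mc_pvalue(-1, c(0, 1)), 1)
  expect_error(mc_pvalue(1, numeric(0)), "empty")
})
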