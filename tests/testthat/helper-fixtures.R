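# Shared fixture builders: everything is generated in code at test time.

# Random PSD Gram matrix with unit diagonal (Gaussian kernel of random points).
random_gram <- function(m, p = 2) {
  pts <- matrix(rnorm(m * p), m)
  sigma <- median_bandwidth(pts)
  exp(-as.matrix(dist(pts))^2 / sigma^2)
}

random_gram_list <- function(m, d, p = 2) {
  replicate(d, random_gram(m, p), simplify = FALSE)
}

# Small white-noise stationary dataset.
white_noise_dataset <- function(T = 100, d = 3, seed = 1) {
  withr::with_seed(seed,
    stationary_dataset(replicate(d, rnorm(T), simplify = FALSE)))
}

# Small iid multi-realization dataset (independent variables).
iid_multireal <- function(n = 40, T = 3, d = 2, seed = 1) {
  withr::with_seed(seed,
    multireal_dataset(replicate(d, matrix(rnorm(n * T), n), simplify = FALSE)))
}
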