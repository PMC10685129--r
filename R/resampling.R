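#' Autocorrelation cutoff lag for the shifting bootstrap
#'
#' The shifting bootstrap must move each series far enough that local
#' temporal dependence cannot masquerade as cross-series dependence. The
#' minimum shift `h` is the first lag at which the sample autocorrelation of
#' the pooled series `s_t = sum_j x_t^j` drops below `threshold` (0.2 by
#' default). The biased sample ACF (normalized by `T`) of the signed values
#' is used. If no lag up to `floor(T/3)` qualifies, `floor(T/3)` is returned
#' with a warning: the pooled series then decorrelates too slowly for
#' shifting to be trustworthy.
#'
#' @param data a [stationary_dataset()].
#' @param threshold autocorrelation threshold, default 0.2.
#' @return Integer lag `h >= 1`.
#' @examples
#' d <- stationary_dataset(list(rnorm(500), rnorm(500)))
#' autocorr_cutoff_lag(d)  # white noise: almost surely 1
#' @export
autocorr_cutoff_lag <- function(data, threshold = 0.2) {
  stopifnot(inherits(data, "stationary_dataset"))
  t_len <- data$T
  if (t_len < 4L) stop("series too short to estimate the cutoff lag")
  pooled <- Reduce(`+`, data$series)
  if (sd(pooled) == 0)
    stop("pooled series is constant; autocorrelation undefined - inspect the data")
  max_lag <- max(1L, t_len %/% 3L)
  rho <- as.numeric(stats::acf(pooled, lag.max = max_lag, plot = FALSE,
                               demean = TRUE)$acf)[-1L]
  below <- which(rho < threshold)
  if (length(below) == 0L) {
    warning(sprintf(
      "pooled autocorrelation never drops below %g up to lag %d; using h = %d",
      threshold, max_lag, max_lag))
    return(max_lag)
  }
  below[[1L]]
}

#' Circular shift of a series
#'
#' Rotates a series so that output position `t` holds input position
#' `(t + tau) mod T` (0-based). `tau = 0` or any multiple of `T` is the
#' identity.
#'
#' @param x a vector.
#' @param tau non-negative integer shift.
#' @return The rotated vector.
#' @examples
#' circular_shift(c(1, 2, 3, 4), 1)  # 2 3 4 1
#' @export
circular_shift <- function(x, tau) {
  t_len <- length(x)
  tau <- as.integer(tau) %% t_len
  if (tau == 0L) return(x)
  x[c((tau + 1L):t_len, 1L:tau)]
}

#' Shifting-bootstrap null distribution (stationary, single realization)
#'
#' Generates `S` samples of the dHSIC statistic under joint independence by
#' circularly shifting every series except the first by independent random
#' offsets `tau` drawn uniformly from the integers strictly between `h` and
#' `T`. Shifting breaks dependence *across* series while preserving the
#' temporal structure *within* each series, which is what makes the scheme
#' valid for stationary processes. Because a circular shift merely relabels
#' the rows/columns of a variable's Gram matrix, the Gram matrices are
#' computed once from the observed data (bandwidths frozen) and each null
#' statistic costs O(d T^2).
#'
#' @param data a [stationary_dataset()].
#' @param spec a [kernel_spec()].
#' @param S number of null samples.
#' @param seed integer seed for the shift plan.
#' @param h minimum shift lag; default from [autocorr_cutoff_lag()].
#' @param grams optional precomputed Gram list (internal reuse).
#' @return An object of class `"dhsic_null"`: list with `values` (raw null
#'   statistics), `scheme = "shift"`, `h`, `S`, `seed` and `plan` (the
#'   `S x (d-1)` matrix of shifts).
#' @export
shifting_null <- function(data, spec = kernel_spec(), S = 200L, seed = 1L,
                          h = NULL, grams = NULL) {
  stopifnot(inherits(data, "stationary_dataset"))
  if (is.null(h)) h <- autocorr_cutoff_lag(data)
  t_len <- data$T
  if (t_len - 1L < h + 1L)
    stop("series too short for shifting null given h: no integer in (h, T)")
  S <- as.integer(S)
  if (S < 0L) stop("S must be non-negative")
  if (is.null(grams)) grams <- dataset_grams(data, spec)
  taus <- with_seed(seed, {
    matrix(sample(seq.int(h + 1L, t_len - 1L), S * (data$d - 1L),
                  replace = TRUE),
           nrow = S, ncol = data$d - 1L)
  })
  values <- if (S == 0L) numeric(0) else
    shift_null_stats(lapply(grams, unclass), taus)
  structure(list(values = values, scheme = "shift", h = h, S = S,
                 seed = seed, plan = taus),
            class = "dhsic_null")
}

#' Permutation null distribution (multiple realizations)
#'
#' Generates `P` samples of the dHSIC statistic under joint independence by
#' randomly permuting, for every variable except the first, which
#' realization is paired with which. Because realizations are iid, this
#' destroys cross-variable dependence exactly, whether or not the processes
#' are stationary. A permutation relabels rows/columns of the variable's
#' `n x n` Gram matrix, so Gram matrices are computed once (bandwidths
#' frozen) and each null statistic costs O(d n^2).
#'
#' @param data a [multireal_dataset()].
#' @param spec a [kernel_spec()].
#' @param P number of null samples.
#' @param seed integer seed for the permutation plan.
#' @param grams optional precomputed Gram list (internal reuse).
#' @return An object of class `"dhsic_null"`: list with `values`,
#'   `scheme = "permute"`, `P`, `seed` and `plan` (list of `n x (d-1)`
#'   permutation matrices, 1-based).
#' @export
permutation_null <- function(data, spec = kernel_spec(), P = 200L, seed = 1L,
                             grams = NULL) {
  stopifnot(inherits(data, "multireal_dataset"))
  n <- data$n
  if (n < 2L) stop("need at least 2 realizations")
  P <- as.integer(P)
  if (P < 0L) stop("P must be non-negative")
  if (is.null(grams)) grams <- dataset_grams(data, spec)
  plan <- with_seed(seed, {
    lapply(seq_len(P), function(p)
      vapply(seq_len(data$d - 1L), function(j) sample.int(n), integer(n)))
  })
  values <- if (P == 0L) numeric(0) else
    perm_null_stats(lapply(grams, unclass),
                    lapply(plan, function(pm) pm - 1L))
  structure(list(values = values, scheme = "permute", P = P, seed = seed,
                 plan = plan),
            class = "dhsic_null")
}

#' @export
print.dhsic_null <- function(x, ...) {
  cat(sprintf("dHSIC null distribution: %d %s resamples\n",
              length(x$values),
              if (x$scheme == "shift") "circular-shift" else "permutation"))
  invisible(x)
}

#' Monte Carlo p-value
#'
#' Add-one Monte Carlo estimator `p = (1 + #{null >= observed}) / (1 + S)`.
#' Ties count toward the null, and the add-one correction guarantees
#' `p > 0` and exact test validity under the null.
#'
#' @param observed observed (raw) statistic.
#' @param null a `"dhsic_null"` object or numeric vector of null statistics.
#' @return p-value in `(0, 1]`.
#' @examples
#' mc_pvalue(3, c(1, 2, 3, 4))  # (1 + 2) / 5
#' @export
mc_pvalue <- function(observed, null) {
  values <- if (inherits(null, "dhsic_null")) null$values else as.numeric(null)
  if (length(values) == 0L) stop("null distribution is empty")
  (1 + sum(values >= observed)) / (1 + length(values))
}
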