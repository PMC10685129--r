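#' Test joint independence of d time series
#'
#' Tests the null hypothesis that the `d` variables of `data` are jointly
#' independent (their joint distribution factorizes into the product of the
#' univariate marginals) using the dHSIC statistic with a resampling null:
#'
#' * `scheme = "shift"` (stationary, single realization): the statistic is
#'   computed over the `T` time points and the null is generated by the
#'   circular-shifting bootstrap ([shifting_null()]).
#' * `scheme = "permute"` (multiple realizations, stationarity not
#'   required): the statistic is computed over the `n` realizations and the
#'   null is generated by cross-realization permutation
#'   ([permutation_null()]).
#' * `scheme = "auto"` picks by the class of `data`.
#'
#' Bandwidths (median heuristic by default) are computed per variable on the
#' observed data and frozen across all resamples, so every null statistic
#' targets the same functional as the observed one. `H0` is rejected when
#' `alpha > p_value`.
#'
#' @param data a [stationary_dataset()] or [multireal_dataset()].
#' @param scheme `"auto"`, `"shift"` or `"permute"`.
#' @param spec a [kernel_spec()].
#' @param resamples number of null samples (`S` shifts or `P` permutations).
#' @param alpha significance level in (0, 1).
#' @param seed integer seed controlling the resampling plan.
#' @param h minimum shift lag (shift scheme only); default
#'   [autocorr_cutoff_lag()] on the pooled series.
#' @return An object of class `"dhsic_test"`: list with `statistic` (clamped
#'   at 0), `raw`, `terms`, `p_value`, `alpha`, `rejected`, `scheme`,
#'   `resamples`, `seed`, `variables`, `sigmas` (per-variable bandwidths
#'   used), `h` (shift scheme), `m`, `d` and `null` (raw null statistics).
#' @examples
#' d <- sim_ar_pairwise_coupled(T = 150, lambda = 1, seed = 1)
#' dhsic_test(d, resamples = 100, seed = 1)
#' @export
dhsic_test <- function(data, scheme = c("auto", "shift", "permute"),
                       spec = kernel_spec(), resamples = 200L, alpha = 0.05,
                       seed = 1L, h = NULL) {
  scheme <- match.arg(scheme)
  if (!(alpha > 0 && alpha < 1)) stop("`alpha` must be in (0, 1)")
  resamples <- as.integer(resamples)
  if (resamples < 1L) stop("`resamples` must be at least 1")
  if (scheme == "auto")
    scheme <- if (inherits(data, "multireal_dataset")) "permute" else "shift"
  if (scheme == "shift" && !inherits(data, "stationary_dataset"))
    stop("shifting scheme requires a stationary_dataset (single realization)")
  if (scheme == "permute" && !inherits(data, "multireal_dataset"))
    stop("permutation scheme requires a multireal_dataset")

  grams <- dataset_grams(data, spec)
  stat <- dhsic_statistic(grams)
  null <- if (scheme == "shift")
    shifting_null(data, spec, S = resamples, seed = seed, h = h, grams = grams)
  else
    permutation_null(data, spec, P = resamples, seed = seed, grams = grams)
  p <- mc_pvalue(stat$raw, null)
  structure(
    list(statistic = stat$value, raw = stat$raw, terms = stat$terms,
         p_value = p, alpha = alpha, rejected = alpha > p, scheme = scheme,
         resamples = resamples, seed = seed,
         variables = data$variable_names,
         sigmas = vapply(grams, function(g) attr(g, "sigma"), numeric(1)),
         h = if (scheme == "shift") null$h else NULL,
         m = stat$m, d = stat$d, null = null$values),
    class = "dhsic_test"
  )
}

#' @export
print.dhsic_test <- function(x, ...) {
  cat("\n\tdHSIC test of joint independence\n\n")
  cat("variables:", paste(x$variables, collapse = ", "), "\n")
  cat(sprintf("scheme: %s (%d resamples%s), %s\n",
              if (x$scheme == "shift") "circular shifting" else
                "cross-realization permutation",
              x$resamples,
              if (!is.null(x$h)) sprintf(", min shift h = %d", x$h) else "",
              if (x$scheme == "shift")
                sprintf("T = %d time points", x$m)
              else sprintf("n = %d realizations", x$m)))
  cat(sprintf("dHSIC = %.6g, p-value = %.4g\n", x$statistic, x$p_value))
  cat(sprintf("H0 (joint independence) %s at alpha = %g\n",
              if (x$rejected) "REJECTED" else "not rejected", x$alpha))
  invisible(x)
}

#' @export
summary.dhsic_test <- function(object, ...) {
  print(object)
  cat("per-variable kernel bandwidths (sigma):\n")
  print(stats::setNames(round(object$sigmas, 4), object$variables))
  invisible(object)
}
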