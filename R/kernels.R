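#' Kernel specification
#'
#' Chooses the kernel family and bandwidth rule used to build Gram matrices.
#' Only the Gaussian kernel `k(x, y) = exp(-||x - y||^2 / sigma^2)` is
#' implemented; it is characteristic, so the resulting dHSIC is zero if and
#' only if the variables are jointly independent. Note the `sigma^2`
#' denominator convention (no factor 2).
#'
#' With `bandwidth = "median"` the bandwidth is set per variable to the
#' square root of the median squared pairwise distance among the observed
#' samples (the median heuristic), computed once on the observed data and
#' frozen across all resamples.
#'
#' @param family kernel family; only `"gaussian"`.
#' @param bandwidth `"median"` for the median heuristic or `"fixed"`.
#' @param sigma positive bandwidth, required when `bandwidth = "fixed"`.
#' @return An object of class `"kernel_spec"`.
#' @examples
#' kernel_spec()
#' kernel_spec(bandwidth = "fixed", sigma = 2)
#' @export
kernel_spec <- function(family = "gaussian",
                        bandwidth = c("median", "fixed"),
                        sigma = NULL) {
  family <- match.arg(family)
  bandwidth <- match.arg(bandwidth)
  if (bandwidth == "fixed") {
    if (is.null(sigma) || !is.finite(sigma) || sigma <= 0)
      stop("fixed bandwidth requires a positive `sigma`")
  } else {
    sigma <- NULL
  }
  structure(list(family = family, bandwidth = bandwidth, sigma = sigma),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  cat("Gaussian kernel, bandwidth:",
      if (x$bandwidth == "median") "median heuristic" else
        sprintf("fixed (sigma = %g)", x$sigma), "\n")
  invisible(x)
}

#' Gaussian kernel evaluation
#'
#' `exp(-||x - y||^2 / sigma^2)` for two points of equal dimension.
#'
#' @param x,y numeric vectors of equal length.
#' @param sigma positive bandwidth.
#' @return A number in `(0, 1]`.
#' @examples
#' gaussian_kernel(0, 1, 1)  # exp(-1)
#' @export
gaussian_kernel <- function(x, y, sigma) {
  if (length(x) != length(y)) stop("`x` and `y` must have the same dimension")
  if (!is.finite(sigma) || sigma <= 0) stop("`sigma` must be positive")
  exp(-sum((x - y)^2) / sigma^2)
}

#' Median-heuristic bandwidth
#'
#' The square root of the median of the squared pairwise Euclidean distances
#' over all distinct pairs of the `m` input points. If that median is zero
#' (constant input) the fallback value 1 is returned, which makes the Gram
#' matrix of a degenerate variable all ones.
#'
#' @param points a numeric vector (scalar samples) or a matrix whose rows are
#'   points; at least 2 points.
#' @return A positive bandwidth.
#' @examples
#' median_bandwidth(c(0, 1))        # 1
#' median_bandwidth(c(0, 1, 3))     # sqrt(median(1, 4, 9)) = 2
#' @export
median_bandwidth <- function(points) {
  if (is.null(dim(points))) points <- matrix(as.numeric(points), ncol = 1L)
  m <- nrow(points)
  if (m < 2L) stop("need at least 2 points")
  med <- median(stats::dist(points)^2)
  if (!is.finite(med) || med <= 0) return(1)
  sqrt(med)
}

# Squared Euclidean distance matrix between rows of a matrix.
sq_dist_matrix <- function(pts) {
  rn <- rowSums(pts^2)
  d2 <- outer(rn, rn, "+") - 2 * tcrossprod(pts)
  d2[d2 < 0] <- 0
  d2
}

# Shared Gram construction from a point matrix (rows = samples).
gram_from_points <- function(pts, spec, label = NULL) {
  if (!all(is.finite(pts))) stop("non-finite values in input")
  sigma <- if (spec$bandwidth == "fixed") spec$sigma else median_bandwidth(pts)
  k <- exp(-sq_dist_matrix(pts) / sigma^2)
  # exact symmetry / unit diagonal despite round-off
  k <- (k + t(k)) / 2
  diag(k) <- 1
  structure(k, sigma = sigma, label = label,
            class = c("gram_matrix", "matrix", "array"))
}

#' Gram matrix of a stationary series over time points
#'
#' Evaluates the kernel between all pairs of time points of one series,
#' producing the `T x T` matrix that captures the autocorrelational structure
#' of the variable. Circular series are embedded as `(cos, sin)` pairs first.
#'
#' @param series numeric vector of length `T >= 2`.
#' @param spec a [kernel_spec()].
#' @param circular if `TRUE`, treat values as angles and embed on the unit
#'   circle before computing distances.
#' @param label optional variable label stored on the result.
#' @return A `T x T` matrix of class `"gram_matrix"` with attributes `sigma`
#'   (the bandwidth used) and `label`.
#' @examples
#' g <- gram_stationary(c(0, 1), kernel_spec(bandwidth = "fixed", sigma = 1))
#' g[1, 2]  # exp(-1)
#' @export
gram_stationary <- function(series, spec = kernel_spec(), circular = FALSE,
                            label = NULL) {
  x <- as.numeric(series)
  if (length(x) < 2L) stop("series length must be at least 2")
  pts <- if (circular) cbind(cos(x), sin(x)) else matrix(x, ncol = 1L)
  gram_from_points(pts, spec, label)
}

#' Gram matrix of a variable over realizations
#'
#' Evaluates the kernel between all pairs of whole realizations (rows) of one
#' variable's `n x T_j` block, producing the `n x n` matrix that captures the
#' similarity structure across realizations.
#'
#' @param block numeric matrix, `n >= 2` rows (realizations) and `T_j`
#'   columns (time points).
#' @param spec a [kernel_spec()].
#' @param label optional variable label stored on the result.
#' @return An `n x n` matrix of class `"gram_matrix"` with attributes `sigma`
#'   and `label`.
#' @examples
#' b <- rbind(c(0, 0), c(3, 4))
#' g <- gram_multireal(b, kernel_spec(bandwidth = "fixed", sigma = 5))
#' g[1, 2]  # exp(-25/25) = exp(-1)
#' @export
gram_multireal <- function(block, spec = kernel_spec(), label = NULL) {
  block <- as.matrix(block)
  if (nrow(block) < 2L) stop("need at least 2 realizations")
  gram_from_points(block, spec, label)
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat(sprintf("Gram matrix (%d x %d), Gaussian kernel, sigma = %g",
              nrow(x), ncol(x), attr(x, "sigma")))
  if (!is.null(attr(x, "label"))) cat(", variable:", attr(x, "label"))
  cat("\n")
  invisible(x)
}

# Gram matrices for every variable of a dataset, bandwidths from observed
# data (frozen for all downstream resampling).
dataset_grams <- function(data, spec = kernel_spec()) {
  if (inherits(data, "stationary_dataset")) {
    lapply(seq_len(data$d), function(j)
      gram_stationary(data$series[[j]], spec, circular = data$circular[j],
                      label = data$variable_names[j]))
  } else if (inherits(data, "multireal_dataset")) {
    lapply(seq_len(data$d), function(j)
      gram_multireal(data$variables[[j]], spec, label = data$variable_names[j]))
  } else {
    stop("`data` must be a stationary_dataset or multireal_dataset")
  }
}
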