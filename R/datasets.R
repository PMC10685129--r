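#' Stationary single-realization dataset
#'
#' Container for `d` jointly observed real-valued time series, each a single
#' realization of length `T`. This is the input for the shifting-bootstrap
#' test ([dhsic_test()] with `scheme = "shift"`), which is valid only for
#' stationary processes.
#'
#' @param series a list of `d >= 2` numeric vectors of common length `T >= 2`,
#'   or a numeric matrix / data frame with `T` rows and `d` columns.
#' @param variable_names optional character vector of `d` labels; defaults to
#'   list/column names or `X1..Xd`.
#' @param circular logical vector of length `d` (recycled): marks variables
#'   that are angles on the unit circle (e.g. instantaneous phases). Circular
#'   variables are embedded as `(cos(x), sin(x))` before kernel evaluation so
#'   that distances respect the wrap-around at +/- pi.
#'
#' @return An object of class `"stationary_dataset"`: a list with elements
#'   `series` (list of numeric vectors), `variable_names`, `circular`,
#'   `d` and `T`.
#' @seealso [multireal_dataset()], [dhsic_test()]
#' @examples
#' x <- stationary_dataset(list(a = rnorm(50), b = rnorm(50)))
#' x
#' @export
stationary_dataset <- function(series, variable_names = NULL, circular = FALSE) {
  if (is.data.frame(series)) series <- as.matrix(series)
  if (is.matrix(series)) {
    if (is.null(variable_names)) variable_names <- colnames(series)
    series <- lapply(seq_len(ncol(series)), function(j) as.numeric(series[, j]))
  }
  if (!is.list(series)) stop("`series` must be a list, matrix or data frame")
  d <- length(series)
  if (d < 2L) stop("need at least 2 variables")
  series <- lapply(series, as.numeric)
  lens <- vapply(series, length, integer(1))
  if (length(unique(lens)) != 1L) stop("all series must share a common length")
  t_len <- lens[[1L]]
  if (t_len < 2L) stop("series length must be at least 2")
  if (!all(vapply(series, function(x) all(is.finite(x)), logical(1))))
    stop("series contain missing or non-finite values; complete panels are required")
  if (is.null(variable_names)) variable_names <- names(series)
  if (is.null(variable_names) || any(!nzchar(variable_names)))
    variable_names <- paste0("X", seq_len(d))
  if (length(variable_names) != d) stop("variable_names must have one label per series")
  if (anyDuplicated(variable_names)) stop("variable names must be unique")
  circular <- rep_len(as.logical(circular), d)
  names(series) <- variable_names
  structure(
    list(series = series, variable_names = variable_names,
         circular = circular, d = d, T = t_len),
    class = "stationary_dataset"
  )
}

#' @export
print.stationary_dataset <- function(x, ...) {
  cat(sprintf("Stationary time-series dataset: d = %d variables, T = %d time points\n",
              x$d, x$T))
  cat("  variables:", paste(x$variable_names, collapse = ", "), "\n")
  if (any(x$circular))
    cat("  circular: ", paste(x$variable_names[x$circular], collapse = ", "), "\n")
  invisible(x)
}

#' Multi-realization dataset
#'
#' Container for `d` variables observed as `n` independent realizations of a
#' (possibly non-stationary) time series. Realization `i` of variable `j` is
#' row `i` of the `j`-th block, a numeric vector of length `T_j`; lengths may
#' differ across variables but row order must align realizations. This is the
#' input for the cross-realization permutation test ([dhsic_test()] with
#' `scheme = "permute"`).
#'
#' @param variables a list of `d >= 2` numeric matrices, each with the same
#'   number of rows `n >= 2` (realizations); columns are time points.
#' @param variable_names optional character vector of `d` labels.
#'
#' @return An object of class `"multireal_dataset"`: a list with elements
#'   `variables` (list of n x T_j matrices), `variable_names`, `d`, `n`
#'   and `T` (integer vector of per-variable lengths).
#' @seealso [stationary_dataset()], [dhsic_test()]
#' @examples
#' blocks <- replicate(3, matrix(rnorm(40), nrow = 8), simplify = FALSE)
#' multireal_dataset(blocks)
#' @export
multireal_dataset <- function(variables, variable_names = NULL) {
  if (!is.list(variables)) stop("`variables` must be a list of matrices")
  d <- length(variables)
  if (d < 2L) stop("need at least 2 variables")
  variables <- lapply(variables, function(v) {
    v <- as.matrix(v)
    storage.mode(v) <- "double"
    v
  })
  ns <- vapply(variables, nrow, integer(1))
  if (length(unique(ns)) != 1L)
    stop("all variables must have the same number of realizations")
  n <- ns[[1L]]
  if (n < 2L) stop("need at least 2 realizations")
  if (!all(vapply(variables, function(v) all(is.finite(v)), logical(1))))
    stop("realizations contain missing or non-finite values")
  t_lens <- vapply(variables, ncol, integer(1))
  if (any(t_lens < 1L)) stop("every variable needs at least 1 time point")
  if (is.null(variable_names)) variable_names <- names(variables)
  if (is.null(variable_names) || any(!nzchar(variable_names)))
    variable_names <- paste0("X", seq_len(d))
  if (length(variable_names) != d) stop("variable_names must have one label per variable")
  if (anyDuplicated(variable_names)) stop("variable names must be unique")
  names(variables) <- variable_names
  structure(
    list(variables = variables, variable_names = variable_names,
         d = d, n = n, T = t_lens),
    class = "multireal_dataset"
  )
}

#' @export
print.multireal_dataset <- function(x, ...) {
  cat(sprintf("Multi-realization time-series dataset: d = %d variables, n = %d realizations\n",
              x$d, x$n))
  tl <- if (length(unique(x$T)) == 1L) as.character(x$T[1L]) else
    paste(x$T, collapse = "/")
  cat("  lengths T_j:", tl, "\n")
  cat("  variables:", paste(x$variable_names, collapse = ", "), "\n")
  invisible(x)
}

# Subset a dataset to the named variables (order preserved as given).
subset_dataset <- function(data, vars) {
  idx <- match(vars, data$variable_names)
  if (anyNA(idx)) stop("unknown variable name(s): ",
                       paste(vars[is.na(idx)], collapse = ", "))
  if (inherits(data, "stationary_dataset")) {
    stationary_dataset(data$series[idx], variable_names = data$variable_names[idx],
                       circular = data$circular[idx])
  } else {
    multireal_dataset(data$variables[idx], variable_names = data$variable_names[idx])
  }
}
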