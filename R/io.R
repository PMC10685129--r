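# Delimited-text readers/writers. Wide layout: header row of variable
# names, one row per time point. Long layout: realization id, time index,
# then one column per variable. Delimiter auto-detected (comma or tab);
# time is implicit row/index order.

detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty file: ", path)
  if (lengths(regmatches(first, gregexpr("\t", first))) > 0) "\t" else ","
}

read_numeric_table <- function(path) {
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  for (j in seq_along(df)) {
    col <- df[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s'",
                     bad[1L], names(df)[j]))
      df[[j]] <- num
    }
    miss <- which(is.na(df[[j]]))
    if (length(miss))
      stop(sprintf("missing value at row %d, column '%s'; complete panels are required",
                   miss[1L], names(df)[j]))
  }
  df
}

#' Read a wide-layout table as a stationary dataset
#'
#' Expects a delimited text file (comma or tab, auto-detected) with a header
#' row of variable names and one row per time point, in time order. Missing
#' or non-numeric cells are errors: the estimators assume complete panels
#' and no imputation is performed.
#'
#' @param path file path.
#' @return A [stationary_dataset()].
#' @export
read_wide_table <- function(path) {
  df <- read_numeric_table(path)
  if (ncol(df) < 2L) stop("need >= 2 variables (columns)")
  stationary_dataset(as.matrix(df))
}

#' Write a stationary dataset as a wide-layout table
#'
#' @param data a [stationary_dataset()].
#' @param path output path; `.tsv` extension writes tabs, otherwise commas.
#' @return `path`, invisibly.
#' @export
write_wide_table <- function(data, path) {
  stopifnot(inherits(data, "stationary_dataset"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- as.data.frame(data$series)
  names(df) <- data$variable_names
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-layout table as a multi-realization dataset
#'
#' Expects a delimited text file whose first two columns are the
#' realization id and the time index, followed by one numeric column per
#' variable. Every (realization, time) pair must be unique and every
#' realization must cover the same set of time indices; missing cells are
#' errors.
#'
#' @param path file path.
#' @return A [multireal_dataset()].
#' @export
read_long_table <- function(path) {
  sep <- detect_sep(path)
  df <- read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 3L)
    stop("long layout needs realization id, time index and >= 1 variable column; with < 2 variables no joint test is possible")
  if (ncol(df) < 4L) stop("need >= 2 variables")
  real_id <- df[[1L]]
  time_id <- df[[2L]]
  key <- paste(real_id, time_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("duplicated (realization, time) pair at row %d", dup[1L]))
  reals <- unique(real_id)
  times <- sort(unique(time_id))
  per_real <- table(real_id)
  if (length(unique(as.integer(per_real))) != 1L)
    stop("realizations have differing numbers of time points (ragged panel)")
  vars <- df[-(1:2)]
  for (j in seq_along(vars)) {
    col <- vars[[j]]
    if (!is.numeric(col)) {
      suppressWarnings(num <- as.numeric(col))
      bad <- which(is.na(num) & !is.na(col))
      if (length(bad))
        stop(sprintf("non-numeric cell at row %d, column '%s'",
                     bad[1L], names(vars)[j]))
      vars[[j]] <- num
    }
    miss <- which(is.na(vars[[j]]))
    if (length(miss))
      stop(sprintf("missing value at row %d, column '%s'", miss[1L],
                   names(vars)[j]))
  }
  ord <- order(match(real_id, reals), match(time_id, times))
  n <- length(reals); t_len <- length(times)
  blocks <- lapply(vars, function(col)
    matrix(col[ord], nrow = n, ncol = t_len, byrow = TRUE))
  multireal_dataset(blocks, variable_names = names(vars))
}

#' Write a multi-realization dataset as a long-layout table
#'
#' Variables with differing lengths are not representable in one long
#' table; all `T_j` must be equal.
#'
#' @param data a [multireal_dataset()].
#' @param path output path; `.tsv` writes tabs, otherwise commas.
#' @return `path`, invisibly.
#' @export
write_long_table <- function(data, path) {
  stopifnot(inherits(data, "multireal_dataset"))
  if (length(unique(data$T)) != 1L)
    stop("long layout requires equal T_j across variables")
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  n <- data$n; t_len <- data$T[[1L]]
  df <- data.frame(realization = rep(seq_len(n), each = t_len),
                   time = rep(seq_len(t_len), times = n))
  for (j in seq_len(data$d))
    df[[data$variable_names[j]]] <- as.numeric(t(data$variables[[j]]))
  write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sequential lag differencing
#'
#' Applies lag-`p` differencing for each period in `periods` in turn, the
#' standard device for removing polynomial trends (period 1) and seasonal
#' cycles (period equal to the season length). Output length is
#' `length(x) - sum(periods)`.
#'
#' @param x numeric vector.
#' @param periods integer vector of differencing lags.
#' @return The differenced series.
#' @examples
#' difference_detrend(c(1, 2, 4, 8), 1)  # 1 2 4
#' @export
difference_detrend <- function(x, periods) {
  periods <- as.integer(periods)
  stopifnot(all(periods >= 1L))
  if (length(x) <= sum(periods))
    stop("series too short for the requested differencing")
  for (p in periods) x <- diff(x, lag = p)
  x
}
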