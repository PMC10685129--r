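#' Estimate test power / type-I error over a parameter grid
#'
#' For every row of `grid`, simulates `replicates` datasets from the chosen
#' benchmark system, runs the appropriate joint-independence test on each,
#' and returns the rejection fraction with a Wilson 95% binomial interval.
#' For independence configurations (`lambda = 0`, or the uncoupled system)
#' the same readout is the empirical type-I error.
#'
#' Every (grid point, replicate) pair gets its own seed derived from `seed`
#' and the parameter values, so results are invariant to grid ordering and
#' extending the grid does not reshuffle earlier points.
#'
#' @param model one of `"ar_pairwise_coupled"`, `"ar_three_way"`,
#'   `"ar_independent"` (shifting test on a single realization);
#'   `"rw_trend_linear"`, `"rw_trend_oscillatory"`,
#'   `"ar_trend_interaction"`, `"xor"` (permutation test across
#'   realizations).
#' @param grid data frame of parameter combinations; recognized columns:
#'   `lambda`, `a`, `T`, `n` (missing columns take the generator defaults).
#' @param replicates simulated datasets per grid point.
#' @param resamples null samples per test (`S` or `P`).
#' @param alpha significance level.
#' @param seed integer master seed.
#' @return A data frame of class `"power_curve"`: the grid columns plus
#'   `power`, `ci_low`, `ci_high`, `replicates`.
#' @examples
#' pc <- estimate_power("ar_pairwise_coupled",
#'                      expand.grid(lambda = c(0, 1), T = 100),
#'                      replicates = 5, resamples = 50, seed = 1)
#' pc
#' @export
estimate_power <- function(model, grid, replicates = 100L, resamples = 200L,
                           alpha = 0.05, seed = 1L) {
  stopifnot(is.data.frame(grid), nrow(grid) >= 1L, replicates >= 1L)
  known <- c("ar_pairwise_coupled", "ar_three_way", "ar_independent",
             "rw_trend_linear", "rw_trend_oscillatory",
             "ar_trend_interaction", "xor")
  model <- match.arg(model, known)
  bad <- setdiff(names(grid), c("lambda", "a", "T", "n"))
  if (length(bad)) stop("unknown grid column(s): ", paste(bad, collapse = ", "))

  out <- grid
  out$power <- NA_real_; out$ci_low <- NA_real_; out$ci_high <- NA_real_
  out$replicates <- as.integer(replicates)
  for (i in seq_len(nrow(grid))) {
    pt <- as.list(grid[i, , drop = FALSE])
    label_pt <- paste(model, paste(names(pt), unlist(pt), sep = "=",
                                   collapse = ","))
    rejections <- vapply(seq_len(replicates), function(r) {
      rseed <- derive_seed(seed, paste(label_pt, r, sep = "#"))
      data <- generate_model(model, pt, rseed)
      res <- dhsic_test(data, resamples = resamples, alpha = alpha,
                        seed = derive_seed(rseed, "test"))
      res$rejected
    }, logical(1))
    ci <- wilson_ci(sum(rejections), replicates)
    out$power[i] <- mean(rejections)
    out$ci_low[i] <- ci[["low"]]
    out$ci_high[i] <- ci[["high"]]
  }
  class(out) <- c("power_curve", "data.frame")
  attr(out, "model") <- model
  attr(out, "alpha") <- alpha
  attr(out, "resamples") <- as.integer(resamples)
  out
}

generate_model <- function(model, pt, seed) {
  g <- function(name, default) if (!is.null(pt[[name]]) && !is.na(pt[[name]]))
    pt[[name]] else default
  switch(model,
    ar_pairwise_coupled = sim_ar_pairwise_coupled(
      T = g("T", 300L), lambda = g("lambda", 1), seed = seed, n = g("n", 1L)),
    ar_three_way = sim_ar_three_way(
      T = g("T", 300L), lambda = g("lambda", 1), seed = seed, n = g("n", 1L)),
    ar_independent = sim_ar_independent(
      T = g("T", 300L), a = g("a", 0.5), seed = seed, n = g("n", 1L)),
    rw_trend_linear = sim_rw_trend(
      n = g("n", 100L), T = g("T", 20L), lambda = g("lambda", 1),
      trend = "linear", seed = seed),
    rw_trend_oscillatory = sim_rw_trend(
      n = g("n", 100L), T = g("T", 20L), lambda = g("lambda", 1),
      trend = "oscillatory", seed = seed),
    ar_trend_interaction = sim_ar_trend_interaction(
      n = g("n", 100L), T = g("T", 20L), lambda = g("lambda", 1),
      a = g("a", 0.8), seed = seed),
    xor = sim_xor_gate(n = g("n", 200L), T = g("T", 20L), seed = seed,
                       invert_prob = 0))
}

#' @export
print.power_curve <- function(x, ...) {
  cat(sprintf("Power curve for model '%s' (alpha = %g, %d resamples per test)\n",
              attr(x, "model"), attr(x, "alpha"), attr(x, "resamples")))
  print.data.frame(cbind(x[setdiff(names(x), c("power", "ci_low", "ci_high",
                                               "replicates"))],
                         power = round(x$power, 3),
                         ci = sprintf("[%.3f, %.3f]", x$ci_low, x$ci_high),
                         replicates = x$replicates),
                   row.names = FALSE)
  invisible(x)
}

#' Plot a power curve
#'
#' Rejection fraction against `lambda` (or `a`), one line per `T` (and `n`)
#' value, with shaded Wilson intervals. Base graphics.
#'
#' @param x a `"power_curve"`.
#' @param xvar which grid column to place on the x axis; default `"lambda"`
#'   if present, else `"a"`.
#' @param ... passed to [graphics::plot.default()].
#' @export
plot.power_curve <- function(x, xvar = NULL, ...) {
  if (is.null(xvar)) xvar <- if ("lambda" %in% names(x)) "lambda" else "a"
  stopifnot(xvar %in% names(x))
  groups <- interaction(x[setdiff(names(x), c(xvar, "power", "ci_low",
                                              "ci_high", "replicates"))],
                        drop = TRUE)
  if (length(groups) == 0L) groups <- factor(rep(1, nrow(x)))
  cols <- grDevices::hcl.colors(max(3L, nlevels(groups)), "Dark 3")
  graphics::plot(NULL, xlim = range(x[[xvar]]), ylim = c(0, 1),
                 xlab = xvar, ylab = "rejection fraction", ...)
  graphics::abline(h = attr(x, "alpha"), lty = 3)
  for (k in seq_len(nlevels(groups))) {
    sel <- which(groups == levels(groups)[k])
    sel <- sel[order(x[[xvar]][sel])]
    graphics::polygon(c(x[[xvar]][sel], rev(x[[xvar]][sel])),
                      c(x$ci_low[sel], rev(x$ci_high[sel])),
                      border = NA, col = grDevices::adjustcolor(cols[k], 0.2))
    graphics::lines(x[[xvar]][sel], x$power[sel], col = cols[k], lwd = 2)
  }
  if (nlevels(groups) > 1L)
    graphics::legend("bottomright", legend = levels(groups), col = cols,
                     lwd = 2, bty = "n", cex = 0.8)
  invisible(x)
}

#' Compare shifting and permutation resampling on matched data
#'
#' For stationary data observed as `n` realizations of length `T`, both
#' resampling schemes are valid. This harness generates multi-realization
#' data from the pairwise-coupled stationary system and, per grid point,
#' estimates (i) the permutation test's power across the `n` realizations
#' and (ii) the shifting test's power on the single series formed by
#' concatenating the `n` realizations (a matched data budget of `n * T`
#' points). Permutation tends to win when `n` is large relative to `T`;
#' shifting when `T` dominates.
#'
#' @param T time points per realization.
#' @param n_grid vector of realization counts (each >= 2; the permutation
#'   test is undefined for a single realization).
#' @param lambda dependence coefficient of the generator.
#' @param S,P null samples for the shifting / permutation arm.
#' @param replicates datasets per grid point and arm.
#' @param alpha significance level.
#' @param seed master seed.
#' @return A data frame of class `"power_curve"` with columns `n`, `scheme`
#'   (`"shift"` / `"permute"`), `power`, `ci_low`, `ci_high`, `replicates`.
#' @export
compare_resampling <- function(T = 20L, n_grid = c(4L, 8L, 16L), lambda = 1,
                               S = 200L, P = 200L, replicates = 50L,
                               alpha = 0.05, seed = 1L) {
  if (any(n_grid < 2L))
    stop("permutation resampling needs n >= 2 realizations; n = 1 admits only the shifting test")
  rows <- list()
  for (n in n_grid) {
    rej <- matrix(NA, replicates, 2L,
                  dimnames = list(NULL, c("shift", "permute")))
    for (r in seq_len(replicates)) {
      rseed <- derive_seed(seed, sprintf("cmp n=%d rep=%d", n, r))
      data <- sim_ar_pairwise_coupled(T = T, lambda = lambda, seed = rseed,
                                      n = n)
      perm <- dhsic_test(data, scheme = "permute", resamples = P,
                         alpha = alpha, seed = derive_seed(rseed, "perm"))
      concat <- stationary_dataset(
        lapply(data$variables, function(v) as.numeric(t(v))),
        variable_names = data$variable_names)
      shift <- dhsic_test(concat, scheme = "shift", resamples = S,
                          alpha = alpha, seed = derive_seed(rseed, "shift"))
      rej[r, ] <- c(shift$rejected, perm$rejected)
    }
    for (scheme in colnames(rej)) {
      ci <- wilson_ci(sum(rej[, scheme]), replicates)
      rows[[length(rows) + 1L]] <- data.frame(
        n = n, scheme = scheme, power = mean(rej[, scheme]),
        ci_low = ci[["low"]], ci_high = ci[["high"]],
        replicates = replicates, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_curve", "data.frame")
  attr(out, "model") <- "ar_pairwise_coupled (multi-realization)"
  attr(out, "alpha") <- alpha
  attr(out, "resamples") <- as.integer(max(S, P))
  out
}

#' Write a power curve as a delimited table or JSON
#'
#' @param x a `"power_curve"`.
#' @param path output path; extension `.json` writes JSON, anything else a
#'   tab-separated table.
#' @return `path`, invisibly.
#' @export
write_power_curve <- function(x, path) {
  stopifnot(inherits(x, "power_curve"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(as.data.frame(x), path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  } else {
    write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(path)
}
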