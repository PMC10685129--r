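# Internal helpers: seeding and a minimal unit-root screen.

# Evaluate `code` under a fixed seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic 31-bit seed derived from a base seed and a character label.
# Used to give every purpose (resampling plan, each scanned subset, each
# simulation replicate) its own substream, so that results do not depend on
# the order in which tests are run.
derive_seed <- function(seed, label) {
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(paste(label, collapse = "|"))) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Augmented Dickey-Fuller screen (constant, no trend). Returns the t-statistic
# of the lagged level; values below the 5% asymptotic critical value (-2.86)
# reject a unit root, i.e. look stationary. Lag order follows the common
# floor((T-1)^(1/3)) rule.
adf_tstat <- function(x, k = NULL) {
  x <- as.numeric(x)
  t_len <- length(x)
  if (is.null(k)) k <- max(1L, floor((t_len - 1)^(1 / 3)))
  dx <- diff(x)
  n <- length(dx) - k
  if (n < 5L) stop("series too short for the unit-root screen")
  y <- dx[(k + 1):length(dx)]
  lag_level <- x[(k + 1):(length(x) - 1)]
  lagged_diffs <- sapply(seq_len(k), function(i) dx[(k + 1 - i):(length(dx) - i)])
  fit <- stats::lm(y ~ lag_level + lagged_diffs)
  summary(fit)$coefficients["lag_level", "t value"]
}

adf_looks_stationary <- function(x, level_crit = -2.86) {
  adf_tstat(x) < level_crit
}

# Wilson 95% binomial interval.
wilson_ci <- function(successes, trials, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- successes / trials
  denom <- 1 + z^2 / trials
  centre <- (p + z^2 / (2 * trials)) / denom
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2)) / denom
  c(low = max(0, centre - half), high = min(1, centre + half))
}
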