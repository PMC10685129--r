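# Benchmark generators. The stationary AR systems use zero initial states
# and a 100-step burn-in so the retained sample starts near the stationary
# law; the non-stationary systems use zero initial states and no burn-in
# (they have no stationary law to converge to).

BURN_IN <- 100L

# Simulate one realization of the three stationary AR systems.
sim_ar3_once <- function(model, t_len, lambda, a) {
  total <- t_len + BURN_IN
  eps <- rnorm(total); eta <- rnorm(total); zeta <- rnorm(total)
  theta <- if (model == "interaction") rnorm(total) else NULL
  x <- y <- z <- numeric(total)
  xp <- yp <- zp <- 0
  for (t in seq_len(total)) {
    if (model == "independent") {
      x[t] <- a * xp + eps[t]
      y[t] <- a * yp + eta[t]
      z[t] <- a * zp + zeta[t]
    } else {
      x[t] <- 0.5 * xp + eps[t]
      y[t] <- 0.5 * yp + eta[t]
      z[t] <- 0.5 * zp + zeta[t] +
        if (model == "coupled") lambda * (x[t] + y[t])
        else lambda * abs(theta[t]) * sign(x[t] * y[t])
    }
    xp <- x[t]; yp <- y[t]; zp <- z[t]
  }
  keep <- (BURN_IN + 1L):total
  cbind(X = x[keep], Y = y[keep], Z = z[keep])
}

sim_ar3 <- function(model, t_len, lambda, a, n, seed) {
  stopifnot(t_len >= 2)
  with_seed(seed, {
    if (n == 1L) {
      m <- sim_ar3_once(model, t_len, lambda, a)
      stationary_dataset(list(X = m[, "X"], Y = m[, "Y"], Z = m[, "Z"]))
    } else {
      reals <- lapply(seq_len(n), function(i) sim_ar3_once(model, t_len, lambda, a))
      multireal_dataset(list(
        X = do.call(rbind, lapply(reals, function(r) r[, "X"])),
        Y = do.call(rbind, lapply(reals, function(r) r[, "Y"])),
        Z = do.call(rbind, lapply(reals, function(r) r[, "Z"]))))
    }
  })
}

#' Stationary AR system with two pairwise couplings
#'
#' Three AR(1/2) series where `Z` is additively driven by `X` and `Y`:
#' \deqn{X_t = X_{t-1}/2 + \epsilon_t,\quad Y_t = Y_{t-1}/2 + \eta_t,\quad
#'   Z_t = Z_{t-1}/2 + \zeta_t + \lambda (X_t + Y_t)}
#' with standard-normal innovations. The three-way dependence follows from
#' the two pairwise dependencies (X,Z) and (Y,Z); (X,Y) stay independent.
#' `lambda = 0` gives joint independence.
#'
#' @param T series length retained after a 100-step burn-in.
#' @param lambda dependence coefficient (>= 0).
#' @param seed integer seed; the generator is fully deterministic given it.
#' @param n number of realizations; `n = 1` (default) returns a
#'   [stationary_dataset()], `n > 1` a [multireal_dataset()].
#' @return A dataset with variables `X`, `Y`, `Z`.
#' @export
sim_ar_pairwise_coupled <- function(T = 300L, lambda = 1, seed = 1L, n = 1L) {
  sim_ar3("coupled", as.integer(T), lambda, a = NA, as.integer(n), seed)
}

#' Stationary AR system with a pure three-way interaction
#'
#' Three AR(1/2) series where `Z` is driven by the *sign interaction* of `X`
#' and `Y`:
#' \deqn{Z_t = Z_{t-1}/2 + \zeta_t + \lambda |\theta_t|\,
#'   \mathrm{sign}(X_t Y_t)}
#' with standard-normal innovations and `theta`. By the sign symmetry all
#' pairwise correlations vanish: the dependence exists only at third order
#' (an emergent three-way dependency). `lambda = 0` gives joint
#' independence.
#'
#' @inheritParams sim_ar_pairwise_coupled
#' @return A dataset with variables `X`, `Y`, `Z`.
#' @export
sim_ar_three_way <- function(T = 300L, lambda = 1, seed = 1L, n = 1L) {
  sim_ar3("interaction", as.integer(T), lambda, a = NA, as.integer(n), seed)
}

#' Jointly independent AR system
#'
#' Three uncoupled AR(a) series with standard-normal innovations; the
#' type-I-error benchmark. Requires `|a| < 1` for stationarity.
#'
#' @inheritParams sim_ar_pairwise_coupled
#' @param a autocorrelation coefficient, `|a| < 1`.
#' @return A dataset with variables `X`, `Y`, `Z`.
#' @export
sim_ar_independent <- function(T = 300L, a = 0.5, seed = 1L, n = 1L) {
  stopifnot(abs(a) < 1)
  sim_ar3("independent", as.integer(T), lambda = 0, a = a, as.integer(n), seed)
}

#' Non-stationary unit-root system with trend and pairwise couplings
#'
#' Three unit-root (random-walk) series with deterministic trends, where `Z`
#' is additively driven by `X` and `Y`:
#' \deqn{X_t = g_1(t) + X_{t-1} + \epsilon_t,\ Y_t = g_2(t) + Y_{t-1} +
#'   \eta_t,\ Z_t = g_3(t) + Z_{t-1} + \zeta_t + \lambda (X_t + Y_t)}
#' for `t = 1..T`, zero initial states, no burn-in (the process is
#' non-stationary by construction). Trends: `"linear"` uses
#' `g_1 = g_2 = g_3 = t`; `"oscillatory"` uses `g_1 = sin^2(t)/log(1+t)`,
#' `g_2 = cos^2(t)/log(1+t)`, `g_3 = sin(t)cos(t)/log(1+t)`.
#'
#' @param n number of iid realizations (>= 2 for testing).
#' @param T time points per realization.
#' @param lambda dependence coefficient; 0 gives joint independence.
#' @param trend `"linear"` or `"oscillatory"`.
#' @param seed integer seed.
#' @return A [multireal_dataset()] with variables `X`, `Y`, `Z`.
#' @export
sim_rw_trend <- function(n = 100L, T = 20L, lambda = 1,
                         trend = c("linear", "oscillatory"), seed = 1L) {
  trend <- match.arg(trend)
  n <- as.integer(n); t_len <- as.integer(T)
  stopifnot(n >= 1, t_len >= 1)
  tt <- seq_len(t_len)
  if (trend == "linear") {
    g1 <- g2 <- g3 <- tt
  } else {
    g1 <- sin(tt)^2 / log(1 + tt)
    g2 <- cos(tt)^2 / log(1 + tt)
    g3 <- sin(tt) * cos(tt) / log(1 + tt)
  }
  with_seed(seed, {
    xs <- matrix(0, n, t_len); ys <- matrix(0, n, t_len); zs <- matrix(0, n, t_len)
    for (i in seq_len(n)) {
      xp <- yp <- zp <- 0
      for (t in tt) {
        x <- g1[t] + xp + rnorm(1)
        y <- g2[t] + yp + rnorm(1)
        z <- g3[t] + zp + rnorm(1) + lambda * (x + y)
        xs[i, t] <- x; ys[i, t] <- y; zs[i, t] <- z
        xp <- x; yp <- y; zp <- z
      }
    }
    if (n == 1L && t_len >= 2L)
      stationary_dataset(list(X = xs[1, ], Y = ys[1, ], Z = zs[1, ]))
    else
      multireal_dataset(list(X = xs, Y = ys, Z = zs))
  })
}

#' Non-stationary AR system with a three-way sign interaction
#'
#' Three AR(a) series with growing oscillatory trends where `Z` is driven by
#' the sign interaction of `X` and `Y`:
#' \deqn{X_t = a X_{t-1} + \epsilon_t + t\sin(t),\ Y_t = a Y_{t-1} + \eta_t
#'   + t\cos(t),\ Z_t = a Z_{t-1} + \zeta_t + \lambda\, t\,
#'   \mathrm{sign}(X_t Y_t)}
#' for `t = 1..T`, zero initial states, no burn-in. The default `a = 0.8`
#' combined with the amplitude-growing deterministic component makes the
#' series non-stationary; pairwise dependence of detrended pairs stays null
#' while the three-way dependence grows with `lambda`.
#'
#' @inheritParams sim_rw_trend
#' @param a autoregressive coefficient, default 0.8.
#' @return A [multireal_dataset()] with variables `X`, `Y`, `Z`.
#' @export
sim_ar_trend_interaction <- function(n = 100L, T = 20L, lambda = 1, a = 0.8,
                                     seed = 1L) {
  n <- as.integer(n); t_len <- as.integer(T)
  stopifnot(n >= 1, t_len >= 1)
  tt <- seq_len(t_len)
  with_seed(seed, {
    xs <- matrix(0, n, t_len); ys <- matrix(0, n, t_len); zs <- matrix(0, n, t_len)
    for (i in seq_len(n)) {
      xp <- yp <- zp <- 0
      for (t in tt) {
        x <- a * xp + rnorm(1) + t * sin(t)
        y <- a * yp + rnorm(1) + t * cos(t)
        z <- a * zp + rnorm(1) + lambda * t * sign(x * y)
        xs[i, t] <- x; ys[i, t] <- y; zs[i, t] <- z
        xp <- x; yp <- y; zp <- z
      }
    }
    multireal_dataset(list(X = xs, Y = ys, Z = zs))
  })
}

#' Boolean XOR-parity system
#'
#' Four 0/1 variables: `X`, `Y`, `W` are lazy bit-flip processes (each flips
#' its previous value when its own uniform draw falls below `flip_prob`),
#' and `Z_t` equals the parity `X_t XOR Y_t XOR W_t`, inverted when an
#' independent uniform draw falls below `invert_prob`. Initial bits are fair
#' coins. With `invert_prob = 0` the parity constraint is deterministic and
#' the dependence is purely four-way: every pair and triple of variables is
#' independent, only the full quadruple is dependent. With
#' `invert_prob = 0.5` the output inversion makes `Z` an independent fair
#' coin, removing all dependence (see the methods vignette).
#'
#' @param n realizations.
#' @param T time points.
#' @param seed integer seed.
#' @param flip_prob per-step flip probability of `X`, `Y`, `W` (default 0.5,
#'   which makes them iid fair bits over time).
#' @param invert_prob probability that `Z_t` is the complement of the
#'   parity (default 0.5).
#' @return A [multireal_dataset()] with variables `X`, `Y`, `W`, `Z`.
#' @export
sim_xor_gate <- function(n = 200L, T = 20L, seed = 1L, flip_prob = 0.5,
                         invert_prob = 0.5) {
  n <- as.integer(n); t_len <- as.integer(T)
  stopifnot(n >= 1, t_len >= 1)
  with_seed(seed, {
    xs <- matrix(0, n, t_len); ys <- matrix(0, n, t_len)
    ws <- matrix(0, n, t_len); zs <- matrix(0, n, t_len)
    for (i in seq_len(n)) {
      x <- runif(1) < 0.5; y <- runif(1) < 0.5; w <- runif(1) < 0.5
      for (t in seq_len(t_len)) {
        if (runif(1) < flip_prob) x <- !x
        if (runif(1) < flip_prob) y <- !y
        if (runif(1) < flip_prob) w <- !w
        parity <- xor(xor(x, y), w)
        z <- if (runif(1) < invert_prob) !parity else parity
        xs[i, t] <- x; ys[i, t] <- y; ws[i, t] <- w; zs[i, t] <- z
      }
    }
    multireal_dataset(list(X = xs, Y = ys, W = ws, Z = zs))
  })
}
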