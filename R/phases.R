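# Frequency mixing: a quadratic nonlinearity applied to the sum of two
# tones creates harmonics (2 f1, 2 f2) and emergent sum/difference
# components (f1 + f2, f2 - f1). The instantaneous phases of the four
# components at f1, f2, f_sum, f_diff carry a purely higher-order
# dependence: phi_1 + phi_2 = phi_sum + const and phi_2 - phi_1 = phi_diff
# + const, so every pair of phases is independent while the triplets (and
# the quadruplet) are not.

#' Frequency-mixing signal
#'
#' Applies a quadratic nonlinearity `q(x) = x + x^2` to the superposition
#' `s(t) = sin(2 pi f1 t) + sin(2 pi f2 t)` and adds weighted Gaussian
#' noise: `F(t) = s(t) + s(t)^2 + w e(t)`, sampled at `fs` Hz for
#' `duration` seconds. By the product-to-sum identities the noise-free
#' signal has a DC term of 1 and spectral lines at the roots `f1`, `f2`
#' (from the linear term), the second harmonics `2 f1`, `2 f2`, and the
#' emergent mixing components `f2 - f1` and `f1 + f2`. The linear term is
#' essential: a pure square would annihilate the root components whose
#' phases the mixing analysis tracks.
#'
#' @param f1,f2 input tone frequencies in Hz (defaults 7 and 18).
#' @param fs sampling rate in Hz; must exceed twice the highest generated
#'   line, i.e. `fs > 4 max(f1, f2)`.
#' @param duration record length in seconds.
#' @param noise_weight standard deviation multiplier of the additive
#'   Gaussian noise.
#' @param seed integer seed (used only when `noise_weight > 0`).
#' @return An object of class `"freqmix_signal"`: list with `signal`, `fs`,
#'   `f1`, `f2`, `f_diff`, `f_sum`, `noise_weight`.
#' @examples
#' fm <- sim_frequency_mixing(noise_weight = 0, duration = 2)
#' round(mean(fm$signal), 2)  # ~1, the DC term
#' @export
sim_frequency_mixing <- function(f1 = 7, f2 = 18, fs = 100, duration = 10,
                                 noise_weight = 0.1, seed = 1L) {
  if (f1 == f2) stop("`f1` and `f2` must differ")
  if (fs <= 2 * (2 * max(f1, f2)))
    stop("`fs` must exceed twice the highest generated frequency (second harmonic)")
  stopifnot(noise_weight >= 0, duration > 0)
  n <- round(fs * duration)
  tt <- (seq_len(n) - 1) / fs
  s <- sin(2 * pi * f1 * tt) + sin(2 * pi * f2 * tt)
  base <- s + s^2
  if (noise_weight > 0)
    base <- base + noise_weight * with_seed(seed, rnorm(n))
  structure(list(signal = base, fs = fs, f1 = f1, f2 = f2,
                 f_diff = abs(f2 - f1), f_sum = f1 + f2,
                 noise_weight = noise_weight),
            class = "freqmix_signal")
}

#' @export
print.freqmix_signal <- function(x, ...) {
  cat(sprintf(
    "Frequency-mixing signal: f1 = %g Hz, f2 = %g Hz (emergent %g and %g Hz), fs = %g Hz, %d samples\n",
    x$f1, x$f2, x$f_diff, x$f_sum, x$fs, length(x$signal)))
  invisible(x)
}

#' Spectral line frequencies of a signal
#'
#' Amplitude spectrum via FFT; returns the frequencies (in Hz, at FFT-bin
#' resolution) of local maxima whose amplitude exceeds `rel_threshold`
#' times the largest non-DC amplitude. Used to verify which components a
#' signal contains.
#'
#' @param x numeric vector or `"freqmix_signal"`.
#' @param fs sampling rate in Hz (taken from the object if omitted).
#' @param rel_threshold relative amplitude cutoff for reporting a peak.
#' @return Numeric vector of peak frequencies in Hz (DC excluded), sorted.
#' @export
spectral_peaks <- function(x, fs = NULL, rel_threshold = 0.05) {
  if (inherits(x, "freqmix_signal")) {
    if (is.null(fs)) fs <- x$fs
    x <- x$signal
  }
  if (is.null(fs)) stop("`fs` required for a plain numeric signal")
  n <- length(x)
  amp <- Mod(stats::fft(x - mean(x)))[seq_len(n %/% 2 + 1L)]
  freqs <- (seq_along(amp) - 1) * fs / n
  cut <- rel_threshold * max(amp[-1L])
  is_peak <- vapply(seq_along(amp), function(i) {
    if (i == 1L || amp[i] < cut) return(FALSE)
    left <- if (i > 1L) amp[i - 1L] else -Inf
    right <- if (i < length(amp)) amp[i + 1L] else -Inf
    amp[i] >= left && amp[i] >= right
  }, logical(1))
  sort(freqs[is_peak])
}

#' Instantaneous phases at target frequencies
#'
#' Extracts the instantaneous phase of each target component by analytic
#' Morlet wavelet filtering at a single scale per frequency: the signal's
#' FFT is multiplied by the Morlet transfer function
#' `exp(-omega0^2 (nu/f - 1)^2 / 2)` on positive frequencies only (the
#' complex Morlet continuous wavelet coefficient at the scale whose centre
#' frequency is `f`), and the phase is the argument of the resulting
#' complex series, wrapped to `(-pi, pi]`. A fraction `trim` of samples is
#' dropped at each edge to discard cone-of-influence artifacts.
#'
#' The returned dataset marks all variables as circular, so Gram matrices
#' embed the phases on the unit circle before distance computation.
#'
#' @param x numeric signal or `"freqmix_signal"`.
#' @param fs sampling rate in Hz (from the object if omitted).
#' @param target_freqs frequencies in Hz at which to extract phases; for a
#'   `"freqmix_signal"` the default is `c(f1, f2, f_diff, f_sum)` with
#'   names `phi1`, `phi2`, `phiD`, `phiS`.
#' @param omega0 Morlet centre-frequency parameter, which sets the filter's
#'   frequency selectivity: the transfer function's standard deviation is
#'   `f / omega0` Hz. The default 20 keeps each extracted component's
#'   nearest spectral neighbour several standard deviations away for the
#'   default frequency-mixing layout (lines at 11 and 14 Hz are only 3 Hz
#'   apart); wider filters (e.g. the classical omega0 = 6) leak adjacent
#'   components into the phase estimate and manufacture spurious pairwise
#'   dependence.
#' @param trim fraction trimmed from each edge (default 0.05).
#' @return A [stationary_dataset()] of phase series (circular variables);
#'   if a single target frequency is given, the phase series itself as a
#'   numeric vector.
#' @examples
#' fm <- sim_frequency_mixing(noise_weight = 0, duration = 4)
#' ph <- extract_phases(fm)
#' ph$variable_names
#' @export
extract_phases <- function(x, fs = NULL, target_freqs = NULL, omega0 = 20,
                           trim = 0.05) {
  if (inherits(x, "freqmix_signal")) {
    if (is.null(fs)) fs <- x$fs
    if (is.null(target_freqs))
      target_freqs <- c(phi1 = x$f1, phi2 = x$f2,
                        phiD = x$f_diff, phiS = x$f_sum)
    x <- x$signal
  }
  if (is.null(fs)) stop("`fs` required for a plain numeric signal")
  if (is.null(target_freqs)) stop("`target_freqs` required")
  n <- length(x)
  dur <- n / fs
  if (any(target_freqs * dur < 2))
    stop("unresolvable target frequency: need at least 2 cycles in the record")
  if (is.null(names(target_freqs)))
    names(target_freqs) <- paste0("phi_", signif(target_freqs, 4), "Hz")
  xf <- stats::fft(x - mean(x))
  freqs <- (seq_len(n) - 1) * fs / n
  pos <- freqs <= fs / 2 & freqs > 0
  keep <- seq.int(floor(n * trim) + 1L, n - floor(n * trim))
  phases <- lapply(target_freqs, function(f) {
    h <- numeric(n)
    h[pos] <- exp(-omega0^2 * (freqs[pos] / f - 1)^2 / 2)
    coefs <- stats::fft(xf * h, inverse = TRUE) / n
    Arg(coefs)[keep]
  })
  if (length(phases) == 1L) return(phases[[1L]])
  stationary_dataset(phases, variable_names = names(target_freqs),
                     circular = TRUE)
}
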