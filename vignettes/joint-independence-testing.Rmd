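---
title: "Testing joint independence of time series with dHSIC"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Testing joint independence of time series with dHSIC}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhsicts)
```

## The problem

Given $d \ge 2$ co-observed time series $X^1, \dots, X^d$, are they *jointly
independent* — does their joint distribution factorize into the product of the
univariate marginals,
$P_{X^1,\dots,X^d} = \prod_{j=1}^d P_{X^j}$?
Joint independence of a set implies joint independence of every subset, so a
rejection for a subset forces a rejection for the full set. Conversely, a set
can fail to factorize even though every proper subset does; such *emergent*
(first-time) rejections mark genuinely higher-order structure — XOR-type
parity constraints and frequency-mixing phase locking are the canonical
examples, and they are invisible to any pairwise analysis.

## The statistic

The d-variable Hilbert–Schmidt independence criterion (dHSIC) embeds
distributions in a reproducing-kernel Hilbert space via a characteristic
kernel and measures the squared distance between the embedding of the joint
distribution and the embedding of the product of marginals. It is zero if and
only if the variables are jointly independent. With Gram matrices
$K^j_{ab} = k^j(x^j_a, x^j_b)$ over $m$ samples, the plug-in (V-statistic)
estimator is the three-term expansion

$$\widehat{\mathrm{dHSIC}} \;=\;
\frac{1}{m^2}\sum_{a,b}\prod_{j=1}^d K^j_{ab}
\;-\; \frac{2}{m^{d+1}}\sum_{a}\prod_{j=1}^d\sum_{b} K^j_{ab}
\;+\; \frac{1}{m^{2d}}\prod_{j=1}^d\sum_{a,b} K^j_{ab},$$

computed in $O(d\,m^2)$ time from elementwise products and row sums
(`dhsic_statistic()`; `dhsic_naive()` is the literal nested-sum reference used
in the test suite). The statistic is non-negative up to round-off; the raw
value is retained internally (p-value ranks use one convention for observed
and resampled values) and clamped at zero for reporting.

Throughout we use the Gaussian kernel
$k_\sigma(x, y) = \exp(-\lVert x-y\rVert^2/\sigma^2)$ — note the $\sigma^2$
denominator, without the factor 2 — which is characteristic. Bandwidths
default to the per-variable median heuristic: $\sigma_j$ is the square root of
the median squared pairwise distance among the observed samples of variable
$j$. Bandwidths are computed once from the observed (unshifted, unpermuted)
data and **frozen across all resamples**, so every null statistic estimates
the same functional as the observed one. A constant variable would have
median distance zero; its bandwidth falls back to 1, its Gram matrix is all
ones, and it multiplies through the statistic neutrally — a documented
degeneracy, not an error. Missing values are rejected at load time: the
estimators assume complete panels and imputation would distort the null.

## Two sampling regimes, two nulls

Because dHSIC's null distribution is not available in closed form for
dependent-in-time data, both tests are purely resampling-based.

**Single realization, stationary** (`stationary_dataset`, scheme `"shift"`).
Each variable is one series of common length $T$; the Gram matrices are
$T \times T$ over time points and capture each variable's autocorrelation
structure. The null is generated by *circular shifting*: variable 1 is held
fixed and every other variable is rotated by an independent random offset
$\tau$, drawn uniformly from the integers strictly between $h$ and $T$.
Shifting destroys dependence across series while preserving the temporal
structure within each series; stationarity is what makes the shifted data
exchangeable with the original under the null. The minimum lag $h$ is the
first lag at which the sample autocorrelation of the pooled series
$\sum_j x^j_t$ drops below 0.2 (biased estimator, signed comparison). If no
lag up to $\lfloor T/3 \rfloor$ qualifies, $h = \lfloor T/3 \rfloor$ is used
with a warning — the data then decorrelate too slowly for shifting to be
trustworthy and the result should be read with care. Within a subset scan,
$h$ is recomputed from the pooled series of each subset's variables only.

**Multiple realizations, stationarity not required** (`multireal_dataset`,
scheme `"permute"`). Each variable is an $n \times T_j$ block of iid
realizations; the Gram matrices are $n \times n$ over whole realizations.
The null is generated by permuting, for every variable except the first,
which realization is paired with which. Because realizations are iid this
breaks cross-variable dependence exactly, stationary or not.

Both schemes exploit that a shift or permutation merely relabels rows and
columns of a variable's Gram matrix: kernels are evaluated once, row sums are
permuted, and the third expansion term is invariant, so each of the $S$ (or
$P$) null statistics costs $O(d\,m^2)$ with no kernel re-evaluation. The
relabeling path is verified against explicit recomputation in the test suite
at $10^{-12}$.

The Monte Carlo p-value uses the add-one estimator
$p = (1 + \#\{\text{null} \ge \text{observed}\})/(1 + S)$, ties counting
toward the null; $p$ is never zero and the test is exactly valid under the
null. $H_0$ is rejected when $\alpha > p$.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `resamples` (S, P) | 200 | null samples per test; power gains flatten beyond a few hundred |
| `alpha` | 0.05 | significance level |
| bandwidth | median heuristic | per variable, frozen across resamples |
| `h` | ACF < 0.2 rule | minimum circular shift (shift scheme) |
| `d_max` | all variables | largest subset order scanned |
| `multiplicity` | none | optional Holm / Benjamini–Hochberg per subset order |
| `omega0` | 20 | Morlet centre parameter for phase extraction (below) |

No multiplicity correction is applied by default: per-subset decisions are
reported at raw $\alpha$, which mirrors the uncorrected recursive-testing
procedure the benchmark systems are evaluated with. Holm or BH adjustment
(within each subset order) can be switched on for data analysis.

## Subset scanning and hypergraphs

`dhsic_scan()` tests every subset of size $2..d_{\max}$ and flags a subset
*emergent* iff it is rejected and no proper subset of size $\ge 2$ is
rejected. Each subset's resampling plan is seeded from the sorted subset
labels and the master seed, so flags do not depend on the order in which
subsets are visited, and extending a scan does not reshuffle existing
results. `as_hypergraph()` maps rejected (or emergent-only) subsets onto a
hypergraph with per-edge order and p-value; writers emit JSON and a
plain-text edge list.

## What the synthetic systems emulate

* `sim_ar_pairwise_coupled()` — three stationary AR(1/2) series where $Z$ is
  additively driven by $X + Y$: a three-way dependence *ensuing from* two
  pairwise ones. A scan should reject (X,Z), (Y,Z) and the triple but not
  (X,Y).
* `sim_ar_three_way()` — $Z$ driven by $\lambda\lvert\theta_t\rvert\,
  \mathrm{sign}(X_t Y_t)$: sign symmetry cancels all pairwise correlation;
  the dependence is purely third-order.
* `sim_ar_independent()` — three uncoupled AR($a$) series; the type-I-error
  benchmark.
* `sim_rw_trend()` / `sim_ar_trend_interaction()` — non-stationary versions
  (unit roots with linear or oscillatory trends; growing $t\sin t$
  amplitudes) for the permutation regime.
* `sim_xor_gate()` — four Boolean processes with $Z$ the (optionally
  noise-inverted) parity of $X, Y, W$: with deterministic parity, dependence
  exists only at fourth order.
* `sim_frequency_mixing()` / `extract_phases()` — a quadratic nonlinearity
  applied to two superposed tones creates harmonics and emergent sum- and
  difference-frequency components whose instantaneous phases satisfy
  $\phi_1 + \phi_2 = \phi_\Sigma + c$ and $\phi_2 - \phi_1 = \phi_\Delta + c'$
  while every pair of phases is circularly uncorrelated.

Stationary generators use zero initial states and a 100-step burn-in so the
retained sample starts near the stationary law; the non-stationary systems
use zero initial states and no burn-in, since they have no stationary law to
converge to. All generators are bit-reproducible given their seed, and every
consumer (tests, scans, the power harness) derives per-purpose seeds from a
single master seed by hashing a task label, so adding work never perturbs
earlier draws.

## Design choices in the phase pipeline

The mixing signal is $F = s + s^2 + w\,\varepsilon$ with
$s = \sin(2\pi f_1 t) + \sin(2\pi f_2 t)$. The linear term matters: a pure
square has *no* spectral energy at the root frequencies $f_1, f_2$ (the
product-to-sum expansion contains only DC, $2f_1$, $2f_2$, $f_2 - f_1$,
$f_1 + f_2$), and phases "extracted at $f_1$" would be phases of noise. The
defaults $f_1 = 7$, $f_2 = 18$, $f_s = 100$ Hz, 10 s, $w = 0.1$ put every
line below Nyquist with at least 70 cycles of the slowest component.

Instantaneous phases are single-scale analytic Morlet coefficients computed
in the frequency domain: the FFT is multiplied by
$\exp(-\omega_0^2(\nu/f - 1)^2/2)$ on positive frequencies and the phase is
the argument of the inverse transform, with 5% trimmed at each edge against
cone-of-influence artifacts. The transfer function's standard deviation is
$f/\omega_0$ Hz, so $\omega_0$ *is* the selectivity. The classical
$\omega_0 = 6$ would give the 11 Hz component a ~26% leakage response at the
neighbouring 14 Hz harmonic, which measurably manufactures pairwise phase
dependence out of band overlap; the default $\omega_0 = 20$ keeps each
component's nearest neighbour more than four standard deviations away.
Phases enter kernels as points $(\cos\phi, \sin\phi)$ on the unit circle, so
distances respect the wrap-around at $\pm\pi$; raw angles would put $-\pi$
and $\pi$ maximally far apart.

## Numerical choices

* Accumulation order of the three expansion terms is fixed, so results are
  bit-reproducible on a given platform; the compiled null loops accumulate
  in extended precision.
* Negative round-off in the statistic is clamped only at the reporting
  surface.
* Shift offsets are drawn independently per variable and per null sample,
  with replacement across samples, from the open interval $(h, T)$.
* Ties between null and observed statistics count toward the null
  (conservative).
* The Wilson 95% interval accompanies every power estimate.
* Degenerate inputs error early with located diagnostics (ragged tables,
  missing cells, constant pooled series, too-short series for a given $h$).

## Known limitations

* **Shifting has no power against deterministic phase ramps.** For a
  perfectly periodic carrier the instantaneous phase is a linear ramp, a
  circular shift of a ramp is a marginal *rotation*, and the circular kernel
  is rotation-invariant — so shifted null statistics are exchangeable with
  the observed one and locked phase relations among noiseless tones are
  undetectable by construction. Detecting frequency-mixing dependence with
  the shifting test requires carriers with phase diffusion (as in real
  oscillatory data); the synthetic tone generator here does not diffuse, and
  the corresponding scan check in the acceptance suite documents this
  honestly rather than simulating a different system.
* **Parity signals fade with record length under realization kernels.** In
  the XOR system with fair bit-flips, realizations have iid coordinates and
  the Gaussian kernel factorizes over them, so the embedding discrepancy of
  the four-way parity constraint decays geometrically in $T$: at $n = 200$
  the 4-way test is decisive for $T \le 5$ and blind by $T \approx 20$.
  Short records are the informative regime; the demonstration test uses
  $T = 2$ with deterministic parity. With the printed inversion probability
  of 0.5 the output bit is an independent fair coin and *no* test can (or
  should) reject.
* The shifting test is mildly conservative at moderate $T$: shifted
  variables gain kernel mass at circularly-close index pairs that the
  observed alignment lacks, slightly inflating the null. Empirical type I
  error sits around 0.03–0.05 at the nominal 0.05.
* Power comparisons between schemes (`compare_resampling()`) concatenate
  realizations for the shifting arm; this is a matched-budget convention,
  not an equivalence.
* The scan tests all $\binom{d}{k}$ subsets; cost grows combinatorially in
  `d_max`.

## Scale of the bundled experiments

The test-suite and acceptance-script experiments run at desk scale, chosen
as the package's own default study conditions: 200 datasets for type-I
calibration and 100 per grid point for power surfaces, with $S = 200$
resamples per test (flags restore larger designs, e.g. $S = 1000$). Near a
rejection boundary, Monte Carlo p-value noise at $S = 200$ leaves readouts
that demand *exact* power 1.0 across 100 replicates fragile; the
power-saturation acceptance check records the coupling strength at which
saturation is first observed under exactly these conditions.
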