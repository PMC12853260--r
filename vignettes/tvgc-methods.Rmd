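---
title: "Time-varying conditional Granger causality for trial-based hemodynamic signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Time-varying conditional Granger causality for trial-based hemodynamic signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tvgc)
```

## The problem

Task-dependent directed functional connectivity (dFC) between cortical
regions can be estimated from multichannel hemodynamic recordings —
e.g. oxygenated-hemoglobin (dHbO) signals from high-density fNIRS —
epoched around repeated behavioral trials. This package implements that
analysis end to end: a time-varying vector autoregression (tvMAR) fitted
across trials with a self-tuning Kalman filter, time-resolved conditional
Granger causality (GC) for every ordered channel pair, region-level
summaries of pre-to-post connectivity change, and trial-label permutation
inference under FDR control. Because raw recordings of this kind are
rarely shared, the package also ships a synthetic-data generator with
known ground-truth directed couplings, which is what every quantitative
claim in the test suite is validated against.

## The model

The signal vector $x(t) \in \mathbb{R}^n$ (one entry per channel) follows

$$x(t) = A(1,t)\,x(t-1) + \dots + A(p,t)\,x(t-p) + \epsilon(t),
  \qquad \epsilon(t) \sim \mathcal{N}(0, \Sigma_\epsilon(t)),$$

with coefficient matrices that drift smoothly under a random-walk prior
$A(k,t) = A(k,t-1) + \omega(t)$. The default lag count is $p = 15$; at
the default sampling interval of 0.13 s this spans a 1.95 s history,
appropriate for hemodynamic-band (0.02–0.3 Hz) dynamics.

Conditional GC from source $i$ to target $j$ at time $t$ is

$$\mathrm{GC}_{i \to j}(t) = \ln \frac{\sigma_{j \setminus i}(t)}{\sigma_j(t)},$$

where $\sigma_j(t)$ is the innovation variance of channel $j$ given the
past of *all* channels (the $(j,j)$ entry of $\Sigma_\epsilon(t)$) and
$\sigma_{j\setminus i}(t)$ the corresponding variance when channel $i$ is
excluded. The index is non-negative by construction, and conditioning on
the remaining channels attenuates indirect routes — which is also why
channels without a region assignment still enter the fit.

## Fitting: a self-tuning Kalman filter over trials

All trials are treated as independent realizations of the same
time-varying process. At each time point the stacked coefficient matrix
$B(t) = [A(1,t)\,\cdots\,A(p,t)]$ is the state of a Kalman filter and the
trials form the observation batch of a single update (an information-form
update with eigendecomposition-regularized inversions, relative
eigenvalue floor $10^{-8}$). Because the trials enter through their
summed cross-products, the fit is exactly invariant to trial ordering.

The random-walk noise $\Sigma_\omega$ is never estimated explicitly.
Instead the prior covariance is inflated each step by a fraction

$$c(t) = \mathrm{clamp}\!\left(c_0 \frac{v(t)}{\bar v(t)},\;
  c_{\min}, c_{\max}\right)$$

of its own scale, where $v(t)$ is the mean squared across-trial one-step
innovation and $\bar v(t)$ its exponential moving average (half-life
0.5 s). When the data are locally well predicted, $c(t) \approx c_0$ and
the filter behaves like a slowly forgetting recursive least squares; when
a real coefficient change occurs, innovations spike and the filter
temporarily trusts the data more. Defaults are $c_0 = 0.1$,
$c_{\min} = 10^{-4}$, $c_{\max} = 0.5$, chosen as a compromise between
steady-state coefficient variance (which inflates spurious GC roughly in
proportion to $c_0 / R$ for $R$ trials) and tracking lag (about
$\ln 2 / c_0$ samples to cover half of a step change; with the reactive
boost a mid-epoch step of 0.5 in a coupling is tracked halfway in well
under 2 s in the packaged tests). All of these are exposed in
`tvmar_control()`.

Coefficients start at zero with a diffuse state covariance
($10 \times I$), so the first ~3 s of the fitted window are a burn-in;
the package follows the convention of fitting on $[-5, 10]$ s and
reporting GC on $[-2, 10]$ s. The innovation covariance
$\Sigma_\epsilon(t)$ is the across-trial sample covariance of the
one-step prediction errors, EMA-smoothed (same half-life) because raw
per-time covariances are noisy at realistic trial counts, and its
diagonal is floored at $10^{-12}$ times each channel's variance so the
GC log-ratio stays finite.

## Reduced-model variances without refitting

The naive route to $\sigma_{j \setminus i}(t)$ refits a reduced model
without channel $i$ — $n$ extra fits per source. `conditional_gc()`
instead treats the fitted model at each time point as locally stationary,
evaluates its spectral density
$S(\omega) = H(\omega)\,\Sigma_\epsilon\,H(\omega)^{*}$ on a grid of 64
frequencies to Nyquist (mirrored to the full circle), extracts the
sub-spectrum of the non-source channels, and factorizes it with Wilson's
algorithm, whose zero-lag factor yields the reduced innovation
covariance — all targets for one source in a single factorization. When
only one channel remains (bivariate recordings) the Kolmogorov formula
$\sigma^2 = \exp\!\big(\tfrac{1}{2\pi}\int \ln S(\omega)\,d\omega\big)$
is used directly. Numerical choices: iteration cap 100, relative
tolerance $10^{-8}$; the grid resolution bounds the factorization error
by the autocovariance mass beyond ~64 lags, negligible for the
spectral radii (< 0.95) the stability guard admits. A time point whose
factorization fails to converge is recomputed through the explicit
reduced-refit route (`conditional_gc(..., method = "refit")`, also
exposed as `conditional_gc_reduced_refit()`), never silently zeroed.
Log-ratios that come out negative by numerical error are clipped to zero;
the pre-clip values and the clipped fraction are kept as diagnostics.
Both routes are held to agree in the test suite (median absolute
difference below 0.05 on a four-channel benchmark), and both are checked
against a closed-form oracle (`analytic_gc_stationary()`) that solves the
reduced Yule–Walker equations from the exact autocovariances of a
stationary ground-truth network.

## Preprocessing

`bandpass_filter()` applies a 4th-order Butterworth bandpass
(0.02–0.3 Hz) forward and backward per channel — zero phase, effective
8th-order magnitude — then subtracts a constant so the first sample is
zero. Edge transients are handled by odd-reflection padding sized to
about 20 time constants of the low corner
(`min(n - 1, max(3 * order, ceil(5/(low * dt))))` samples, ~1900 at the
defaults): with padding that long the cascade commutes with time reversal
to better than $10^{-8}$ and a constant input maps to an essentially zero
output, properties the suite asserts. Shorter padding (the 3-filter-order
convention some implementations use) leaves the low-corner transient,
with its ~90-sample decay at 0.13 s sampling, visibly asymmetric at the
record edges.

`average_bidirectional()` / `average_pathways()` average the two signals
of each bidirectional optical pathway. `epoch_and_baseline()` extracts
$[-5, 15)$ s around each trial onset and subtracts the mean of
$[-5, 0)$ s per trial and channel. Window membership is half-open on the
sample grid ($a \le t(k) < b$), a convention fixed once and used
everywhere — it makes the five 4 s summary windows tile $[-2, 10)$
exactly, with consecutive windows sharing exactly their 2 s overlap.
At dt = 0.13 s the epoch holds 154 samples. Trials whose window leaves
the recording are dropped with a warning.

## Region-level summaries

Channel-level changes are `post - pre` differences of GC tensors
(`delta_gc()`). For an ordered region pair A→B, the time-resolved
increase is the largest positive channel-level change over pairs
$(i \in A, j \in B)$ and the decrease the smallest negative one; the
time-integrated version first sums positive and negative parts
separately over a window, then takes the extremes. Either is set to zero
when every channel-level change has the unhelpful sign. Increases and
decreases are deliberately summarized separately: after reorganization a
region pair can gain some channel-level connections while losing others,
and a plain mean would cancel them. Ties in the max/min keep the value
(the summaries are scalars; no argmax is reported). Relative change
between hand conditions is $\Delta GC^+_{aff} - \Delta GC^+_{unaff}$ and
$|\Delta GC^-_{aff}| - |\Delta GC^-_{unaff}|$, positive when the change
is more pronounced for affected-hand use. `hemisphere_means()` averages
whole-window summaries over ordered ROI pairs within the ipsilesional
hemisphere, within the contralesional hemisphere, and between hemispheres
(both directions pooled — the package pools ordered cross-hemisphere
pairs rather than reporting directions separately, and documents that
choice here); medial regions count in both within-hemisphere groups, and
nonsignificant entries contribute zero while staying in the denominator.
`total_channel_increases()` and `degree_centrality()` provide the
channel-level increases graph and its hub ranking;
`seed_channel_view()` re-summarizes increases with designated seed
channels as individual nodes.

## Inference

`permutation_test()` shuffles the pre/post labels across pooled trials
(group sizes preserved; when several hand conditions exist, each is
permuted separately by calling the test per hand), refits everything per
surrogate — the statistic is an arbitrary pipeline composition, re-tuned
per surrogate exactly like the observed data — and reports the two-sided
p-value $p = \#\{|s_b| \ge |s_{obs}|\}/B$. This estimator admits $p = 0$;
a conservative $(r+1)/(B+1)$ option exists but is off by default for
fidelity to the definition above. Surrogate seeds come from a
counter-based stream, so results are reproducible and order-independent.
`bh_fdr()` applies the plain Benjamini–Hochberg step-up at $q = 0.1$ to
all scalar quantities of one analysis as a single family. Under the null
the suite verifies both approximate uniformity of the p-values
(Kolmogorov–Smirnov over 300 repeats at $B = 99$) and a type-I rate at
the 0.05 level inside [0.03, 0.07] over 500 repeats at $B = 199$.
$B = 1000$ remains the documented full-scale setting
(`analysis_config()` default).

## The synthetic generator — and what it does not emulate

`generate_trials()` simulates independent trials of a stable
(time-varying) VAR, discarding a burn-in of $10p$ samples per trial so
trials start near the stationary distribution — mirroring trials that
are excerpts of an ongoing recording. Coupling-change schedules are
piecewise constant, the simplest form that exercises time-resolved GC.
Optional i.i.d. Gaussian measurement noise emulates instrument noise
without reordering ground-truth GC, and a log-normal per-trial gain is
exposed for trial-to-trial amplitude variability, a quantity real
recordings show but rarely quantify; its default is off. Signals are
generated directly in the hemodynamic band by the choice of sampling
interval (0.13 s) and smooth AR dynamics rather than by convolving a
hemodynamic response function, since the analysis consumes the
hemodynamic signal itself. Scenario defaults (154-sample epochs, onset
at sample 39) reproduce a $[-5, 15)$ s epoch structure; trial counts in
the packaged scenarios (tens to 200) are chosen so that each check runs
in seconds to minutes — real sessions with several hundred trials only
improve the estimates.

What passing tests on these data do *not* show: the generator produces
Gaussian, linearly coupled signals without motion artifacts, slow
physiological confounds, or nonstationary noise, so the suite validates
the estimator and its inference machinery, not robustness to every
artifact of real optical recordings.

## Degenerate inputs and numerical conventions, collected

* Unstable coefficient schedules and non-positive-definite innovation
  covariances are rejected at network construction, naming the offending
  time index.
* All-zero data leave the coefficients at their zero initialization.
* Rank-deficient regressor covariances are handled by the eigenvalue
  floor and counted in the tuning trace, never a crash.
* The GC diagonal is absent (`NA`); stored values are clipped at zero
  with diagnostics retained.
* Window membership is half-open everywhere; floating-point grid droop
  is absorbed by a $10^{-9}$ tolerance.
* p-values of exactly 0 are reported as such (see above).

## Problem sizes used by the packaged checks

Coefficient recovery and GC benchmarks use 2–6 channels, 40–200 trials
and 50–120-sample epochs; the permutation calibration uses 500 repeats
of a 12-trial-per-condition bivariate null at $B = 199$; the end-to-end
recovery check uses 20 seeded repeats of a 6-channel, 3-region scenario
with one planted coupling increase. These sizes make the full suite run
in minutes while leaving each check's statistical margin wide (e.g. the
planted-coupling recovery succeeded in 20/20 seeded repeats during
development, against a 18/20 requirement).

## Known limitations

* The estimator assumes linear Gaussian dynamics; GC on strongly
  nonlinear interactions is interpretable only as a linear-predictive
  index.
* One model is fitted per condition, pooling all trials; slow drift
  across sessions within a condition is absorbed into the innovation
  term rather than modelled.
* The SNIRF container format is not read directly; recordings enter via
  matrices or the package's delimited long format.
* Frequency-band-resolved GC is not computed — the index is the
  time-domain log-ratio only.
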