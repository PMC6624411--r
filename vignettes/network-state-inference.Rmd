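---
title: "Switching-AR inference of neural network states: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Switching-AR inference of neural network states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netstates)
```

## The generative model and its assumptions

`netstates` models a trial of `D`-channel neural activity `x_t` as a
hard-switching linear dynamical system. A discrete latent state
`z_t ∈ {1..K}` evolves as a first-order Markov chain with transition
matrix `Φ`; conditional on the state, the observation follows a
state-specific multivariate autoregression of order `P`:

$$x_t = \sum_{\tau=1}^{P} A_{z_t\tau}\, x_{t-\tau} + \mu_{z_t} +
        Q_{z_t}^{1/2} v_t, \qquad v_t \sim \mathcal N(0, I).$$

The assumptions this buys and the price paid:

* **Piecewise-linear dynamics.** Within a state the dynamics are linear
  and Gaussian; all nonlinearity is carried by the switching. This keeps
  inference exact given the state sequence and makes each state
  interpretable as a directed (Granger-style) network through its lag
  tensor `A_z`.
* **Activity-independent switching.** The chain `z_t` evolves
  independently of `x_t`. Consequently state dwell times are
  geometrically distributed a priori, and the model cannot represent
  interactions whose switching is driven by the signal itself; the
  posterior can still concentrate on non-geometric dwell patterns when
  the data demand it.
* **Conditional likelihood.** The first `P` samples of every trial are
  conditioned on, not modeled. This is the standard AR-HMM treatment: it
  avoids computing a stationary distribution per state (which need not
  exist near the stability boundary) at the cost of `P` samples of
  evidence per trial. The latent chain still runs over the full trial,
  with flat emission evidence on the first `P` steps.
* **Trials are i.i.d. sequences** sharing one parameter set. Pooling
  across trials (or subjects, by concatenating their trial lists) is
  therefore a data operation, not a model change.

## Estimation

Parameters are fit by Baum–Welch EM. The E-step runs a scaled
forward–backward pass per trial (compiled; per-step normalization plus
per-row max-subtraction of the emission log-densities keeps the
recursion finite for sequences up to at least $10^5$ samples — checked in
the tests). The M-step solves, for each state, the
responsibility-weighted least-squares regression of `x_t` on its `P`
lags and an intercept, pooled over all trials; `Q_z` is the weighted
residual covariance.

The transition estimate is the row-normalized sum of pairwise posterior
marginals, then smoothed by the sticky map

$$\Phi_{\text{smooth}} = \frac{\Phi + uI}{1+u},$$

which leaves the identity fixed, floors the diagonal at `u/(1+u)`, and
for `u = 0` is the identity map. The default `u = 0.5` encodes a weak
preference for dwell over switching (diagonal mass at least 1/3) without
forcing any particular time constant. The smoothing is applied at every
M-step, which is a pseudocount (MAP-style) reading of the prior. Because
the smoothed update is not the exact maximizer of the EM surrogate, the
log-likelihood trace is not *guaranteed* monotone; in practice decreases
are rare and tiny (the test suite asserts non-decrease within a `1e-8`
relative tolerance across 20 seeded fits at the reference design, and
the fit driver warns if a decrease ever exceeds that tolerance rather
than silently continuing).

Numerical and degenerate-input choices:

* `Q_z` estimates are symmetrized and, for `K > 1`, ridged by
  `1e-6 · (mean data variance) · I` to guard against collapse of
  low-responsibility states. A single-state fit receives no ridge, so it
  coincides exactly with pooled multivariate OLS (asserted to `1e-8`).
* A state whose total responsibility falls below roughly one regression's
  worth of samples (`PD + D + 1`) keeps its dynamics, has its bias
  re-seeded near the global mean, and triggers a warning.
* Viterbi ties break toward the lower state index. State labels are
  arbitrary; every comparison against ground truth first finds the best
  label permutation by exhaustive search over the `K!` possibilities
  (exact for the `K ≤ 8` regimes this package targets).
* Convergence: relative log-likelihood change below `1e-6`, at most 200
  iterations, 3 restarts by default (the first from the windowed-MVAR
  initialization, later ones from seeded jitter of it).

### Initialization

EM on switching models is multimodal, so the starting point matters. The
package follows the field's windowed-MVAR convention: fit MVAR models in
100-ms windows stepped by 50 ms, pooling trials at fixed latency; k-means
(Euclidean metric, 10 restarts, seeded) clusters the flattened
coefficient tensors; each cluster is refit by pooled least squares and
becomes one state. Clustering uses coefficients only by default —
including the residual covariances is a flag (`includeCov`) — because
the coefficient tensors carry the directed-network structure the states
are meant to capture. The window pooling embodies exactly the
fixed-latency assumption the ARHMM then relaxes, which is what makes it
a good initializer and a poor final estimator. State biases receive a
seeded Gaussian jitter of 1% of the data standard deviation to break
symmetry between clusters that tie.

### Model selection

`selectModel()` sweeps state count and AR order, scoring each fit by BIC
on all trials, with the parameter count
`K(PD² + D + D(D+1)/2) + K(K−1) + (K−1)` and `N = Σ(T − P)` regressed
samples, plus the mean per-sample log-likelihood on a held-out trial
fraction (default 20%). On well-separated synthetic data BIC recovers
the generating `K` in ≥ 8/10 seeds (asserted).

## Connectivity summaries

Each state's directed network is reported as partial directed coherence:
the column-normalized frequency response of the state's AR operator.
Entry `(j, k)` is the outflow from channel `k` to channel `j` as a
fraction of `k`'s total outflow, so every column satisfies
`Σ_j |π_jk(f)|² = 1` (asserted to `1e-10`). The magnitude `|π|` is
integrated over frequency — magnitude, not squared magnitude, and a
trapezoidal rule on a 256-point grid over `[0, rate/2]` by default; the
grid is configurable and halving its spacing moves smooth integrals by
less than `1e-3` (asserted). Networks are compared by the Frobenius
distance between Frobenius-normalized integrated-PDC matrices, a
scale-invariant score in `[0, 2]`. Exported edge lists drop self-loops
by default: the within-channel AR diagonal is always strong and would
dominate any graph display of *inter*-regional flow.

## Preprocessing

The pipeline order is fixed: common-average reference → band-pass
Hilbert power → baseline normalization → resampling → reaction-time
selection (→ optional region meta-electrodes). Tunables, with defaults:

| parameter | default | units | role |
|---|---|---|---|
| band edges | 60–120 | Hz | broadband gamma; site-specific, so configurable |
| flank half-width | 1 | Hz | logistic rise/fall of the band-pass gain |
| baseline window | (−0.7, −0.2) | s vs stimulus | prestimulus power reference |
| target rate | 200 | Hz | analysis rate after anti-aliased resampling |
| RT window | (0.6, 2.8) | s | strict bounds; drops lapses and anticipations |
| AMVAR window / step | 0.1 / 0.05 | s | initialization windows |
| stickiness `u` | 0.5 | — | self-transition pseudocount weight |
| majority filter | 0.2 | s | state-raster smoothing window |
| duration interval | (0, 3.2) | s vs stimulus | cumulative state durations |
| offset window | 0.1 | s | language-state termination scan |

The band-pass is implemented in the frequency domain: positive
frequencies are shaped by the product of two logistic flanks and
doubled, negative frequencies zeroed, so the inverse transform is the
analytic signal and its squared magnitude the instantaneous band power.
Resampling is polyphase: zero-stuffing, a windowed-sinc FIR low-pass at
the target Nyquist with exactly normalized DC gain, then decimation;
edges are replicated so constants resample to themselves. Region
meta-electrodes are the leading principal component of the region's
channels over pooled trials and samples, computed on per-channel
standardized data so one hot electrode cannot dominate, with the sign
fixed to positive mean loading.

## The simulator: what it emulates, and what it does not

`simConfig()` + `makeGroundTruthParams()` + `simulateDataset()` generate
the robustness-study conditions: 3 states × 6 channels, AR order 2,
100 trials of 400 samples at 200 Hz by default. Per-state lag tensors
are drawn as sparse Gaussian matrices rescaled to a companion spectral
radius in 0.7–0.95 (stable but lively), rejection-sampled until all
state pairs differ by more than 0.1 in integrated-PDC dissimilarity.
Three schedule modes: `markov` (chain sampling), `fixed_blocks`, and the
default `variable_blocks` — an ordered pass through the states with
trial-varying gamma-distributed durations, emulating trial-to-trial
timing variability. Two controlled mismatches mirror the robustness
design: mean-dependent process noise,
`σ_t = σ_0 (1 + α |mean_c x_{c,t−1}|)` with default `α = 0.5` (a
monotone, bounded-below, single-knob injector), and additive white
observation noise calibrated so each channel's variance ratio
`var(signal)/var(noise)` equals the requested SNR (the model's own SNR
definition; the mean over channels then equals it too). Events are
synthesized so that the designated language state's duration *is* the
trial's reaction time, which gives the behavioral-correlation analyses a
known answer.

What passing tests on this simulator do **not** show about real
recordings: real broadband gamma is nonnegative, heavy-tailed and
nonstationary within states; real state transitions can be
activity-dependent and non-geometric; real electrodes share common
artifacts that are neither white nor mean-dependent. The simulator
operates at the band-power level the model consumes — it does not
synthesize raw voltage traces with spectral content. Recovery numbers
here are best read as "the estimator works when its assumptions hold,
and degrades gracefully under the two mismatches we inject", not as
expected field performance.

At observation SNR 3 the recovered networks carry a visible
errors-in-variables attenuation: a least-squares fit on noisy
regressors shrinks toward zero, and an oracle that knows the true state
sequence shows the same integrated-PDC dissimilarity to the truth as
the ARHMM estimate does (about 0.2–0.35 depending on the draw). This
bias is a property of fitting an AR model through unmodeled observation
noise, shared by every method in this family, and disappears on the
noiseless signal (oracle dissimilarity ≈ 0.02).

## Problem sizes used by the test suite

The suite runs at desk scale, chosen so the full run stays within a few
minutes on one CPU while keeping every assertion meaningful: exact
inference is cross-checked against exhaustive path enumeration on
sequences up to `T = 8, K = 3`; EM monotonicity across 20 seeded fits of
the reference design (3 states, 6 channels, order 2, 50 trials × 400
samples); the robustness study at the simulator's default size
(100 trials × 400 samples) across SNR ∈ {0.3, 1.5, 3, 30}; model
selection across 10 seeds at 30 trials × 300 samples; whiteness
self-tests across 20 seeded fit-then-resimulate rounds. The acceptance
script repeats the headline computations from scratch at the same sizes.

## Known limitations

* Point-estimate EM: no posterior over parameters, hence no uncertainty
  on the networks themselves (only on the state sequences, via the
  responsibilities).
* Geometric dwell-time prior, softened but not removed by stickiness.
* Observation noise is unmodeled; at low SNR the state sequence can stay
  recoverable while the network estimates attenuate (see above).
* The HDF5-style container is not provided; the plain-text CSV-directory
  container is the supported interchange format.
* No artifact or epileptiform detection: channel and trial screening is
  assumed upstream.
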