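---
title: "Models and methods behind dynclicks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind dynclicks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dynclicks)
```

# The task and its generative model

The dynamic clicks task asks a subject to report which of two hidden
environmental states is active at the moment of a go cue.  The hidden
state is a telegraph process switching at hazard rate $h$ (default
1 event/s); state 1 ("go right") plays Poisson click trains at 38 Hz
from the right speaker and 2 Hz from the left, state 2 swaps them.
Stimulus durations are uniform on $[0.5, 2]$ s and the state freezes at
the go cue.  `generate_trial()` simulates the telegraph with exponential
inter-event waits (exact at any duration) and draws clicks per state
epoch as a Poisson count placed uniformly, which is an exact sampler for
a homogeneous Poisson process on the epoch.

Under these defaults the analytic state-change distribution is 31.4%
of trials with no change, 33.6% with exactly one, 35.0% with more than
one, and 1.25 changes per trial on average — the quantities the task
statistics check in `tests/` and `scripts/acceptance.R` recompute by
simulation.

# The accumulation model

The decision variable $a$ integrates clicks with five noise/dynamics
parameters and three decision parameters
(see `model_params()`):

$$da = (\delta_R \eta_R C - \delta_L \eta_L C)\,dt - \lambda a\,dt +
\sigma_a dW,$$

with per-click sensory adaptation

$$\frac{dC}{dt} = \frac{1 - C}{\tau_\phi} +
(\phi - 1)\,C\,(\delta_R + \delta_L).$$

A click's effective magnitude is the value of $C$ immediately before the
click; the click then multiplies $C$ by $\phi$ ($\phi < 1$ depresses
successive clicks, $\phi > 1$ facilitates), and $C$ relaxes back toward 1
with time constant $\tau_\phi$.  The first click of a trial always has
unit weight.  `adapt_clicks()` evaluates this recursion in closed form
between clicks; an independent micro-stepped ODE integration is used as
the test oracle.

Because the SDE is linear given the stimulus, the accumulator is
Gaussian at every time with closed-form moments (`forward_moments()`):
the mean is the discounted signed sum of adapted magnitudes and the
variance accrues the initial variance $\sigma_i^2 e^{2\lambda t}$, the
memory term $\sigma_a^2 (e^{2\lambda t} - 1) / 2\lambda$, and one
per-click term per click.  All $\lambda \to 0$ limits are handled by
series expansion of $(e^x - 1)/x$.

**Per-click noise convention.**  Written as multiplicative unit-mean
noise on the adapted magnitude, a click's noise variance would scale as
$\sigma_s^2 C^2$; the variance recursion printed alongside the model in
the literature instead accrues $\sigma_s^2 C$.  The two only differ when
$\phi \neq 1$.  We default to variance $\propto C$ and expose
`var_convention = "C2"` as a switch; crucially, the simulator draws its
per-click noise under the *same* convention as the analytic moments, so
the oracle-equivalence tests hold under both settings.

**Choice and likelihood.**  The choice is right when the final
accumulator exceeds the boundary $B$, mixed with a lapse probability
$l$ of a fair coin.  The likelihood of a choice is the Gaussian tail
probability above $B$ mixed with $l/2$; `fit_parameters()` maximizes the
product over trials with half-Gaussian priors on $\sigma_i^2$ and
$\sigma_a^2$ (SD 30 by default; the scale is configurable because no
canonical value is available), bounded L-BFGS-B with optional
multi-start, a probability floor of $10^{-10}$ inside the logarithm,
and standard errors from the inverse numeric Hessian.  Parameters that
finish on a bound are excluded from the Hessian inversion (they have no
interior curvature) and reported without standard errors.

**Exact simulation.**  `simulate_agent()` and `simulate_ensemble()` do
not Euler-step the SDE: between clicks the process is an
Ornstein-Uhlenbeck bridge whose transition is known exactly, so paths
are sampled at grid points (or click-to-click) with *zero*
discretization bias at any step size.  This matters for parameter
recovery at $n = 50{,}000$ trials, where the standard errors are small
enough that an Euler bias would dominate; it also makes the
Monte-Carlo ensembles a clean oracle for the analytic moments.

# The posterior over the accumulator

Conditioning the forward distribution on the observed choice yields the
posterior used by all neural analyses.  The forward density $f(a)$
carries the initial-condition constraint; a *backward* distribution
$b(a)$ carries only the final constraint that $a_N$ lies on the chosen
side of $B$.  $b$ is approximated by a mixture: a unit of probability
mass on each point of a grid $B + (j - \tfrac12)\Delta a$ on the choice
side (half-step offsets avoid double-counting the boundary), truncated
at $12\times$ the maximum forward SD, each mass evolved backward in
time by inverting the affine accumulation map.  Adaptation is a
property of the stimulus, not of the latent path, so the forward
adapted magnitudes are reused.  The posterior is the per-time
normalized product $f \cdot b$.

Since every backward component is Gaussian with a shared variance, each
product slice is itself a Gaussian mixture in closed form; weights are
normalized per slice by log-sum-exp.  Three numerical choices matter:

* **Cell smearing.**  A component stands for a grid *cell* of width
  $\Delta a$, so its posterior image is convolved with the affine image
  of that cell (a Gaussian ⊗ uniform convolution with closed-form CDF).
  Without this, the final slice — where the backward variance vanishes
  and the mixture degenerates to a comb of point masses — is unstable
  under grid refinement.  With it, halving $\Delta a$ changes slice
  masses by well under $10^{-3}$ total variation, and no mass ever
  leaks across $B$ at the final time because the uniform cell overlap
  is exact there.
* **Component truncation.**  Components with posterior weight below
  $10^{-9}$ are dropped per slice before the CDF evaluations (error
  bounded by $J \times 10^{-9}$, removed by renormalization).
* **Default spacing** $\Delta a = 0.1$: refinement experiments show
  the final-slice error is $O(\Delta a^2)$, and 0.1 reaches the
  $10^{-3}$ total-variation stability level.

The lapse process is deliberately *not* part of the conditioning: the
posterior assumes the choice was read from the accumulator.  The
posterior mean trace needed for change-of-mind detection has a closed
form (mixture weights times component means), so the 1 ms trace is
computed without any accumulator grid (`posterior_mean()`).

For the tuning analyses the posterior mass in the coarse accumulator
bins is likewise evaluated analytically per time slice
(`posterior_coarse_mass()`), which is exact where the fine-grid
evaluate-then-downsample procedure (`posterior_grid()` +
`downsample_posterior()`, also provided) is approximate; the two paths
are cross-checked in the tests.  Tuning analyses evaluate slices every
5 ms within each 25 ms bin; 1 ms changes results only in the fourth
decimal and triples the cost.

# Behavioral assays

* **Ideal observer** (`ideal_observer_logodds()`): the exact
  discrete-time Bayesian filter on the telegraph process, applied at
  1 ms.  Because both states share the same total click rate, each bin's
  likelihood update reduces to $\kappa (n_R - n_L)$ with
  $\kappa = \log(r_{\text{high}} / r_{\text{low}})$, followed by the
  hazard transition; the continuous-time limit is
  $\dot a = \kappa(\delta_R - \delta_L) - 2h \sinh a$.  The filter is
  validated against exhaustive enumeration of state paths on a coarse
  chain.  Its final log-odds is the canonical psychometric predictor.
* **Psychometric curve** (`psychometric()`): 10 quantile bins, Wilson
  95% intervals (the interval method is unspecified in the source
  material; Wilson behaves well in saturated bins), and a model overlay
  that averages `choice_prob()` within the same bins.
* **Chronometric curve** (`chronometric()`): accuracy against
  final-state duration, grouped by 0 / 1 / >1 state changes.
* **Reverse correlation** (`reverse_correlation()`): causal 5 ms
  Gaussian smoothing of the click difference, subtraction of the
  state-conditional expectation $\pm(r_{\text{high}} -
  r_{\text{low}})$, choice-conditioned averaging aligned to trial end
  over a 500 ms window (the shortest trial; configurable), and
  normalization of each kernel to integrate to one over that window.
  A leaky agent produces the characteristic upweighting of late
  clicks; a non-leaky agent on a stationary stimulus produces a flat
  kernel.

# Neural analyses

Firing rates are 25 ms binned counts smoothed with a causal one-sided
Gaussian (SD 100 ms, truncated at 4 SD, renormalized), so spikes never
influence earlier bins; stimulus-aligned rates are masked after the
movement and movement-aligned rates before stimulus onset.  Cells are
*active* above 1 Hz mean rate from 1 s before stimulus onset to
movement, and *pre-movement side-selective* when stimulus-to-movement
spike counts differ by choice (two-tailed Welch t-test at 0.05; the
pooled-variance variant is not materially different here, Welch is the
safer default).  Choice selectivity over time uses the rank-based AUC
per bin with significance from 250 label permutations (add-one rule,
two-tailed by min-tail doubling) and a latency defined by 8 consecutive
significant bins.

**Tuning maps.**  The joint distribution of rate, accumulator value,
and time uses 25 ms time bins, 100 rate bins spanning the unit's
range, and 10 accumulator bins — 8 inner bins of width 1.625 about
zero plus two unbounded tail bins.  (The source material widens only
"the last" bin; both tails need capture once left- and
right-preferring cells are pooled, so the symmetric layout is used.)
Each trial contributes its posterior mass at each valid time bin to
the rate bin holding its average rate in that bin; slabs are
normalized by contributing-trial count.  The conditional expectation
$E[r\,|\,a,t]$, the residual after removing the $P(a|t)$-weighted
slice mean, and the time-averaged tuning curve follow.  The rank-1
SVD approximation reports variance explained $s_1 / \sum_i s_i$, a
temporal gain $\hat m(t) = u_1 s_1\,\mathrm{range}(v_1)$ and a
unit-range tuning curve $\hat f(a) = v_1 / \mathrm{range}(v_1)$,
oriented toward the unit's preferred side.  Masked cells are
zero-filled when they cover under 5% of the map, otherwise the worst
rows/columns are dropped.  Population maps average per-cell z-scored
residual maps (z-scored over unmasked stimulus-to-movement bins) after
inverting the accumulator axis of left-preferring cells; cells
contribute only to time bins with at least 10 trials.

**Changes of mind.**  Model-predicted state changes are crossings of
$B$ by a centered 100-sample running average of the 1 ms posterior
mean (a trailing average would date every crossing half a window
late), excluding the first and last 200 ms and crossings that
immediately reverse, formalized as: the 100 ms pre/post means of the
smoothed trace must sit on the old/new side of $B$, and the
finite-difference slope over ±10 ms at the crossing must have the new
state's sign.  State-change triggered responses realign residual
rates (rate minus its across-trial mean at each time point) to events
shifted by a 100 ms response lag, mask data beyond the neighboring
events, and average by change direction relative to each unit's
preferred side; discriminability is d′ with event-count-weighted
pooled SD and direction-label permutation significance.
State-change-aligned tuning maps rebuild the joint in event-relative
time, excluding ±300 ms around the event where the posterior is too
narrow to estimate tuning.

# What the synthetic data emulate — and what they do not

Synthetic units fire as inhomogeneous Poisson processes (exact
thinning at 1 ms rate resolution) with rate
$\max(0, \text{baseline} + m(t - \text{lag}) f(a(t - \text{lag})))$:
a bounded sigmoid of the *true* latent accumulator times a gain that
rises linearly to its plateau at 0.5 s — the earliest possible go cue
— with a 100 ms response lag.  The default population is 60% tuned
(half per side) and 40% untuned.  Default agent parameters are
$\sigma_i^2 = 0.2$, $\sigma_a^2 = 1$, $\sigma_s^2 = 0.5$,
$\lambda = -3$/s (a leaky regime of the same order as optimal for
this hazard rate and click signal-to-noise), $\phi = 0.5$,
$\tau_\phi = 0.2$ s, $B = 0$, lapse 0.05.  These were chosen once as
the study conditions: they give psychophysically sensible accuracy
(~80%), accumulator excursions that span the tuning bins, and
frequent changes of mind.

Passing tests on these data show that the estimators recover a known
separable, lag-shifted, accumulator-driven code from Poisson spikes.
Real recordings differ in ways the generator deliberately omits:
non-Poisson spiking and history dependence, heterogeneous and
non-separable tuning, movement- and reward-locked dynamics,
session-level nonstationarity, and the gap between the fitted and the
true generative model of behavior.  Recovery here is therefore a
correctness check of the machinery, not evidence about cortex.

# Problem sizes and test design

The test suite and the acceptance script regenerate everything from
seeds: 100,000 trials for task statistics; 50 trials × 100,000 exact
paths for the forward oracle; 100,000 paths for the rejection-sampling
posterior oracle; 50,000 choices for parameter recovery (one optimizer
start — the likelihood surface for this model family is unimodal in
practice); 1,000 trials × 24 units for the population tuning and
change-of-mind analyses; 1,000 null units for calibration.  Where a
Monte-Carlo oracle is compared checkpoint-by-checkpoint, thousands of
z-scores are produced, so the tests bound the family-wise maximum at
the Bonferroni level and the 3-SE exceedance rate at its chance level
rather than asserting every single draw stays below 3 SE — the
statistically meaningful reading of "agreement within sampling
error".

# Known limitations

* The fitted $\sigma_i^2$ and $\sigma_a^2$ trade off strongly at
  realistic trial counts (both inflate terminal variance with similar
  time profiles); $\lambda$, $B$ and the lapse are the well-identified
  parameters, which is why recovery is asserted for those.
* The backward mixture truncation at $12\times$ the forward SD and the
  half-step component grid are implementation choices validated by the
  refinement property, not prescribed by any source.
* `run_pipeline()` chains the stages for convenience at smoke-test
  sizes; serious use should call the stage functions directly.
* Gridded outputs (posteriors, maps) live as in-memory R objects;
  export helpers write plain CSV/JSON only.
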