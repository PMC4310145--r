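---
title: "Profile-likelihood sensitivity: uncertainty propagation and experimental design for ODE models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profile-likelihood sensitivity: uncertainty propagation and experimental design for ODE models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
library(plsens)
```

## The problem

Dynamic models of biochemical networks are ordinary differential equation
systems

$$\dot x(t) = f(x(t,\theta_x),\, u(t),\, \theta_x), \qquad
  y(t) = g(x(t,\theta_x),\, \theta_y) + \epsilon,$$

whose states $x$ are only partially observable: an experiment records a few
readouts $y$ (through a readout map $g$ with scaling/offset parameters
$\theta_y$) under a stimulus $u(t)$, with additive Gaussian measurement
noise $\epsilon \sim N(0, \sigma_\mathrm{exp}^2)$. The combined parameter
vector $\theta = [\theta_x, \theta_y]^\mathsf{T}$ is estimated by minimising
the weighted residual sum of squares

$$\chi^2(\theta) = \sum_{i=1}^n
  \frac{\left(y_\mathrm{exp}(t_i) - y_\mathrm{sim}(t_i, \theta)\right)^2}
       {\sigma^2_\mathrm{exp}(t_i)},$$

which is $-2\log L$ up to a constant, so the minimiser $\hat\theta$ is the
maximum-likelihood estimate. With few readouts and noisy data, parameters
are routinely *practically non-identifiable*: an unbounded set of parameter
vectors fits the data equally well, and predictions of the unmeasured
states can be arbitrarily wrong even when the fit to the data looks
perfect. This package quantifies which parameter's uncertainty drives which
prediction's uncertainty, and turns that quantification into a criterion
for choosing the next experiment.

## Profile likelihood and identifiability

The profile likelihood of parameter $\theta_i$,

$$\chi^2_\mathrm{PL}(\theta_i) = \min_{\theta_{j \neq i}} \chi^2(\theta),$$

traces the least possible objective increase as $\theta_i$ is forced away
from $\hat\theta_i$ while all other parameters re-adjust. A confidence
region follows by thresholding,
$\mathrm{CR} = \{\theta \,|\, \chi^2_\mathrm{PL}(\theta) -
\chi^2_\mathrm{PL}(\hat\theta) < \delta_\alpha\}$, with $\delta_\alpha$ the
$1-\alpha$ quantile of $\chi^2_{df}$ ($df = 1$ pointwise, $df = n_\theta$
simultaneous; `profile_control(df = )`). A branch that never crosses the
threshold inside the explored range yields an infinite bound: the parameter
is practically non-identifiable on that side. We use the exact quantile
`qchisq(0.95, 1) = 3.841` for the pointwise 95% threshold throughout;
some published analyses of this benchmark quote 3.68 for the same setting,
a value we could not derive from any quantile convention and deliberately
do not reproduce.

`profile_parameter()` walks outward from $\hat\theta_i$ with an adaptive
step: each accepted step targets a profile increase of about
$\delta_\alpha/10$, bisecting the step (floor $10^{-3}$ log10 units) when
the profile climbs too fast and doubling it (cap $0.1$) on flat stretches.
The cap is deliberately 0.1 rather than something coarser so that flat
(unbounded) branches carry at least 10 re-optimised points per decade — the
sampling density the uncertainty propagation below relies on. A direction
stops at $1.2\,\delta_\alpha$ above the minimum or at the range limit
($\pm 3$ log10 units, matching the default estimation bounds).

Numerical choices that matter in practice:

* **Warm starts.** Each grid point re-optimises the nuisance parameters
  starting from the neighbouring point's optimum *and* from a linear
  extrapolation of the optimiser path, keeping whichever re-optimum is
  lower; a failed point falls back to a restart from $\hat\theta$. Before a
  threshold crossing is allowed to terminate a branch (and hence decide
  identifiability), the point is additionally re-optimised from fresh
  starts. Without these safeguards, curved flat ridges produce spurious
  finite bounds.
* **Backward sweep.** $\chi^2_\mathrm{PL}$ is non-decreasing away from the
  optimum by construction, so after the walk any point lying above its
  outward neighbour is re-optimised from that neighbour's parameters.
  `profile_wings_monotone()` reports whether residual violations remain.
* **Threshold reference.** If profiling uncovers a point below the fitted
  $\chi^2_\mathrm{min}$ — which happens on multimodal sloppy surfaces —
  confidence intervals measure the threshold from the best value seen
  anywhere (`chi2_ref`), not from the stale fit minimum.
* **Crossing refinement.** Interval bounds are bracketed on the grid and
  then polished by root finding on the re-optimised profile itself, so the
  bound's accuracy is not limited by the grid resolution.

Estimation itself (`fit_mle()`) is bounded trust-region least squares
(Levenberg–Marquardt) on log10 parameters — all rates are positive and
their plausible ranges span decades, so log space is the natural
optimisation scale — with multi-start via Latin hypercube sampling inside
the bounds, the first start being the user's guess, unperturbed. Two
refinements address stalls we observed on the fluorescence model's sloppy,
multimodal surface: the winning start is re-polished by restarting the
trust-region iteration until it stops improving, and an optional
coordinate "shake" (`shake = TRUE`) fixes one parameter at a time at
offsets up to $\pm 1$ log10 unit, briefly re-optimises the rest, and
restarts the full fit from any deeper point found. Simulation failures
during optimisation are treated as rejected steps (large finite residuals),
never as fatal errors.

## The PLS index and PLS entropy

Let $\{p_i(t_k)\}$ be a model prediction $p$ (a state or readout
trajectory) evaluated at every parameter vector sampled along the profile
likelihood of $\theta_i$ inside its confidence region — for an unbounded
interval, along $\pm 3$ decades around $\hat\theta_i$ (the `extension`
argument of `profile_samples()`; such samples are flagged
`extended-range`). The *profile-likelihood sensitivity index* of
$\theta_i$ for $p$ at time $t_k$ is the squared normalised ensemble spread

$$s_i(t_k) = \left(
  \frac{\max\{p_i(t_k)\} - \min\{p_i(t_k)\}}{\langle \hat p(t)\rangle_t}
  \right)^2,$$

where $\langle \hat p(t)\rangle_t$ is the time average (trapezoidal, since
prediction grids may be log-spaced) of the prediction at $\hat\theta$. The
overall uncertainty of prediction $p$ aggregates over parameters and
times, $s_\mathrm{tot} = \sum_i \sum_k s_i(t_k)$, and the *homogeneity* of
the parameter contributions is measured by the Shannon entropy of the
per-time normalised indices
$\tilde s_i(t_k) = s_i(t_k) / \sum_i s_i(t_k)$:

$$J_k = \sum_i -\tilde s_i(t_k) \log \tilde s_i(t_k), \qquad
  J_\mathrm{tot} = \sum_k J_k,$$

with $0 \log 0 := 0$. We use the natural logarithm — the criterion-space
*rankings* that drive design decisions are base-invariant — and
`pls_entropy(normalize = TRUE)` divides by $\log n_\theta$ when analyses
with different parameter counts must be compared. An all-zero index column
contributes $J_k = 0$. $J_k = \log n_\theta$ exactly when all parameters
contribute equally.

## Experimental design in the criterion space

Candidate experiments are scored by the pair
$O = [s_\mathrm{tot}, J_\mathrm{tot}]^\mathsf{T}$, both maximised: a good
next experiment probes a prediction that is (a) very uncertain and (b)
uncertain because of *many* parameters at once, so the new data constrain
them all. These goals genuinely trade off, so `score_candidates()` reports
the full Pareto front rather than collapsing to one winner.

* A **readout candidate** (an unmeasured state proposed as a new readout)
  inherits its coordinates from the base analysis: the $(s_\mathrm{tot},
  J_\mathrm{tot})$ of predicting that state under the current design.
* An **inhibition candidate** emulates an inhibitor by multiplying the
  targeted rate constant by $10^{-4}$ (configurable; the value is
  illustrative, a real application would use the inhibitor's measured
  efficiency). Its coordinates come from re-simulating the prediction
  ensembles under the inhibited parameter set — samples and the reference
  trajectory alike. For a pure inhibition the coordinates are summed over
  the design's observed readouts; for a readout + inhibition combination,
  over the added readouts under the inhibited dynamics. The aggregation
  rule is a package choice: the benchmark analyses report one point per
  inhibition scenario without stating how multiple readouts combine.
* The cheap criterion-space score is complemented by the expensive
  **anticipatory** loop (`anticipatory_experiment()` +
  `evaluate_design()`): simulate the candidate at $\hat\theta$, add
  Gaussian noise (default SD 5% of the time-averaged signal, floored at
  $10^{-3}$), merge with the real data, refit and re-profile everything.
  Multi-condition datasets keep a `condition` column so records measured
  under different designs (e.g. with and without an inhibitor) are
  simulated under their own design during fitting.

## The bundled models

**Four-species network (`insilico_model()`).** Mass-action kinetics with a
constant input $u = 1$ feeding A, two parallel routes
A$\to$B$\to$D and A$\rightleftharpoons$C$\to$D activating the readout
state D, and a first-order sink $d$ on D; all initial conditions zero. The
exact equations are a reconstruction from the benchmark's verbal
description (parallel activation routes plus a sink; $k_{11}$ governs
activation of B, $k_{21}$ of C), chosen so that D-only data leave the rate
constants mutually compensating. Under this structure the compensation is
real but not total: the five rate constants are practically
non-identifiable in both directions, while the sink $d$ acquires a finite
lower bound as well as the expected upper bound, because with a constant
input the D time course saturates and a vanishing sink would force
unbounded linear growth. A reconstruction driven by a decaying input, or a
horizon ending before saturation, would leave the lower side open; we
document rather than hide this structural sensitivity of the benchmark.

**Chlorophyll fluorescence induction (`dsalina_model()`).** Five states —
excited antennae A\*, the reduced quinone acceptors Q$_A^-$, Q$_B^-$,
Q$_B^{2-}$ and the oxidised plastoquinone pool PQ — with four reversible
and two irreversible electron-transfer reactions, driven by a 1 s light
pulse of 166 µE m⁻² s⁻¹. The antenna pool $A_0 = 290$ is fixed; 13
parameters (rates $k_1 \ldots k_{10}$, pool sizes $PQ_0$ and $r_2$, gain
$G$) are free, and the initial condition $x_5(0) = PQ_0$ depends on an
estimated parameter, so initial states are re-derived from the current
parameter vector at every simulation. The second term of the
$\dot x_2$ equation as printed in the source model contains an obvious
typesetting slip ("$-k_7 x - 2 x_3$"); the only reading consistent with the
matched $\mp k_7 x_2 x_3$ terms of the $\dot x_3$/$\dot x_4$ equations —
the electron transfer Q$_A^-$ + Q$_B^-$ $\to$ Q$_A$ + Q$_B^{2-}$ — is
$-k_7 x_2 x_3$, which is what both the R and the compiled right-hand side
implement. The 3 µE measuring light of a PAM instrument is treated as
non-actinic and ignored; the stimulus is the rectangular actinic pulse
only, and integration is split at the pulse edges so the stiff solver
(lsoda, atol $10^{-9}$, rtol $10^{-7}$ — the rates span $10^{-2}$ to
$3\times 10^5$ s⁻¹) never steps across a discontinuity.

## What the synthetic scenarios emulate — and what they do not

`make_fixture()` builds four seeded scenarios; every dataset is a pure
function of the scenario name and one master seed (436 by default):

| scenario | observed | grid | noise SD |
|---|---|---|---|
| `insilico_baseline` | D | 16 uniform points on [0, 10] | 10% of the time-averaged signal, floor 0.01 |
| `insilico_full_readout` | A, B, C, D | same | same |
| `dsalina_baseline` | F | 200 log-spaced points on [10⁻⁴, 1] s | 0.02 absolute (normalised-fluorescence scale) |
| `dsalina_augmented` | F + in-silico Q$_B^-$ ($x_3$) | same | 0.02 |

The fluorescence grid is log-spaced because the induction phases span four
decades of time; the noise level 0.02 approximates the tight replicate
band of normalised PAM data. Real PAM measurements differ in ways the
generator does not emulate: they sample at $10^{-4}$ s (thousands of
points, not 200), carry per-point replicate SDs rather than one constant
SD, and include instrument effects (detector saturation, measuring-light
flicker) outside the model class. Passing tests on these scenarios
therefore demonstrate the machinery — estimation, profiling, uncertainty
propagation, design scoring — under controlled conditions; they do not
certify the fluorescence model against new laboratory data. With the
synthetic information content (200 points, SD 0.02) the likelihood surface
is sloppier and more multimodal than with the full original recordings:
estimates can legitimately wander along near-flat valleys far from the
generating truth, which is why the robustified optimisation above exists,
and why confidence intervals here are wider than those published for the
original data. Replicate handling for real data is available separately:
`normalize_replicates()` rescales each trace by its own ground value $F_0$
and maximum $F_m$, $F_n = (F - F_0)/(F_m - F_0)$, then takes pointwise
means and SDs, flooring the SD at $\max(10^{-3}\max|y|, 10^{-12})$ so
coincident replicates never create infinite weights.

## Problem sizes and defaults used by the shipped analyses

The package's own test-suite and acceptance analyses run the in-silico
scenario with 20 multi-starts and 100 prediction times, the coverage study
with 100 replications of a two-parameter decay model, and the fluorescence
scenarios warm-started at the bundled reference estimate with a single
start (the anticipatory analyses in the underlying design methodology are
likewise performed at the current MLE). The fluorescence scenarios ask
only for interval bounds — no PLS sampling — so their profiling policy
strides at 0.25 log10 units on flat stretches and takes bounds from grid
interpolation; the 10-points-per-decade density cap applies where profile
samples feed uncertainty propagation. These sizes were chosen as the
smallest that exercise every code path with stable results; all of them
are plain function arguments, and nothing in the implementation depends on
them.

## Known limitations

* Single rectangular pulse stimuli only; no event handling beyond the
  pulse edges, no delay or partial differential terms.
* The design space covers added readouts and single-parameter inhibitions
  (and their pairs) — not stimulus shapes or measurement-schedule
  optimisation.
* The Gaussian, known-SD noise model of the objective is assumed, not
  checked; non-Gaussian noise requires a different likelihood.
* Identifiability classification is relative to the explored profile range
  ($\pm 3$ decades by default): a bound just outside the range is
  indistinguishable from no bound.
* The in-silico network is a reconstruction; its identifiability pattern
  (notably the lower bound on $d$) depends on structural choices the
  verbal description does not pin down, as discussed above.
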