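---
title: "Models and methods: collective decisions on networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: collective decisions on networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadenet)
```

`cascadenet` simulates a group of `N` agents deciding between two world
states, `S⁺ = +1` and `S⁻ = −1`, over a communication network. This
vignette is the package's account of the two models it implements, the
parameters that matter, the numerical choices behind the implementation,
and what the simulations do and do not establish.

## Communication topologies

Agents communicate on an undirected graph. The default generator is the
random geometric graph (RGG): `n` nodes placed uniformly in the unit
square, an edge whenever two nodes lie closer than a radius `delta`. RGGs
are the natural abstraction for physically embedded groups, where who hears
whom is set by distance. Because experiments are usually specified by a
target mean degree `kappa` rather than a radius, and the analytic relation
`kappa = n·pi·delta²` is biased by the square's boundary,
`radius_for_target_degree()` calibrates `delta` by bisection on the
empirical mean degree over a fixed panel of 200 point sets (common random
numbers make the objective monotone and deterministic; tolerance 0.5 in
mean degree). Connectivity, when required, is enforced by rejection
sampling, with the rejection count reported as an attribute. Erdős–Rényi
and ring-lattice generators are provided behind the same interface to check
that conclusions do not hinge on the geometric construction.

## The synchronous scenario

At `t = 0` each agent holds an opinion `x_i` and a confidence
`c_i = ln(alpha_i / (1 − alpha_i))`, the log-odds of its accuracy
`alpha_i`. Accuracies are drawn from `Normal(mu_alpha, sigma_alpha)` with
draws below 1/2 flipped to `1 − alpha` (an agent systematically below
chance would be carrying information about the *wrong* answer; flipping
encodes that its label convention is reversed). The default
`mu_alpha = 0.5` puts all skill into the heterogeneity `sigma_alpha`, so
homogeneous groups (`sigma_alpha = 0`) are exactly at chance and
heterogeneity simultaneously raises mean individual accuracy — a property
of the folded distribution worth keeping in mind when reading accuracy
curves. Accuracies are clamped to `(0.5, 1 − 1e−6)` so log-odds stay
finite; under the continuous sampler the clamp binds with probability zero.

**Weighted Bayes Consensus (WBC).** Every round, each agent pools its own
signed evidence `y_i = x_i c_i` with its neighbours' pre-update evidence:

    s_i = y_i + sum_{j in M_i} y_j
    Lambda_i = s_i + ln(p⁺ / p⁻)

and adopts `x′_i = sign(Lambda_i)`, `c′_i = |Lambda_i|`. This is the exact
naive-Bayes posterior over the two states given the local votes (the test
suite verifies `plogis(y′_i)` against an independently coded posterior,
`direct_bayes_posterior()`, to 1e−10 under random priors). A frequently
seen variant applies the sign to `s_i` alone and adds the prior only inside
the confidence magnitude; the two coincide for a flat prior — the default
and the standard experimental condition — but only the formulation above
remains Bayes-coherent when prior and votes disagree in sign, which is why
the package adopts it. Ties (`Lambda_i = 0`) retain the previous opinion:
deterministic, minimal-change semantics.

On the evidence vector the update is `y ← (I + A) y`, with spectral radius
above 1 on any graph with an edge. The instability is the scientific point:
the dominant eigenvector of `I + A` is not the ones vector on non-regular
graphs, so the growing mode need not carry the sign of the group's pooled
evidence — fast unanimity, sometimes on the wrong state (a negative
cascade). Magnitudes are irrelevant to opinions, so `run_synchronous()`
rescales the whole evidence vector by its maximum whenever that maximum
exceeds 1e100; linearity guarantees the sign trajectory — hence every
opinion ever held — is unchanged, and the cumulative log-scale is reported.

**Belief Consensus (BC).** The stable alternative averages instead of
summing: `y ← (I − εL) y` with Laplacian `L`. The step `ε` defaults to the
uniform safe value `1/(1 + max degree)`; the full Metropolis–Hastings
weight matrix (off-diagonal `1/(1 + max(d_i, d_j))`) is available and both
make the update doubly stochastic, so the total evidence is conserved and,
on a connected graph, every agent converges to the initial mean — the
globally optimal pooled statistic. The destabilized variant
`y ← (εI + F) y` adds a tunable unstable mode along the ones vector
(dominant eigenvalue `1 + ε`), showing that speed does not require
corrupting the statistic: its growing mode *is* the average.

**Run protocol.** Initial opinions are independent draws, each agent
correct with probability `alpha_i`. Iteration stops at unanimity or at
`max_iter` (default 1000). Group accuracy counts a run as a success only if
it ends unanimous on the true state; timeouts count as failures and are
excluded from consensus-time summaries. Both conventions are flagged
because a different accounting (e.g. majority at horizon) would change
numbers, not orderings.

## The asynchronous scenario

Each agent integrates private evidence as a drift-diffusion process
`dy_i = A_i dt + sigma dW` from `y_i(0) = 0` to thresholds `±z`, deciding
with the sign of the crossed threshold and broadcasting that decision
exactly once. Drift magnitudes are population-distributed as the folded
normal `|N(mu_A, sigma_A)|` with the sign of the true state (no
systematically misinformed agents); agents know the distribution but not
their own drift. Units: evidence is dimensionless log-odds-like
accumulation, drift is evidence per unit time, `sigma` evidence per square
root time, costs `omega_t` per unit time and `omega_e` per error.

**Thresholds.** All agents share the `z` minimizing the expected Bayes risk
`omega_t·E[T(z)] + omega_e·P(error; z)` using the standard closed forms
`E[T] = (z/Ã)·tanh(Ãz/σ²)` and `P(error) = 1/(1 + exp(2Ãz/σ²))`,
marginalized over the drift prior by quadrature (a point-evaluation mode at
`mu_A` is exposed as a flag, since either convention is defensible when
agents only know the prior). Minimization is golden-section search seeded
from a 60-point bracketing grid on `(0, 20]`; the risk is smooth with one
interior minimum for positive costs. At the reference operating point
(`mu_A = 0.2`, `sigma_A = 0.5`, `sigma = 1`, `omega_t = 1`,
`omega_e = 100`) the optimum is `z ≈ 3.35`.

**First-passage machinery.** The decision-time density conditioned on the
crossed boundary uses the method-of-images series `theta(t, u, v)` summed
outward from `k = 0` until two consecutive pairs of terms fall below 1e−12
(super-exponential tail). Two facts the implementation relies on, both
verified in the tests: the printed conditional density integrates to one,
and it is *even in the drift* — for symmetric thresholds and an unbiased
start, correct and error decisions share the same time distribution. The
analytic formulas assume symmetric thresholds; asymmetric configurations
raise an explicit error and route to the Monte Carlo simulator, rather than
silently using a formula outside its domain.

**Kicks.** A neighbour's decision `x_j` at time `t` is worth, to a naive
receiver, the log-odds

    k(t) = ln [ ∫ P(t|z⁺, +Ã) P(z⁺|+Ã) p(Ã) dÃ
              / ∫ P(t|z⁺, −Ã) P(z⁺|−Ã) p(Ã) dÃ ] + prior log-odds,

added to the receiver's accumulator in the direction of `x_j`. Because the
conditional time density is even in the drift, a *known* drift
(`sigma_A = 0`) makes the time-dependent factor cancel, leaving only the
constant threshold-choice log-odds: time-resolved confidence requires
population heterogeneity. Marginals are computed as expectations over the
underlying standard normal (`a = |mu_A + sigma_A·u|`, `u ∈ (−8, 8)`,
relative tolerance 1e−8), a parameterization that remains well conditioned
down to the point-mass limit instead of collapsing onto a vanishing
integration range. Within a run, kick values are memoized by decision time
(times are multiples of `dt`, so repeated lookups are common).

**Scheduler.** Time advances in steps of `dt` (default 0.01, a compromise
between discretization of the diffusion and the granularity of kick
delivery). Kicks are delivered one step after the sender's crossing —
same-step delivery would make outcomes depend on within-step processing
order. Crossings are evaluated at step boundaries after drift, noise, and
kicks are summed; simultaneous deciders are processed together and their
broadcasts all arrive next step. A decision is attributed to a kick when
the agent's pre-kick evidence had not crossed; among several helpful kicks
the largest contribution in the crossing direction wins (ties: earlier
sender decision, then lower index) — deterministic and magnitude-meaningful
where any convention would do. Decided agents are frozen: they neither
integrate nor receive. The horizon defaults to 10 times the prior-averaged
asocial mean decision time; agents undecided at the horizon are recorded,
and the cost accounting charges them the horizon time under a flag.

**Cascades and leaders.** The event log induces a causal forest: kick-caused
decisions are children of their attributed sender, spontaneous decisions are
roots. A cascade is a root plus its descendants, trigger included; the
conventional reporting threshold is `N/10` members. Trigger counts per
drift-rank use that threshold, while the size distributions used for
quartile comparisons cover *all* causal trees: at the reference operating
point nearly every above-threshold cascade spans most of the group, so only
the full tree-size distribution (which keeps the unheeded, small trees of
poorly informed roots) resolves who sparks large followings.

**Monte Carlo oracle.** `simulate_ddm()`/`simulate_ddm_paths()` use
Euler–Maruyama with per-step Brownian-bridge crossing probabilities
`exp(−2(z − y₀)(z − y₁)/(σ²dt))`: purely boundary-sampled detection misses
intra-step excursions and biases decision times late by more than the
Monte Carlo error at 10⁴ paths, while the bridge correction makes the
simulator match the analytic density and hit probability within sampling
error at `dt = 1e−3`. The collective scheduler intentionally does *not*
bridge-correct: there `dt` is the model's communication granularity, shared
by all agents, not a numerical approximation to be refined away.

## Experiment drivers and reproducibility

Sweeps derive one child seed per (sweep value, replicate) from the master
seed via a multiplicative hash (`split_seed()`), so arbitrary subsets of an
experiment are reproducible in isolation and paired designs are exact: the
two algorithms in `paired_comparison()`, or the social/asocial twin runs in
`sweep_sequential()`, see identical topologies, accuracies or drifts, and
initial conditions, so contrasts are attributable to the mechanism alone.
Proportions carry Wilson 95% intervals; time and cost means carry
percentile-bootstrap intervals (1000 resamples). Per-run rows are written
as CSV, and summaries are recomputed from those rows, so the written
artefacts round-trip to the reported aggregates.

Default problem sizes — 50 agents at mean degree 10, 100-replicate paired
sweeps for the synchronous comparison, 60–200 runs per operating point for
the asynchronous statistics, 10⁴ Monte Carlo paths for the first-passage
cross-checks — were chosen so the documented orderings are resolved at
three standard errors; all are plain arguments, and larger campaigns
(e.g. 500–1000 replicates) are a matter of raising `replicates` in a
config.

## What the generators do and do not emulate

The synthetic conditions capture: distance-limited communication on static
undirected graphs, population heterogeneity in skill (folded-normal
accuracies or drifts), equal priors and symmetric error costs, and honest,
one-shot (asynchronous) or synchronous broadcast of opinion and confidence.
They do not capture: time-varying or directed networks, correlated private
evidence (all correlation in the models comes from communication),
misinformed agents with wrong-signed drift, asymmetric costs or priors in
the analytic first-passage path, strategic or deceptive signalling, or
agents that exploit the *absence* of neighbours' decisions as evidence.
Passing tests therefore establishes the internal consistency of the models
and the robustness of the qualitative orderings under these idealized
conditions — not that any particular animal group implements these rules.

## Known limitations

- The exact-posterior pooling step is `O(N²)` per round through a dense
  adjacency product; groups beyond a few thousand agents would want sparse
  matrices.
- The naive-Bayes agents double-count the prior across synchronous rounds
  (each round re-applies it); with the default flat prior the term is zero,
  and the convention is isolated in one place (`wbc_step`).
- Kick evaluation assumes all agents started integrating at `t = 0` and
  share `z`; staggered starts would invalidate the decision-time
  calibration.
- Undecided-at-horizon handling (rare at the default horizon) is a
  reporting convention, flagged rather than resolved.
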