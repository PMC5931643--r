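---
title: "Inferring directed functional connectivity with SpikeNetGLM"
author: "SpikeNetGLM maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring directed functional connectivity with SpikeNetGLM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

A population of neurons is recorded in discrete time bins while a set of
external stimuli is presented under the experimenter's control.  The goal
is a sparse directed graph: which neurons and which stimuli causally
(in the Granger sense) drive each neuron's spiking rate, with signed
weights.  Because stimulation time is expensive, a second goal is to
*choose the next stimuli* so that the edges still in doubt are probed as
efficiently as possible.

SpikeNetGLM implements the full loop: a Poisson generalized linear model
of spiking, a BIC- and Wald-test-driven forward search for each neuron's
parent set, an active-learning policy that converts candidate-edge
deviances into a stimulus distribution, simulators that generate ground
truth for validation, and a small-world network-analysis suite for the
recovered graphs.

# The model

Counts `X_c(t)` of neuron `c` in bin `t` are conditionally Poisson:

    eta_c(t) = b_c + sum_j W[j,c] Xhat_j(t) + sum_s H[s,c] Ihat_s(t)
    X_c(t) | past ~ Poisson( lambda(eta_c(t)) )

`Xhat_j` and `Ihat_s` are boxcar sums of source j's spikes and stimulus
s's indicator over the delay window `[t-5, t-2]` (both windows
configurable through `boxcarWindow()`).  The nonlinearity is the
softplus-kappa function

    lambda(eta) = log(1 + exp(kappa * eta)) / kappa,

approximately exponential for low drive and linear for high drive, so
inhibition can be strong without rates hitting zero and excitation
cannot blow up.  The calibration constant `kappa` defaults to 10; larger
values sharpen the elbow but cause numerical trouble in the Wald
approximation, smaller values blur the distinction between inhibition
and excitation at the low rates (about 0.05 spikes/bin) this model is
aimed at.

The model is time homogeneous, and influence is restricted to the boxcar
window: no raised-cosine bases, no slow adaptation terms.

## Likelihood conventions

The log-likelihood drops the additive `-log(X!)` constant, so printed
log-likelihoods are comparable only within this package; BIC differences
and deviances are unaffected.  Bins without full boxcar history (the
first `lower` bins) are excluded from every likelihood, Fisher and BIC
sum, and `m` in the BIC is the number of *contributing* bins.  BIC
counts only the selected regressors - the always-present bias is free:

    BIC = log(m) * |PA_c| - 2 * logLik.

## Estimation

`fitNeuronGLM()` maximizes the concave likelihood by damped Newton
ascent with the closed-form observed Fisher information as curvature
(gradient max-norm below 1e-6 or relative log-likelihood change below
1e-9, at most 500 iterations; step halving up to 40 times).  The solver
is written in C++; `logLikelihood()` and `observedFisher()` are the
R-level reference implementations, and the test suite checks the
closed-form Fisher matrix against a finite-difference Hessian at
relative tolerance 1e-4.

Per-parameter confidence comes from the Wald statistic
`theta_j^2 / [J^-1]_jj` against chi-square(1).  When the Fisher matrix
is numerically singular (reciprocal condition number below 1e-12) every
p-value is set to 1: a near-singular information matrix means at least
one parameter variance is effectively unbounded, so the subset must be
rejected under any p-value ceiling.  This is what keeps the
under-sampled regime (more candidate regressors than bins) safe.

# Selecting each neuron's parents

`elasticForwardSelect()` minimizes BIC subject to `max p-value <= gamma`
over parent sets, by a greedy elastic-forward search:

1. **Proposal.**  Every regressor outside the current set is fitted
   jointly with the current set on `nSplits` random subsamples (each a
   fraction `nu` of the valid bins, drawn without replacement from the
   prebuilt design so boxcar history is never broken) and on the full
   data.  A candidate's p-value score and BIC score are
   `max(median over subsamples, full-data value)` - the max guards
   against regressors that only look good on a lucky subsample.  Up to
   `kMax` candidates that beat the current BIC under the ceiling are
   returned, best BIC first, ties broken by regressor index.
2. **Elastic shrink.**  The top-n proposed candidates are added jointly;
   n shrinks by one until the joint model both satisfies the ceiling and
   improves the best BIC seen.  If nothing qualifies the search stops.

Defaults: `gamma = 0.01`, `nu = 0.7`, `nSplits = 10`, `kMax = 5`.  The
subsample count is a free choice ("several" is all the method needs);
10 is comfortable, and the package's own simulation studies in the test
suite run with 5, which gives the same recoveries measurably faster.
Subsamples are drawn per proposal step, with the step index folded into
the seed, so selection is a pure function of (data, seed).  Since the
search reruns from scratch at every acquisition, edges can disappear
between interventions - removal needs no extra mechanism.

An optional prescreen (`prescreen = TRUE`) ranks candidates by a
closed-form approximation of the single-regressor Wald z-score, built
only from the target's conditional mean rates when the candidate is
active versus inactive, and keeps the top `3 * kMax` before the
proposal fits.  It is a pruning device only - no edge is ever accepted
on the approximate score - and it is off by default.  The package's
simulation-heavy tests switch it on.

The baseline for comparison is an L1-penalized fit of the same
likelihood (`lassoBaseline()`, proximal-gradient with backtracking,
penalties descending from the data-derived value that zeroes every
regressor).  `oracleLasso()` picks the penalty that maximizes F1 against
the known truth, which makes the baseline as strong as it can be; the
forward search receives no such oracle help.

# Active learning

Between acquisitions the loop (`runActiveLoop()`) asks: which stimulus,
if favoured in the next batch, is expected to raise the spiking rate of
neurons that sit at the source of *promising but unaccepted* edges?

* A candidate edge's promise is its deviance: twice the log-likelihood
  gain from adding that one regressor to the target's current model,
  refit warm-started from the current estimate
  (`devianceCandidates()`).  At the MLE this gain is non-negative, and
  larger means more promising; refits that fail contribute zero.
* The effect of favouring stimulus s is its expected rate change (ERC):
  the ratio of each source's expected rate under the surrogate
  distribution `(1 - beta) delta_s + beta uniform` to its rate under
  uniform stimulation.  For stimulus sources this ratio is exact:
  `(1 - beta) n_s delta(s - si) + beta`.  For neuron sources it is
  estimated by forward-simulating the *fitted* network under both
  distributions with common random numbers (the same uniforms drive the
  stimulus draws and the Poisson inversions), which cancels most of the
  Monte-Carlo noise from the ratio.  Defaults: horizon 2000 bins, 5
  replicates; the package's own loop evaluations use 1000 bins and 3
  replicates, which the common-random-number coupling makes adequate.
* Stimulus s's score sums, over sources, ERC times the source's mean
  deviance over its absent outgoing edges (a source with no absent
  edges contributes zero, the mean over an empty set being defined as
  zero).  Scores are z-scored across stimuli (sample standard
  deviation; all-equal scores map to the uniform distribution),
  truncated to [-2, 2], and softmaxed.  The truncation bounds the
  probability ratio between any two stimuli by e^4, so no stimulus is
  ever starved.

`beta` defaults to 1/4.  Setting `beta = 1` makes every surrogate equal
to the uniform distribution, all ERCs equal one, all scores tie, and
the loop reduces *exactly* to uniform (random) stimulation - that is
the control arm in every comparison.

# The simulators

`makeSmallWorldNetwork()` builds the ground truth the package validates
against:

* Topology: per cluster, a directed nearest-neighbour ring thinned (or
  thickened) to hit the target directed edge density exactly, then each
  edge rewired with probability 0.1 - short-range wiring plus a few
  long-range shortcuts, the small-world construction.  The stated
  density 0.03 is read as directed edge density over ordered
  within-cluster pairs; at 18 neurons per cluster this gives 9 edges
  per cluster.
* Weights: rate *increments* are drawn per cluster from normal
  distributions (SW1CL: N(0.05, 0.005); SW3CL clusters: means
  0.075/0.05/0.035) and converted so that one source event in the
  boxcar window raises the child's rate by exactly the drawn increment
  at the network's kappa:
  `w = lambdaInv(lambda(b) + increment) - b`.  Exactly
  `round(0.30 * nEdges)` inter-neuron edges are negated (inhibitory) -
  the fraction is enforced, not merely expected.
* Stimuli: 30 available, all excitatory, but only a fraction (default
  1/6, i.e. 5) receive outgoing edges (increments N(0.10, 0.014)); the
  rest are confounders the selection must ignore.  With 3 targets per
  active stimulus the SW1CL truth carries 9 + 15 = 24 nonzero weights
  among 864 candidates; the SW3CL preset wires 6 targets per active
  stimulus for 27 + ~30 weights among 4536 candidates.  Stimulus
  sequences hold each i.i.d. draw for 4 consecutive bins.
* Baseline rate 0.05 spikes/bin for every neuron (two-photon-like).

`simulatePoissonNetwork()` runs the generative model bin by bin (early
bins use the partially available history).  `simulateLIFNetwork()` is
the model-mismatch check: leaky integrate-and-fire dynamics,
Euler-discretized one step per bin, threshold 1, reset 0, per-bin
uniform direct current `b(t) ~ U[0, bMax]`, and a unit-area alpha-like
synaptic kernel `h(t) = a^2 exp(-a(t - tD))(t - tD)` truncated at
`10/a` bins (defaults a = 1.5, tD = 2).  `bMax` is calibrated so the
baseline spiking probability matches the Poisson simulations
(`bMax = 1/(1 - rate)`), and the GLM weights are linearly rescaled to
preserve conditional rate changes: in the GLM one source spike adds
(window length) x lambda'(eta0) x w expected child spikes, in the LIF
it adds w/bMax, giving `w_LIF = w_GLM * windowLength * lambda'(eta0) *
bMax` (`lifWeightsFromModel()`).  Recovering the right directed edges
from LIF data with the Poisson GLM is the package's evidence that the
method does not lean on the Poisson assumption.

Hartley-basis gratings (amplitude +-1, integer frequencies kx, ky in
[-12, 12]) are encoded by spatial frequency `r = sqrt(kx^2 + ky^2)` and
orientation `phi = atan2(ky, kx)`, each discretized into 7 equal-width
bins over its attainable range (r over [0, sqrt(2)*12], phi over
(-pi, pi]; the bin edges are a package choice), for 49 stimulus
classes.  The pixel-level grating itself is never rendered.

What the simulators deliberately do not emulate: calcium indicator
dynamics and spike inference from fluorescence, imaging noise, slow
nonstationarity, eye movements, or realistic receptive-field structure.
Passing the simulation suite therefore says the *inference machinery*
is correct under the model class and robust to one dynamical mismatch
(LIF); it does not certify performance on raw imaging data.

# Evaluation and network analysis

`edgeRecoveryMetrics()` scores presence-only recovery (sign ignored)
with set-intersection precision/recall/F1 summed over neurons, reported
for W, H and combined; all 0/0 cases are defined as 0.
`heldoutLogLikDiff()` compares models on held-out bins;
`toARModel()` builds the autoregressive restriction (self + stimulus
edges only).  `longRangeForecast()` propagates *expected rates* through
the boxcar history instead of sampled spikes - a deterministic whole-
system forecast given only the stimulus sequence, seeded with
`lambda(b)` for the first window.

The analysis suite works on the presence graph.  The motif census
classifies every connected 3-node subgraph into five direction-aware
classes - divergent (one source feeds two targets), convergent, chain,
acyclic triangle, cyclic triangle - with reciprocal pairs folded into
the chain/triangle/cycle classes; weight and sign are ignored.  Only
two connected triad shapes exist undirected, so a five-class taxonomy
is necessarily direction-aware; the classification rules are spelled
out in the source and verified against a brute-force isomorphism oracle
in the tests.  `cliqueMembership()` enumerates maximal cliques of the
symmetrized graph, and `smallWorldNullTest()` compares any statistic
vector against a matched small-world ensemble (same node count and
density, Gaussian z and two-sided p; degenerate spread reports NA).

# Numerical and degenerate-input choices

* Fisher singularity: reciprocal condition number below 1e-12 forces
  p = 1 for all parameters of that subset.
* Prescreen with a zero conditional rate on either side returns 0
  (uninformative), as does a never-active regressor column.
* `scoresToDistribution()` with zero score spread returns uniform.
* Deviances are clamped at 0; non-convergent refits contribute 0.
* Lasso support threshold: |w| > 1e-6.
* Forecast initialization: the first `lower` bins carry `lambda(b_c)`.
* All randomized internals draw through an internal seeded-RNG helper
  that restores the caller's RNG state, so package calls never perturb
  a session's random stream and every result is reproducible from the
  config seeds.

# Problem sizes in the shipped tests

The simulation studies in `tests/testthat/` and `scripts/acceptance.R`
run the SW1CL design (18 neurons, 30 stimuli) with 500-bin acquisition
batches, selection at `nSplits = 5` with the prescreen on, and
rate-change estimation at horizon 1000 with 3 replicates; the
elastic-forward versus oracle-lasso comparison is evaluated at
m = 4000, the closed-loop comparison over 3 interventions plus a final
refit (m up to 2000), and the LIF study at m up to 4500.  These are the
package's standard evaluation sizes; the dominance orderings they check
(forward search at least as good as the oracle lasso at large m; active
learning at least as good as uniform stimulation from the second
intervention on, with the larger gap on stimulus-response edges) are
scale-reduced versions of the full study designs, which use more
interventions and more seeds.

# Known limitations

* Influence kernels are boxcars; latency structure finer than the
  window is invisible.
* The Wald/BIC machinery assumes enough bins per candidate that the
  observed Fisher information is informative; at very small m the
  search (correctly) returns few or no edges rather than guessing.
* The active-learning score only credits *first-order* stimulus
  effects through the fitted network; stimuli whose value is purely
  higher-order (through edges not yet in any candidate set) are
  explored only via the beta-smoothed floor.
* Edge signs are recovered but not separately tested by the recovery
  metrics (presence-only, matching the evaluation convention).
* The LIF weight rescaling is a first-order rate-matching argument,
  adequate for detection studies, not a dynamical equivalence.
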