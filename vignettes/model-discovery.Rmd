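---
title: "Two-stage model discovery for noisy biological dynamical systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage model discovery for noisy biological dynamical systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hybriddx)
```

## The problem

Biological time-series data — population counts, protein concentrations,
cell-state proportions — are noisy, short, and often measured many times
over (replicates), while the governing equations are only partially
known. Classical sparse equation-learning (SINDy) regresses measured
derivative estimates on a library of candidate terms; with noisy data the
derivative estimates degrade quickly, and with partially-known models the
sparsity threshold fights the known terms. This package implements a
two-stage alternative: first learn a smooth surrogate for the unknown
part of the dynamics with a small neural network embedded in an ODE
solver, then sparsify the surrogate — not the raw data — symbolically.

## The hybrid model

The dynamics are `x' = g(x) + NN(x)` with `x` in `R^d`. The prior `g` is
species-wise linear, `g_i(x) = a_i x_i` (`known_part()`): this covers the
priors used throughout — growth/death terms `(alpha x1, -delta x2)` for
the predator–prey system, unit degradation `-x_i` for the repressilator
and for cell-state losses — and `a = 0` gives the fully data-driven
(pure-NN) formulation. The residual `NN` is a fully-connected perceptron
with tanh hidden layers and a linear output layer. The tanh choice is
deliberate (the activation is not prescribed by the problem): the network
is integrated by a Runge–Kutta scheme, so the field must be smooth with
bounded derivatives, which also keeps the solver's step-error estimates
meaningful. Default widths are one hidden layer of 8 for two-species
problems and two layers of 8 for three-species problems — deliberately
small, since depth beyond this mostly buys overfitting on short
trajectories.

## Stage 1: fitting the residual

Training samples on a shared grid are cut into all sliding windows of
length `w` (step 1), pooled across samples, shuffled, and batched
(`sliding_windows()`, `make_batches()`). Windows are re-shuffled every
epoch with epoch-indexed seeds; a trailing partial batch is kept, since
the loss is a mean and discarding data buys nothing. Each window is
simulated from its own first *observed* (noisy) state — no denoised or
learned initial condition — and the window loss is the MSE over all `w`
points and `d` species; the batch loss is the mean over windows.

Gradients are computed discretize-then-optimize: the window simulation
uses classical RK4 with a fixed number of substeps per data interval
(default 4), and forward-mode sensitivities are propagated through the
same stages, so the gradient is the exact derivative of the computed
discrete trajectory. Forward mode is the right direction here because the
networks are tiny (42–131 weights): sensitivity matrices are `d x P` and
cost a handful of small matrix products per stage. An adaptive adjoint
solver would add machinery without accuracy: on window spans of 0.4–1
time units for these non-stiff systems, RK4 at `h = dt/4` has local error
many orders below the smallest (0.1%) observation noise. Windows whose
simulation leaves `[-1e6, 1e6]` or turns non-finite are skipped within
their batch (the default failure policy), so one exploding window cannot
poison training.

Optimization is Adam at a constant learning rate for 10 epochs. After
each epoch the model is scored on the validation split: each validation
sample is simulated over its *full* time span from its own first
observation, and the per-sample MSE is averaged. The returned weights are
those of the best epoch, not the last — the full-span validation loss of
these models is noisy across epochs (long-horizon simulation amplifies
small field differences), and the best-epoch rule is what the per-epoch
validation scoring is for. `grid_search_nn()` trains every `(w, b, lr)`
combination (defaults: `w` in 5/10, `b` in 5/10/20, `lr` in
0.001/0.01/0.1) and keeps the lowest-validation-loss fit; combinations
that fail numerically are recorded in the search table rather than
raised.

## Stage 2: sparse symbolic recovery

`simulate_regression_data()` re-simulates the fitted hybrid model from
every training sample's first observation over the training span at step
`dt` — interpolation to finer grids than the data is exactly what the
fitted ODE enables — and evaluates `NN` pointwise on the simulated
states. `stlsq()` then solves `NN(X) = Theta(X) Xi` per output dimension:
ridge-solve on the active columns, zero coefficients below `lambda`,
shrink the active set, repeat until stable (cap 20 sweeps; convergence is
"active set unchanged"). Ridge is applied to raw, unstandardized columns
on purpose: the thresholds used downstream (0.1 for polynomial problems,
1.0 for Hill production rates near 10) are calibrated to raw coefficient
scales. There is no implicit intercept — a constant enters only if the
library contains it. An equation whose active set empties returns an
all-zero column with a warning; the model may still be valid through `g`.

Candidates over the `(dt, library, alpha)` grid are assembled as
`g + Theta Xi` and ranked by AICc computed on the validation samples,
with `n` = number of validation samples, `k` = number of *learned*
nonzero coefficients (known terms are free: they were never estimated),
and RSS from simulating each candidate over the training span from each
validation sample's first observation. Unstable candidates (solver
failure, state blow-up past 1e6) get infinite RSS and sink to the bottom;
`rss = 0` maps to `-Inf` with a warning; the small-sample correction
requires `n > k + 2` and candidates violating it are not scored.
Topology correctness (`topology_correct()`) compares canonicalized term
labels per equation — monomials with sorted species indices, Hill terms
keyed by species and order — including coefficient *signs* but not
values. A learned term that lands on a known term's label merges into a
net coefficient, so a learned `+0.97 x3` against a known `-x3` correctly
reads as "no net loss" rather than as two terms. Where a candidate's
library cannot express the truth at all, the strict mode errors (you
asked an unanswerable question) while ranking mode counts it as simply
incorrect.

Correctness is deliberately topology-only, not parameter-accuracy: the
selection question is whether the right interaction structure was found;
coefficient error is reported alongside (the acceptance checks assert it
separately) rather than folded into the correctness flag.

## Baselines

Four reference methods share the dataset and report schema so
comparisons are apples-to-apples (`compare_methods()`):
finite-difference SINDy (`base_sindy`; second-order centered stencils,
second-order one-sided at the ends — the standard default, exact for
quadratics), the same with the prior subtracted from the derivative
estimates (`base_known`; with a zero prior it reduces bitwise to
`base_sindy`), weak-form SINDy (`weak_sindy`), and the pure-NN pipeline
(`pure_nn`, the hybrid with `g = 0`). The derivative-based and weak-form
methods have no `dt` hyperparameter — they cannot interpolate — so their
stage-2 grid is `(library, alpha)` only.

The weak form uses polynomial bump test functions
`phi(t) = ((t - a)(b - t))^p` with `p = 3` on `K = 100` random subwindows
per sample (lengths 20–80% of the span), peak-normalized; integration by
parts turns `int phi x'` into `-int phi' x` (the bump vanishes at the
subwindow ends), and both sides are integrated by trapezoidal quadrature
on the data grid. All of this is configurable; the defaults were chosen
once as sensible smooth-test-function practice, and the method's results
are expected to match qualitative noise-regime behaviour, not specific
reference numbers.

## Synthetic data: what it emulates and what it does not

`make_dataset()` simulates one ground-truth trajectory per grid with
LSODA at `rtol = atol = 1e-8` — tight enough that integration error is
negligible against even 0.1% noise — then draws independent noise
realizations per sample. Additive noise for species `k` has standard
deviation `eps * mean_t(x_k)` (constant over time); multiplicative noise
has standard deviation `eps * |x_k(t)|`. The second Gaussian argument is
read as a *standard deviation*, not a variance; the alternative reading
exists, but s.d. scaling is the one consistent with noise "ribbons" whose
width is visually proportional to `eps`. Draws are independent across
time, species and samples; negative observations are not clipped. All
variation across samples is observation noise around a single shared
truth — the generator emulates measurement replicates, not biological
heterogeneity, process noise, or irregular sampling, so passing tests
say nothing about intrinsic stochasticity or time-correlated errors.

Benchmark presets pin the study conditions: predator–prey with
parameters (1.3, 0.9, 0.8, 1.8) from `x0 = (0.4425, 4.6281)`, train and
validation on `[0, 4]` at step 0.1, test on `[0, 20]`; repressilator
(`beta = 10`, `n = 3`, `gamma = 1`, `k = 1` fixed and not configurable)
from `x0 = (1, 1, 1.2)`, train on `[0, 10]` at step 0.2, test on
`[0, 30]`; 200/50/50 samples by default. Two alternative predator–prey
parameterizations circulate with conflicting descriptions — the same
parameters from `x0 = (2.5, 0.7)`, and parameters (2.1, 1.2, 0.7, 1.1) —
so both are exposed as presets (`lotka_volterra_alt`,
`lotka_volterra_alt2`) rather than resolved. The asymmetric
repressilator takes per-species `beta` with a scalar `n`
(`beta = (7, 6, 8)`, `n = 2` in the preset); full per-edge generality is
out of scope.

## Compositional cell-state data

`sample_proportion_trajectory()` draws, per pseudotime bin, the first
`n_states - 1` states from Gaussians truncated to within one standard
deviation of the bin median and to `[0, 1]`, and closes the last state to
`1 -` the rest, redrawing the whole bin (cap 1000) if closure leaves
`[0, 1]`. Every emitted row sums to 1 exactly. Which states are drawn and
which closed is configurable (default: draw the first two, close the
third). `synthetic_emt_profile()` supplies logistic-shaped median curves
for a progressive epithelial-to-mesenchymal transition — E falls, I rises
then falls, M rises towards 1 — on an integer pseudotime grid; the test
split can use an extended profile (13 bins against 9) built from the same
curves, which is how extrapolation data beyond the fitted bins is
defined here.

One identifiability caveat matters for interpreting discovered models on
compositional data: since `x1 + x2 + x3 = 1` on every sample, the
constant and the linear terms of any library are collinear on the data
manifold, and individual coefficients of a discovered model are not
unique — different sparse representations produce the same field on the
simplex. Statements like "the learned `+c x3` cancels the assumed `-x3`
loss" are therefore checked in this package at the level of the model
*field* (the net `x3'` near the relevant states), which is identified,
rather than at the level of a single coefficient, which is not. The
package's own chain-recovery test spreads initial conditions slightly off
the simplex for the same reason.

## Numerical choices and degenerate inputs

* Grids are closed intervals; `round((T - t0)/dt) + 1` points, endpoints
  included. A zero-length span returns the initial state as a single row.
* Ground-truth integration failure raises an error carrying the last
  valid time; candidate-model failure during scoring is *not* an error —
  it is information (infinite RSS).
* Training solver: RK4, `substeps` per interval (default 4); validation
  and regression re-simulation use the same scheme, so stage-1 scores and
  stage-2 inputs are consistent. Candidate scoring uses LSODA at 1e-6
  tolerances, looser than data generation — candidates only need to be
  resolved well below the noise floor.
* All randomness flows from explicit integer seeds: dataset seeds derive
  per-sample substreams; network initialization (fan-in-scaled uniform)
  sits in `nn_spec`; batch shuffling is epoch-indexed from the training
  seed. Identical seeds give bit-identical runs on the same platform.
* STLSQ ties: a coefficient exactly at the threshold is kept
  (`|c| >= lambda`).

## Problem sizes used in the checks

The package's own end-to-end checks run scaled-down versions of the
benchmark studies, chosen as the smallest sizes at which the scientific
claims are cleanly visible: 50 training / 50 validation samples for the
predator–prey pipeline (against 200/50 in the full design), 30/20 for
the repressilator, single stage-1 configurations where the full grid
search is exercised separately at miniature sizes. At these sizes the
learned interaction coefficients land within roughly 10% of the truth at
0.1% noise — the full-size, full-grid pipeline tightens this — and the
topology is recovered at the top AICc rank. The complete 12-dataset,
five-method benchmark is hours of compute and is exposed as an explicit
long-run path (`compare_methods()` over all noise configurations), not
as part of the default checks.

## Known limitations

* Priors are species-wise linear; arbitrary nonlinear `g` would need the
  training core extended (the Jacobian of `g` enters the sensitivity
  propagation).
* Best-epoch selection leans on a noisy validation curve; at higher
  noise the selected epoch can be genuinely under-trained, which is
  visible as shrunken learned coefficients before it is visible as wrong
  topology.
* AICc ranks long-horizon prediction error; structurally correct
  oscillators with slightly wrong periods accumulate phase error and can
  rank below structurally wrong but flatter models at high noise. This
  is a property of the criterion, not a bug; inspecting the top-10 table
  is the recommended practice.
* No process noise, no delays, no PDEs, no six-species
  (mRNA + protein) repressilator; single-cell RNA-seq processing
  (clustering, pseudotime inference, batch correction) is upstream of
  this package and out of scope.
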