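# hybriddx

Data-driven discovery of ordinary differential equation models from noisy
multi-sample biological time series, for systems that are *partially*
known. The package targets the common situation in systems biology where
some terms of a dynamical model are trusted (growth, degradation, loss
rates) but the interaction structure is not: it learns the missing part
from data and returns it as interpretable symbolic equations, with model
selection at every stage.

## The method

The dynamics are modelled as a **hybrid dynamical system**

```
x' = f(x) = g(x) + NN(x),        x in R^d
```

where `g(x)` holds the known closed-form terms and `NN(x)` is a small
fully-connected neural network (tanh hidden layers, linear output) that
absorbs the unknown residual dynamics. Discovery is a two-stage pipeline:

1. **Fit the residual.** Training trajectories are cut into sliding
   windows of length `w` (step 1), shuffled into batches of size `b`, and
   the hybrid ODE is simulated from each window's first observation with a
   Runge–Kutta solver. The batch-mean MSE between simulation and data is
   backpropagated through the solver (exact gradients of the discrete
   solution via forward sensitivities) and minimized with Adam for 10
   epochs. A grid over `(w, b, learning rate)` is scored by validation
   loss — the mean full-span simulation MSE on held-out samples — and the
   best network is retained.

2. **Sparsify the residual.** The fitted model is re-simulated from the
   training initial conditions at step `dt` (which may be finer than the
   data), the network is evaluated pointwise on those states, and the
   regression `NN(X) = Theta(X) Xi` is solved by **sequentially
   thresholded least squares** (STLSQ: alternate ridge regression and
   hard-thresholding at `lambda` until the active set stabilizes) over a
   grid of `(dt, basis library, ridge alpha)`. Candidate models
   `x' = g(x) + Theta(x) Xi` are ranked by the corrected Akaike
   information criterion on `n` validation samples,

   ```
   AICc = n log(RSS/n) + 2k + 2(k+1)(k+2)/(n - k - 2),
   ```

   with `k` the number of learned nonzero coefficients and RSS the summed
   squared error of each candidate simulated over the training span.

Basis libraries cover polynomials (`poly_max_2`, `poly_2_3`, ...) and
repression Hill functions `1/(1 + x_i^n)` (`hill_1` ... `hill_3`,
`hill_max_3`, and mixed Hill/polynomial sets), so the same machinery
handles predator–prey interactions, gene-circuit repression, and
cell-state transition models.

Four baselines share the dataset and report formats: finite-difference
SINDy (`base_sindy`), finite-difference SINDy with known terms subtracted
(`base_known`), weak-form SINDy (`weak_sindy`), and a pure neural network
with `g = 0` (`pure_nn`).

Benchmark generators are included: the Lotka–Volterra predator–prey
system, the symmetric and asymmetric repressilator, additive and
multiplicative Gaussian observation noise at configurable levels, and a
truncated-Gaussian sampler for compositional cell-state-proportion
trajectories (epithelial / intermediate / mesenchymal) over pseudotime.

## Worked example

Recover the predator–prey model from a noise-free trajectory with
finite-difference derivatives and STLSQ:

```r
library(hybriddx)

p   <- ode_preset("lotka_volterra")            # alpha,beta,gamma,delta = 1.3, 0.9, 0.8, 1.8
tr  <- simulate_ode(p$system, p$x0, sim_grid(0, 4, 0.1))
lib <- build_library("poly_max_2", 2)
co  <- stlsq(eval_basis(lib, tr$states), finite_difference(tr)$values,
             alpha = 0, lambda = 0.1)
print(assemble_model(known_zero(2), co, lib))
#> <sindy_model> d = 2  library: poly_max_2
#> x1' = 1.3*x1 - 0.891*x1*x2
#> x2' = 0.792*x1*x2 - 1.8*x2
```

All four true terms are found, and only those; the coefficients differ
from the truth (0.9 and 0.8) only by the finite-difference truncation
error at step 0.1.

The full two-stage pipeline on noisy data, with the growth/death terms
assumed known:

```r
ds   <- make_dataset(p$system, p$x0, p$train_grid, p$test_grid,
                     noise_spec("additive", 0.001),
                     n_train = 50, n_val = 50, n_test = 50, seed = 1)
fit  <- train_hybrid(ds, known_part(c(1.3, -1.8)), nn_spec(2, 8, init_seed = 1),
                     w = 5, b = 5, train_config(lr = 0.01, epochs = 10, seed = 1))
rep  <- select_models(fit, ds, default_selection_grid("lotka_volterra"))
print(best_model(rep))
#> <sindy_model> d = 2  library: poly_max_2
#> x1' = [1.3*x1] - 0.82*x1*x2
#> x2' = - [1.8*x2] + 0.721*x1*x2
```

Bracketed terms are the fixed prior; the learned interaction terms have
the correct sign and form (`topology_correct` is `TRUE` for the top-ranked
model), with coefficients within about 10% of the truth at this noise
level and training budget. `run_experiment()` drives the same pipeline
from a declarative YAML config (including the stage-1 grid search), and
`compare_methods()` produces a method-by-dataset comparison table; both
are also reachable from the thin command-line wrapper in
`inst/scripts/hybriddx-cli.R`.

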