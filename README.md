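# endoreg

Mechanistic and neural modelling of endocrine gland networks, with
closed-loop intervention design — for systems biologists and methods
researchers who need a self-contained, reproducible sandbox for hormonal
regulation: no external data, everything generated, trained and controlled
in-package.

The stack has three layers:

1. **A mechanistic plant.** A directed gland network with signed couplings,
   first-order degradation and per-edge secretion responses,

   $$\frac{dh_i}{dt} = \sum_j \beta_{ij}\, g_{ij}(h_j) - \gamma_i h_i + u_i(t),$$

   integrated by fixed-step fourth-order Runge-Kutta with non-negativity
   clamping. Stimuli $u(t)$ are rectangular dose pulses over closed time
   windows. The simulator doubles as the synthetic-data generator (uniform
   initial states, Gaussian observation noise, seeded).

2. **A graph-attention recurrent forecaster.** Scalar concentrations are
   lifted to node features, passed through attention-weighted message
   passing over the gland graph (softmax attention with LeakyReLU scores,
   self-loops, row-wise L2 normalization), combined with an encoded
   stimulus, and fed through per-gland LSTMs (shared weights) with an
   affine readout to the next-step concentrations. Trained by teacher
   forcing under MSE with Adam (lr 5e-4, ×0.85 decay every 10 epochs),
   dropout 0.4, gradient clipping, early stopping — with backpropagation
   implemented analytically and verified against central finite
   differences.

3. **An adaptive regulation loop.** Per control step the controller
   minimizes
   $\sum_i w_i(\hat h_i(u) - h_i^{target})^2 + \lambda_{risk}\mathcal R(u)$
   with risk $\mathcal R(u) = \|u\|^2 + \sum_{i\neq j}\rho_{ij}|u_i-u_j|$,
   subject to the safety constraint $C(u)\le\epsilon$ via a hinge penalty;
   sensitivities flow analytically through the RK4 plant (or the
   forecaster). It logs deviations, a stability index
   $\|\Delta h(t+1)\|/\|\Delta h(t)\|$, and decays its learning rate with
   the distance to target. Patient-specific parameters (degradations,
   couplings) are personalized by Gaussian Bayesian inference — exact
   conjugate updates for linear-Gaussian observations, Laplace
   (Gauss-Newton) posteriors through the nonlinear plant otherwise.

## Worked example

Simulate the hypothalamic-pituitary-thyroid preset under a thyroxine
pulse, then regulate a two-gland cascade to clinical targets:

```r
library(endoreg)

net <- load_config(system.file("extdata", "hpt_axis.yaml",
                               package = "endoreg"), "network")
net
#> Endocrine gland network with 3 glands: TRH, TSH, T3
#> coupling (beta[i, j], effect of j on i):
#>     TRH TSH   T3
#> TRH 0.0 0.0 -0.5
#> TSH 0.8 0.0  0.0
#> T3  0.0 0.9  0.0
#> degradation rates: TRH=0.6, TSH=0.7, T3=0.5
#> secretion responses: identity, sigmoid

sched <- load_config(system.file("extdata", "thyroxine_pulse.yaml",
                                 package = "endoreg"), "schedule")
traj <- simulate_network(net, h0 = c(1, 0.8, 0.6), horizon = 6,
                         step = 0.01, schedule = sched)
traj
#> Hormone trajectory: 601 time points, 3 glands, t in [ 0 , 6 ]
#> final state: 0, 0.57673, 1.2495
```

The T3 pulse (dose 0.4 over t ∈ [1, 3]) raises circulating T3 to ~1.25,
and the negative feedback edge drives TRH to zero — the qualitative
signature of thyroid hormone replacement suppressing the upstream
secretagogue.

```r
fx  <- fixture_suite("linear_2g")
cfg <- control_config(targets = c(0.8, 1.2), intervention_lr = 0.5,
                      decay = 0.05)
log <- regulate(fx$network, cfg, h0 = c(1.5, 0.3), horizon = 30)
log
#> Closed-loop regulation log: 30 steps
#>   total deviation D: 1.3 -> 0
#>   final learning rate: 0.4685; max C(u): 0.4541
```

The controller finds the steady-state dose `u = (0.64, 0.12)` that holds
the plant exactly at the targets `(0.8, 1.2)`; `D` is the summed squared
distance to target, driven from 1.3 to 0.

Forecaster fitting follows the classic modelling idiom:

```r
data <- generate_dataset(fx$network,
                         synthetic_dataset_spec(50, horizon = 6, step = 0.1,
                                                noise_sd = 0.02, seed = 1))
fit <- endo_forecaster(data, fx$network,
                       config = training_config(max_epochs = 20, window = 10))
summary(fit)          # split sizes, losses, parameter count
predict(fit, data[[1]])                     # one-step predictions
rollout(fit, c(1, 1), steps = 20, dt = 0.1) # autoregressive forecast
```

A thin command-line interface wraps the same functions
(`system.file("exec", "endoreg", package = "endoreg")`), with subcommands
`simulate`, `make-dataset`, `train`, `forecast`, `control` and `fixtures`,
YAML configuration files, JSON run manifests and exit codes 0/2/3
(success / validation error / numerical failure).

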