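---
title: "Hybrid deep modeling of fed-batch cell culture: models, training and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid deep modeling of fed-batch cell culture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

`hybridfb` implements serial hybrid models of fed-batch bioreactor
cultures: the parts of the system that are well understood — the
macroscopic material balances of a perfectly mixed, fed-batch vessel — are
written as ordinary differential equations, while the part that lacks
mechanistic basis — the specific reaction kinetics of the cells — is
supplied by a feedforward neural network embedded in those balances.

For a state vector $c$ of $n_s$ extracellular concentrations (viable cell
density $X_v$, product, and metabolites) and culture volume $V$, with feed
streams $k$ at piecewise-constant rates $F_k(t)$ and inlet compositions
$c_{k,\mathrm{in}}$:

$$
\frac{dc}{dt} = v(c; w)\, X_v + \sum_k D_k\, c_{k,\mathrm{in}} -
  c \sum_k D_k, \qquad
\frac{dV}{dt} = V \sum_k D_k, \qquad D_k = F_k / V .
$$

The specific-rate vector $v$ (one entry per species, per-cell units) is a
feedforward network applied to the normalized state: the input layer is
$H_0 = c \oslash c_{\max}$ (element-wise division by each species'
absolute maximum), optionally augmented by the normalized volume
$V/V_{\max}$; hidden layers apply `tanh` (the classical shallow choice) or
`ReLU` (the deep choice); the output layer is affine and unscaled, so the
network learns rate magnitudes directly. The volume is a state variable in
addition to the measured concentrations, so a model with $n_s$ measured
species integrates $n_s + 1$ states.

$X_v$ is identified **by name** in the species roster, never by position.

## Integration

The coupled system is integrated with a fixed-step classical Runge–Kutta
(RK4) scheme. The substep grid between two output (sampling) times is
uniform, and feed-schedule breakpoints force additional step boundaries, so
every substep sees a constant feed rate; this makes the volume balance
exact for piecewise-constant schedules, a property the test suite asserts
to 1e-10. The default substep is 0.5 h between 24 h samples, which resolves
the culture dynamics comfortably; training-time analyses in the tests and
the acceptance script use 1 h substeps (the trajectories differ at the
1e-6 level at these time scales, far below measurement noise).

The state is integrated unconstrained; only the network inputs are clamped
at zero before normalization, which prevents extrapolation pathologies of
the network at (numerically) negative concentrations without hiding
balance errors. An optional post-step projection onto non-negative
concentrations exists and is off by default; the ground-truth generator
(below) enables it so that simulated "true" concentrations are physical at
every substep. Non-finite states abort integration with a classed
divergence condition carrying the failing time.

## Gradients: indirect and semidirect sensitivities

Training minimizes the weighted mean squared error
$\mathrm{WMSE} = \tfrac1T \sum_t (c_t^* - c_t)^2/\sigma_t^2$ over all $T$
non-missing scalar measurements, where $\sigma_t$ is the measurement SD.
Both gradient engines propagate **forward sensitivities through the same
RK4 substeps as the states** (discretize-then-differentiate), so the
computed gradient is the exact derivative of the discrete objective the
optimizer sees — the property the finite-difference oracle tests rely on.

* The **indirect** method carries $S = \partial y/\partial w$
  (dimension $(n_s+1) \times n_w$) through the stage recursion, with the
  source term $(\partial f/\partial v)(\partial v/\partial w)$ evaluated at
  every stage. Its cost grows linearly with the number of weights $n_w$.
* The **semidirect** method carries only quantities whose dimension is
  independent of $n_w$: the per-step state transition matrix and the
  sensitivities of the states with respect to the network's $n_s$ output
  channels. These are composed with the network weight Jacobian evaluated
  along the trajectory to assemble the identical gradient. The two methods
  are algebraically equivalent factorizations of the same discrete
  derivative, and the tests require agreement to 1e-6 (observed: machine
  precision) and agreement with central finite differences to 1e-4.

Measurement SDs of zero are disallowed; error models floor $\sigma$ at a
configurable fraction of the species maximum (default 2% for the relative
model) because the objective divides by $\sigma^2$.

## The two training regimes

**Classical (shallow) regime** — `train_lmm()`: damped Levenberg–Marquardt
steps on the weighted residual vector, with the residual Jacobian from the
indirect sensitivities. Damping adapts multiplicatively (×10 on rejection,
÷10 on acceptance, starting at 1e-3 — a standard Marquardt schedule, not
prescribed by the method description). Overfitting is controlled by
cross-validation against a **noise-augmented** copy of the training data:
every training measurement receives Gaussian noise with the SD of its own
measurement error, and training stops when the validation error has not
improved for `patience` consecutive accepted steps (default 25; a raw
"stops when it increases" rule is noisy iteration-to-iteration). The
augmented points are used purely for stopping, never in the training
objective, and both errors are recorded. The whole procedure restarts from
fresh uniform $U(-0.01, 0.01)$ initializations (default 10), keeping the
restart with the lowest validation error.

**Deep regime** — `train_adam()`: ADAM with the standard hyperparameters
($\alpha = 0.001$, $\beta_1 = 0.9$, $\beta_2 = 0.999$, offset
$\eta = 10^{-7}$, interpreted as the canonical denominator offset) and
stochastic regularization: each iteration samples a minibatch of **whole
experiments** (fraction 0.8, without replacement — the integration unit is
a trajectory, so subsampling time points would break the sensitivity
propagation) and one dropout mask (drop probability 0.2, hidden nodes
only, inverted scaling) held fixed for all time steps and experiments of
that iteration — a per-time-step mask would make the ODE right-hand side
discontinuous within a single gradient evaluation. Weights are kept at the
iteration with minimum full-batch maskless training WMSE; iteration 0 (the
initialization) is part of the trace. A single initialization is used.

Both trainers are bit-reproducible under a fixed seed. The generic
optimizer engines (`lm_optimize()`, `adam_optimize()`) are exposed
separately and are validated against the closed-form weighted
least-squares optimum on linear residual problems; exact weight-linearity
cannot be realized inside the hybrid model class itself because $X_v$
multiplies every rate, making every trajectory nonlinear in the
$X_v$-rate weights.

## Model selection

`aicc()` implements the small-sample corrected AIC,
$T\ln(\mathrm{WMSE}) + 2n_w + 2n_w(n_w+1)/(T-n_w-1)$, computed on the
training subset. $T$ is defined as the **total number of scalar residuals**
(a measured value at one time point for one species is one residual) — the
same $T$ that normalizes the WMSE. `resample_partitions()` draws random
batch-wise train/test partitions that are reused across all structures
under comparison, and `selection_report()` flags the structure with the
lowest mean test WMSE — the resampling rule, which takes precedence over
AICc when they disagree. A partition whose training diverges, returns a
non-finite objective, or lands more than 10× above the
variance-normalized constant-predictor baseline of its training subset is
recorded as unstable and excluded from the statistics (the published
analyses report such rows as "Unstable" without stating criteria; the 10×
rule is this package's operational definition).

## The synthetic data generator

Real process-development campaigns are proprietary, so the package ships a
generator whose output has the statistical structure such a study needs: a
mechanistic **ground-truth** model, a designed set of runs, and
heterogeneous Gaussian noise.

The ground truth is a deliberately reduced CHO-like kinetic model
(~30 rate parameters; `cho_kinetics()`), not a reimplementation of any
published large-scale metabolic model: Monod growth on glucose and
glutamine with mild ammonium inhibition; glutamine-driven decline of
growth into a death phase; overflow lactate production proportional to
growth-linked glucose uptake, switching to lactate consumption as
glutamine wanes (the classic metabolic shift, reproduced in every design
run of the default configuration); ammonium production from glutaminolysis
with late consumption; growth-coupled amino-acid uptake with multi-day
depletion profiles; and product synthesis that steps up at a configurable
induction time (default 96 h), emulating a temperature-shift induction.
Units are 1e9 cells/L, mM, g/L and hours, chosen so all specific rates are
of order 0.001–0.1 — realistic per-cell magnitudes that also keep the
unscaled network outputs on one scale. Because the induction step is an
explicit function of *time*, it is only partially identifiable from
concentrations alone; this is an intended, realistic mismatch (real
induction triggers are likewise invisible to the state vector).

The 9 runs come from a rotatable two-factor central composite design over
the pre- and post-induction feed rates (axial scaling $\sqrt 2$; center
$5\times10^{-4}$ / $8\times10^{-4}$ L/h for a 0.25 L culture). Extracellular
concentrations are recorded for 240 h at 24 h sampling (11 samples of 25
variables per run — the generator reports its own residual counts), and
noise with SD = 10% of each species' maximum over the noiseless dataset is
added. Simulations start from the known shared inoculation state rather
than the noisy first sample: all design runs share one inoculum, and at
10%-of-maximum noise a "measured" initial cell density can be negative,
which would be nonsense as an initial condition. A 30-variable,
24-experiment, daily-sampled variant with randomized feeds and the
relative error model (5% product / 10% cells / 20% metabolites, floored at
2% of each maximum) emulates the shape of an experimental campaign; it is
synthetic stand-in data and is labelled as such.

What the generator does **not** emulate: intracellular state (hidden
regulatory dynamics that make real kinetics history-dependent), missing
samples, batch-to-batch inoculum variability, and assay-specific error
structure. Passing tests on generated data therefore demonstrate that the
machinery — integration, gradients, trainers, selection — works and that
the method recovers a process of this complexity from noisy data; they do
not certify performance on any real campaign.

## Numerical choices and scales used by the tests

* Gradient checks: central differences at $h = 10^{-6}$; cross-method
  tolerance 1e-6; FD tolerance 1e-4 (10 random small problems).
* RK4 order check over substeps 0.5/0.25/0.125 h; washout oracle is the
  exact fed-batch solution $c_\mathrm{in} + (c_0 - c_\mathrm{in}) V_0/V(t)$
  (a *constant* dilution rate is unrealizable in a fed-batch balance, so
  the constant-volume exponential form is only its limit).
* Noise-floor check: the ground truth scores WMSE in [0.85, 1.15] against
  its own noisy data over ≥ 2000 residuals (chi-square concentration).
* Training checks run at reduced scale: 300 ADAM iterations for the
  denoising check (noise-free test error below noisy test error), 500 for
  the identifiability check (noisy test WMSE within [0.8, 3]), against the
  full protocol's 1000; the structure sweep uses 3 structures × 2 trainers
  × 2 partitions with 100 ADAM iterations / 20 LM steps. These sizes are
  the package's own test design; the full-scale protocol is available
  through the same functions.
* ReLU subgradient at 0 is 0; the clamp derivative at exactly 0 is 0.
* Weight flattening order: layer by layer, connections row-major, then
  biases (documented contract used by the gradient tests).

## A practical note on narrow deep ReLU networks

Under the prescribed initialization ($U(-0.01, 0.01)$) and non-negative
normalized inputs, narrow deep ReLU hybrid networks (e.g. two hidden
layers of 10) can collapse early in ADAM training: units whose
pre-activations go negative for every training state receive no gradient
and die, and with only 10 units per layer the network can degenerate to
its output bias. This mirrors the published observation that deep
structures below a certain width train to very high or unstable errors
while wider ones do not. The package's fixed-architecture acceptance
checks therefore use `tanh` hidden layers (which cannot die) at width 10,
and exercise ReLU in the structure sweep and at larger widths. Users
building deep ReLU models should prefer widths ≳ 15–20 per layer at these
input scales.

## Known limitations

* Fixed-step RK4 only; stiff kinetics would need smaller substeps (no
  adaptive or implicit solvers, by design).
* No pH/DO/temperature sub-models: environmental control is assumed
  external, and induction enters only through the ground-truth generator.
* The semidirect engine stores per-stage network weight-Jacobians
  transiently per step; memory grows with $n_w$, though the carried ODE
  dimension does not.
* `AICc` requires $T > n_w + 1$; structures too large for their training
  set are rejected rather than scored.

## Minimal workflow

```{r workflow}
library(hybridfb)

ds <- synthetic_cho_dataset(seed = 1)        # 9-run CC-DoE dataset
split <- doe_split(ds)                       # center+square train, star test

layout <- network_layout(25, c(10, 10), 25, "tanh", extra_inputs = "volume")
model <- hybrid_model(ds$species, layout, vmax = ds$vmax, substep = 1)

run <- train_adam(model, ds, adam_config(iterations = 300, seed = 11,
                                         substep = 1), ids = split$train)
fitted <- hybrid_model(ds$species, layout, weights = run$weights,
                       vmax = ds$vmax, substep = 1)
dataset_wmse(fitted, ds, ids = split$test)$wmse          # noisy test error
dataset_wmse(fitted, ds, ids = split$test, truth = TRUE)$wmse  # noise-free
```
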