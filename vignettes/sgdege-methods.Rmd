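---
title: "Stochastic gradient descent with estimated global errors: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stochastic gradient descent with estimated global errors: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup, message = FALSE}
library(sgdege)
```

# The problem

Cerebellar learning theories must explain how a single, scalar evaluation of
a movement can improve the firing of many output neurones at many time
points: a credit assignment problem. The classical picture (climbing fibres
broadcast the error, active parallel-fibre synapses are depressed) optimises
at most the population-average signed error. This package implements, as
reusable simulators, a perturbation-based alternative: *stochastic gradient
descent with estimated global errors* (SGDEGE). Spontaneous climbing-fibre
"perturbation complex spikes" transiently raise the firing of small groups
of Purkinje cells during a movement; whether the resulting change made the
movement better or worse is signalled by the presence or absence of a
subsequent "error complex spike", emitted when the global error exceeds an
adaptively learned inhibitory estimate of its own average at the inferior
olive. Synapses tagged by the perturbation are then potentiated or depressed
accordingly — a gradient descent that needs only a single broadcast bit per
movement.

The package contains four models, from most to least detailed:

1. `run_network()` — a full cerebellar microzone (mossy fibres, Purkinje
   cells, nuclear projection and nucleo-olivary neurones).
2. `run_mai()` — the Marr-Albus-Ito broadcast-error baseline on the same
   microzone, which demonstrates the credit-assignment failure.
3. `run_reduced()` — a single P-cell reduction whose two-dimensional state
   admits a complete phase-plane analysis (`corridor_geometry()`,
   `check_convergence_conditions()`).
4. `run_perceptron()` — an analog perceptron trained with SGDEGE or with the
   delta rule, for learning-speed and storage-capacity comparisons
   (`capacity_scan()`).

# The microzone model

`S * L` Purkinje cells (PC) sit on a grid, `S` sagittal rows by `L` lateral
columns. Each movement lasts `T` time bins. `N` mossy fibres (M) per row
carry binary input; a movement (pattern) activates exactly half of the
`N * S` fibres, each in one random time bin. All rates pass through the
saturating threshold-linear f-I curve `phi()` (0 below zero, linear,
saturating at `rmax`).

Rates for pattern activity `M`, contact mask `sigma` (probability 1/2) and
perturbations `eta`:

$$PC_{s,l}(t) = \Phi\Big(\sum_i w_{i,s}^l \sigma_{i,s}^l M_{i,s}(t) + \eta_l(t) A\Big)$$

$$PN_l(t) = \Phi\Big(\sum_{i,s} u_{i,s}^l M_{i,s}(t) + u_{PC\to PN} \sum_s PC_{s,l}(t)\Big)$$

and the analogous nucleo-olivary (NO) expression with plastic weights `v`
and `u_{PC\to NO} = q\,u_{PC\to PN}`. Each fibre contacts exactly one
projection neurone and one nucleo-olivary neurone (the same column in the
default model). The global error of a movement is the mean absolute
difference between projection-neurone output and target,
$\mathcal{E} = \langle |PN - R| \rangle$, and the olivary inhibition is the
mean nucleo-olivary rate $\mathcal{I} = \langle NO \rangle$. An error
complex spike is broadcast when $\mathcal{E} - \mathcal{I} > 0$; its
presence/absence sets the update sign `c` (`ecs_sign()`; the tie emits no
spike, `c = -1`). The two plasticity rules are

$$w \leftarrow w - \alpha_w\, c \sum_t \eta_l(t) M_{i,s}(t), \qquad
  v \leftarrow \Big[v + \alpha_v\, c \sum_t M_{i,s}(t)\Big]_+ .$$

`w` changes only at synapses active in the same bin as a perturbation of
their column's climbing fibre; `v` changes at every active synapse and is
rectified at zero. `w` is not sign-constrained: effective negative weights
stand in for plasticity of interneuron pathways.

## Parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `S`, `L`, `T`, `N` | 10, 40, 10, 2000 | counts | microzone geometry |
| `rmax` | 300 | Hz | saturation of the f-I curve |
| `rho` | 0.03 | probability | perturbation per climbing fibre per movement |
| `A` | 2 | Hz | perturbation amplitude |
| `alpha_w`, `alpha_v` | 0.02, 0.0002 | Hz | learning rates |
| `rbar_PC`, `rbar_D` | 50, 30 | Hz | mean PC / nuclear rates |
| `q` | 0.5 | — | PC→NO strength relative to PC→PN |
| `NO0` | 15 | Hz | initial mean NO rate |

The fixed weights are not free: `u_M_PN = 4 T L rbar_D / (N S)` (= 2.4),
`u_PC_PN = -rbar_D / (rbar_PC S)` (= -0.06), `u_PC_NO = q u_PC_PN`. Initial
plastic weights are uniform, `w` on `[0, 8 T rbar_PC / N]` and `v` on
`[0, (NO0 + q rbar_D) 4 T L/(N S)]`, so that initial PC rates average
`rbar_PC`, nuclear rates average `rbar_D`, and the initial inhibition
already sits within ~1 Hz of the expected initial error — `NO0 = 15` Hz is
chosen precisely for that.

## Trial accounting

Learning curves for interleaved patterns are counted in *trials per
pattern*: the reference run presents `p = 2` patterns cyclically for 60,000
trials each, i.e. 120,000 presentations. `run_network()` itself counts
presentations (the natural simulator unit); the `network` recipe converts.
Summary windows are the first 500 trials per pattern and the final 1/12 of
the run (trials 55,000–60,000 per pattern at the reference length); both are
configurable through `glance()`'s underlying windows and were chosen to
estimate the initial and final error robustly against single-trial noise.

# The Marr-Albus-Ito baseline

`run_mai()` shares geometry, rates, connectivity and initial weights, but
has no perturbations and no nucleo-olivary population. The broadcast error
is either the signed population mean `mean(R - PN)` or the unsigned
`mean(|PN - R|)`. When the error is positive, active synapses are depressed
by `alpha_w`; otherwise *all* weights drift up by `beta_w` (0.002) — the
drift is applied to every weight, exactly as the rule is usually stated.
With the signed error the population mean firing converges to the mean
target while individual profiles remain wrong (the unsigned error stays
high); with the unsigned error, which is never negative, the rule only
depresses, Purkinje rates pin at the rectifier and the error grows. The
signed-mode demonstration uses a 50 Hz target mean so that the population
mean has somewhere to travel; the unsigned mode uses the standard 30 Hz
statistics.

# The reduced model

The reduced model keeps two scalars: the P-cell rate `P` and the mossy
drive `J` to the nucleo-olivary pathway. Each trial is perturbed with
probability `rho`; the error is `|P (+A) - R|` and the estimate is the
rectified inhibition `[J - qP (-qA)]+`. Their comparison gives `c`;
perturbed trials move `P` by `-c dP`, every trial moves `J` by `+c dJ`.
Update directions flip on two borders of the `(P, J)` plane — `C` (the
perturbed-trial comparison) and `D` (unperturbed) — whose half-lines bound
two "convergence corridors". For `q < 1` the corridor closes at

$$(P^*, J^*) = \big(R - A(q+1)/2,\; qR + (1-q^2)A/2\big),$$

so the final error fluctuates around `A(q+1)/2`; sufficient conditions for
reaching and descending a corridor are `0 < rho < 1`, `dJ < (1-q)A` and
`dP + dJ/(1+q) < A`. At `q = 1` these conditions fail and the error grows to
its maximal admissible value `~A` (empirically the dynamics still hover
there); for `q > 1` the borders never cross and `P` travels past the target
without stopping. Near `rho = 1` the rare unperturbed trials are the only
`J`-only corrections, so convergence still occurs but slowly — the tests use
a long run for that case.

Two conventions required a decision. Ties (`error == estimate`) emit no
error complex spike, consistently with the network's strict inequality. On
unperturbed trials the estimate is rectified, `[J - qP]+`, consistent with
the definition of the inhibition; the literal unrectified variant (which
differs only when `J < qP`) is available via `rectify_unperturbed = FALSE`.

# The analog perceptron

A single P-cell with `Nm = 1000` binary inputs at coding level `f = 0.2`,
rate `P = Phi(gamma (w·x - theta) + A [perturbed])` saturating at
`Pmax = 100` Hz, threshold `theta = 12.85`, `gamma = 1`, and non-negative
weights. SGDEGE uses the reduced-model steps (`A = 2`, `dP = 0.2`,
`dJ = 0.4`, `rho = 0.2`, `q = 0.5`); per-synapse steps are divided by
`gamma * n_active` so one update moves the pattern's rate by exactly `dP`
in the linear regime, which is what makes the reduced-model corridor
analysis apply pattern by pattern, including the error floor `A(1+q)/2`
(1.5 Hz at the defaults). A printed example elsewhere gives "1.5A" for
`q = 0.5`; the formula `A(1+q)/2` (= 0.75A), which is consistent with the
fixed point and with the `q = 0` case, is used throughout.

The delta rule is the full-information comparison: active weights move by
`lr (R - P) / (gamma n_active)`, i.e. the rate moves by `lr (R - P)`,
with `lr = 0.1` by default and the same rectification of weights. We use
the plain proportional form rather than a step-capped variant: the
comparisons made with it (zero final error below capacity, faster learning
than SGDEGE) are properties of convergence, not of a particular rate, and
the proportional form is the field's standard.

Targets default to uniform on `[0, 2 * 30]` Hz and input/target statistics
are arguments of `perceptron_params()` and recorded in results, because the
storage capacity depends on them strongly. Under these default statistics
the empirical critical pattern count of the delta rule — measured by
`capacity_scan()` as the largest `p` whose final error falls below 1 Hz —
is of order one hundred (the test suite shows convergence at 10 patterns
and failure by 120).
A much larger theoretical capacity figure is sometimes quoted for
sign-constrained analog perceptrons with these size parameters; it is not
reproducible under any rate-like association statistics we examined
(verified against an independent linear-programming feasibility check
during development), because with non-negative inputs *and* weights the
patterns with low targets cap most weights, making spread-out targets
jointly infeasible at a few hundred patterns. Deriving capacity formulas is
out of scope here; `capacity_scan()` reports what the simulated rules
actually achieve under explicit, recorded statistics.

# Randomness and reproducibility

Every simulator takes a single integer seed. Named substreams (patterns,
targets, connectivity, initial weights, perturbations) are derived from it,
so changing the trial count never changes the generated patterns, and the
compiled and pure-R engines consume identical draws. All randomness is drawn
in R; the C++ loops are deterministic given their inputs, and the `"r"`
engines reproduce them to floating-point summation order (the suite asserts
equality at 1e-10 and typically observes 1e-15). The network loop maintains
per-pattern synaptic-drive caches incrementally — only the ~0.1% of synapses
touched per trial are updated — which is exact, not an approximation, and is
verified against the naive reference. Indices (patterns, fibres, trials) are
1-based throughout, as is idiomatic in R. All arithmetic is double
precision.

# What the synthetic inputs do and do not emulate

The generators reproduce the model's stated input statistics: exact-count
sparse binary mossy-fibre patterns with one active bin per fibre, uniform
target-rate profiles, Bernoulli contact masks and uniform nuclear
assignments. They do not emulate realistic granule-cell population codes —
temporal bursts, rate (rather than binary) coding, or correlations between
fibres or patterns. Passing tests therefore demonstrate the learning
algorithm's behaviour under its defining conditions, not performance on
physiological input statistics.

# Problem sizes used by the test suite

The acceptance-level tests run the reference microzone (S=10, L=40, T=10,
N=2000) for 60,000 trials per pattern, three seeds, plus the 9-run
sensitivity sweep; the reduced-model sweeps use 1e4–1e6 trials; perceptron
runs use up to 20,000 sweeps at up to 450 patterns. Unit tests use small
microzones (2–4 cells per population) where compiled and naive
implementations are compared exhaustively.

# Known limitations

* Rate-based, discrete-bin dynamics: no spiking, conduction delays,
  eligibility-trace kinetics or molecular plasticity models; the olive is a
  threshold comparator.
* The climbing-fibre perturbation is one bin, one amplitude; biological
  complex spikes are richer.
* Sensitivity analysis covers the four key convergence parameters
  (`alpha_w`, `alpha_v`, `rho`, `A`) at +/-10%, not a global exploration.
* Storage-capacity results are empirical under stated statistics (see
  above).
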