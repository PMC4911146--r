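---
title: "Continuous-signal-coding spiking networks: models, training, and control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Continuous-signal-coding spiking networks: models, training, and control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7,
                      fig.height = 3.2)
set.seed(1)
```

```{r setup}
library(pcsn)
```

This vignette documents the models and numerical methods implemented in
`pcsn`: deterministic spiking networks whose spikes *code* continuous
dynamical variables, trained online by recursive least squares so that the
emergent continuous dynamics realize a desired computation — periodic pattern
generation, chaotic-attractor imitation, input-driven memory, and a learned
forward model used for stochastic optimal control.

## 1. Continuous signal coding by spiking neurons

The package implements leaky integrate-and-fire neurons. Neuron $n$ has a
membrane potential $V_n(t)$ and emits a spike train $s_n(t)$; each spike
increments a synaptically filtered trace
$$\dot r_n = -\lambda_s r_n + s_n(t),$$
which decays with the synaptic rate $\lambda_s$. The central idea is that a
*continuous* signal is jointly coded by the membrane potential and the
synaptic trace, so that spiking is not noise around a rate but a
deterministic part of a continuous dynamical system.

### Direct coding with saturating synapses

Each neuron codes one signal component $x_n = V_n + \theta r_n$. The
membrane dynamics are
$$\dot V_n = -\lambda_V V_n + A_{nm}\tanh(\gamma\, r_m) +
V_{\mathrm r}\lambda_s r_n - \theta s_n(t) + I_{e,n}(t),$$
with threshold at $\theta/2$, reset by $-\theta$ (so that $x_n$ is continuous
across spikes), a saturating synaptic nonlinearity $\tanh(\gamma r)$ with
$\gamma = \theta$ by default, and an after-depolarization ("recovery")
current of integrated size $V_{\mathrm r}$ that partially refunds the reset.
In the limit of fast synapses and suprathreshold activity, $x_n$ follows the
rate dynamics
$$\dot x_n = -\lambda_x [x_n]_+ - \lambda_V [x_n]_- +
A_{nm}\tanh\!\big(\tfrac{\gamma}{\theta}[x_m]_+\big) + I_{e,n}(t),
\qquad \lambda_x = \lambda_s\big(1 - V_{\mathrm r}/\theta\big),$$
i.e. the recovery current slows the decay of positive activity from
$\lambda_s$ down to $\lambda_x$.

### Distributed coding with nonlinear dendrites

$N$ neurons jointly code $J \le N$ signals $\mathbf x \approx \Gamma\mathbf
r$ through a decoding matrix $\Gamma \in \mathbb R^{J\times N}$. Requiring
that the decoded signal follow target dynamics
$\dot{\mathbf x} = -\lambda_x \mathbf x + A\tanh(\mathbf x + \mathbf b) +
\mathbf c(t)$ fixes the connectivity in terms of $\Gamma$ and $A$:

* slow (filtered) recurrent input through nonlinear dendrites,
  $\Gamma^T A \tanh(\Gamma \mathbf r + \mathbf b)$;
* slow linear input $-\tilde U \mathbf r\,$ with
  $\tilde U = a\,\Gamma^T\Gamma + \mu\lambda_s I$, $a = \lambda_s -
  \lambda_x$;
* fast (unfiltered) lateral input $-U \mathbf s(t)$ with
  $U = \Gamma^T\Gamma + \mu I$, whose diagonal implements the reset;
* thresholds $\theta_n = U_{nn}/2$.

The parameter $\mu$ penalizes spike-rate magnitude and regularizes the code;
the columns of $\Gamma$ are normalized to a common norm $\gamma_s\sqrt J$,
which makes all thresholds equal and distributes spiking uniformly. External
input enters through the coded variables, $I_e = \Gamma^T(W f(t))$.

`dendritic_network()` and `saturating_network()` construct these
specifications; `derive_dendritic_params()` exposes the mapping from
$(\Gamma, A, \mu, \lambda_x)$ to $(D, U, \tilde U, \theta)$. The recurrent
matrix $A$ is sparse (connection probability $p$) with Gaussian weights
scaled so its spectral radius is approximately $g$.

### Why the code works: rate-model equivalence and echo state property

`integrate_rate_saturating()` and `integrate_rate_dendritic()` integrate the
corresponding ideal rate dynamics with a classical Runge–Kutta scheme. They
serve as *oracles*: a correctly implemented spiking network, enslaved to the
same input, must decode to the oracle's trajectory up to one coding quantum
($\theta$, respectively one spike's contribution to $\Gamma\mathbf r$). The
test suite enforces this equivalence and its improvement with network size.
`echo_state_sufficient()` checks the sufficient contraction condition
$\lVert A\rVert_2 < \min(\lambda_V, \lambda_x)$ under which two rate
trajectories driven by the same input converge — the regime in which the
network reliably maps inputs to outputs without self-generated dynamics.

## 2. Numerical integration

Simulation is grid-based (`csn_run()`, step `dt`). Between spikes the
synaptic traces decay analytically within each step; membrane potentials are
advanced with a fourth-order Runge–Kutta scheme for deterministic dynamics
and an Euler–Maruyama scheme when white-noise robustness input
($\sigma_\eta > 0$) is enabled (a plain Euler scheme is also available, used
by the sawtooth benchmark). After each step, threshold crossings are
processed *sequentially*: the neuron with the highest membrane potential
above threshold spikes first, its fast effect ($-U$ column) is applied, and
the procedure repeats on the updated potentials. This ordering emulates a
small conduction delay and prevents synchronous over-spiking of neurons
coding similar features; more than $10N$ sequential spikes in one step abort
the simulation as runaway excitation. Outputs $z = w_o\,\tilde r$ are linear
readouts of the activations $\tilde r$ ($\tanh(\gamma r)$ for direct coding,
$\tanh(\Gamma r + b)$ for distributed coding), recorded at end-of-step
times.

## 3. Learning

`readout_learner()` holds the readout weights and the inverse-correlation
matrix $P$ (initialized to $I/\alpha$). Every $\Delta t_{\mathrm{update}}$
(default 10 ms) recursive least squares updates
$$P \leftarrow P - \frac{P\tilde r \tilde r^T P}{1 + \tilde r^T P \tilde r},
\qquad w_o \leftarrow w_o - e\,(P\tilde r)^T,$$
with the error $e = z - F$ evaluated *before* the weight update. One pass of
these updates solves ridge regression with penalty $\alpha$ exactly (a
property the test suite verifies), which is what makes online training
stable at high gain.

Autonomous pattern generation requires output feedback. The package
implements it in two exactly equivalent forms (verified step-for-step in the
tests): an explicit feedback loop that injects $w^{f} z$ (optionally mixing
the network's output with the target, `feedback_spec(mix = ...)`), and
*absorbed* feedback, where the rank-one update $-w^{f} e (P\tilde r)^T$ is
folded directly into the recurrent matrix ($A$, or $D = \Gamma^T A$ for the
distributed code). Absorbed training (`learn = "force_rec"`) turns the
trained computation into genuine recurrent connectivity.

## 4. Benchmark experiments

`csn_preset()` / `run_preset()` package the experiments end to end:

| preset | variant | task |
|---|---|---|
| `fig3b` | dendritic | sine $2\sin(t/2)$, period $4\pi$ s |
| `fig3d` | saturating | sawtooth, period 2 s |
| `fig3e_sat`, `fig3e_dendr` | both | two-frequency superposition $\sin(2t)+\cos(t)$ |
| `fig3fgh` | dendritic | Lorenz attractor imitation |
| `fig4abc` | saturating | delayed reaction (9 s) to input pulses |
| `fig4d` | dendritic | instruction-switched computation with persistent memory |
| `fig5` | dendritic | pendulum forward model + path-integral control |

Tasks are generated by `pattern_task()`, `lorenz_task()`,
`delayed_reaction_trials()`, `instruction_task_signals()` and
`simulate_pendulum()`. Quality metrics include the mean spike rate
(`mean_spike_rate()`), the phase-aligned normalized RMSE for periodic
patterns (`phase_aligned_nrmse()`, which removes the free recall phase by
FFT cross-correlation), the normalized delayed-reaction error
(`delayed_reaction_error()`, 1 = fully extinguished response), and the
tent-map analysis of successive Lorenz maxima (`tent_map_outliers()`), which
scores whether generated chaotic trajectories respect the attractor's
first-return structure rather than merely resembling it.

A worked example (scaled down so the vignette builds quickly — problem sizes
throughout the package's examples and tests are the package's own choice):

```{r example, eval = FALSE}
res <- run_preset("fig3b", seed = 1, N = 200, J = 20, Tt = 40, recall = 40)
res$metrics  # mean spike rate (Hz) and phase-aligned NRMSE
```

Two conventions deserve note. First, the decoding-matrix normalization
pins each column of $\Gamma$ to norm $\gamma_s\sqrt J$; the per-neuron spike
rate at a given coded trajectory scales inversely with this norm, so
reported rates are meaningful only relative to the stated convention.
Second, the sawtooth target is the rising ramp of period 2 s spanning
$[-5, 5]$. Training of autonomous patterns starts from a small random
synaptic state because the silent network is a fixed point of the
deterministic dynamics.

For the delayed-reaction experiment, the memory that bridges stimulus and
response lives in the recurrent network dynamics, and its quality depends on
the recurrent gain $g$ relative to the effective leak $\lambda_x$: for
$g \ll \lambda_x$ activity (and the memory) dies out, for $g \gg \lambda_x$
self-sustained chaotic activity overwrites it, and an intermediate,
moderately supercritical $g$ retains it best. The package's choice of the
three regimes for this experiment is set in the acceptance tests.

## 5. Path-integral control with a learned world model

`train_world_model()` drives a noisy damped pendulum
($\ddot\varphi = -0.1\,\dot\varphi - 10\sin\varphi + \xi + u$) with
white-noise force, and trains a dendritic-code network that receives the
same force as input to predict $(\sin\varphi, -\cos\varphi, \dot\varphi)$
through its readout, with an explicit feedback loop that mixes the network's
own prediction with the true trajectory during training.

`control_loop()` then performs receding-horizon stochastic optimal control:
every $\Delta$ seconds the forward model (either the true plant,
`pendulum_plant()`, or the trained network, `pcsn_world_model()`) simulates
$M$ rollouts under fresh exploration noise $\xi_i$ from the currently
observed state; each rollout is scored by its accumulated height
$R_i = \int y\,dt$, and the applied control is the softmax-weighted average
$$u = \sum_i \frac{e^{\lambda_c R_i}}{\sum_j e^{\lambda_c R_j}}
\,\bar\xi_i,$$
where $\bar\xi_i$ is the rollout's noise averaged over the first $\delta$
seconds (computed with a log-sum-exp stabilized softmax;
`path_integral_control()`). Because $R_i$ is a continuous-time integral, the
inverse temperature $\lambda_c$ must scale inversely with the resolution at
which costs are accumulated: a weighting of $0.01$ per $1\,$ms cost step
corresponds to $\lambda_c = 10\,\mathrm{s}^{-1}$ in this convention, which is
the value used by the `fig5` preset (a weighting so soft that
$|\lambda_c R_i| \ll 1$ leaves the softmax uniform and produces no net
control). Before each planning cycle the network model is
synchronized to the observed plant state by briefly clamping its feedback to
the observation. With a well-trained model the controller swings the
pendulum up and holds it inverted despite sustained process noise; model
realizations differ in quality, and unsuitable ones fail to do so.

```{r control, eval = FALSE}
model <- pendulum_plant()
cfg <- control_config(M = 200, horizon = 1, delta = 0.1, Delta = 0.01,
                      lambda_c = 10)
loop <- control_loop(model, cfg, duration = 20)
mean(-cos(loop$phi[loop$time > 15]))  # mean height, +1 = inverted
```

## 6. Reproducibility

All randomness flows through R's RNG (`set.seed()` before any draw;
`run_preset(seed = ...)`). Simulation traces, spike logs, task signals and
network specifications can be written as plain-text TSV/JSON
(`write_spike_log()`, `write_task_signals()`, `write_network_spec()`).
The package's acceptance script (`scripts/acceptance.R`) recomputes the
headline benchmark quantities from scratch against the installed package.
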