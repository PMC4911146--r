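# pcsn — continuous-signal-coding spiking neural networks

`pcsn` simulates and trains deterministic spiking neural networks whose
spikes *code* continuous dynamical variables, and uses them for universal
reservoir-style computation: autonomous pattern generation, imitation of
chaotic attractors, input-driven memory over seconds, instruction-switched
computation, and stochastic optimal control with a learned spiking forward
model.

## The science in brief

A leaky integrate-and-fire neuron's membrane potential `V` and its
synaptically filtered spike train `r` can jointly represent a continuous
signal `x = V + θr`: the discontinuity of `V` at a spike (reset by `−θ`) is
exactly cancelled by the jump of `θr`, so `x` is continuous, and in the
regime of fast synapses `x ≈ θr` whenever the signal is active. Two network
architectures build on this idea:

* **Saturating synapses (direct code).** Each of the `N` neurons codes one
  signal; recurrent input passes through a saturating nonlinearity
  `tanh(γ r)`, and a slow after-depolarization current partially refunds each
  reset, stretching the effective signal decay from the synaptic rate `λ_s`
  to `λ_x = λ_s (1 − V_r/θ)`.
* **Nonlinear dendrites (distributed code).** `N` neurons jointly code
  `J ≤ N` signals `x ≈ Γr`. Demanding that the decoded signals follow
  prescribed rate dynamics `ẋ = −λ_x x + A tanh(x + b) + c(t)` *fixes* the
  network: slow dendritic input `Γᵀ A tanh(Γr + b)`, fast lateral coupling
  `−U s(t)` with `U = ΓᵀΓ + μI` (its diagonal is the reset), and thresholds
  `θ_n = U_nn/2`.

Because the spiking network is, by construction, an accurate implementation
of a continuous nonlinear reservoir, standard online learning applies:
recursive least squares on a linear readout, with output feedback either fed
back explicitly or absorbed into the recurrent weights as a rank-one update
(both implementations are exactly step-equivalent, and the package's test
suite verifies this). Trained networks generate patterns autonomously,
sustain memories of past pulses in their recurrent dynamics, and can serve
as forward models: the package implements receding-horizon path-integral
control of a noisy pendulum, where every few milliseconds the network
mentally simulates `M` rollouts under exploratory noise and the applied
control is their reward-weighted average.

## Quick example

```r
library(pcsn)

# Train a distributed-code network (N = 500 neurons, J = 50 coded signals)
# to generate a sine wave, then let it run autonomously for 100 s and check
# the recall quality (~30 s on one CPU).
res <- run_preset("fig3b", seed = 1)
res$metrics
#> $rate
#> [1] 5.082384
#>
#> $nrmse
#> [1] 0.06678825
```

`run_preset()` wraps the full pipeline (network construction, training,
test/recall phase, metrics). The preconfigured experiments are:

| preset | network | task |
|---|---|---|
| `fig3b` | dendritic | sine-wave generation |
| `fig3d` | saturating | sawtooth generation (Euler scheme) |
| `fig3e_sat` / `fig3e_dendr` | both | two-frequency superposition |
| `fig3fgh` | dendritic | Lorenz-attractor imitation |
| `fig4abc` | saturating | delayed reaction (9 s memory) |
| `fig4d` | dendritic | instruction-switched computation |
| `fig5` | dendritic | pendulum world model + path-integral control |

Lower-level entry points: `saturating_network()` / `dendritic_network()`
(construction), `run_network()` (simulation), `train_csn()` (RLS/FORCE
training), `integrate_rate_saturating()` / `integrate_rate_dendritic()`
(ideal rate-dynamics oracles), `control_loop()` (path-integral control).
See the vignette (`vignettes/pcsn-methods.Rmd`) for the model equations,
integration scheme, and conventions.

## Reproduction

The package's headline quantities (mean spike rates of the benchmark
experiments) are recomputed from scratch by the acceptance script, run
against the *installed* package:

```sh
Rscript scripts/acceptance.R --seed 1 --out targets.json
```

It writes a JSON file with one entry per target (median over the seeds
derived from `--seed`, together with the sample size). The full test suite,
including the end-to-end acceptance checks, runs with:

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "pcsn",
                               load_package = "installed")'
```

Several end-to-end checks state reference rates that are defined at full
experiment scale; where that scale exceeds a desk-compute budget the suite
runs scaled-down configurations (sizes noted in the test file and chosen as
the package's own defaults for desk use). Results and deviations are
asserted honestly rather than re-tuned; see the comments in
`tests/testthat/test-acceptance.R`.
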