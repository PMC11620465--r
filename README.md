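# qifnet

Ephaptic and synaptic spiking networks with multiscale-entropy complexity.

`qifnet` asks a concrete computational-neuroscience question: does *ephaptic*
communication — the direct electric-field interaction between neighbouring
neurons, with no chemical or electrical synapse in between — change the
complexity of the collective electrical activity of a neuronal network? The
package is written for modellers who want to simulate the competing
communication layers and quantify the resulting local field potential (LFP)
with a single, well-defined complexity score.

## The model

Each of the `N` neurons is a quadratic integrate-and-fire unit with an
ephaptic term (QIF-E). Membrane potential `V_i` (mV) evolves in time (s) as

    dV_i/dt = a_i V_i^2 + b_i V_i
              - sum_{j != i} c_ij (V_i - V_j)          (ephaptic layer)
              + sum_{k ~ i} s_k * omega * e^{-(t - t0_k)/T}   (synapses)
              + I

with the hyperpolarisation reset `V_i(t) >= 90 mV  =>  V_i(t+1) = -5 mV`,
the spike time recorded at the crossing step. Per-neuron coefficients are
heterogeneous, `a_i ~ U(25 ± 5%)`, `b_i ~ U(30 ± 5%)`, with constant drive
`I = 9.5`; an uncoupled neuron at the nominal values fires tonically with
period `∫ dV/(aV² + bV + I) ≈ 0.879 s`.

* **Synaptic layer** — a Watts–Strogatz small-world graph (`nb` first
  neighbours, rewiring probability `rp`); each presynaptic spike injects a
  current-based kernel of intensity `omega` decaying with `T = 6 ms`;
  `s_k = ±1` marks excitatory/inhibitory neurons.
* **Ephaptic layer** — all-to-all, with coupling constants
  `c_ij = factor / ring_distance(i, j)` (default `factor = 1e-2`),
  symmetric and conservative: the total ephaptic drive is exactly zero.
  Switching this layer off (`ephaptic = FALSE`) gives the pure synaptic
  network.

The network is integrated by forward Euler (`dt = 1 ms`, 60 s with the
first 10 s discarded), and the LFP is the spatial mean of all membrane
potentials, `x(t) = mean_i V_i(t)` — 50 000 samples at the defaults.

Complexity is measured by multiscale entropy: the LFP is coarse-grained at
scale factors `tau = 2..100` (non-overlapping block means), sample entropy
`S_E = -ln(A/B)` is computed at each scale (`m = 2`,
`r = 0.15 * SD` of the scale-1 series, Chebyshev tolerance), and the
complexity score is the trapezoidal integral `K = ∫ S_E(tau) d tau`.

## Worked example

A desk-scale paired comparison (30 s simulated, 20 000 LFP samples):

```r
library(qifnet)
net <- qife_network(n_neurons = 100, nb = 4, rp = 0.1, omega = 5,
                    ephaptic = TRUE, duration = 30, transient = 10)
sim <- run_network(net, seed = 1)
sim
#> QIF-E simulation (seed 1, compiled engine)
#>   N = 100, ephaptic on, omega = 5, rp = 0.1, nb = 4
#>   LFP: 20000 samples; mean firing rate 1.07 Hz
curve <- mse(sim)
curve
#> Multiscale entropy: 99 scales (tau 2..100), m = 2, r = 0.09454 (chebyshev)
#>   entropy range [0.447, 1.571]
complexity_K(curve)
#> Complexity K = 109.9734 (integrated to tau_max = 100)
```

The firing rate sits near the tonic 1/0.879 ≈ 1.1 Hz; `r` is 0.15 times
the LFP standard deviation; and `K` integrates the 99-scale entropy curve.
Rerunning with `ephaptic = FALSE` at the same seed — which reuses the
identical graph, parameter draws and initial state — gives
`K = 101.3946` for this realisation, so switching the field coupling on
raised this particular network's complexity by about 8%. Seed-to-seed
variability of such paired differences is substantial; the
`condition_spec()` / `run_condition()` / `run_sweep()` layer aggregates
many matched seeds and applies Wilcoxon rank-sum comparisons with the usual
star labels.

A thin command-line front end (`inst/cli/qifnet.R`) exposes `simulate`,
`mse`, `gen-signal`, `sweep` and `compare` subcommands over the same
functions, reading and writing delimited text series.

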