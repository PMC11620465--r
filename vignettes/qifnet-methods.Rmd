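---
title: "Ephaptic and synaptic QIF networks: model, complexity measure, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ephaptic and synaptic QIF networks: model, complexity measure, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qifnet)
```

## The scientific question

Neurons communicate chiefly through synapses, but they are also immersed in
each other's electric fields. This *ephaptic* interaction is weak, short
ranged and usually ignored in network models. `qifnet` implements a network
model in which both communication layers coexist and can be switched
independently, so that one can ask how the field coupling changes the
complexity of the collective signal — the local field potential (LFP) —
relative to a purely synaptic network.

## Model

### Single neuron

Each neuron is a quadratic integrate-and-fire unit,

$$\dot V_i = a_i V_i^2 + b_i V_i + e_i(t) + s_i(t) + I,$$

with the threshold/reset rule: when $V_i(t) \ge 90$ mV the spike time is
recorded at $t$ and $V_i(t + \Delta t) = -5$ mV. Time is in seconds and
$\dot V$ in mV/s (the printed coefficients admit other unit readings; see
*Design choices*). Coefficients are heterogeneous across neurons,
$a_i \sim U(23.75, 26.25)$, $b_i \sim U(28.5, 31.5)$ (±5% around nominal),
modelling biological variability; the drive is $I = 9.5$. At the nominal
values $b^2 - 4 a I < 0$, so the neuron has no subthreshold fixed point and
fires tonically with the closed-form period

$$\mathrm{ISI} = \int_{-5}^{90} \frac{dV}{a V^2 + b V + I}
  = \frac{1}{\sqrt{aB}}\left[\arctan\sqrt{\tfrac{a}{B}}\Big(V + \tfrac{b}{2a}\Big)\right]_{-5}^{90},
  \quad B = I - \frac{b^2}{4a},$$

which is 0.879 s here (`isi_closed_form()`). Note that the ±5% coefficient
intervals allow individual draws with $b^2 - 4 a I > 0$: roughly a fifth of
neurons acquire a stable subthreshold fixed point and fire only when driven
by their neighbours. This is a direct consequence of drawing $a$ and $b$
independently and uniformly over the stated intervals and we keep it —
heterogeneity is the point of those intervals — but it shapes the dynamics
appreciably (driven, intermittently firing units coexist with tonic ones).

### Ephaptic layer

The field interaction between two neurons enters as a current proportional
to their potential difference. With superposition over the whole
population,

$$e_i(t) = -\sum_{j \ne i} c_{ij}\,\big(V_i(t) - V_j(t)\big),$$

where $c_{ij} = \mathrm{factor} / d_{ij}$ and $d_{ij}$ is the *ring
distance* between the neuron indices (neurons are treated as evenly spaced
on a ring; the distance is the shorter arc, `ring_distance()`). The matrix
is symmetric with zero diagonal, so the pairwise contributions are
antisymmetric and $\sum_i e_i \equiv 0$ to machine precision: the layer
redistributes potential but injects none. `ephaptic = FALSE` (or
`factor = 0`) zeroes the matrix and gives the pure synaptic regime —
bit-identically, which the test suite asserts.

The default `factor = 1e-2` (units 1/s) absorbs the membrane and
extracellular circuit constants into a single number. An alternative
parameterisation expresses the same law through a physical inter-neuron
spacing, `factor = 5e-2 / d` with `d = 50` µm, i.e. `1e-3` — an order of
magnitude weaker. Both are reachable through the `ephaptic_factor`
argument; the package defaults to `1e-2` and carries `d` as metadata only.
No further geometric embedding is attempted: distance means index distance
on the ring.

### Synaptic layer

Synapses live on a Watts–Strogatz small-world graph
(`build_small_world()`): a ring lattice with `nb` first neighbours
(default 4), each lattice edge independently rewired with probability `rp`
(default 0.1) to a uniform non-duplicate, non-self target. Rewiring
preserves the edge count $N\,\mathrm{nb}/2$. The graph is undirected and
synapses act both ways — the minimal reading when no direction is
specified. Generation is delegated to `igraph::sample_smallworld()` under
the package's seed discipline.

Each presynaptic spike produces a current-based exponential kernel at every
neighbour:

$$s_i(t) = \omega \sum_{k \sim i} s_k\, e^{-(t - t_0^{(k)})/T},$$

with intensity $\omega$ (default 5), decay $T = 6$ ms, and
$s_k = \pm 1$ the excitatory/inhibitory sign of the *presynaptic* neuron
(an optional fraction of inhibitory neurons, e.g. 20%, is drawn uniformly).
The kernel references one spike time per presynaptic neuron; the default
uses the most recent spike only (`kernel = "latest"`), which is exact for
$T \ll$ ISI. A variant accumulating all past spikes into a decaying trace
(`kernel = "sum"`) is available; at the default rates the two differ
negligibly.

### Integration protocol and LFP

The full network is advanced by explicit forward Euler with `dt = 1 ms`
for 60 s, both drives evaluated at the current state, no sub-stepping. The
first 10 s are discarded as transient, making results insensitive to the
(unstated, hence chosen) initial condition
$V_i(0) \sim U(-5, 90)$. The LFP is the spatial mean
$x(t) = \tfrac1N \sum_i V_i(t)$ of the *pre-reset* potentials — the reset
takes effect only on the following step, so the suprathreshold crossing
value appears in the series. At the defaults the LFP has exactly 50 000
samples. A guard aborts with the step and neuron index if any potential
exceeds $10^6$ in magnitude, since explicit Euler of a quadratic vector
field can diverge for pathological configurations (e.g. thresholds placed
above the guard).

Accuracy of the integrator is checked against the closed-form ISI: at
`dt = 1e-4` s the uncoupled-neuron period matches the quadrature to within
0.1% (the tolerance asserted is 2%).

## Complexity measure

Sample entropy of a series $X$ of length $M$ is
$S_E = -\ln(A/B)$: $B$ counts pairs of length-$m$ templates within
tolerance $r$, $A$ the pairs still matching at length $m+1$. Conventions
(all asserted by tests against a naive $O(n^2)$ enumeration oracle,
bit-for-bit):

* both counts run over the $M - m$ templates that admit an extension,
* self-matches are excluded,
* the distance is the maximum coordinate difference (Chebyshev). The
  tolerance could equally be read as a true Euclidean norm over the
  template; both metrics are implemented (`metric =` argument) and
  Chebyshev — the standard sample-entropy convention — is the default.

The multiscale curve (`mse()`) applies non-overlapping block averaging
(`coarse_grain()`) at scale factors $\tau = 2..100$ and evaluates
$S_E(m = 2, r)$ on each coarse series. The tolerance
$r = 0.15 \cdot SD$ is computed once from the scale-1 series and held
fixed across scales (the Costa convention; recomputing $r$ per scale is the
main alternative and changes the curve's large-$\tau$ behaviour, but in our
checks it did not change the weak-synapse regime comparison).
Fixing $r$ makes the curve invariant under positive rescaling
of the series, which is asserted as a property.

Degenerate scales — zero match counts, e.g. on very short or spread-out
coarse series — are flagged missing rather than propagated as infinities.
The complexity score $K$ (`complexity_K()`) integrates the curve by the
trapezoidal rule over the computed grid $\tau \in [2, 100]$; missing scales
are excluded by integrating each maximal finite run separately and are
reported in `n_missing`. A constant series has $K = 0$; a flat unit curve
over $\tau = 2..100$ has $K = 98$.

Calibration: for iid Gaussian noise the conditional matching probability
per extra coordinate is $p = 2\Phi\!\big(\tfrac{0.15}{\sqrt2}\big) - 1$,
so $S_E \to -\ln p \approx 2.4714$; the estimator at $M = 10^5$ agrees
within 3%.

## Experiment layer

`condition_spec()` bundles a network configuration with a seed block;
`run_condition()` maps each seed through simulate → MSE → $K$. Paired
ephaptic-on/off conditions share their seed block, so regime differences
are never confounded with topology or parameter draws — realisation $i$ of
both regimes uses the identical graph, coefficients and initial state.
`wilcoxon_compare()` applies the two-sided rank-sum test (exact null for
combined $n \le 20$ without ties, normal approximation with tie correction
otherwise) and maps p-values to the usual stars (`*` < 0.05, `**` < 0.01,
`***` < 0.001, `ns` otherwise); no multiple-testing correction is applied
across grid cells. `run_sweep()` executes grids of pairs (shipped
constructors: $\omega \in \{5,10,15,20,30\}$, $N \in \{50..200\}$, a 0–1
decade grid of `rp`, and `nb` $\in \{4, 12\}$ at $N = 200$), writes
long-format results and comparison tables, and checkpoints every
(condition, seed) cell in a ledger file so interrupted sweeps resume
without recomputing completed cells. Seeds are `seed_base + index`,
making grids reproducible and extendable; `n_seeds` defaults to 20.

## Validation signals

The fixtures module generates signals with known entropy behaviour, so the
estimator chain is testable without the simulator:

* `gen_white_noise()` — iid Gaussian; sample entropy matches the closed
  form above, and the MSE curve falls with $\tau$ (block averaging shrinks
  the variance while $r$ stays fixed).
* `gen_pink_noise()` — $1/f$ noise by direct spectral shaping: exact
  $f^{-1/2}$ amplitude profile, random phases, zero DC, unit variance.
  The exact profile makes the periodogram slope $-1$ by construction —
  the simplest spectrum contract to test — at the cost of not modelling
  amplitude fluctuations of natural $1/f$ signals. Its MSE curve stays
  above the white-noise curve at large scales, the canonical multiscale
  contrast.
* `gen_periodic()`, constant series — zero-entropy references.
* `tiny_network_fixture()` — a four-neuron ring with homogeneous
  coefficients, small enough that Euler steps are checked against a
  hand-unrolled scalar computation.

These signals validate the estimators, not the biology: passing them shows
the entropy pipeline is correct, and the engine cross-checks (compiled vs
plain-R integrator, rotation equivariance on the lattice) show the
dynamics are integrated as written. None of this certifies that the model
captures real cortical LFPs — no empirical recordings enter the package.

## Problem sizes

Full-protocol runs (60 s, $M = 50\,000$, $N = 100$) take well under a
minute each including the 99-scale MSE. The statistical tests in the suite
use a desk-scale protocol — 30 s simulated, 10 s transient,
$M = 20\,000$ — with 8–10 matched seeds per condition, and the
acceptance script uses the full protocol with 10 matched seeds; these
sizes were chosen so the whole suite completes comfortably on a single
CPU while keeping the rank-sum comparisons meaningful.

## Design choices made where the design was open

* **Unit convention.** Reading the printed coefficients as mV/s with time
  in seconds yields the 0.879 s tonic period and rich network dynamics.
  Reading them as mV/ms collapses every neuron to a degenerate two-step
  spike cycle (the quadratic term overshoots threshold in one 1 ms step
  from reset), destroying all dynamics — we checked. The `unit = "ms"`
  option exists for completeness.
* **Ephaptic weight constant.** `1e-2` versus `5e-2/50 = 1e-3` (both
  stated parameterisations); default `1e-2`, both selectable. The
  difference rescales the coupling tenfold; in our checks the weak-synapse
  regime comparison behaved the same under both.
* **Reset timing.** Threshold is detected on the current step, the reset
  value appears on the next; the recorded LFP keeps the crossing
  (overshoot) values. Clamping recorded potentials at threshold was
  evaluated and shifts $K$ by a few percent in both regimes alike, leaving
  the weak-synapse comparison unchanged.
* **Tie-breaks in the entropy counts.** Matches use $\le r$ throughout;
  with counts returned separately, $-\ln(A/B)$ is computed in R so the
  optimized and oracle paths are bit-comparable.
* **Integration grid for $K$.** The entropy grid starts at $\tau = 2$
  (the scale-1 value would mostly measure sampling noise), and $K$
  integrates exactly over the computed grid.

## Known limitations

* The headline regime contrast at weak synapses ($\omega = 5$, $N = 100$,
  `rp = 0.1`) is *not* a robust population-level effect in this model:
  across matched-seed realisations the paired difference
  $K_\mathrm{on} - K_\mathrm{off}$ is consistent within a given network
  draw but varies in sign across draws, with a mean near zero (the test
  suite computes and reports exactly this comparison, and the acceptance
  script prints the measured percentage). The robust, reproducible
  regime effects at these settings are: the *inversion* at strong
  synapses ($\omega = 30$: ephaptic-on lowers $K$), the decrease of $K$
  with $\omega$ in both regimes, its increase with $N$, and the
  disadvantage of larger neighbourhoods (`nb` 12 vs 4) at weak synapses.
* Neurons are points on a ring; no axonal propagation, conductance-based
  synapses, spatial compartments, or geometric (2-D/3-D) embedding.
* Explicit Euler with per-step threshold detection makes spike times
  accurate only to `dt`; the overshoot value recorded at a crossing
  depends on `dt`.
* Only the standard multiscale entropy is provided — no refined/composite
  variants, and no permutation or recurrence entropies.
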