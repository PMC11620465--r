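# Per-neuron membrane dynamics: heterogeneous parameters, ephaptic and
# synaptic drives, the quadratic derivative, and the threshold/reset rule.

#' Draw heterogeneous neuron parameters
#'
#' Each neuron receives its own quadratic coefficient `a` and linear
#' coefficient `b`, drawn independently and uniformly over +/-5% intervals
#' around the nominal values (defaults `a = 25 +/- 1.25`,
#' `b = 30 +/- 1.5`), mimicking biological variability between neurons.
#' A fraction of neurons, chosen uniformly at random, is marked inhibitory
#' (`sign = -1`): their outgoing synaptic kernel enters with a negative sign.
#'
#' @param n_neurons number of neurons.
#' @param inhib_fraction fraction in `[0, 1)`; exactly
#'   `round(n_neurons * inhib_fraction)` neurons become inhibitory.
#' @param seed integer seed, or `NULL` for the current RNG stream.
#' @param a_range,b_range numeric length-2 uniform supports.
#' @return A data frame with columns `a`, `b`, `sign` (one row per neuron).
#' @examples
#' p <- draw_neuron_params(100, inhib_fraction = 0.2, seed = 1)
#' sum(p$sign == -1)  # 20
#' @export
draw_neuron_params <- function(n_neurons, inhib_fraction = 0, seed = NULL,
                               a_range = c(23.75, 26.25),
                               b_range = c(28.5, 31.5)) {
  stopifnot_scalar_number(n_neurons, "n_neurons", lower = 1)
  if (inhib_fraction < 0 || inhib_fraction >= 1)
    stop("`inhib_fraction` must lie in [0, 1)", call. = FALSE)
  with_seed(seed, {
    a <- runif(n_neurons, a_range[1L], a_range[2L])
    b <- runif(n_neurons, b_range[1L], b_range[2L])
    sign <- rep(1, n_neurons)
    k <- round(n_neurons * inhib_fraction)
    if (k > 0) sign[sample.int(n_neurons, k)] <- -1
    data.frame(a = a, b = b, sign = sign)
  })
}

#' Ephaptic coupling drive
#'
#' The electric-field interaction drives each neuron towards the potentials
#' of all others, weighted by the ephaptic coupling matrix:
#' `e_i = -sum_{j != i} c[i, j] * (v_i - v_j)`. The pairwise contributions
#' are antisymmetric, so for any symmetric weight matrix the total drive
#' `sum_i e_i` is zero to machine precision: the ephaptic layer redistributes
#' potential but injects none.
#'
#' @param v membrane potentials (mV).
#' @param weights square symmetric coupling matrix, e.g.
#'   [ephaptic_weights()].
#' @return Per-neuron drive (mV/s), same length as `v`.
#' @export
ephaptic_current <- function(v, weights) {
  if (!is.matrix(weights) && !inherits(weights, "ephaptic_weights"))
    stop("`weights` must be a matrix", call. = FALSE)
  if (length(v) != nrow(weights) || nrow(weights) != ncol(weights))
    stop("dimension mismatch between `v` and `weights`", call. = FALSE)
  w <- unclass(weights)
  as.vector(w %*% v) - rowSums(w) * v
}

#' Synaptic drive from exponentially decaying current-based synapses
#'
#' Each presynaptic neuron `k` that has spiked contributes
#' `sign_k * omega * exp(-(t - t0_k) / tau_syn)` to every postsynaptic
#' neighbour, where `t0_k` is its most recent spike time. Neurons with no
#' spiking neighbours receive zero.
#'
#' @param t current time (s); must be >= every recorded spike time.
#' @param last_spike per-neuron most recent spike times; `-Inf` (or `NA`)
#'   marks a neuron that has not spiked.
#' @param graph a [build_small_world()] graph (its adjacency list is used).
#' @param omega synaptic intensity (magnitude).
#' @param tau_syn decay constant (s), default 6 ms.
#' @param signs per-neuron `+1`/`-1` excitatory/inhibitory signs.
#' @return Per-neuron drive, same length as `last_spike`.
#' @export
synaptic_current <- function(t, last_spike, graph, omega, tau_syn = 0.006,
                             signs = rep(1, length(last_spike))) {
  last_spike[is.na(last_spike)] <- -Inf
  if (any(last_spike > t))
    stop("`t` must be >= all recorded spike times", call. = FALSE)
  kern <- ifelse(is.finite(last_spike),
                 exp(-(t - last_spike) / tau_syn), 0)
  contrib <- signs * kern
  vapply(graph$adj, function(nb) omega * sum(contrib[nb]), numeric(1L))
}

#' Quadratic integrate-and-fire derivative
#'
#' The subthreshold membrane equation:
#' `dV_i/dt = a_i V_i^2 + b_i V_i + eph_i + syn_i + i_bias`. With the
#' default `a = 25`, `b = 30`, `i_bias = 9.5` the discriminant
#' `b^2 - 4 a I` is negative, so an uncoupled neuron has no fixed point and
#' fires tonically.
#'
#' @param v membrane potentials (mV).
#' @param a,b per-neuron quadratic and linear coefficients (recycled).
#' @param i_bias constant drive.
#' @param eph,syn ephaptic and synaptic drives (default 0).
#' @return `dV/dt` per neuron.
#' @export
qife_deriv <- function(v, a = 25, b = 30, i_bias = 9.5, eph = 0, syn = 0) {
  a * v^2 + b * v + eph + syn + i_bias
}

#' Threshold/reset rule
#'
#' Implements the hyperpolarisation reset: every neuron whose potential has
#' reached `v_thresh` at the end of a step has its spike time recorded at the
#' current step and its potential replaced by `v_reset` on the following
#' step; all other neurons are unchanged.
#'
#' @param v end-of-step membrane potentials.
#' @param last_spike per-neuron most recent spike times (`-Inf` = none).
#' @param t current step time (s).
#' @param v_thresh spike threshold (mV), default 90.
#' @param v_reset post-spike potential (mV), default -5.
#' @return A list with next-step `v`, updated `last_spike`, and the logical
#'   `spiked` flags.
#' @export
apply_reset <- function(v, last_spike, t, v_thresh = 90, v_reset = -5) {
  spiked <- v >= v_thresh
  last_spike[spiked] <- t
  v[spiked] <- v_reset
  list(v = v, last_spike = last_spike, spiked = spiked)
}

#' Closed-form inter-spike interval of an uncoupled neuron
#'
#' For a tonically firing quadratic neuron (`b^2 - 4*a*i_bias < 0`) the time
#' from reset to threshold is
#' `integral dV / (a V^2 + b V + I)` from `v_reset` to `v_thresh`, which
#' evaluates to `(1/sqrt(a*B)) * [atan(sqrt(a/B) (V + b/(2a)))]` at the
#' bounds, with `B = I - b^2/(4a)`. Used as an independent oracle for the
#' Euler integrator.
#'
#' @inheritParams qife_deriv
#' @param v_reset,v_thresh integration bounds (mV).
#' @return Inter-spike interval (s).
#' @examples
#' isi_closed_form()  # about 0.88 s at the default parameters
#' @export
isi_closed_form <- function(a = 25, b = 30, i_bias = 9.5, v_reset = -5,
                            v_thresh = 90) {
  B <- i_bias - b^2 / (4 * a)
  if (B <= 0)
    stop("no tonic firing: b^2 - 4*a*i_bias must be negative", call. = FALSE)
  f <- function(v) atan(sqrt(a / B) * (v + b / (2 * a)))
  (f(v_thresh) - f(v_reset)) / sqrt(a * B)
}
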