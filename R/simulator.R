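# Network model object, forward-Euler simulation, and LFP extraction.

#' Specify a QIF-E network model
#'
#' Collects all structural and dynamical parameters of the ephaptically and
#' synaptically coupled quadratic integrate-and-fire network. The defaults
#' encode the reference protocol: 100 neurons with four first neighbours,
#' rewiring probability 0.1, synaptic intensity 5 with a 6 ms decay,
#' ephaptic weights `1e-2 / ring distance`, constant drive 9.5, threshold
#' 90 mV, reset -5 mV, Euler step 1 ms, 60 s simulated with the first 10 s
#' discarded as transient (so the LFP has 50 000 samples).
#'
#' Time is measured in seconds and the membrane derivative in mV/s
#' (`unit = "s"`); `unit = "ms"` instead reads the same coefficients as
#' mV/ms. `kernel = "latest"` makes each presynaptic neuron contribute its
#' exponentially decayed most recent spike only; `kernel = "sum"`
#' accumulates over all past spikes.
#'
#' @param n_neurons,nb,rp small-world topology: size, even neighbour count,
#'   rewiring probability (see [build_small_world()]).
#' @param omega synaptic intensity (magnitude; inhibitory neurons flip the
#'   sign of their outgoing kernel).
#' @param ephaptic logical; `FALSE` zeroes the ephaptic weight matrix.
#' @param ephaptic_factor numerator of the ephaptic weight law.
#' @param inhib_fraction fraction of inhibitory neurons in `[0, 1)`.
#' @param dt,duration,transient Euler step, total simulated time, and
#'   discarded initial transient, all in seconds.
#' @param tau_syn synaptic decay constant (s).
#' @param i_bias constant drive.
#' @param a_range,b_range uniform supports of the per-neuron coefficients.
#' @param v_thresh,v_reset spike threshold and post-spike potential (mV).
#' @param unit `"s"` (default) or `"ms"` derivative convention.
#' @param kernel `"latest"` (default) or `"sum"` synaptic kernel mode.
#' @return An object of class `qife_net`.
#' @seealso [run_network()], [simulate.qife_net()]
#' @examples
#' net <- qife_network(n_neurons = 20, duration = 2, transient = 0.5)
#' net
#' @export
qife_network <- function(n_neurons = 100, nb = 4, rp = 0.1, omega = 5,
                         ephaptic = TRUE, ephaptic_factor = 1e-2,
                         inhib_fraction = 0, dt = 1e-3, duration = 60,
                         transient = 10, tau_syn = 0.006, i_bias = 9.5,
                         a_range = c(23.75, 26.25), b_range = c(28.5, 31.5),
                         v_thresh = 90, v_reset = -5, unit = c("s", "ms"),
                         kernel = c("latest", "sum")) {
  unit <- match.arg(unit)
  kernel <- match.arg(kernel)
  stopifnot_scalar_number(dt, "dt")
  stopifnot_scalar_number(duration, "duration")
  stopifnot_scalar_number(transient, "transient", lower = 0)
  if (dt <= 0) stop("`dt` must be positive", call. = FALSE)
  if (transient >= duration)
    stop("`transient` must be smaller than `duration`", call. = FALSE)
  if (omega < 0) stop("`omega` must be nonnegative", call. = FALSE)
  if (tau_syn <= 0) stop("`tau_syn` must be positive", call. = FALSE)
  if (v_reset >= v_thresh)
    stop("`v_reset` must be below `v_thresh`", call. = FALSE)
  if (n_neurons > 1) {
    if (nb %% 2 != 0 || nb >= n_neurons)
      stop("invalid topology: `nb` must be even and below `n_neurons`",
           call. = FALSE)
  }
  structure(
    list(n_neurons = as.integer(n_neurons), nb = as.integer(nb), rp = rp,
         omega = omega, ephaptic = isTRUE(ephaptic),
         ephaptic_factor = ephaptic_factor,
         inhib_fraction = inhib_fraction, dt = dt, duration = duration,
         transient = transient, tau_syn = tau_syn, i_bias = i_bias,
         a_range = a_range, b_range = b_range, v_thresh = v_thresh,
         v_reset = v_reset, unit = unit, kernel = kernel),
    class = "qife_net")
}

#' @export
print.qife_net <- function(x, ...) {
  cat("QIF-E network model\n")
  cat(sprintf("  topology : N = %d, nb = %d, rp = %g\n",
              x$n_neurons, x$nb, x$rp))
  cat(sprintf("  synapses : omega = %g, tau = %g s, kernel = %s, %g%% inhibitory\n",
              x$omega, x$tau_syn, x$kernel, 100 * x$inhib_fraction))
  cat(sprintf("  ephaptic : %s (factor = %g)\n",
              if (x$ephaptic) "on" else "off", x$ephaptic_factor))
  cat(sprintf("  protocol : dt = %g s, %g s simulated, %g s transient\n",
              x$dt, x$duration, x$transient))
  invisible(x)
}

#' Local field potential series
#'
#' Thin container for the spatially averaged membrane potential after
#' transient removal: sample times `t` (s), values `x` (mV) and the step
#' `dt`.
#'
#' @param x LFP samples (mV).
#' @param dt sampling step (s).
#' @param t0 time of the first retained sample (s).
#' @return An object of class `lfp_series`.
#' @export
lfp_series <- function(x, dt, t0 = 0) {
  structure(list(t = t0 + (seq_along(x) - 1) * dt, x = as.numeric(x),
                 dt = dt),
            class = "lfp_series")
}

#' @export
print.lfp_series <- function(x, ...) {
  cat(sprintf("LFP series: %d samples, dt = %g s, t in [%g, %g] s\n",
              length(x$x), x$dt, x$t[1L], x$t[length(x$t)]))
  cat(sprintf("  mean %.3f mV, sd %.3f mV\n", mean(x$x), sd(x$x)))
  invisible(x)
}

#' @export
as.data.frame.lfp_series <- function(x, ...) {
  data.frame(time_s = x$t, lfp_mV = x$x)
}

#' @export
plot.lfp_series <- function(x, ..., max_samples = 5000L) {
  idx <- seq_len(min(length(x$x), max_samples))
  plot(x$t[idx], x$x[idx], type = "l", xlab = "time (s)",
       ylab = "LFP (mV)", ...)
  invisible(x)
}

#' Compute the LFP from per-neuron traces
#'
#' The local field potential is the spatial average of all membrane
#' potentials: `x(t) = mean_i V_i(t)` at every retained step.
#'
#' @param traces numeric matrix, one row per time step, one column per
#'   neuron.
#' @param dt sampling step (s).
#' @param t0 time of the first row (s).
#' @return An [lfp_series()].
#' @export
compute_lfp <- function(traces, dt = 1e-3, t0 = 0) {
  if (!is.matrix(traces) || ncol(traces) < 1L || nrow(traces) < 1L)
    stop("`traces` must be a non-empty matrix (time x neurons)",
         call. = FALSE)
  lfp_series(rowMeans(traces), dt = dt, t0 = t0)
}

#' Run the network simulation
#'
#' Integrates the full network equation by forward Euler: at every step the
#' ephaptic and synaptic drives are evaluated at the current state, the
#' quadratic membrane equation is advanced by `dt`, and neurons at or above
#' threshold are reset on the following step with their spike time recorded.
#' The first `transient` seconds are discarded and the LFP (spatial mean of
#' the pre-reset potentials) is returned. All randomness — graph rewiring,
#' per-neuron parameter draws and initial conditions
#' `V(0) ~ Uniform(v_reset, v_thresh)` — is governed by `seed`, so a given
#' `(net, seed)` pair is exactly reproducible, and paired ephaptic-on/off
#' runs at the same seed share identical topology, parameters and initial
#' state.
#'
#' @param net a [qife_network()] model.
#' @param seed integer seed.
#' @param keep_traces logical; also return the full time-by-neuron potential
#'   matrix (memory grows as `samples x n_neurons`).
#' @param engine `"compiled"` (default) or `"r"` — the plain-R reference
#'   integrator, identical arithmetic, used for cross-checking.
#' @param graph,params,v0 optional overrides for the synaptic graph, the
#'   neuron parameter data frame and the initial potentials; any that are
#'   `NULL` are drawn from `seed`.
#' @return An object of class `qife_sim`: list with `lfp` ([lfp_series()]),
#'   `spike_count`, `graph`, `params`, `net`, `seed`, and `traces` (matrix
#'   or `NULL`).
#' @examples
#' net <- qife_network(n_neurons = 10, duration = 2, transient = 0.5)
#' sim <- run_network(net, seed = 1)
#' sim
#' @export
run_network <- function(net, seed = 1L, keep_traces = FALSE,
                        engine = c("compiled", "r"), graph = NULL,
                        params = NULL, v0 = NULL) {
  stopifnot(inherits(net, "qife_net"))
  engine <- match.arg(engine)
  n <- net$n_neurons

  with_seed(seed, {
    if (is.null(graph)) {
      graph <- if (n > 1) {
        build_small_world(n, net$nb, net$rp, seed = NULL)
      } else {
        structure(list(n_neurons = 1L, nb = 0L, rp = 0, seed = NULL,
                       edges = matrix(integer(0), 0, 2),
                       adj = list(integer(0))),
                  class = "synaptic_graph")
      }
    }
    if (is.null(params))
      params <- draw_neuron_params(n, net$inhib_fraction, seed = NULL,
                                   a_range = net$a_range,
                                   b_range = net$b_range)
    if (is.null(v0)) v0 <- runif(n, net$v_reset, net$v_thresh)
  })

  weights <- if (n > 1) {
    ephaptic_weights(n, factor = net$ephaptic_factor, enabled = net$ephaptic)
  } else {
    structure(matrix(0, 1, 1), factor = net$ephaptic_factor,
              enabled = net$ephaptic, d = 50,
              class = c("ephaptic_weights", "matrix", "array"))
  }

  n_steps <- round(net$duration / net$dt)
  transient_steps <- round(net$transient / net$dt)
  deriv_scale <- if (net$unit == "ms") 1000 else 1
  eph_on <- net$ephaptic && net$ephaptic_factor > 0

  adj0 <- lapply(graph$adj, function(v) as.integer(v - 1L))
  args <- list(a = params$a, b = params$b, i_bias = net$i_bias,
               signs = params$sign, adj = adj0, cmat = unclass(weights),
               omega = net$omega, tau_syn = net$tau_syn, v0 = v0,
               dt = net$dt, n_steps = n_steps,
               transient_steps = transient_steps, v_thresh = net$v_thresh,
               v_reset = net$v_reset, deriv_scale = deriv_scale,
               sum_kernel = net$kernel == "sum", eph_enabled = eph_on,
               record_traces = keep_traces, div_guard = 1e6)
  out <- if (engine == "compiled") {
    do.call(simulate_qife_cpp, args)
  } else {
    do.call(run_engine_r, args)
  }

  structure(
    list(lfp = lfp_series(out$lfp, dt = net$dt,
                          t0 = transient_steps * net$dt),
         spike_count = as.integer(out$spike_count),
         v_final = out$v_final, graph = graph, params = params, net = net,
         seed = seed, engine = engine,
         traces = if (keep_traces) out$traces else NULL),
    class = "qife_sim")
}

# Plain-R reference integrator; mirrors simulate_qife_cpp step for step.
run_engine_r <- function(a, b, i_bias, signs, adj, cmat, omega, tau_syn, v0,
                         dt, n_steps, transient_steps, v_thresh, v_reset,
                         deriv_scale, sum_kernel, eph_enabled, record_traces,
                         div_guard) {
  n <- length(v0)
  v <- v0
  last_spike <- rep(-Inf, n)
  strace <- rep(0, n)
  spike_count <- integer(n)
  n_keep <- n_steps - transient_steps
  lfp <- numeric(n_keep)
  traces <- if (record_traces) matrix(0, n_keep, n) else NULL
  crow <- rowSums(cmat)
  decay <- exp(-dt / tau_syn)
  adj1 <- lapply(adj, function(x) x + 1L)

  for (l in seq_len(n_steps) - 1L) {
    t <- l * dt
    if (sum_kernel && l > 0) strace <- strace * decay
    spiked <- v >= v_thresh
    last_spike[spiked] <- t
    spike_count[spiked] <- spike_count[spiked] + 1L
    if (sum_kernel) strace[spiked] <- strace[spiked] + 1

    if (l >= transient_steps) {
      lfp[l - transient_steps + 1L] <- sum(v) / n
      if (record_traces) traces[l - transient_steps + 1L, ] <- v
    }

    kern <- if (sum_kernel) strace else
      ifelse(is.finite(last_spike), exp(-(t - last_spike) / tau_syn), 0)
    contrib <- signs * kern
    syn <- omega * vapply(adj1, function(nb) sum(contrib[nb]), numeric(1L))
    eph <- if (eph_enabled) as.vector(cmat %*% v) - crow * v else 0

    dv <- a * v^2 + b * v + eph + syn + i_bias
    vnew <- v + dt * deriv_scale * dv
    vnew[spiked] <- v_reset
    bad <- which(!is.finite(vnew) | abs(vnew) > div_guard)
    if (length(bad) > 0L)
      stop(sprintf("membrane potential diverged at step %d (t = %g), neuron %d",
                   l + 1L, t, bad[1L]), call. = FALSE)
    v <- vnew
  }
  list(lfp = lfp, spike_count = spike_count, v_final = v,
       last_spike = last_spike, traces = traces)
}

#' @export
print.qife_sim <- function(x, ...) {
  dur <- x$net$duration
  cat(sprintf("QIF-E simulation (seed %s, %s engine)\n",
              format(x$seed), x$engine))
  cat(sprintf("  N = %d, ephaptic %s, omega = %g, rp = %g, nb = %d\n",
              x$net$n_neurons, if (x$net$ephaptic) "on" else "off",
              x$net$omega, x$net$rp, x$net$nb))
  cat(sprintf("  LFP: %d samples; mean firing rate %.2f Hz\n",
              length(x$lfp$x), mean(x$spike_count) / dur))
  invisible(x)
}

#' @export
summary.qife_sim <- function(object, ...) {
  rate <- object$spike_count / object$net$duration
  out <- list(n_neurons = object$net$n_neurons,
              samples = length(object$lfp$x),
              rate_mean = mean(rate), rate_range = range(rate),
              lfp_mean = mean(object$lfp$x), lfp_sd = sd(object$lfp$x))
  class(out) <- "summary.qife_sim"
  out
}

#' @export
print.summary.qife_sim <- function(x, ...) {
  cat(sprintf("N = %d neurons, %d LFP samples\n", x$n_neurons, x$samples))
  cat(sprintf("firing rate: mean %.2f Hz, range [%.2f, %.2f] Hz\n",
              x$rate_mean, x$rate_range[1L], x$rate_range[2L]))
  cat(sprintf("LFP: mean %.3f mV, sd %.3f mV\n", x$lfp_mean, x$lfp_sd))
  invisible(x)
}

#' @export
plot.qife_sim <- function(x, ...) {
  plot(x$lfp, ...)
}

#' Simulate realisations of a QIF-E network model
#'
#' Runs [run_network()] for `nsim` consecutive seeds starting at `seed`.
#'
#' @param object a [qife_network()] model.
#' @param nsim number of realisations.
#' @param seed first seed; realisation `i` uses `seed + i - 1`.
#' @param ... passed to [run_network()].
#' @return A single `qife_sim` when `nsim = 1`, else a list of them.
#' @export
simulate.qife_net <- function(object, nsim = 1, seed = 1L, ...) {
  sims <- lapply(seq_len(nsim) - 1L,
                 function(k) run_network(object, seed = seed + k, ...))
  if (nsim == 1L) sims[[1L]] else sims
}
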