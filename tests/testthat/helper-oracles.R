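# Independent reference implementations used as oracles.

# Naive O(n^2) sample entropy by explicit pair enumeration over outer()
# difference matrices; Chebyshev tolerance, self-matches excluded, both
# counts over the n - m templates that admit an extension.
naive_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m
  tmpl <- function(k) x[seq_len(nt) + k]          # k-th coordinate, 0-based
  match_mat <- function(k) abs(outer(tmpl(k), tmpl(k), "-")) <= r
  mm <- match_mat(0)
  if (m > 1) for (k in seq_len(m - 1)) mm <- mm & match_mat(k)
  B <- (sum(mm) - nt) / 2
  mm1 <- mm & match_mat(m)
  A <- (sum(mm1) - nt) / 2
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

# Closed-form sample entropy of iid Gaussian noise under the Chebyshev
# tolerance: each extra coordinate matches independently with probability
# P(|X - Y| <= r) = 2*pnorm(r / (sigma*sqrt(2))) - 1.
iid_gaussian_sampen <- function(r_frac) {
  -log(2 * pnorm(r_frac / sqrt(2)) - 1)
}

# Hand-unrolled Euler steps for a homogeneous network: one step of
# dV = a V^2 + b V + eph + syn + I with the pairwise ephaptic drive and the
# most-recent-spike synaptic kernel, followed by threshold/reset.
unrolled_step <- function(v, last_spike, t, dt, a, b, i_bias, cmat, adj,
                          omega, tau_syn, signs, v_thresh = 90,
                          v_reset = -5) {
  n <- length(v)
  spiked <- v >= v_thresh
  last_spike[spiked] <- t
  kern <- ifelse(is.finite(last_spike), exp(-(t - last_spike) / tau_syn), 0)
  syn <- sapply(seq_len(n), function(i)
    omega * sum(signs[adj[[i]]] * kern[adj[[i]]]))
  eph <- sapply(seq_len(n), function(i)
    -sum(cmat[i, -i] * (v[i] - v[-i])))
  vn <- v + dt * (a * v^2 + b * v + eph + syn + i_bias)
  vn[spiked] <- v_reset
  list(v = vn, last_spike = last_spike)
}

# Desk-scale network protocol used by the heavier statistical tests:
# 30 s simulated, first 10 s discarded (20 000 LFP samples).
desk_net <- function(...) {
  qife_network(duration = 30, transient = 10, ...)
}

k_of <- function(sim, taus = 2:100) complexity_K(mse(sim, taus = taus))$K
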