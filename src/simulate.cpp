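#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Forward-Euler integration of the ephaptically and synaptically coupled
// quadratic integrate-and-fire network.
//
// Per step, with state V(t):
//   1. neurons with V >= v_thresh are flagged as spiking; their spike time
//      is recorded at the current step,
//   2. the (pre-reset) potentials are recorded into the LFP / traces,
//   3. drives are evaluated at the current state:
//        ephaptic  e_i = -sum_j c_ij (V_i - V_j)
//        synaptic  s_i = omega * sum_{k in adj(i)} sign_k * kern_k
//      where kern_k = exp(-(t - t0_k)/tau) from the most recent spike
//      (or an accumulating trace when sum_kernel is true),
//   4. V(t+1) = V + dt*scale*(a V^2 + b V + e + s + I); neurons flagged in
//      step 1 are overwritten with v_reset, implementing the rule
//      "V >= threshold at t implies V = v_reset at t+1".
//
// adj is a 0-based adjacency list; cmat the dense symmetric ephaptic weight
// matrix (all zeros when the ephaptic layer is off).
// [[Rcpp::export]]
List simulate_qife_cpp(NumericVector a, NumericVector b, double i_bias,
                       NumericVector signs, List adj, NumericMatrix cmat,
                       double omega, double tau_syn, NumericVector v0,
                       double dt, int n_steps, int transient_steps,
                       double v_thresh, double v_reset, double deriv_scale,
                       bool sum_kernel, bool eph_enabled, bool record_traces,
                       double div_guard) {
  const int n = v0.size();
  const int n_keep = n_steps - transient_steps;
  std::vector<double> v(v0.begin(), v0.end());
  std::vector<double> vnew(n), kern(n), eph(n, 0.0), syn(n), contrib(n);
  std::vector<double> last_spike(n, R_NegInf), strace(n, 0.0), crow(n, 0.0);
  std::vector<char> spiked(n, 0);
  IntegerVector spike_count(n, 0);
  NumericVector lfp(n_keep);
  NumericMatrix traces = record_traces ? NumericMatrix(n_keep, n)
                                       : NumericMatrix(0, 0);
  const double *pc = cmat.begin();          // column-major
  const double *pa = a.begin(), *pb = b.begin(), *psg = signs.begin();
  std::vector<std::vector<int> > nbrs(n);
  for (int i = 0; i < n; ++i) {
    IntegerVector ai = adj[i];
    nbrs[i].assign(ai.begin(), ai.end());
  }
  if (eph_enabled)
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      for (int j = 0; j < n; ++j) s += pc[i + (size_t)n * j];
      crow[i] = s;
    }
  const double decay = std::exp(-dt / tau_syn);
  const double step = dt * deriv_scale;

  for (int l = 0; l < n_steps; ++l) {
    const double t = l * dt;
    if (sum_kernel && l > 0)
      for (int k = 0; k < n; ++k) strace[k] *= decay;

    // threshold detection at the current state
    for (int i = 0; i < n; ++i) {
      spiked[i] = v[i] >= v_thresh;
      if (spiked[i]) {
        last_spike[i] = t;
        spike_count[i] += 1;
        if (sum_kernel) strace[i] += 1.0;
      }
    }

    // record pre-reset potentials
    if (l >= transient_steps) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += v[i];
      lfp[l - transient_steps] = s / n;
      if (record_traces)
        for (int i = 0; i < n; ++i) traces(l - transient_steps, i) = v[i];
    }

    // synaptic kernel per presynaptic neuron
    if (sum_kernel) {
      for (int k = 0; k < n; ++k) kern[k] = strace[k];
    } else {
      for (int k = 0; k < n; ++k)
        kern[k] = std::isfinite(last_spike[k])
                    ? std::exp(-(t - last_spike[k]) / tau_syn) : 0.0;
    }
    for (int k = 0; k < n; ++k) contrib[k] = psg[k] * kern[k];
    for (int i = 0; i < n; ++i) {
      double s = 0.0;
      const std::vector<int> &nb = nbrs[i];
      for (size_t q = 0; q < nb.size(); ++q) s += contrib[nb[q]];
      syn[i] = omega * s;
    }

    // ephaptic drive e = C v - diag(rowsum(C)) v
    if (eph_enabled) {
      for (int i = 0; i < n; ++i) eph[i] = -crow[i] * v[i];
      for (int j = 0; j < n; ++j) {
        const double vj = v[j];
        const double *col = pc + (size_t)n * j;
        for (int i = 0; i < n; ++i) eph[i] += col[i] * vj;
      }
    }

    bool bad = false;
    for (int i = 0; i < n; ++i) {
      const double vi = v[i];
      const double dv = pa[i] * vi * vi + pb[i] * vi + eph[i] + syn[i]
                        + i_bias;
      vnew[i] = spiked[i] ? v_reset : vi + step * dv;
      if (!std::isfinite(vnew[i]) || std::fabs(vnew[i]) > div_guard)
        bad = true;
    }
    if (bad)
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(vnew[i]) || std::fabs(vnew[i]) > div_guard)
          stop("membrane potential diverged at step %d (t = %g), neuron %d",
               l + 1, t, i + 1);
    v.swap(vnew);
  }

  return List::create(_["lfp"] = lfp, _["spike_count"] = spike_count,
                      _["v_final"] = NumericVector(v.begin(), v.end()),
                      _["last_spike"] = NumericVector(last_spike.begin(),
                                                      last_spike.end()),
                      _["traces"] = traces);
}
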