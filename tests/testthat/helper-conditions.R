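# Shared, lazily computed simulation results for the statistical tests.
# Conditions follow the reference protocol at desk scale: 30 s simulated,
# 10 s transient (20 000 LFP samples), dt = 1 ms, full MSE grid tau = 2:100.
# Paired regimes share seeds, so topology and parameter draws are matched.

acc_cache <- new.env(parent = emptyenv())

acc_pair <- function(tag, n_seeds, seed_base = 1L, ...) {
  if (!is.null(acc_cache[[tag]])) return(acc_cache[[tag]])
  on <- qife_network(..., ephaptic = TRUE, duration = 30, transient = 10)
  off <- qife_network(..., ephaptic = FALSE, duration = 30, transient = 10)
  seeds <- seed_base + seq_len(n_seeds) - 1L
  kon <- koff <- numeric(n_seeds)
  for (i in seq_along(seeds)) {
    kon[i] <- k_of(run_network(on, seed = seeds[i]))
    koff[i] <- k_of(run_network(off, seed = seeds[i]))
  }
  acc_cache[[tag]] <- list(kon = kon, koff = koff)
  acc_cache[[tag]]
}

# the five conditions used by the regime-comparison tests
acc_w5 <- function() acc_pair("w5", 10L, omega = 5)
acc_w30 <- function() acc_pair("w30", 10L, omega = 30)
acc_n50 <- function() acc_pair("n50", 8L, omega = 5, n_neurons = 50)
acc_n200 <- function() acc_pair("n200", 8L, omega = 5, n_neurons = 200)
acc_nb12 <- function() acc_pair("nb12", 8L, omega = 5, n_neurons = 200,
                                nb = 12)
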