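test_that("configuration validation catches bad protocols", {
  expect_error(qife_network(duration = 5, transient = 5), "transient")
  expect_error(qife_network(dt = 0), "dt")
  expect_error(qife_network(nb = 3), "topology")
  expect_error(qife_network(v_reset = 95), "v_reset")
})

test_that("the default protocol yields exactly 50 000 LFP samples", {
  net <- qife_network()   # 60 s, 10 s transient, 1 ms step, N = 100
  sim <- run_network(net, seed = 1)
  expect_equal(length(sim$lfp$x), 50000L)
  expect_equal(sim$lfp$t[1], 10)
  expect_equal(sim$lfp$dt, 1e-3)
})

test_that("runs are bit-identical for identical seeds", {
  net <- qife_network(n_neurons = 30, duration = 3, transient = 0.5)
  s1 <- run_network(net, seed = 9)
  s2 <- run_network(net, seed = 9)
  expect_identical(s1$lfp$x, s2$lfp$x)
  expect_identical(s1$spike_count, s2$spike_count)
  s3 <- run_network(net, seed = 10)
  expect_false(identical(s1$lfp$x, s3$lfp$x))
})

test_that("ephaptic factor 0 reproduces the off regime bit-identically", {
  on0 <- qife_network(n_neurons = 25, duration = 3, transient = 0.5,
                      ephaptic = TRUE, ephaptic_factor = 0)
  off <- qife_network(n_neurons = 25, duration = 3, transient = 0.5,
                      ephaptic = FALSE)
  s_on0 <- run_network(on0, seed = 4)
  s_off <- run_network(off, seed = 4)
  expect_identical(s_on0$lfp$x, s_off$lfp$x)
  expect_identical(s_on0$spike_count, s_off$spike_count)
})

test_that("compiled and plain-R engines agree", {
  net <- qife_network(n_neurons = 12, duration = 1.5, transient = 0.2,
                      rp = 0.3)
  sc <- run_network(net, seed = 2, engine = "compiled", keep_traces = TRUE)
  sr <- run_network(net, seed = 2, engine = "r", keep_traces = TRUE)
  expect_equal(sc$lfp$x, sr$lfp$x, tolerance = 1e-10)
  expect_identical(sc$spike_count, sr$spike_count)
  expect_equal(sc$traces, sr$traces, tolerance = 1e-10)
  # and with the accumulating kernel and inhibitory neurons
  net2 <- qife_network(n_neurons = 12, duration = 1, transient = 0.2,
                       kernel = "sum", inhib_fraction = 0.25)
  expect_equal(run_network(net2, seed = 3, engine = "compiled")$lfp$x,
               run_network(net2, seed = 3, engine = "r")$lfp$x,
               tolerance = 1e-10)
})

test_that("LFP is the spatial mean of the traces", {
  net <- qife_network(n_neurons = 8, duration = 1, transient = 0.25)
  sim <- run_network(net, seed = 6, keep_traces = TRUE)
  expect_equal(sim$lfp$x, rowMeans(sim$traces), tolerance = 1e-12)
  lf <- compute_lfp(sim$traces, dt = 1e-3, t0 = 0.25)
  expect_equal(lf$x, sim$lfp$x, tolerance = 1e-12)
  expect_equal(lf$t, sim$lfp$t)
})

test_that("compute_lfp handles degenerate inputs per definition", {
  tr <- matrix(rnorm(30), 10, 3)
  # identical neurons: LFP equals any single trace
  expect_equal(compute_lfp(cbind(tr[, 1], tr[, 1]))$x, tr[, 1])
  # antisymmetric pair cancels
  expect_equal(compute_lfp(cbind(tr[, 2], -tr[, 2]))$x, rep(0, 10))
  # single neuron: LFP is its trace
  expect_equal(compute_lfp(tr[, 3, drop = FALSE])$x, tr[, 3])
  expect_error(compute_lfp(matrix(numeric(0), 0, 0)), "non-empty")
})

test_that("ring rotation maps lattice solutions to rotated solutions", {
  n <- 10
  net <- qife_network(n_neurons = n, nb = 4, rp = 0, omega = 5,
                      duration = 1, transient = 0)
  g <- build_small_world(n, 4, 0, seed = 1)
  params <- draw_neuron_params(n, seed = 21)
  v0 <- runif(n, -5, 90)
  rot <- function(x, k) x[((seq_len(n) - 1 + k) %% n) + 1]
  base <- run_network(net, seed = 1, graph = g, params = params, v0 = v0,
                      keep_traces = TRUE)
  shifted <- run_network(net, seed = 1, graph = g,
                         params = params[((seq_len(n) - 1 + 3) %% n) + 1, ],
                         v0 = rot(v0, 3), keep_traces = TRUE)
  # neuron i of the shifted run follows neuron i+3 of the base run
  expect_equal(shifted$traces, base$traces[, ((seq_len(n) - 1 + 3) %% n) + 1],
               tolerance = 1e-9)
  expect_equal(shifted$lfp$x, base$lfp$x, tolerance = 1e-9)
})

test_that("divergent dynamics abort with step and neuron diagnostics", {
  net <- qife_network(n_neurons = 3, nb = 2, duration = 0.1, transient = 0,
                      v_thresh = 1e7, v_reset = -5, omega = 0,
                      ephaptic = FALSE)
  # threshold above the guard: the quadratic blows up before any reset
  expect_error(run_network(net, seed = 1), "diverged at step .* neuron")
})

test_that("simulate() returns one realisation per consecutive seed", {
  net <- qife_network(n_neurons = 10, duration = 1, transient = 0.2)
  sims <- simulate(net, nsim = 2, seed = 5)
  expect_length(sims, 2L)
  expect_identical(sims[[1]]$lfp$x, run_network(net, seed = 5)$lfp$x)
  expect_identical(sims[[2]]$lfp$x, run_network(net, seed = 6)$lfp$x)
})
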