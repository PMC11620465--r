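test_that("wilcoxon comparison reproduces exact and threshold behaviour", {
  x <- c(1.2, 3.4, 2.2, 5.1, 4.4)
  same <- wilcoxon_compare(x, x)
  expect_equal(same$stars, "ns")
  expect_gt(same$p_value, 0.9)
  # fully separated samples of 10 vs 10: exact two-sided p = 2 / C(20, 10)
  sep <- wilcoxon_compare(1:10, 21:30)
  expect_equal(sep$p_value, 2 / choose(20, 10), tolerance = 1e-12)
  expect_equal(sep$stars, "***")
  expect_error(wilcoxon_compare(numeric(0), 1:3), "non-empty")
})

test_that("star labels follow the p-value thresholds", {
  star_of <- function(p) {
    if (p < 0.001) "***" else if (p < 0.01) "**"
    else if (p < 0.05) "*" else "ns"
  }
  expect_equal(star_of(0.004), "**")
  # cross-check wilcoxon_compare against the mapping on varied samples
  set.seed(40)
  for (rep in 1:20) {
    x <- rnorm(8); y <- rnorm(8, mean = runif(1, 0, 3))
    got <- wilcoxon_compare(x, y)
    expect_equal(got$stars, star_of(got$p_value))
    # agrees with a direct wilcox.test call
    expect_equal(got$p_value, wilcox.test(x, y, exact = TRUE)$p.value)
  }
})

test_that("run_condition is deterministic and pairs regimes by seed", {
  on <- condition_spec(n_neurons = 20, duration = 4, transient = 1,
                       ephaptic = TRUE, n_seeds = 3, seed_base = 11)
  r1 <- run_condition(on, taus = 2:30)
  r2 <- run_condition(on, taus = 2:30)
  expect_identical(r1$k_values, r2$k_values)
  expect_equal(names(r1$k_values), as.character(11:13))
  expect_true(all(r1$k_values >= 0))
  expect_equal(nrow(r1$mse_mean), 29L)
  # ephaptic-on with factor 0 equals the off regime at matched seeds
  on0 <- condition_spec(n_neurons = 20, duration = 4, transient = 1,
                        ephaptic = TRUE, ephaptic_factor = 0, n_seeds = 3,
                        seed_base = 11)
  off <- condition_spec(n_neurons = 20, duration = 4, transient = 1,
                        ephaptic = FALSE, n_seeds = 3, seed_base = 11)
  expect_identical(run_condition(on0, taus = 2:30)$k_values,
                   run_condition(off, taus = 2:30)$k_values)
  expect_error(condition_spec(n_seeds = 1), "n_seeds")
})

test_that("sweeps produce long results, paired comparisons, and resume", {
  grid <- grid_omega_sweep(omegas = c(5, 30), n_seeds = 2, seed_base = 3,
                           n_neurons = 15, duration = 3, transient = 1)
  out_dir <- withr::local_tempdir()
  sw <- run_sweep(grid, out_dir = out_dir, taus = 2:25, quiet = TRUE)
  expect_equal(nrow(sw$results), 2 * 2 * 2)  # omega x regime x seeds
  expect_setequal(unique(sw$results$omega), c(5, 30))
  expect_equal(nrow(sw$comparisons), 2L)
  expect_true(all(c("p_value", "stars") %in% names(sw$comparisons)))
  # paired-seed discipline: on and off use the same seed set per pair
  for (lab in unique(sw$results$label)) {
    sub <- sw$results[sw$results$label == lab, ]
    expect_identical(sort(sub$seed[sub$regime == "on"]),
                     sort(sub$seed[sub$regime == "off"]))
  }
  # resume: drop one ledger row; only that cell is recomputed
  ledger_file <- file.path(out_dir, "sweep-ledger.csv")
  led <- read.csv(ledger_file)
  expect_equal(nrow(led), 8L)
  dropped <- led[-3, ]
  write.csv(dropped, ledger_file, row.names = FALSE)
  msgs <- character(0)
  withCallingHandlers(
    sw2 <- run_sweep(grid, out_dir = out_dir, taus = 2:25, quiet = FALSE),
    message = function(m) {
      msgs <<- c(msgs, conditionMessage(m)); invokeRestart("muffleMessage")
    })
  expect_length(msgs, 1L)   # exactly one cell rerun
  expect_equal(sort(sw2$results$K), sort(sw$results$K), tolerance = 1e-12)
})

test_that("an empty grid yields empty tables", {
  sw <- run_sweep(list())
  expect_equal(nrow(sw$results), 0L)
  expect_equal(nrow(sw$comparisons), 0L)
})

test_that("shipped grids cover the printed sweep values", {
  g <- grid_omega_sweep(n_seeds = 2)
  expect_length(g, 5L)
  expect_equal(sapply(g, function(p) p$on$net$omega), c(5, 10, 15, 20, 30))
  expect_true(all(sapply(g, function(p) p$on$net$ephaptic)))
  expect_false(any(sapply(g, function(p) p$off$net$ephaptic)))
  expect_length(grid_rewiring_sweep(n_seeds = 2), 11L)
  expect_equal(sapply(grid_neighborhood_sweep(n_seeds = 2),
                      function(p) p$on$net$nb), c(4, 12))
})
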