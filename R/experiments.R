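# Paired ephaptic-on/off condition grids, per-seed complexity aggregation,
# and Wilcoxon rank-sum comparisons.

#' Specify a simulation condition
#'
#' A condition is a network model plus a block of seeds: realisations use
#' seeds `seed_base, seed_base + 1, ..., seed_base + n_seeds - 1`. Two
#' conditions that differ only in the ephaptic flag and share `seed_base`
#' are *paired*: realisation `i` of each uses the same seed and therefore
#' the same topology, parameter draws and initial state, so regime
#' differences are not confounded with topology draws.
#'
#' @param ... arguments forwarded to [qife_network()].
#' @param n_seeds number of realisations (>= 2).
#' @param seed_base first seed.
#' @return An object of class `condition_spec`.
#' @export
condition_spec <- function(..., n_seeds = 20L, seed_base = 1L) {
  if (n_seeds < 2L)
    stop("`n_seeds` must be >= 2 for any statistical comparison",
         call. = FALSE)
  structure(list(net = qife_network(...), n_seeds = as.integer(n_seeds),
                 seed_base = as.integer(seed_base)),
            class = "condition_spec")
}

condition_key <- function(spec) {
  n <- spec$net
  paste(sprintf("N%d", n$n_neurons), sprintf("nb%d", n$nb),
        sprintf("rp%g", n$rp), sprintf("om%g", n$omega),
        sprintf("eph%d", as.integer(n$ephaptic)),
        sprintf("f%g", n$ephaptic_factor),
        sprintf("inh%g", n$inhib_fraction), sprintf("dt%g", n$dt),
        sprintf("dur%g", n$duration), sprintf("tr%g", n$transient),
        n$unit, n$kernel, sep = "_")
}

#' Run all realisations of a condition
#'
#' For each seed of the condition, simulates the network, computes the
#' multiscale-entropy curve of the LFP, and integrates it to the complexity
#' score `K`.
#'
#' @param spec a [condition_spec()].
#' @param taus,m,r_frac passed to [mse()].
#' @return An object of class `condition_result`: list with `spec`,
#'   `k_values` (one `K` per seed, named by seed), `mse_mean` (data frame
#'   `tau`, `se`, averaged over seeds with missing scales dropped) and
#'   `se_matrix` (scales x seeds).
#' @export
run_condition <- function(spec, taus = 2:100, m = 2L, r_frac = 0.15) {
  stopifnot(inherits(spec, "condition_spec"))
  seeds <- spec$seed_base + seq_len(spec$n_seeds) - 1L
  se_mat <- matrix(NA_real_, length(taus), length(seeds),
                   dimnames = list(NULL, seeds))
  k <- numeric(length(seeds))
  for (i in seq_along(seeds)) {
    res <- tryCatch({
      sim <- run_network(spec$net, seed = seeds[i])
      curve <- mse(sim, taus = taus, m = m, r_frac = r_frac)
      list(curve = curve, K = complexity_K(curve)$K)
    }, error = function(e) {
      stop(sprintf("condition %s, seed %d: %s", condition_key(spec),
                   seeds[i], conditionMessage(e)), call. = FALSE)
    })
    se_mat[, i] <- res$curve$se
    k[i] <- res$K
  }
  names(k) <- seeds
  structure(
    list(spec = spec, k_values = k,
         mse_mean = data.frame(tau = taus,
                               se = rowMeans(se_mat, na.rm = TRUE)),
         se_matrix = se_mat),
    class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("Condition %s\n", condition_key(x$spec)))
  cat(sprintf("  %d seeds: K mean %.3f, sd %.3f, range [%.3f, %.3f]\n",
              length(x$k_values), mean(x$k_values), sd(x$k_values),
              min(x$k_values), max(x$k_values)))
  invisible(x)
}

#' Wilcoxon rank-sum comparison with significance stars
#'
#' Two-sided rank-sum (Mann-Whitney) test between two samples of complexity
#' scores: the exact null distribution is used when the combined sample size
#' is at most 20 and there are no ties, otherwise the normal approximation
#' with tie correction. Stars follow the usual thresholds: `*` for
#' `p < 0.05`, `**` for `p < 0.01`, `***` for `p < 0.001`, `ns` otherwise.
#'
#' @param x,y numeric samples (each at least 2 values).
#' @param exact force (`TRUE`/`FALSE`) or auto-select (`NULL`) the exact
#'   null.
#' @return A list with `statistic` (the rank-sum `W`), `p_value` and
#'   `stars`.
#' @examples
#' wilcoxon_compare(1:10, 11:20)  # fully separated
#' @export
wilcoxon_compare <- function(x, y, exact = NULL) {
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (is.null(exact)) exact <- (length(x) + length(y)) <= 20L
  wt <- suppressWarnings(wilcox.test(x, y, exact = exact,
                                     alternative = "two.sided"))
  p <- wt$p.value
  stars <- if (p < 0.001) "***" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "ns"
  list(statistic = unname(wt$statistic), p_value = p, stars = stars)
}

#' Run a grid of paired ephaptic-on/off conditions
#'
#' Takes a list of condition pairs (as produced by the `grid_*()`
#' constructors), runs every (condition, seed) cell, and returns a
#' long-format results table plus a comparison table with rank-sum p-values
#' and stars per pair. When `out_dir` is given, per-cell `K` values are
#' check-pointed in a run ledger (`sweep-ledger.csv`, keyed on the condition
#' parameters and seed): a rerun recomputes only missing cells, never
#' silently redoing completed ones.
#'
#' @param grid list of pairs; each pair is a list with elements `label`,
#'   `on` and `off` (two [condition_spec()]s).
#' @param out_dir optional directory for the ledger and result tables.
#' @param taus,m,r_frac passed to [mse()].
#' @param quiet suppress per-cell progress messages.
#' @return An object of class `sweep_result`: list with `results` (one row
#'   per condition and seed), `comparisons` (one row per pair) and
#'   `ledger_path` (or `NULL`).
#' @export
run_sweep <- function(grid, out_dir = NULL, taus = 2:100, m = 2L,
                      r_frac = 0.15, quiet = FALSE) {
  if (length(grid) == 0L) {
    return(structure(list(results = empty_results_df(),
                          comparisons = empty_comparisons_df(),
                          ledger_path = NULL),
                     class = "sweep_result"))
  }
  ledger_path <- NULL
  ledger <- empty_ledger_df()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    ledger_path <- file.path(out_dir, "sweep-ledger.csv")
    if (file.exists(ledger_path))
      ledger <- utils::read.csv(ledger_path,
                                colClasses = c("character", "integer",
                                               "numeric"))
  }

  rows <- list()
  comps <- list()
  for (pair in grid) {
    ks <- list()
    for (regime in c("on", "off")) {
      spec <- pair[[regime]]
      key <- condition_key(spec)
      seeds <- spec$seed_base + seq_len(spec$n_seeds) - 1L
      kv <- numeric(length(seeds))
      for (i in seq_along(seeds)) {
        hit <- ledger$key == key & ledger$seed == seeds[i]
        if (any(hit)) {
          kv[i] <- ledger$K[which(hit)[1L]]
        } else {
          if (!quiet)
            message(sprintf("running %s seed %d", key, seeds[i]))
          sim <- run_network(spec$net, seed = seeds[i])
          kv[i] <- complexity_K(mse(sim, taus = taus, m = m,
                                    r_frac = r_frac))$K
          ledger <- rbind(ledger,
                          data.frame(key = key, seed = seeds[i],
                                     K = kv[i]))
          if (!is.null(ledger_path))
            utils::write.csv(ledger, ledger_path, row.names = FALSE)
        }
        n <- spec$net
        rows[[length(rows) + 1L]] <-
          data.frame(label = pair$label, regime = regime,
                     n_neurons = n$n_neurons, nb = n$nb, rp = n$rp,
                     omega = n$omega, ephaptic = n$ephaptic,
                     inhib_fraction = n$inhib_fraction,
                     seed = seeds[i], K = kv[i])
      }
      ks[[regime]] <- kv
    }
    cmp <- wilcoxon_compare(ks$on, ks$off)
    comps[[length(comps) + 1L]] <-
      data.frame(label = pair$label, n_on = length(ks$on),
                 n_off = length(ks$off), mean_k_on = mean(ks$on),
                 mean_k_off = mean(ks$off), statistic = cmp$statistic,
                 p_value = cmp$p_value, stars = cmp$stars)
  }
  results <- do.call(rbind, rows)
  comparisons <- do.call(rbind, comps)
  if (!is.null(out_dir)) {
    utils::write.csv(results, file.path(out_dir, "sweep-results.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons,
                     file.path(out_dir, "sweep-comparisons.csv"),
                     row.names = FALSE)
  }
  structure(list(results = results, comparisons = comparisons,
                 ledger_path = ledger_path),
            class = "sweep_result")
}

empty_ledger_df <- function() {
  data.frame(key = character(0), seed = integer(0), K = numeric(0))
}
empty_results_df <- function() {
  data.frame(label = character(0), regime = character(0),
             n_neurons = integer(0), nb = integer(0), rp = numeric(0),
             omega = numeric(0), ephaptic = logical(0),
             inhib_fraction = numeric(0), seed = integer(0),
             K = numeric(0))
}
empty_comparisons_df <- function() {
  data.frame(label = character(0), n_on = integer(0), n_off = integer(0),
             mean_k_on = numeric(0), mean_k_off = numeric(0),
             statistic = numeric(0), p_value = numeric(0),
             stars = character(0))
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("Sweep: %d condition-seed cells, %d paired comparisons\n",
              nrow(x$results), nrow(x$comparisons)))
  if (nrow(x$comparisons) > 0) print(x$comparisons)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ...) {
  if (nrow(x$results) == 0L) stop("empty sweep", call. = FALSE)
  boxplot(K ~ regime + label, data = x$results, las = 2,
          ylab = "complexity K", ...)
  invisible(x)
}

# --- shipped grid constructors -------------------------------------------

pair_on_off <- function(label, n_seeds, seed_base, ...) {
  list(label = label,
       on = condition_spec(..., ephaptic = TRUE, n_seeds = n_seeds,
                           seed_base = seed_base),
       off = condition_spec(..., ephaptic = FALSE, n_seeds = n_seeds,
                            seed_base = seed_base))
}

#' Shipped experiment grids
#'
#' Pre-configured paired ephaptic-on/off grids over the sweeps studied with
#' this model: synaptic intensity (`omega` in 5, 10, 15, 20, 30), network
#' size (`N` in 50..200), rewiring probability (decade grid 0..1), and
#' neighbourhood size (`nb` in 4, 12 at N = 200). Every pair shares its
#' seed block across regimes.
#'
#' @param omegas,sizes,rps,nbs sweep values.
#' @param n_seeds realisations per condition.
#' @param seed_base first seed.
#' @param ... further arguments to [qife_network()] (e.g. a shorter
#'   `duration` for desk-scale runs).
#' @return A list of pairs suitable for [run_sweep()].
#' @export
grid_omega_sweep <- function(omegas = c(5, 10, 15, 20, 30), n_seeds = 20L,
                             seed_base = 1L, ...) {
  lapply(omegas, function(om)
    pair_on_off(sprintf("omega=%g", om), n_seeds, seed_base,
                omega = om, ...))
}

#' @rdname grid_omega_sweep
#' @export
grid_size_sweep <- function(sizes = c(50, 100, 150, 200), n_seeds = 20L,
                            seed_base = 1L, ...) {
  lapply(sizes, function(nn)
    pair_on_off(sprintf("N=%d", nn), n_seeds, seed_base,
                n_neurons = nn, ...))
}

#' @rdname grid_omega_sweep
#' @export
grid_rewiring_sweep <- function(rps = seq(0, 1, by = 0.1), n_seeds = 20L,
                                seed_base = 1L, ...) {
  lapply(rps, function(rp)
    pair_on_off(sprintf("rp=%g", rp), n_seeds, seed_base, rp = rp, ...))
}

#' @rdname grid_omega_sweep
#' @export
grid_neighborhood_sweep <- function(nbs = c(4, 12), n_seeds = 20L,
                                    seed_base = 1L, ...) {
  lapply(nbs, function(nb)
    pair_on_off(sprintf("nb=%d", nb), n_seeds, seed_base,
                n_neurons = 200, nb = nb, ...))
}
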