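# Synaptic small-world graph and ephaptic weight matrix.

#' Build the small-world synaptic graph
#'
#' Constructs a Watts-Strogatz graph: a ring lattice of `n_neurons` nodes in
#' which every node is connected to its `nb/2` nearest neighbours on each
#' side, followed by independent rewiring of each lattice edge with
#' probability `rp` to a uniformly chosen target (no self-loops, no duplicate
#' edges). Rewiring preserves the edge count `n_neurons * nb / 2`. `rp = 0`
#' returns the exact ring lattice, `rp = 1` an essentially random graph.
#'
#' @param n_neurons number of neurons (must exceed `nb`).
#' @param nb even number of first neighbours in the initial ring.
#' @param rp rewiring probability in `[0, 1]`.
#' @param seed integer seed for the rewiring draws, or `NULL` to use the
#'   current RNG stream.
#' @return An object of class `synaptic_graph`: a list with `n_neurons`,
#'   `nb`, `rp`, `seed`, `edges` (two-column matrix of 1-based endpoints,
#'   each unordered pair once) and `adj` (adjacency list).
#' @examples
#' g <- build_small_world(100, 4, 0.1, seed = 1)
#' nrow(g$edges)  # 200 edges
#' @export
build_small_world <- function(n_neurons, nb, rp, seed = NULL) {
  stopifnot_scalar_number(n_neurons, "n_neurons", lower = 3)
  stopifnot_scalar_number(nb, "nb", lower = 2)
  stopifnot_scalar_number(rp, "rp", lower = 0)
  if (nb %% 2 != 0)
    stop("invalid topology: `nb` must be even", call. = FALSE)
  if (nb >= n_neurons)
    stop("invalid topology: `nb` must be smaller than `n_neurons`",
         call. = FALSE)
  if (rp > 1) stop("`rp` must be in [0, 1]", call. = FALSE)

  g <- with_seed(seed,
    igraph::sample_smallworld(dim = 1, size = n_neurons, nei = nb / 2,
                              p = rp, loops = FALSE, multiple = FALSE))
  edges <- igraph::as_edgelist(g, names = FALSE)
  storage.mode(edges) <- "integer"
  edges <- t(apply(edges, 1L, sort))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(
    list(n_neurons = as.integer(n_neurons), nb = as.integer(nb), rp = rp,
         seed = seed, edges = edges, adj = edges_to_adj(edges, n_neurons)),
    class = "synaptic_graph")
}

edges_to_adj <- function(edges, n) {
  adj <- rep(list(integer(0)), n)
  for (e in seq_len(nrow(edges))) {
    i <- edges[e, 1L]; j <- edges[e, 2L]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, sort)
}

#' @export
print.synaptic_graph <- function(x, ...) {
  cat(sprintf(
    "Small-world synaptic graph: %d neurons, nb = %d, rp = %g, %d edges\n",
    x$n_neurons, x$nb, x$rp, nrow(x$edges)))
  invisible(x)
}

#' Ring distance between neuron indices
#'
#' Neurons are treated as evenly spaced on a ring, so the distance between
#' indices `i` and `j` (1-based, vectorised) is the shorter of the two arc
#' lengths: `min(|i - j|, n_neurons - |i - j|)`.
#'
#' @param i,j neuron indices in `1..n_neurons` (recycled).
#' @param n_neurons ring size.
#' @return Integer distances; 0 exactly when `i == j`.
#' @examples
#' ring_distance(1, 100, 100)  # neighbours across the seam -> 1
#' @export
ring_distance <- function(i, j, n_neurons) {
  stopifnot_scalar_number(n_neurons, "n_neurons", lower = 1)
  if (any(i < 1 | i > n_neurons) || any(j < 1 | j > n_neurons))
    stop("indices must lie in 1..n_neurons", call. = FALSE)
  d <- abs(i - j)
  pmin(d, n_neurons - d)
}

#' Build the all-to-all ephaptic weight matrix
#'
#' Every pair of neurons interacts ephaptically with a coupling constant that
#' decays with their ring distance: `c[i, j] = factor / ring_distance(i, j)`,
#' zero on the diagonal. With the default `factor = 1e-2` adjacent neurons
#' couple at `1e-2` (units 1/s). An equivalent parameterisation in terms of a
#' physical inter-neuron spacing `d` (micrometres) uses
#' `factor = numerator / d`, e.g. `5e-2 / 50`; `d` is carried as metadata
#' only. `enabled = FALSE` gives the all-zero matrix, i.e. the ephaptic-off
#' regime.
#'
#' @param n_neurons number of neurons (at least 2).
#' @param factor nonnegative scalar numerator of the weight law.
#' @param enabled logical; `FALSE` zeroes the matrix.
#' @param d reference inter-neuron distance in micrometres (metadata).
#' @return A symmetric `n_neurons x n_neurons` matrix of class
#'   `ephaptic_weights` with attributes `factor`, `enabled` and `d`.
#' @examples
#' w <- ephaptic_weights(100)
#' w[1, 2]    # 0.01
#' w[1, 100]  # 0.01 as well: ring distance 1
#' @export
ephaptic_weights <- function(n_neurons, factor = 1e-2, enabled = TRUE,
                             d = 50) {
  stopifnot_scalar_number(n_neurons, "n_neurons", lower = 2)
  if (!is.numeric(factor) || length(factor) != 1L || factor < 0)
    stop("`factor` must be a single nonnegative number", call. = FALSE)
  idx <- seq_len(n_neurons)
  dist <- outer(idx, idx, function(a, b) ring_distance(a, b, n_neurons))
  w <- matrix(0, n_neurons, n_neurons)
  if (enabled && factor > 0) {
    off <- dist > 0
    w[off] <- factor / dist[off]
  }
  structure(w, factor = factor, enabled = enabled, d = d,
            class = c("ephaptic_weights", "matrix", "array"))
}

#' @export
print.ephaptic_weights <- function(x, ...) {
  cat(sprintf("Ephaptic weight matrix: %d neurons, factor = %g, %s\n",
              nrow(x), attr(x, "factor"),
              if (attr(x, "enabled")) "enabled" else "disabled (all zero)"))
  invisible(x)
}

#' Read and write graphs and weight matrices as delimited text
#'
#' `write_edge_list()` stores a [build_small_world()] graph as two
#' whitespace-separated integer columns of 0-based endpoints;
#' `read_edge_list()` reconstructs a `synaptic_graph` from such a file
#' (`nb` and `rp` are not recoverable and are set to `NA`).
#' `write_weight_matrix()` stores an [ephaptic_weights()] matrix as dense
#' whitespace-separated text.
#'
#' @param graph a `synaptic_graph`.
#' @param path file path.
#' @param n_neurons ring size; defaults to the largest index + 1.
#' @param w an `ephaptic_weights` (or plain) matrix.
#' @return `read_edge_list()` returns a `synaptic_graph`; the writers return
#'   `path` invisibly.
#' @export
write_edge_list <- function(graph, path) {
  utils::write.table(graph$edges - 1L, path, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
read_edge_list <- function(path, n_neurons = NULL) {
  edges <- as.matrix(utils::read.table(path, colClasses = "integer")) + 1L
  colnames(edges) <- NULL
  n <- n_neurons %||% max(edges)
  edges <- t(apply(edges, 1L, sort))
  edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  structure(
    list(n_neurons = as.integer(n), nb = NA_integer_, rp = NA_real_,
         seed = NULL, edges = edges, adj = edges_to_adj(edges, n)),
    class = "synaptic_graph")
}

#' @rdname write_edge_list
#' @export
write_weight_matrix <- function(w, path) {
  utils::write.table(unclass(w), path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
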