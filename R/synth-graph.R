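#' Seeded Watts-Strogatz-style coupling graph
#'
#' Ground-truth directed coupling topology for the synthetic EEG generator.
#' An undirected ring lattice (each node tied to its `mean_degree/2` nearest
#' neighbours on each side) is rewired edge by edge with probability
#' `rewiring_prob` (one endpoint moved to a uniformly random node, avoiding
#' self-loops and duplicates), and every undirected tie is emitted as a
#' reciprocal pair of directed edges, so the graph always carries exactly
#' `n_nodes * mean_degree` directed edges and its undirected projection has
#' constant density across rewiring probabilities.  `rewiring_prob = 0` is a
#' ring lattice; `rewiring_prob = 1` is fully random wiring with the total
#' degree conserved.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param mean_degree even out-degree, `< n_nodes`.
#' @param rewiring_prob rewiring probability in \[0, 1\]; this is the knob
#'   that moves the graph's small-worldness.
#' @param seed integer seed.
#' @param weight coupling strength attached to every directed edge.
#' @return Object of class `coupling_graph`: list with `n_nodes`, `edges`
#'   (two-column source/target matrix), `weights`, `rewiring_prob`.
#' @export
make_coupling_graph <- function(n_nodes, mean_degree, rewiring_prob, seed,
                                weight = 1) {
  n_nodes <- as.integer(n_nodes); mean_degree <- as.integer(mean_degree)
  if (n_nodes < 2L) stop("n_nodes must be >= 2", call. = FALSE)
  if (mean_degree %% 2L != 0L || mean_degree >= n_nodes)
    stop("mean_degree must be even and < n_nodes", call. = FALSE)
  if (rewiring_prob < 0 || rewiring_prob > 1)
    stop("rewiring_prob must be in [0, 1]", call. = FALSE)
  if (!missing(seed) && !is.null(seed)) set.seed(as.integer(seed))
  k2 <- mean_degree %/% 2L
  adj <- matrix(FALSE, n_nodes, n_nodes)
  for (s in 1:k2) {
    i <- seq_len(n_nodes)
    j <- ((i - 1L + s) %% n_nodes) + 1L
    adj[cbind(i, j)] <- TRUE; adj[cbind(j, i)] <- TRUE
  }
  if (rewiring_prob > 0) {
    eidx <- which(adj & upper.tri(adj), arr.ind = TRUE)
    for (e in seq_len(nrow(eidx))) {
      if (stats::runif(1) >= rewiring_prob) next
      a <- eidx[e, 1]; b <- eidx[e, 2]
      cand <- which(!adj[a, ] & seq_len(n_nodes) != a)
      cand <- setdiff(cand, b)
      if (!length(cand)) next
      w <- cand[sample.int(length(cand), 1L)]
      adj[a, b] <- adj[b, a] <- FALSE
      adj[a, w] <- adj[w, a] <- TRUE
    }
  }
  und <- which(adj & upper.tri(adj), arr.ind = TRUE)
  edges <- rbind(und, und[, 2:1, drop = FALSE])
  colnames(edges) <- c("source", "target")
  ord <- order(edges[, 1], edges[, 2])
  edges <- edges[ord, , drop = FALSE]
  structure(list(n_nodes = n_nodes, edges = edges,
                 weights = rep(as.numeric(weight), nrow(edges)),
                 rewiring_prob = rewiring_prob,
                 mean_degree = mean_degree),
            class = "coupling_graph")
}

#' Assemble a coupling graph from an explicit edge list
#'
#' @param n_nodes number of nodes.
#' @param edges two-column matrix of directed (source, target) pairs.
#' @param weights per-edge coupling strengths (recycled).
#' @param rewiring_prob construction parameter to record (metadata only).
#' @return A `coupling_graph`.
#' @export
coupling_graph <- function(n_nodes, edges, weights = 1, rewiring_prob = NA_real_) {
  edges <- matrix(as.integer(edges), ncol = 2,
                  dimnames = list(NULL, c("source", "target")))
  if (nrow(edges) && any(edges[, 1] == edges[, 2]))
    stop("self-loops are not allowed", call. = FALSE)
  if (nrow(edges) && (min(edges) < 1L || max(edges) > n_nodes))
    stop("edge endpoints out of range", call. = FALSE)
  weights <- rep_len(as.numeric(weights), nrow(edges))
  if (any(!is.finite(weights)) || any(weights < 0))
    stop("weights must be finite and >= 0", call. = FALSE)
  structure(list(n_nodes = as.integer(n_nodes), edges = edges,
                 weights = weights, rewiring_prob = rewiring_prob,
                 mean_degree = NA_integer_),
            class = "coupling_graph")
}

#' @export
print.coupling_graph <- function(x, ...) {
  cat(sprintf(
    "Coupling graph: %d nodes, %d directed edges, rewiring prob %.2f\n",
    x$n_nodes, nrow(x$edges), x$rewiring_prob))
  invisible(x)
}

#' Undirected projection of a coupling graph
#'
#' Two nodes are adjacent iff a directed edge exists in either direction;
#' this is the graph on which ground-truth small-worldness is measured.
#'
#' @param g a `coupling_graph`.
#' @return A [brain_graph()].
#' @export
coupling_to_brain_graph <- function(g) {
  adj <- matrix(FALSE, g$n_nodes, g$n_nodes)
  adj[g$edges] <- TRUE
  brain_graph(adj | t(adj),
              provenance = list(rule = "coupling-graph projection",
                                rewiring_prob = g$rewiring_prob))
}
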