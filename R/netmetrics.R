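#' Threshold a connectivity matrix into a binary undirected brain graph
#'
#' The directed causality matrix is symmetrized by averaging `F(i -> j)` and
#' `F(j -> i)`, and the strongest node pairs are kept as edges until the
#' requested edge density is reached (`ceiling(density * n(n-1)/2)` edges).
#' Ties are broken by lexicographic pair order so the construction is
#' deterministic.
#'
#' @param cm a `connectivity_matrix` (or any square numeric matrix), or an
#'   already-symmetric weight matrix.
#' @param density fraction of possible edges to retain, in (0, 1).
#' @return Object of class `brain_graph`: list with logical `adjacency`,
#'   `density` (realized), and `provenance` (threshold rule, isolated-node
#'   warning if any).
#' @export
matrix_to_graph <- function(cm, density) {
  stopifnot(density > 0, density < 1)
  W <- (unclass(cm) + t(unclass(cm))) / 2
  n <- nrow(W)
  ut <- which(upper.tri(W), arr.ind = TRUE)
  w <- W[ut]
  m <- ceiling(density * n * (n - 1) / 2)
  ord <- order(-w, ut[, 1], ut[, 2])
  sel <- ut[ord[seq_len(m)], , drop = FALSE]
  adj <- matrix(FALSE, n, n)
  adj[sel] <- TRUE
  adj <- adj | t(adj)
  iso <- sum(rowSums(adj) == 0)
  brain_graph(adj, provenance = list(
    rule = "fixed-density symmetrized threshold", requested_density = density,
    n_isolated = iso,
    warning = if (iso > 0) sprintf("%d isolated node(s) at this density", iso)))
}

#' Construct a brain graph from an adjacency matrix
#'
#' @param adj square symmetric logical/0-1 matrix, zero diagonal.
#' @param provenance free-form provenance list.
#' @return A `brain_graph`.
#' @export
brain_graph <- function(adj, provenance = list()) {
  adj <- adj != 0
  diag(adj) <- FALSE
  if (!isTRUE(all(adj == t(adj)))) stop("adjacency must be symmetric", call. = FALSE)
  n <- nrow(adj)
  structure(list(adjacency = adj,
                 n = n,
                 n_edges = sum(adj) / 2,
                 density = sum(adj) / (n * (n - 1)),
                 provenance = provenance),
            class = "brain_graph")
}

#' @export
print.brain_graph <- function(x, ...) {
  cat(sprintf("Brain graph: %d nodes, %d edges (density %.3f)\n",
              x$n, x$n_edges, x$density))
  invisible(x)
}

as_igraph <- function(g) {
  igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
}

#' Mean Watts-Strogatz clustering coefficient
#'
#' Node-wise clustering (closed triangles over possible triangles among
#' neighbours) averaged over all nodes; nodes of degree < 2 contribute 0.
#'
#' @param g a `brain_graph`.
#' @return Scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(g) {
  stopifnot(g$n >= 3)
  lc <- igraph::transitivity(as_igraph(g), type = "localundirected",
                             isolates = "zero")
  mean(lc)
}

#' Characteristic path length
#'
#' Mean shortest-path length (in edges) over all connected ordered node
#' pairs; disconnected pairs are excluded from the mean and their count is
#' returned as an attribute.
#'
#' @param g a `brain_graph`.
#' @return Scalar `L >= 1` with attribute `n_disconnected_pairs`; errors if
#'   the graph has no edges at all.
#' @export
characteristic_path_length <- function(g) {
  stopifnot(g$n >= 2)
  d <- igraph::distances(as_igraph(g))
  off <- d[row(d) != col(d)]
  fin <- is.finite(off)
  if (!any(fin))
    stop("undefined path length: no connected node pairs", call. = FALSE)
  structure(mean(off[fin]), n_disconnected_pairs = sum(!fin))
}

# One pass of degree-preserving double-edge swaps over an edge list.
# mode "random": every admissible swap accepted (Maslov-Sneppen null).
# mode "lattice": a swap is accepted only when it strictly reduces the total
# ring distance of edge endpoints (nodes on the fixed ordering 1..n), driving
# the graph toward a lattice while preserving the degree sequence.
# Uses the current R random stream.
double_edge_swap <- function(g, mode = c("random", "lattice"),
                             n_swaps_per_edge = 10L) {
  mode <- match.arg(mode)
  adj <- g$adjacency
  n <- g$n
  eidx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  m <- nrow(eidx)
  if (m < 2L) return(g)
  u <- eidx[, 1]; v <- eidx[, 2]
  ringd <- function(a, b) { d <- abs(a - b); pmin(d, n - d) }
  attempts <- as.integer(n_swaps_per_edge) * m
  pick <- matrix(sample.int(m, 2L * attempts, replace = TRUE), ncol = 2L)
  flip <- stats::runif(attempts) < 0.5
  for (t in seq_len(attempts)) {
    e1 <- pick[t, 1]; e2 <- pick[t, 2]
    if (e1 == e2) next
    a <- u[e1]; b <- v[e1]; c <- u[e2]; d <- v[e2]
    # two rewiring orientations: (a,d)+(c,b) or (a,c)+(b,d)
    if (flip[t]) { p1 <- a; q1 <- d; p2 <- c; q2 <- b }
    else         { p1 <- a; q1 <- c; p2 <- b; q2 <- d }
    if (p1 == q1 || p2 == q2) next
    if (adj[p1, q1] || adj[p2, q2]) next
    if ((p1 == p2 && q1 == q2) || (p1 == q2 && q1 == p2)) next
    if (mode == "lattice") {
      old <- ringd(a, b) + ringd(c, d)
      new <- ringd(p1, q1) + ringd(p2, q2)
      if (new >= old) next
    }
    adj[a, b] <- adj[b, a] <- FALSE
    adj[c, d] <- adj[d, c] <- FALSE
    adj[p1, q1] <- adj[q1, p1] <- TRUE
    adj[p2, q2] <- adj[q2, p2] <- TRUE
    u[e1] <- min(p1, q1); v[e1] <- max(p1, q1)
    u[e2] <- min(p2, q2); v[e2] <- max(p2, q2)
  }
  brain_graph(adj, provenance = c(g$provenance, list(rewired = mode)))
}

#' Degree-preserving randomization of a graph
#'
#' Maslov-Sneppen double-edge-swap randomization: repeated admissible edge
#' swaps that exactly preserve every node's degree.
#'
#' @param g a `brain_graph` with at least 2 edges.
#' @param n_swaps_per_edge attempted swaps per edge (default 10).
#' @param seed integer seed; `NULL` uses the current random stream.
#' @return A randomized `brain_graph` with the same degree sequence.
#' @export
rewire_random <- function(g, n_swaps_per_edge = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  double_edge_swap(g, "random", n_swaps_per_edge)
}

#' Degree-preserving latticization of a graph
#'
#' Double-edge swaps accepted only when they strictly reduce the total ring
#' distance between edge endpoints (nodes placed on a fixed ring in index
#' order), yielding a lattice-like surrogate with the original degree
#' sequence.  Used as the clustering reference of the small-world
#' coefficient.
#'
#' @inheritParams rewire_random
#' @return A latticized `brain_graph`.
#' @export
latticize <- function(g, n_swaps_per_edge = 10L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  double_edge_swap(g, "lattice", n_swaps_per_edge)
}

#' Small-world coefficient of a connectivity matrix or graph
#'
#' Computes the bounded small-world coefficient
#' \deqn{\omega = \bar L_{rand} / L \; - \; C / \bar C_{latt},}
#' where `C` and `L` are the graph's mean clustering coefficient and
#' characteristic path length and the reference terms are ensemble means over
#' degree-preserving random ([rewire_random()]) and lattice ([latticize()])
#' surrogates.  Values are clamped to \[-1, 1\] (the pre-clamp value is
#' retained): values near 0 indicate small-world organization, positive
#' values a more random and negative values a more regular (lattice-like)
#' topology.
#'
#' @param cm a `connectivity_matrix` (thresholded at `density`), a
#'   `brain_graph`, or a `coupling_graph` (its undirected projection is
#'   used and `density` is ignored for the latter two).
#' @param density edge density used by [matrix_to_graph()] (default 0.2).
#' @param n_surrogates surrogate ensemble size per reference (default 20).
#' @param seed integer seed for the surrogate ensembles.
#' @param n_swaps_per_edge swap attempts per edge in each surrogate.
#' @return Object of class `network_metrics`: list with `C`, `L`, `C_latt`,
#'   `L_rand`, `swc` (clamped), `swc_raw`, `n_surrogates`, `seed`, `graph`.
#' @export
small_world_coefficient <- function(cm, density = 0.2, n_surrogates = 20L,
                                    seed = NULL, n_swaps_per_edge = 10L) {
  g <- if (inherits(cm, "brain_graph")) cm
       else if (inherits(cm, "coupling_graph")) coupling_to_brain_graph(cm)
       else matrix_to_graph(cm, density)
  stopifnot(n_surrogates >= 1L)
  if (!is.null(seed)) set.seed(seed)
  C <- clustering_coefficient(g)
  L <- as.numeric(characteristic_path_length(g))
  Lr <- numeric(n_surrogates); Cl <- numeric(n_surrogates)
  for (s in seq_len(n_surrogates)) {
    Lr[s] <- as.numeric(characteristic_path_length(
      double_edge_swap(g, "random", n_swaps_per_edge)))
    Cl[s] <- clustering_coefficient(
      double_edge_swap(g, "lattice", n_swaps_per_edge))
  }
  c_ratio <- if (mean(Cl) > .Machine$double.eps) C / mean(Cl)
             else if (C <= .Machine$double.eps) 1 else Inf
  raw <- mean(Lr) / L - c_ratio
  structure(list(C = C, L = L, C_latt = mean(Cl), L_rand = mean(Lr),
                 swc = max(-1, min(1, raw)), swc_raw = raw,
                 n_surrogates = n_surrogates, seed = seed,
                 density = g$density, graph = g),
            class = "network_metrics")
}

#' @export
print.network_metrics <- function(x, ...) {
  cat(sprintf(
    "Network metrics: C=%.3f L=%.3f  C_latt=%.3f L_rand=%.3f  omega=%.3f\n",
    x$C, x$L, x$C_latt, x$L_rand, x$swc))
  invisible(x)
}
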