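# Node and edge centrality suite. All measures operate on the largest
# connected component of an undirected, unweighted simple graph, with
# unordered-pair conventions for the path-counting measures and reciprocal
# (CentiScape-style) forms for closeness and eccentricity. Node order is the
# sorted node-id order, so floating-point results are reproducible.

# Canonical arrays for the C++ substrate: sorted node names and a 0-based
# edge matrix in that order.
graph_arrays <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  el <- igraph::as_edgelist(g, names = TRUE)
  edges0 <- cbind(match(el[, 1], nodes), match(el[, 2], nodes)) - 1L
  storage.mode(edges0) <- "integer"
  ord <- order(pmin(edges0[, 1], edges0[, 2]), pmax(edges0[, 1], edges0[, 2]))
  list(nodes = nodes, edges0 = edges0[ord, , drop = FALSE])
}

component_arrays <- function(g) {
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name",
                                 value = as.character(seq_len(igraph::vcount(g))))
  graph_arrays(largest_component(g))
}

#' Shortest-path statistics for all node pairs
#'
#' Breadth-first search from every node of the largest connected component,
#' returning the geodesic distance matrix and the matrix of geodesic counts
#' (Brandes-style path-count accumulation).
#'
#' @param g An igraph graph.
#' @return A list: `nodes` (sorted ids), `dist` (integer matrix), `sigma`
#'   (numeric matrix of shortest-path counts).
#' @export
shortest_path_stats <- function(g) {
  arr <- component_arrays(g)
  bs <- brandes_cpp(length(arr$nodes), arr$edges0)
  dimnames(bs$dist) <- list(arr$nodes, arr$nodes)
  dimnames(bs$sigma) <- list(arr$nodes, arr$nodes)
  list(nodes = arr$nodes, dist = bs$dist, sigma = bs$sigma)
}

#' Betweenness centrality
#'
#' Sum over unordered node pairs of the fraction of geodesics passing
#' through the node (raw, unnormalized values).
#'
#' @param g An igraph graph.
#' @return Named numeric vector over the largest component's nodes.
#' @export
betweenness_centrality <- function(g) {
  arr <- component_arrays(g)
  bs <- brandes_cpp(length(arr$nodes), arr$edges0)
  setNames(bs$betweenness, arr$nodes)
}

#' Stress centrality
#'
#' Number of geodesics (over unordered pairs) passing through the node.
#'
#' @param g An igraph graph.
#' @return Named numeric vector over the largest component's nodes.
#' @export
stress_centrality <- function(g) {
  arr <- component_arrays(g)
  bs <- brandes_cpp(length(arr$nodes), arr$edges0)
  setNames(stress_cpp(bs$dist, bs$sigma), arr$nodes)
}

#' Edge betweenness centrality
#'
#' @param g An igraph graph.
#' @return Data frame `from`, `to`, `edge_betweenness` over the largest
#'   component's edges.
#' @export
edge_betweenness_centrality <- function(g) {
  arr <- component_arrays(g)
  bs <- brandes_cpp(length(arr$nodes), arr$edges0)
  data.frame(from = arr$nodes[arr$edges0[, 1] + 1L],
             to = arr$nodes[arr$edges0[, 2] + 1L],
             edge_betweenness = bs$edge_betweenness,
             stringsAsFactors = FALSE)
}

#' Closeness centrality (reciprocal form)
#'
#' `1 / sum of geodesic distances` to all other nodes of the component.
#'
#' @param g An igraph graph.
#' @return Named numeric vector.
#' @export
closeness_centrality <- function(g) {
  sp <- shortest_path_stats(g)
  if (length(sp$nodes) == 1) return(setNames(NA_real_, sp$nodes))
  setNames(1 / rowSums(sp$dist), sp$nodes)
}

#' Eccentricity centrality (reciprocal form)
#'
#' `1 / maximum geodesic distance` to any node of the component.
#'
#' @param g An igraph graph.
#' @return Named numeric vector.
#' @export
eccentricity_centrality <- function(g) {
  sp <- shortest_path_stats(g)
  if (length(sp$nodes) == 1) return(setNames(NA_real_, sp$nodes))
  setNames(1 / apply(sp$dist, 1, max), sp$nodes)
}

#' Radiality centrality
#'
#' `sum over other nodes of (diameter + 1 - distance) / (n - 1)`; its node
#' average equals `diameter + 1 - average distance`.
#'
#' @param g An igraph graph.
#' @return Named numeric vector.
#' @export
radiality_centrality <- function(g) {
  sp <- shortest_path_stats(g)
  n <- length(sp$nodes)
  if (n == 1) return(setNames(NA_real_, sp$nodes))
  delta <- max(sp$dist)
  setNames((rowSums(delta + 1 - sp$dist) - (delta + 1)) / (n - 1), sp$nodes)
}

#' Centroid centrality
#'
#' For each node v, the minimum over opponents w of
#' `gamma_v(w) - gamma_w(v)`, where `gamma_v(w)` counts the nodes strictly
#' closer to v than to w (endpoints excluded; distance ties count for
#' neither side). Positive values mark globally central "winner" nodes.
#'
#' @param g An igraph graph.
#' @return Named numeric vector.
#' @export
centroid_centrality <- function(g) {
  sp <- shortest_path_stats(g)
  setNames(centroid_cpp(sp$dist), sp$nodes)
}

#' Eigenvector centrality
#'
#' Principal eigenvector of the component's adjacency matrix, nonnegative
#' with unit Euclidean norm, computed by power iteration (on the
#' diagonally shifted adjacency matrix, which shares its eigenvectors, to
#' guarantee convergence on bipartite-like graphs) to relative tolerance
#' 1e-12 with at most 1e5 iterations.
#'
#' @param g An igraph graph.
#' @return Named numeric vector.
#' @export
eigenvector_centrality <- function(g) {
  arr <- component_arrays(g)
  n <- length(arr$nodes)
  if (n == 1) return(setNames(1, arr$nodes))
  A <- matrix(0, n, n)
  A[arr$edges0 + 1L] <- 1
  A[arr$edges0[, 2:1, drop = FALSE] + 1L] <- 1
  diag(A) <- diag(A) + 1  # spectral shift, eigenvectors unchanged
  x <- rep(1 / sqrt(n), n)
  for (i in seq_len(1e5)) {
    y <- as.vector(A %*% x)
    y <- y / sqrt(sum(y^2))
    if (max(abs(y - x)) <= 1e-12 * max(abs(y))) { x <- y; break }
    x <- y
  }
  x <- abs(x)
  setNames(x / sqrt(sum(x^2)), arr$nodes)
}

#' Bridging centrality
#'
#' `betweenness(v)` times the bridging coefficient
#' `(1/deg(v)) / sum over neighbors u of 1/deg(u)`; large for nodes sitting
#' between densely connected modules.
#'
#' @param g An igraph graph.
#' @return Named numeric vector.
#' @export
bridging_centrality <- function(g) {
  arr <- component_arrays(g)
  n <- length(arr$nodes)
  bs <- brandes_cpp(n, arr$edges0)
  deg <- tabulate(c(arr$edges0[, 1], arr$edges0[, 2]) + 1L, nbins = n)
  inv_nb <- numeric(n)
  for (k in seq_len(nrow(arr$edges0))) {
    a <- arr$edges0[k, 1] + 1L; b <- arr$edges0[k, 2] + 1L
    inv_nb[a] <- inv_nb[a] + 1 / deg[b]
    inv_nb[b] <- inv_nb[b] + 1 / deg[a]
  }
  bc <- (1 / deg) / inv_nb
  setNames(bs$betweenness * bc, arr$nodes)
}

#' Full centrality table of a graph
#'
#' Computes the complete node centrality suite (degree, betweenness, stress,
#' closeness, eccentricity, radiality, centroid, eigenvector, bridging) on
#' the largest connected component in one pass over the shared
#' shortest-path substrate, together with edge betweenness and the
#' network-level diameter and average distance.
#'
#' @param g An igraph graph.
#' @return A data frame of class `centrality_table` (one row per component
#'   node, nodes sorted by id), with attributes `edge_betweenness` (data
#'   frame), `diameter`, `average_distance`, `averages` (named vector of
#'   per-centrality means), `component_size`.
#' @export
centrality_table <- function(g) {
  arr <- component_arrays(g)
  n <- length(arr$nodes)
  if (n < 2) stopf("largest component has fewer than 2 nodes")
  bs <- brandes_cpp(n, arr$edges0)
  dist <- bs$dist

  deg <- tabulate(c(arr$edges0[, 1], arr$edges0[, 2]) + 1L, nbins = n)
  delta <- max(dist)
  inv_nb <- numeric(n)
  for (k in seq_len(nrow(arr$edges0))) {
    a <- arr$edges0[k, 1] + 1L; b <- arr$edges0[k, 2] + 1L
    inv_nb[a] <- inv_nb[a] + 1 / deg[b]
    inv_nb[b] <- inv_nb[b] + 1 / deg[a]
  }

  # eigenvector via the dedicated routine (same component, same order)
  ev <- eigenvector_centrality(g)

  tab <- data.frame(
    node = arr$nodes,
    degree = deg,
    betweenness = bs$betweenness,
    stress = stress_cpp(dist, bs$sigma),
    closeness = 1 / rowSums(dist),
    eccentricity = 1 / apply(dist, 1, max),
    radiality = (rowSums(delta + 1 - dist) - (delta + 1)) / (n - 1),
    centroid = centroid_cpp(dist),
    eigenvector = as.numeric(ev[arr$nodes]),
    stringsAsFactors = FALSE)
  tab$bridging <- tab$betweenness * (1 / deg) / inv_nb

  attr(tab, "edge_betweenness") <- data.frame(
    from = arr$nodes[arr$edges0[, 1] + 1L],
    to = arr$nodes[arr$edges0[, 2] + 1L],
    edge_betweenness = bs$edge_betweenness, stringsAsFactors = FALSE)
  attr(tab, "diameter") <- delta
  attr(tab, "average_distance") <- mean(dist[upper.tri(dist)])
  num <- setdiff(names(tab), "node")
  attr(tab, "averages") <- vapply(tab[num], mean, 0)
  attr(tab, "component_size") <- n
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("Centrality table: %d nodes (largest component), diameter %d, avg distance %.3f\n",
              nrow(x), attr(x, "diameter"), attr(x, "average_distance")))
  print.data.frame(head(as.data.frame(x), 10), digits = 4)
  if (nrow(x) > 10) cat(sprintf("  ... and %d more nodes\n", nrow(x) - 10))
  invisible(x)
}

#' Write a centrality table and its network summary
#'
#' @param tab A [centrality_table()].
#' @param path_prefix Output path without extension; writes
#'   `<prefix>.tsv`, `<prefix>_edges.tsv` and `<prefix>_summary.json`.
#' @return Invisibly, the paths written.
#' @export
write_centrality <- function(tab, path_prefix) {
  p1 <- paste0(path_prefix, ".tsv")
  p2 <- paste0(path_prefix, "_edges.tsv")
  p3 <- paste0(path_prefix, "_summary.json")
  write_tsv(as.data.frame(tab), p1)
  write_tsv(attr(tab, "edge_betweenness"), p2)
  write_json(list(component_size = attr(tab, "component_size"),
                  diameter = attr(tab, "diameter"),
                  average_distance = attr(tab, "average_distance"),
                  averages = as.list(attr(tab, "averages"))), p3)
  invisible(c(p1, p2, p3))
}
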