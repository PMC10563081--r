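#' Build an evidence-filtered protein-protein interaction graph
#'
#' Keeps an edge when both endpoints belong to the seed gene set AND its
#' experimental score exceeds `exp_min` OR its database score exceeds
#' `db_min` (both comparisons strict). Self-loops and duplicate edges
#' (a-b = b-a) are removed. Seed genes left without any surviving edge are
#' reported as isolated (graph attribute `isolated`) and excluded from the
#' graph.
#'
#' @param seed_genes Character vector of gene ids seeding the network.
#' @param edge_table Data frame with columns `gene_a`, `gene_b`,
#'   `experimental_score`, `database_score`, scores in \[0, 1\].
#' @param exp_min,db_min Evidence-channel score thresholds.
#' @return An undirected igraph graph with edge attributes
#'   `experimental_score`, `database_score` and graph attribute `isolated`.
#' @export
#' @examples
#' edges <- data.frame(gene_a = "g1", gene_b = "g2",
#'                     experimental_score = 0.5, database_score = 0)
#' build_ppi(c("g1", "g2"), edges)
build_ppi <- function(seed_genes, edge_table, exp_min = 0.1, db_min = 0.3) {
  if (length(seed_genes) == 0) stopf("seed gene set is empty")
  need <- c("gene_a", "gene_b", "experimental_score", "database_score")
  if (!all(need %in% names(edge_table)))
    stopf("edge table must contain columns: %s", paste(need, collapse = ", "))
  sc <- c(edge_table$experimental_score, edge_table$database_score)
  if (any(sc < 0 | sc > 1))
    stopf("edge scores must lie in [0, 1] (see read_ppi_edges(string_scale=))")

  et <- edge_table
  keep <- et$gene_a %in% seed_genes & et$gene_b %in% seed_genes &
    et$gene_a != et$gene_b &
    (et$experimental_score > exp_min | et$database_score > db_min)
  et <- et[keep, , drop = FALSE]
  # canonical edge orientation, then de-duplicate
  a <- pmin(et$gene_a, et$gene_b)
  b <- pmax(et$gene_a, et$gene_b)
  dup <- duplicated(paste(a, b))
  et <- data.frame(gene_a = a[!dup], gene_b = b[!dup],
                   experimental_score = et$experimental_score[!dup],
                   database_score = et$database_score[!dup],
                   stringsAsFactors = FALSE)
  connected <- sort(unique(c(et$gene_a, et$gene_b)))
  isolated <- sort(setdiff(seed_genes, connected))
  if (nrow(et) == 0)
    warnf("no edge survives the evidence filter; graph is empty")
  g <- igraph::graph_from_data_frame(
    et, directed = FALSE,
    vertices = data.frame(name = connected, stringsAsFactors = FALSE))
  g <- igraph::set_graph_attr(g, "isolated", isolated)
  g
}

# Largest connected component (ties broken by smallest node name).
largest_component <- function(g) {
  comp <- igraph::components(g)
  if (comp$no <= 1) return(g)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1) {
    first_name <- vapply(best, function(k)
      min(igraph::V(g)$name[comp$membership == k]), "")
    best <- best[order(first_name)][1]
  }
  igraph::induced_subgraph(g, which(comp$membership == best))
}

#' Topological summary of an interaction graph
#'
#' Node and edge counts for the whole graph; diameter (maximum geodesic
#' length) and average distance (mean geodesic length over connected pairs)
#' computed on the largest connected component, from the package's own
#' breadth-first-search distance substrate.
#'
#' @param g An igraph graph.
#' @return A list: `n_nodes`, `n_edges`, `n_components`, `component_sizes`,
#'   `diameter`, `average_distance`.
#' @export
network_summary <- function(g) {
  if (igraph::vcount(g) == 0) stopf("graph is empty")
  comp <- igraph::components(g)
  lc <- largest_component(g)
  arr <- graph_arrays(lc)
  bs <- brandes_cpp(length(arr$nodes), arr$edges0)
  d <- bs$dist[upper.tri(bs$dist)]
  list(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
       n_components = comp$no,
       component_sizes = sort(comp$csize, decreasing = TRUE),
       diameter = if (length(d)) max(d) else 0,
       average_distance = if (length(d)) mean(d) else NA_real_)
}
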