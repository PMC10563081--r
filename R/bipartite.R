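#' Build bipartite miRNA-target networks per expression direction
#'
#' Builds one directed miRNA-to-gene network per direction class: each
#' network contains the differentially expressed miRNAs of that class, every
#' gene they target according to the interaction map, and the corresponding
#' edges. miRNAs with no known target are retained with out-degree 0 and
#' reported. miRNA identifiers are matched case-insensitively with the
#' species prefix stripped (see [normalize_mirna_ids()]).
#'
#' @param de_mirnas Data frame with columns `feature` and `direction`
#'   (`"up"`/`"down"`), e.g. from [apply_thresholds()].
#' @param target_map Data frame with columns `mirna_id`, `gene_id`.
#' @return A list with elements `up` and `down`, each a `bipartite_net`:
#'   `mirnas`, `genes`, `edges` (data frame mirna/gene), `out_degree`
#'   (named, per miRNA), `in_degree` (named, per gene), `class`.
#' @export
build_bipartite <- function(de_mirnas, target_map) {
  if (nrow(target_map) == 0) stopf("target map is empty")
  map <- data.frame(mirna = normalize_mirna_ids(target_map$mirna_id),
                    gene = as.character(target_map$gene_id),
                    stringsAsFactors = FALSE)
  map <- map[!duplicated(map), , drop = FALSE]
  one_class <- function(cls) {
    mirs <- sort(normalize_mirna_ids(
      de_mirnas$feature[de_mirnas$direction == cls]))
    edges <- map[map$mirna %in% mirs, , drop = FALSE]
    genes <- sort(unique(edges$gene))
    out_deg <- table(factor(edges$mirna, levels = mirs))
    in_deg <- table(factor(edges$gene, levels = genes))
    if (length(mirs) > 0 && nrow(edges) == 0)
      warnf("no %s-regulated miRNA has any target; network is empty", cls)
    structure(list(mirnas = mirs, genes = genes, edges = edges,
                   out_degree = setNames(as.numeric(out_deg), names(out_deg)),
                   in_degree = setNames(as.numeric(in_deg), names(in_deg)),
                   class = cls),
              class = "bipartite_net")
  }
  list(up = one_class("up"), down = one_class("down"))
}

#' @export
print.bipartite_net <- function(x, ...) {
  cat(sprintf("Bipartite miRNA-target network (%s): %d miRNAs, %d genes, %d edges\n",
              x$class, length(x$mirnas), length(x$genes), nrow(x$edges)))
  iso <- sum(x$out_degree == 0)
  if (iso > 0) cat(sprintf("  %d miRNA(s) with no known target\n", iso))
  invisible(x)
}

#' Rank bipartite nodes by degree and select above-average ones
#'
#' Ranks miRNAs by out-degree (genes targeted) and genes by in-degree
#' (miRNAs targeting them). miRNAs strictly above the average out-degree are
#' selected; genes with in-degree at least `multiplier` times the average
#' in-degree are flagged as most-targeted. Averages are recomputed from the
#' network itself over all nodes of the relevant side, degree-0 nodes
#' included.
#'
#' @param net A `bipartite_net`.
#' @param multiplier Multiplier on the average in-degree for the gene rule.
#' @return A list of class `degree_selection`: `avg_out`, `avg_in`,
#'   `selected_mirnas`, `selected_genes`, `mirna_rank`, `gene_rank`,
#'   `multiplier`.
#' @export
rank_and_select <- function(net, multiplier = 2) {
  if (length(net$mirnas) == 0 && length(net$genes) == 0)
    stopf("empty bipartite network")
  avg_out <- if (length(net$out_degree)) mean(net$out_degree) else 0
  avg_in <- if (length(net$in_degree)) mean(net$in_degree) else 0
  sel_m <- names(net$out_degree)[net$out_degree > avg_out]
  sel_g <- names(net$in_degree)[net$in_degree >= multiplier * avg_in]
  rank_m <- net$out_degree[order(-net$out_degree, names(net$out_degree))]
  rank_g <- net$in_degree[order(-net$in_degree, names(net$in_degree))]
  structure(list(avg_out = avg_out, avg_in = avg_in,
                 selected_mirnas = sort(sel_m), selected_genes = sort(sel_g),
                 mirna_rank = rank_m, gene_rank = rank_g,
                 multiplier = multiplier, class_label = net$class),
            class = "degree_selection")
}

#' @export
print.degree_selection <- function(x, ...) {
  cat(sprintf("Degree selection (%s): avg out-degree %.2f, avg in-degree %.2f\n",
              x$class_label %||% "?", x$avg_out, x$avg_in))
  cat(sprintf("  %d miRNAs above average; %d genes with in-degree >= %g x average\n",
              length(x$selected_mirnas), length(x$selected_genes),
              x$multiplier))
  invisible(x)
}

#' Cross-class filter for genes targeted by both miRNA classes
#'
#' Partitions target genes into up-specific and down-specific sets. A gene
#' targeted by both classes is up-specific iff its in-degree in the
#' up-network is at least `multiplier` times that network's average AND its
#' in-degree in the down-network is below that network's average; the
#' down-specific rule is the mirror image. Genes targeted by one class only
#' must pass that class's `multiplier`-times-average rule. All other genes
#' are dropped. With average in-degrees 4 (up) and 5 (down) and multiplier
#' 2 this is the "degree >= 8 and < 5, or < 4 and >= 10" rule.
#'
#' @param up_net,down_net `bipartite_net` objects for the two classes.
#' @param multiplier Multiplier on the average in-degree.
#' @param avg_up,avg_down Optional overrides of the network-average
#'   in-degrees (recomputed from the networks when `NULL`).
#' @return A list: `up_specific`, `down_specific` (character, disjoint),
#'   `avg_up`, `avg_down`, `multiplier`.
#' @export
cross_class_filter <- function(up_net, down_net, multiplier = 2,
                               avg_up = NULL, avg_down = NULL) {
  avg_up <- avg_up %||%
    (if (length(up_net$in_degree)) mean(up_net$in_degree) else 0)
  avg_down <- avg_down %||%
    (if (length(down_net$in_degree)) mean(down_net$in_degree) else 0)
  genes <- sort(union(up_net$genes, down_net$genes))
  du <- setNames(rep(0, length(genes)), genes)
  dd <- du
  du[names(up_net$in_degree)] <- up_net$in_degree
  dd[names(down_net$in_degree)] <- down_net$in_degree
  in_up <- genes %in% up_net$genes
  in_down <- genes %in% down_net$genes
  up_spec <- genes[in_up & du >= multiplier * avg_up &
                     (!in_down | dd < avg_down)]
  down_spec <- genes[in_down & dd >= multiplier * avg_down &
                       (!in_up | du < avg_up)]
  list(up_specific = up_spec, down_specific = down_spec,
       avg_up = avg_up, avg_down = avg_down, multiplier = multiplier)
}

#' Export a bipartite network as SIF and GraphML
#'
#' GraphML nodes carry attributes `side` ("mirna"/"gene") and `class`
#' ("up"/"down").
#'
#' @param net A `bipartite_net`.
#' @param path_prefix Output path without extension.
#' @return Invisibly, the two paths written.
#' @export
write_bipartite <- function(net, path_prefix) {
  sif <- paste0(path_prefix, ".sif")
  gml <- paste0(path_prefix, ".graphml")
  write_sif(net$edges[, c("mirna", "gene")], sif, interaction = "targets")
  nodes <- data.frame(name = c(net$mirnas, net$genes),
                      side = rep(c("mirna", "gene"),
                                 c(length(net$mirnas), length(net$genes))),
                      class = net$class, stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(net$edges[, c("mirna", "gene")],
                                     directed = TRUE, vertices = nodes)
  write_graphml(g, gml)
  invisible(c(sif, gml))
}
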