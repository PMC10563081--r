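#' Kolmogorov-Smirnov contrast of miRNA targeting pressure
#'
#' For differentially expressed genes of one direction (up-regulated in
#' tumor by default), compares the distribution of the number of
#' down-regulated miRNAs targeting each gene against the distribution of the
#' number of up-regulated miRNAs targeting it, with a two-sample
#' Kolmogorov-Smirnov test (D = sup |ECDF1 - ECDF2|, asymptotic p). Genes of
#' the chosen direction that are absent from a network count as in-degree 0.
#' The mirrored contrast (down-regulated genes) is available via
#' `direction = "down"`.
#'
#' @param degs Data frame with columns `feature`, `direction` (from
#'   [apply_thresholds()]).
#' @param up_net,down_net `bipartite_net` objects from [build_bipartite()].
#' @param direction Which DEG direction to analyze.
#' @param exact Passed to [stats::ks.test()] (exact small-sample p).
#' @return A list of class `integration_result`: `direction`, `counts`
#'   (data frame gene, n_down_mirnas, n_up_mirnas), `D`, `p`.
#' @export
ks_target_contrast <- function(degs, up_net, down_net,
                               direction = c("up", "down"), exact = FALSE) {
  direction <- match.arg(direction)
  genes <- sort(degs$feature[degs$direction == direction])
  if (length(genes) == 0) stopf("no DEGs of direction '%s'", direction)
  deg_of <- function(net) {
    d <- setNames(rep(0, length(genes)), genes)
    hit <- intersect(genes, names(net$in_degree))
    d[hit] <- net$in_degree[hit]
    d
  }
  x_down <- deg_of(down_net)
  x_up <- deg_of(up_net)
  ks <- suppressWarnings(stats::ks.test(x_down, x_up, exact = exact))
  structure(list(direction = direction,
                 counts = data.frame(gene = genes,
                                     n_down_mirnas = as.numeric(x_down),
                                     n_up_mirnas = as.numeric(x_up),
                                     stringsAsFactors = FALSE),
                 D = unname(ks$statistic), p = ks$p.value),
            class = "integration_result")
}

#' @export
print.integration_result <- function(x, ...) {
  cat(sprintf("Targeting-pressure contrast on %s-regulated genes (n = %d)\n",
              x$direction, nrow(x$counts)))
  cat(sprintf("  mean #targeting down-miRNAs %.2f vs up-miRNAs %.2f\n",
              mean(x$counts$n_down_mirnas), mean(x$counts$n_up_mirnas)))
  cat(sprintf("  Kolmogorov-Smirnov D = %.4f, p = %.4g\n", x$D, x$p))
  invisible(x)
}

#' Hypergeometric gene-set over-representation
#'
#' Upper-tail hypergeometric test of each gene set's overlap with a query
#' set, against a fixed gene universe, with Benjamini-Hochberg adjustment
#' across the tested sets. Sets are intersected with the universe first.
#'
#' @param query Character vector of genes (must lie in `universe`).
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Character vector: the gene universe.
#' @return Data frame `set`, `k` (overlap), `K` (set size in universe),
#'   `n` (query size), `N` (universe size), `p`, `q` (BH).
#' @export
hypergeom_enrich <- function(query, sets, universe) {
  universe <- unique(universe)
  query <- unique(query)
  if (!all(query %in% universe))
    stopf("query genes must be contained in the universe")
  N <- length(universe)
  n <- length(query)
  rows <- lapply(names(sets), function(nm) {
    s <- intersect(unique(sets[[nm]]), universe)
    K <- length(s)
    k <- length(intersect(s, query))
    p <- if (K == 0) 1 else phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, k = k, K = K, n = n, N = N, p = p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- p.adjust(out$p, method = "BH")
  out[order(out$p, out$set), , drop = FALSE]
}
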