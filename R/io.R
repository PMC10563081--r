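# Readers and writers for the plain-text interchange formats: TSV tables,
# SIF/GraphML graph exports, GMT gene-set collections, JSON summaries.

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

write_counts <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and a first column of feature ids.
#'
#' @param path Path to the TSV file.
#' @return Integer matrix, features x samples.
#' @export
read_counts <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  storage.mode(m) <- "numeric"
  check_count_matrix(m)
  m
}

#' Read sample metadata from TSV
#'
#' Expects columns `sample_id`, `condition` (tumor/control), `stage`, and
#' optionally `time` and `event` for survival.
#'
#' @param path Path to the TSV file.
#' @return Data frame of sample metadata.
#' @export
read_sample_metadata <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "condition")
  if (!all(need %in% names(df)))
    stopf("metadata must contain columns: %s", paste(need, collapse = ", "))
  if (!all(df$condition %in% c("tumor", "control")))
    stopf("condition must be 'tumor' or 'control'")
  df
}

#' Read a miRNA-target interaction table from TSV
#'
#' @param path Path to a TSV with columns `mirna_id`, `gene_id` and
#'   optionally `source`.
#' @return Data frame of unique (mirna_id, gene_id) pairs.
#' @export
read_target_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("mirna_id", "gene_id") %in% names(df)))
    stopf("target map must contain columns mirna_id, gene_id")
  df[!duplicated(df[c("mirna_id", "gene_id")]), , drop = FALSE]
}

#' Read a protein-protein interaction edge table from TSV
#'
#' Expects columns `gene_a`, `gene_b`, `experimental_score`,
#' `database_score`. Scores must lie in \[0, 1\]; tables using the STRING
#' 0-1000 integer convention can be converted with `string_scale = TRUE`.
#'
#' @param path Path to the TSV file.
#' @param string_scale If `TRUE`, divide both score columns by 1000.
#' @return Data frame of scored edges.
#' @export
read_ppi_edges <- function(path, string_scale = FALSE) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_a", "gene_b", "experimental_score", "database_score")
  if (!all(need %in% names(df)))
    stopf("edge table must contain columns: %s", paste(need, collapse = ", "))
  if (string_scale) {
    df$experimental_score <- df$experimental_score / 1000
    df$database_score <- df$database_score / 1000
  }
  sc <- c(df$experimental_score, df$database_score)
  if (any(sc < 0 | sc > 1))
    stopf(paste("edge scores must lie in [0, 1];",
                "use string_scale = TRUE for 0-1000 STRING scores"))
  df
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (gene sets).
#' @export
read_gmt <- function(path) {
  if (requireNamespace("fgsea", quietly = TRUE))
    return(fgsea::gmtPathways(path))
  lines <- strsplit(readLines(path), "\t", fixed = TRUE)
  setNames(lapply(lines, function(x) x[-(1:2)]),
           vapply(lines, `[`, "", 1))
}

#' Export a graph in SIF format
#'
#' Simple interaction format: one `node1 <type> node2` line per edge.
#'
#' @param edges Two-column data frame or matrix of edges.
#' @param path Output path.
#' @param interaction Interaction type label.
#' @return Invisibly, the path written.
#' @export
write_sif <- function(edges, path, interaction = "interacts") {
  df <- data.frame(a = edges[[1]], interaction = interaction, b = edges[[2]])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Export an igraph graph as GraphML
#'
#' @param g An igraph object.
#' @param path Output path.
#' @return Invisibly, the path written.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

write_json <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
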