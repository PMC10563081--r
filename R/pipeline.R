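#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs. Inputs come either from five
#' delimited tables on disk or from the synthetic generator (when
#' `sim = sim_config(...)` is given and `paths` is `NULL`).
#'
#' @param paths Named list of input paths (`gene_counts`, `mirna_counts`,
#'   `samples`, `target_map`, `ppi_edges`), or `NULL` to synthesize.
#' @param sim A [sim_config()] used when `paths` is `NULL`.
#' @param thresholds A [de_thresholds()].
#' @param bipartite_multiplier Multiplier for the degree selection rules.
#' @param exp_min,db_min Evidence-score thresholds for the PPI filter.
#' @param string_scale Divide input PPI scores by 1000 (STRING convention).
#' @param null_config A [null_model_config()].
#' @param survival_rule `"median"` or `"tertile"` stratification.
#' @param outdir Output directory.
#' @param seed Global seed (propagated to `sim` and `null_config`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(paths = NULL, sim = sim_config(),
                            thresholds = de_thresholds(),
                            bipartite_multiplier = 2,
                            exp_min = 0.1, db_min = 0.3,
                            string_scale = FALSE,
                            null_config = null_model_config(),
                            survival_rule = "median",
                            outdir = tempfile("mirhubnet_run"),
                            seed = 1L) {
  if (!is.null(paths)) {
    need <- c("gene_counts", "mirna_counts", "samples", "target_map",
              "ppi_edges")
    miss <- setdiff(need, names(paths))
    if (length(miss))
      stopf("config error: missing input paths: %s", paste(miss, collapse = ", "))
    bad <- !vapply(paths[need], file.exists, TRUE)
    if (any(bad))
      stopf("config error: input files not found: %s",
            paste(unlist(paths[need])[bad], collapse = ", "))
  }
  sim$seed <- as.integer(seed)
  null_config$seed <- as.integer(seed)
  structure(list(paths = paths, sim = sim, thresholds = thresholds,
                 bipartite_multiplier = bipartite_multiplier,
                 exp_min = exp_min, db_min = db_min,
                 string_scale = string_scale, null_config = null_config,
                 survival_rule = survival_rule, outdir = outdir,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Save / load a pipeline configuration as YAML
#'
#' The round trip is lossless for all scalar and vector fields.
#'
#' @param config A [pipeline_config()].
#' @param path YAML file path.
#' @return `write_pipeline_config` invisibly returns `path`;
#'   `read_pipeline_config` returns the reconstructed `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass(config)
  x$sim <- unclass(x$sim)
  # named list so YAML keeps the stage names
  x$sim$stage_proportions <- as.list(x$sim$stage_proportions)
  x$thresholds <- unclass(x$thresholds)
  x$null_config <- unclass(x$null_config)
  yaml::write_yaml(x, path, precision = 15)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim <- do.call(sim_config, c(x$sim[setdiff(names(x$sim), "stage_proportions")],
                               list(stage_proportions = unlist(x$sim$stage_proportions))))
  pipeline_config(paths = x$paths, sim = sim,
                  thresholds = do.call(de_thresholds, x$thresholds),
                  bipartite_multiplier = x$bipartite_multiplier,
                  exp_min = x$exp_min, db_min = x$db_min,
                  string_scale = x$string_scale,
                  null_config = do.call(null_model_config, x$null_config),
                  survival_rule = x$survival_rule, outdir = x$outdir,
                  seed = x$seed)
}

# Run one stage with graceful degradation: on error, record the reason in
# the manifest instead of failing the run.
run_stage <- function(manifest, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, value = conditionMessage(e)))
  manifest$stages[[name]] <- list(
    status = if (res$ok) "ok" else "skipped",
    note = if (res$ok) NULL else res$value,
    seconds = round(proc.time()[["elapsed"]] - t0, 3))
  list(manifest = manifest, value = if (res$ok) res$value else NULL)
}

#' Run the full integrative pipeline
#'
#' Executes, in order: input synthesis or loading; differential expression
#' of genes and miRNAs; threshold selection; bipartite miRNA-target networks
#' with degree ranking and the cross-class filter; evidence-filtered
#' interaction graphs for the DEG set and both target-specific gene sets;
#' the centrality suite and composite hub selection on each graph, validated
#' against degree-preserving random models; the targeting-pressure
#' Kolmogorov-Smirnov contrast; and miRNA-stratified survival tests. Every
#' intermediate table is written under `config$outdir` and a JSON manifest
#' records seeds, input digests, per-stage sizes and wall times. Stages with
#' empty inputs are skipped and recorded, never silently passed.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, the manifest (a list of class `pipeline_manifest`),
#'   with the stage results in its `results` element.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("config error: not a pipeline_config")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(config$outdir, paste0(...))
  manifest <- list(package_version = as.character(utils::packageVersion("mirhubnet")),
                   seed = config$seed, stages = list(), counts = list())
  results <- list()

  ## inputs -----------------------------------------------------------------
  if (is.null(config$paths)) {
    bundle <- simulate_all(config$sim)
    write_sim_inputs(bundle, config$outdir)
    gene_counts <- bundle$genes$counts
    mirna_counts <- bundle$mirnas$counts
    meta <- bundle$samples
    target_map <- bundle$target_map
    ppi_edges <- bundle$ppi$edges
    surv <- bundle$survival
    results$truth <- list(de_genes = bundle$genes$truth,
                          de_mirnas = bundle$mirnas$truth,
                          planted_hubs = bundle$ppi$planted_hubs,
                          prognostic = attr(surv, "prognostic_mirnas"))
    manifest$stages$inputs <- list(status = "synthesized")
  } else {
    gene_counts <- read_counts(config$paths$gene_counts)
    mirna_counts <- read_counts(config$paths$mirna_counts)
    meta <- read_sample_metadata(config$paths$samples)
    target_map <- read_target_map(config$paths$target_map)
    ppi_edges <- read_ppi_edges(config$paths$ppi_edges,
                                string_scale = config$string_scale)
    surv <- if (all(c("time", "event") %in% names(meta)))
      meta[meta$condition == "tumor", c("sample_id", "time", "event")] else NULL
    manifest$stages$inputs <- list(
      status = "loaded",
      digests = as.list(tools::md5sum(unlist(config$paths))))
  }
  manifest$counts$samples <- nrow(meta)
  manifest$counts$genes <- nrow(gene_counts)
  manifest$counts$mirnas <- nrow(mirna_counts)

  ## differential expression ------------------------------------------------
  st <- run_stage(manifest, "diffexpr_genes",
                  de_analysis(gene_counts, meta, config$thresholds))
  manifest <- st$manifest; de_genes <- st$value
  st <- run_stage(manifest, "diffexpr_mirnas",
                  de_analysis(mirna_counts, meta, config$thresholds))
  manifest <- st$manifest; de_mirnas <- st$value

  deg_list <- deg_network <- mir_sel <- NULL
  if (!is.null(de_genes)) {
    write_tsv(de_genes$records, out("de_genes.tsv"))
    write_tsv(volcano_data(de_genes$records, config$thresholds, "gene_list"),
              out("volcano_genes.tsv"))
    deg_list <- apply_thresholds(de_genes$records, config$thresholds, "gene_list")
    deg_network <- apply_thresholds(de_genes$records, config$thresholds, "gene_network")
    write_tsv(deg_list, out("deg_list.tsv"))
    manifest$counts$deg_list <- nrow(deg_list)
    manifest$counts$deg_network <- nrow(deg_network)
  }
  if (!is.null(de_mirnas)) {
    write_tsv(de_mirnas$records, out("de_mirnas.tsv"))
    mir_sel <- apply_thresholds(de_mirnas$records, config$thresholds, "mirna")
    write_tsv(mir_sel, out("de_mirnas_selected.tsv"))
    manifest$counts$de_mirnas_up <- sum(mir_sel$direction == "up")
    manifest$counts$de_mirnas_down <- sum(mir_sel$direction == "down")
  }
  results$de_genes <- de_genes
  results$de_mirnas <- de_mirnas
  results$deg_list <- deg_list
  results$deg_network <- deg_network
  results$mir_sel <- mir_sel

  ## bipartite networks -----------------------------------------------------
  st <- run_stage(manifest, "bipartite", {
    if (is.null(mir_sel) || nrow(mir_sel) == 0) stopf("no selected miRNAs")
    nets <- build_bipartite(mir_sel, target_map)
    sel_up <- rank_and_select(nets$up, config$bipartite_multiplier)
    sel_down <- rank_and_select(nets$down, config$bipartite_multiplier)
    ccf <- cross_class_filter(nets$up, nets$down, config$bipartite_multiplier)
    write_bipartite(nets$up, out("bipartite_up"))
    write_bipartite(nets$down, out("bipartite_down"))
    list(nets = nets, sel_up = sel_up, sel_down = sel_down, ccf = ccf)
  })
  manifest <- st$manifest; bip <- st$value
  if (!is.null(bip)) {
    manifest$counts$bipartite_up <-
      c(mirnas = length(bip$nets$up$mirnas), genes = length(bip$nets$up$genes),
        edges = nrow(bip$nets$up$edges))
    manifest$counts$bipartite_down <-
      c(mirnas = length(bip$nets$down$mirnas),
        genes = length(bip$nets$down$genes),
        edges = nrow(bip$nets$down$edges))
    manifest$counts$up_specific_targets <- length(bip$ccf$up_specific)
    manifest$counts$down_specific_targets <- length(bip$ccf$down_specific)
  }
  results$bipartite <- bip

  ## interaction graphs, centralities, hubs, null models --------------------
  seed_sets <- list(
    deg = if (!is.null(deg_network)) deg_network$feature else character(0),
    up_targets = if (!is.null(bip)) bip$ccf$up_specific else character(0),
    down_targets = if (!is.null(bip)) bip$ccf$down_specific else character(0))
  results$networks <- list()
  for (nm in names(seed_sets)) {
    st <- run_stage(manifest, paste0("ppi_", nm), {
      if (length(seed_sets[[nm]]) < 2) stopf("seed set too small")
      g <- suppressWarnings(build_ppi(seed_sets[[nm]], ppi_edges,
                                      config$exp_min, config$db_min))
      if (igraph::ecount(g) == 0) stopf("empty graph after evidence filter")
      summ <- network_summary(g)
      tab <- centrality_table(g)
      hubs <- select_hubs(tab)
      write_graphml(g, out("ppi_", nm, ".graphml"))
      write_centrality(tab, out("centrality_", nm))
      write_tsv(as.data.frame(hubs), out("hubs_", nm, ".tsv"))
      nt <- null_test(g, config$null_config)
      write_tsv(null_long(nt), out("null_", nm, ".tsv"))
      list(graph = g, summary = summ, centrality = tab, hubs = hubs,
           null = nt)
    })
    manifest <- st$manifest
    if (!is.null(st$value)) {
      manifest$counts[[paste0("ppi_", nm)]] <-
        c(nodes = st$value$summary$n_nodes, edges = st$value$summary$n_edges,
          hubs = sum(st$value$hubs$hub))
      results$networks[[nm]] <- st$value
    }
  }

  ## integration ------------------------------------------------------------
  st <- run_stage(manifest, "integration", {
    if (is.null(bip) || is.null(deg_list) || nrow(deg_list) == 0)
      stopf("missing bipartite networks or DEG list")
    ks_up <- ks_target_contrast(deg_list, bip$nets$up, bip$nets$down, "up")
    ks_down <- tryCatch(
      ks_target_contrast(deg_list, bip$nets$up, bip$nets$down, "down"),
      error = function(e) NULL)
    write_tsv(ks_up$counts, out("ks_counts_up_degs.tsv"))
    list(ks_up = ks_up, ks_down = ks_down)
  })
  manifest <- st$manifest; results$integration <- st$value

  ## survival ---------------------------------------------------------------
  st <- run_stage(manifest, "survival", {
    if (is.null(surv) || is.null(mir_sel) || nrow(mir_sel) == 0)
      stopf("no survival data or no selected miRNAs")
    norm_mir <- median_of_ratios(mirna_counts)
    rows <- lapply(mir_sel$feature, function(m) {
      ms <- suppressWarnings(
        tryCatch(mirna_survival(m, mirna_counts, norm_mir, meta, surv,
                                config$survival_rule),
                 error = function(e) NULL))
      if (is.null(ms)) return(NULL)
      data.frame(mirna = m,
                 direction = mir_sel$direction[mir_sel$feature == m],
                 chisq = ms$logrank$chisq, p = ms$logrank$p,
                 n = ms$n_analyzed, stringsAsFactors = FALSE)
    })
    tab <- do.call(rbind, rows)
    if (is.null(tab)) stopf("no miRNA produced a valid stratification")
    tab <- tab[order(tab$p), ]
    write_tsv(tab, out("survival_logrank.tsv"))
    tab
  })
  manifest <- st$manifest; results$survival <- st$value

  manifest$results_dir <- normalizePath(config$outdir)
  class(manifest) <- "pipeline_manifest"
  manifest_out <- manifest
  manifest_out$stages <- lapply(manifest$stages, function(s) {
    s$seconds <- NULL  # timestamps excluded so manifests are comparable
    s
  })
  write_json(unclass(manifest_out), file.path(config$outdir, "manifest.json"))
  manifest$results <- results
  invisible(manifest)
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("Pipeline run manifest\n")
  cat(sprintf("  seed %d; outputs in %s\n", x$seed, x$results_dir))
  for (nm in names(x$stages))
    cat(sprintf("  %-18s %s%s\n", nm, x$stages[[nm]]$status,
                if (!is.null(x$stages[[nm]]$note))
                  paste0(" (", x$stages[[nm]]$note, ")") else ""))
  invisible(x)
}
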