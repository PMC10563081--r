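#' Configuration for the synthetic cohort generator
#'
#' Bundles every parameter of the synthetic-data module. Defaults emulate a
#' TCGA-style head and neck squamous cell carcinoma cohort: 523 tumor and 44
#' control libraries, stage proportions matching the clinical staging of that
#' cohort (stage IVb deliberately rare so the minimum-group-size exclusion
#' rule downstream is exercised), negative-binomial counts with a common
#' dispersion, log-normal library-size variation, a planted fold-change for a
#' fraction of features, a miRNA-target map in which down-regulated miRNAs
#' preferentially target up-regulated genes, a modular scale-free interaction network
#' with planted hub connectors, and exponential survival whose hazard
#' follows a designated prognostic miRNA.
#'
#' @param n_genes,n_mirnas Number of gene / miRNA features.
#' @param n_tumor,n_control Number of tumor / control samples.
#' @param stage_proportions Named vector over stages I, II, III, IVa, IVb
#'   summing to 1; tumor samples are assigned stages with these probabilities.
#' @param frac_de_genes,frac_de_mirnas Fraction of features carrying a
#'   planted fold change.
#' @param planted_log2fc Magnitude of the planted log2 fold change.
#' @param nb_dispersion Common negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param libsize_log_sd Standard deviation of log-normal per-sample size
#'   factors.
#' @param repression_enrichment Odds multiplier (>= 1) that a down-regulated
#'   miRNA targets an up-regulated gene.
#' @param target_base_prob Base probability that a given miRNA targets a
#'   given gene.
#' @param ba_attachment Edges added per new node in the preferential
#'   attachment interaction-network generator.
#' @param n_planted_hubs Number of nodes given an attachment boost.
#' @param hub_boost Attachment-weight multiplier for planted hubs.
#' @param hazard_log_hr Per-unit log-expression hazard ratio of the planted
#'   prognostic miRNA(s).
#' @param n_prognostic Number of prognostic miRNAs planted.
#' @param base_hazard Baseline exponential hazard (per day).
#' @param censor_max Upper bound of the uniform censoring time (days); the
#'   default gives roughly 30% censoring at the baseline hazard.
#' @param baseline_log_mean,baseline_log_sd Log-normal parameters of the
#'   per-feature baseline mean counts.
#' @param seed Integer master seed; all sub-generators derive their streams
#'   from it.
#' @return An object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 200, n_tumor = 30, n_control = 10, seed = 1)
#' cfg$stage_proportions
sim_config <- function(n_genes = 2000,
                       n_mirnas = 300,
                       n_tumor = 523,
                       n_control = 44,
                       stage_proportions = c(I = 21, II = 97, III = 106,
                                             IVa = 268, IVb = 10) / 502,
                       frac_de_genes = 0.1,
                       frac_de_mirnas = 0.2,
                       planted_log2fc = 2,
                       nb_dispersion = 0.2,
                       libsize_log_sd = 0.25,
                       repression_enrichment = 5,
                       target_base_prob = 0.02,
                       ba_attachment = 7,
                       n_planted_hubs = 10,
                       hub_boost = 10,
                       hazard_log_hr = 1,
                       n_prognostic = 1,
                       base_hazard = 1 / 1000,
                       censor_max = 3200,
                       baseline_log_mean = log(100),
                       baseline_log_sd = 1,
                       seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_mirnas = as.integer(n_mirnas),
              n_tumor = as.integer(n_tumor), n_control = as.integer(n_control),
              stage_proportions = stage_proportions,
              frac_de_genes = frac_de_genes, frac_de_mirnas = frac_de_mirnas,
              planted_log2fc = planted_log2fc, nb_dispersion = nb_dispersion,
              libsize_log_sd = libsize_log_sd,
              repression_enrichment = repression_enrichment,
              target_base_prob = target_base_prob,
              ba_attachment = as.integer(ba_attachment),
              n_planted_hubs = as.integer(n_planted_hubs),
              hub_boost = hub_boost, hazard_log_hr = hazard_log_hr,
              n_prognostic = as.integer(n_prognostic),
              base_hazard = base_hazard, censor_max = censor_max,
              baseline_log_mean = baseline_log_mean,
              baseline_log_sd = baseline_log_sd, seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stages <- c("I", "II", "III", "IVa", "IVb")
  if (cfg$n_genes <= 0 || cfg$n_mirnas <= 0 || cfg$n_tumor <= 0 ||
      cfg$n_control <= 0)
    stopf("configuration error: dimensions must be positive")
  if (!identical(sort(names(cfg$stage_proportions)), sort(stages)))
    stopf("stage_proportions must be named over %s",
          paste(stages, collapse = ", "))
  if (abs(sum(cfg$stage_proportions) - 1) > 1e-9)
    stopf("stage_proportions must sum to 1")
  if (cfg$frac_de_genes < 0 || cfg$frac_de_genes > 1 ||
      cfg$frac_de_mirnas < 0 || cfg$frac_de_mirnas > 1)
    stopf("DE fractions must lie in [0, 1]")
  if (cfg$planted_log2fc < 0) stopf("planted_log2fc must be >= 0")
  if (cfg$nb_dispersion < 0) stopf("nb_dispersion must be >= 0")
  if (cfg$libsize_log_sd < 0) stopf("libsize_log_sd must be >= 0")
  if (cfg$repression_enrichment < 1)
    stopf("repression_enrichment must be >= 1")
  if (cfg$target_base_prob <= 0 || cfg$target_base_prob >= 1)
    stopf("target_base_prob must lie in (0, 1)")
  if (cfg$ba_attachment < 1) stopf("ba_attachment must be >= 1")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  features: %d genes, %d miRNAs\n", x$n_genes, x$n_mirnas))
  cat(sprintf("  samples:  %d tumor + %d control\n", x$n_tumor, x$n_control))
  cat(sprintf("  planted:  %.0f%% DE genes, %.0f%% DE miRNAs at |log2FC| = %g\n",
              100 * x$frac_de_genes, 100 * x$frac_de_mirnas, x$planted_log2fc))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Deterministic sub-seeds so each generator has an independent stream.
sub_seed <- function(cfg, offset) (cfg$seed %% 1000000L) * 101L + offset

# Sample metadata shared by the gene and miRNA count generators: identical
# stage assignment for a given config/seed.
sim_sample_meta <- function(cfg) {
  set.seed(sub_seed(cfg, 1L))
  ids <- c(sprintf("tumor%03d", seq_len(cfg$n_tumor)),
           sprintf("control%03d", seq_len(cfg$n_control)))
  condition <- rep(c("tumor", "control"), c(cfg$n_tumor, cfg$n_control))
  stage <- rep(NA_character_, length(ids))
  stage[condition == "tumor"] <- sample(names(cfg$stage_proportions),
                                        cfg$n_tumor, replace = TRUE,
                                        prob = cfg$stage_proportions)
  data.frame(sample_id = ids, condition = condition, stage = stage,
             stringsAsFactors = FALSE)
}

#' Simulate a raw count matrix with planted differential expression
#'
#' Draws negative-binomial counts with mean
#' `baseline * sizefactor * 2^(log2FC * is_tumor)` and common dispersion.
#' Exactly `round(frac_de * n_features)` features carry a nonzero planted
#' log2 fold change, half positive and half negative (ties to positive).
#' Stage labels are assigned to tumor samples only, following
#' `stage_proportions`; gene and miRNA calls under the same config share the
#' identical sample metadata.
#'
#' @param config A [sim_config()].
#' @param feature_kind `"gene"` or `"mirna"`.
#' @return A list of class `sim_counts` with elements `counts`
#'   (features x samples integer matrix), `samples` (metadata data frame:
#'   sample_id, condition, stage) and `truth` (data frame of DE features
#'   with their signed planted log2FC).
#' @export
#' @examples
#' sim <- simulate_counts(sim_config(n_genes = 100, n_tumor = 20,
#'                                   n_control = 10, seed = 7))
#' dim(sim$counts)
simulate_counts <- function(config, feature_kind = c("gene", "mirna")) {
  feature_kind <- match.arg(feature_kind)
  validate_sim_config(config)
  meta <- sim_sample_meta(config)

  n_feat <- if (feature_kind == "gene") config$n_genes else config$n_mirnas
  frac <- if (feature_kind == "gene") config$frac_de_genes else config$frac_de_mirnas
  prefix <- if (feature_kind == "gene") "gene" else "mir"
  features <- sprintf("%s%04d", prefix, seq_len(n_feat))

  set.seed(sub_seed(config, if (feature_kind == "gene") 11L else 23L))
  n_de <- round(frac * n_feat)
  n_up <- ceiling(n_de / 2)
  de_idx <- if (n_de > 0) sample(n_feat, n_de) else integer(0)
  lfc <- numeric(n_feat)
  if (n_de > 0)
    lfc[de_idx] <- rep(c(1, -1), c(n_up, n_de - n_up)) * config$planted_log2fc

  baseline <- rlnorm(n_feat, config$baseline_log_mean, config$baseline_log_sd)
  n_samp <- nrow(meta)
  sf <- rlnorm(n_samp, 0, config$libsize_log_sd)
  is_tumor <- as.numeric(meta$condition == "tumor")

  mu <- outer(baseline, sf) * 2^(outer(lfc, is_tumor))
  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$nb_dispersion),
           nrow = n_feat)
  } else {
    matrix(stats::rpois(length(mu), lambda = mu), nrow = n_feat)
  }
  dimnames(counts) <- list(features, meta$sample_id)

  truth <- data.frame(feature = features[de_idx], log2fc = lfc[de_idx],
                      stringsAsFactors = FALSE)
  truth <- truth[order(truth$feature), , drop = FALSE]
  rownames(truth) <- NULL
  structure(list(counts = counts, samples = meta, truth = truth,
                 feature_kind = feature_kind, features = features),
            class = "sim_counts")
}

#' @export
print.sim_counts <- function(x, ...) {
  cat(sprintf("Simulated %s counts: %d features x %d samples (%d planted DE)\n",
              x$feature_kind, nrow(x$counts), ncol(x$counts), nrow(x$truth)))
  invisible(x)
}

#' Simulate a miRNA-to-target interaction map
#'
#' Each (miRNA, gene) pair becomes an edge with base probability
#' `target_base_prob`; for pairs where the miRNA carries a planted negative
#' fold change and the gene a planted positive one, the odds are multiplied
#' by `repression_enrichment`. This plants the repression signature the
#' downstream Kolmogorov-Smirnov contrast is designed to detect. Pairs are
#' unique by construction.
#'
#' @param config A [sim_config()].
#' @param gene_sim,mirna_sim Results of [simulate_counts()] for genes and
#'   miRNAs under the same config.
#' @return Data frame with columns `mirna_id`, `gene_id`, `source`.
#' @export
simulate_target_map <- function(config, gene_sim, mirna_sim) {
  validate_sim_config(config)
  genes <- gene_sim$features
  mirnas <- mirna_sim$features
  if (length(genes) == 0 || length(mirnas) == 0)
    stopf("empty feature universe")
  set.seed(sub_seed(config, 37L))

  up_gene <- genes %in% gene_sim$truth$feature[gene_sim$truth$log2fc > 0]
  down_mir <- mirnas %in% mirna_sim$truth$feature[mirna_sim$truth$log2fc < 0]

  p0 <- config$target_base_prob
  r <- config$repression_enrichment
  p_enriched <- r * p0 / (1 - p0 + r * p0)

  # probability matrix (miRNA x gene), enriched on down-miRNA/up-gene pairs
  p <- matrix(p0, nrow = length(mirnas), ncol = length(genes))
  p[down_mir, up_gene] <- p_enriched
  hit <- matrix(runif(length(p)) < p, nrow = length(mirnas))
  idx <- which(hit, arr.ind = TRUE)
  data.frame(mirna_id = mirnas[idx[, 1]], gene_id = genes[idx[, 2]],
             source = "simulated", stringsAsFactors = FALSE)
}

#' Simulate a modular scale-free interaction edge table with planted hubs
#'
#' Emulates the modular organization of protein interaction networks: the
#' gene universe is partitioned into a handful of modules, each grown as a
#' preferential-attachment (scale-free) graph with `ba_attachment` edges per
#' new node, joined by a thin baseline of random cross-module edges. Planted
#' hubs are then inserted as inter-module connectors: each receives
#' `hub_boost * ba_attachment` edges spread evenly across all modules, with
#' targets drawn degree-preferentially (so hubs attach to module cores —
#' the rich-club pattern of real interactomes). This makes the planted nodes
#' simultaneously high-degree, high-betweenness, high-centroid and
#' high-bridging, i.e. true composite hubs. Each edge receives independent
#' uniform evidence scores on \[0, 1\] for the "experimental" and "database"
#' channels.
#'
#' @param config A [sim_config()].
#' @param gene_ids Character vector of node identifiers (the gene universe).
#' @return A list of class `sim_ppi`: `edges` (data frame gene_a, gene_b,
#'   experimental_score, database_score) and `planted_hubs` (character).
#' @export
simulate_ppi <- function(config, gene_ids) {
  validate_sim_config(config)
  n <- length(gene_ids)
  if (n < 2) stopf("need at least two nodes")
  set.seed(sub_seed(config, 53L))

  order_ids <- sample(gene_ids)
  n_hubs <- min(config$n_planted_hubs, max(0L, n %/% 10L))
  hub_idx <- seq_len(n_hubs)
  rest <- setdiff(seq_len(n), hub_idx)
  n_mod <- max(1L, min(4L, length(rest) %/% 10L))
  module <- rep_len(seq_len(n_mod), length(rest))

  m <- config$ba_attachment
  deg <- integer(n)
  src <- integer(0); dst <- integer(0)
  add_edges <- function(v, tgt) {
    src <<- c(src, rep.int(v, length(tgt)))
    dst <<- c(dst, tgt)
    deg[v] <<- deg[v] + length(tgt)
    deg[tgt] <<- deg[tgt] + 1L
  }

  # scale-free growth within each module
  for (b in seq_len(n_mod)) {
    members <- rest[module == b]
    for (i in seq_along(members)[-1]) {
      prev <- members[seq_len(i - 1L)]
      k <- min(m, length(prev))
      tgt <- if (k == length(prev)) prev else
        sample(prev, k, prob = deg[prev] + 1)
      add_edges(members[i], tgt)
    }
  }
  # minimal cross-module baseline (a ring, so the graph is connected even
  # with no planted hubs)
  if (n_mod > 1) {
    for (b in seq_len(n_mod)) {
      b2 <- 1L + b %% n_mod
      a <- sample(rest[module == b], 1)
      z <- sample(rest[module == b2], 1)
      add_edges(a, z)
    }
  }
  # planted hubs: degree-preferential connectors across all modules
  for (h in hub_idx) {
    k_tot <- min(config$hub_boost * m, length(rest))
    per_mod <- diff(round(seq(0, k_tot, length.out = n_mod + 1)))
    for (b in seq_len(n_mod)) {
      members <- rest[module == b]
      k <- min(per_mod[b], length(members))
      if (k > 0) {
        tgt <- if (k == length(members)) members else
          sample(members, k, prob = deg[members] + 1)
        add_edges(h, tgt)
      }
    }
  }
  # de-duplicate (canonical orientation)
  a <- pmin(src, dst); b <- pmax(src, dst)
  keep <- !duplicated(paste(a, b)) & a != b
  a <- a[keep]; b <- b[keep]
  edges <- data.frame(gene_a = order_ids[a], gene_b = order_ids[b],
                      experimental_score = runif(length(a)),
                      database_score = runif(length(a)),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges,
                 planted_hubs = sort(order_ids[hub_idx]),
                 modules = setNames(module, order_ids[rest])),
            class = "sim_ppi")
}

#' Simulate survival outcomes driven by a prognostic miRNA
#'
#' Tumor samples receive exponential survival times with hazard
#' `base_hazard * exp(hazard_log_hr * z)`, where `z` is the standardized log
#' expression (library-size-normalized) of a designated prognostic miRNA,
#' plus independent uniform censoring on `[0, censor_max]`.
#'
#' @param config A [sim_config()].
#' @param mirna_sim Result of [simulate_counts()] for miRNAs.
#' @return Data frame (tumor samples only) with columns `sample_id`, `time`
#'   (days), `event` (0/1), and attribute `prognostic_mirnas` naming the
#'   planted miRNA(s) and hazard direction.
#' @export
simulate_survival <- function(config, mirna_sim) {
  validate_sim_config(config)
  set.seed(sub_seed(config, 71L))
  meta <- mirna_sim$samples
  tum <- meta$sample_id[meta$condition == "tumor"]
  counts <- mirna_sim$counts[, tum, drop = FALSE]

  # prefer an up-regulated planted miRNA as the prognostic one
  up <- mirna_sim$truth$feature[mirna_sim$truth$log2fc > 0]
  pool <- if (length(up) >= config$n_prognostic) up else mirna_sim$features
  prog <- sort(sample(pool, config$n_prognostic))

  cpm <- sweep(counts, 2, pmax(colSums(counts), 1), "/") * 1e6
  z <- log2(cpm[prog[1], ] + 1)
  z <- if (sd(z) > 0) (z - mean(z)) / sd(z) else z * 0

  rate <- config$base_hazard * exp(config$hazard_log_hr * z)
  t_event <- rexp(length(tum), rate = rate)
  t_cens <- runif(length(tum), 0, config$censor_max)
  out <- data.frame(sample_id = tum,
                    time = pmin(t_event, t_cens),
                    event = as.integer(t_event <= t_cens),
                    stringsAsFactors = FALSE)
  attr(out, "prognostic_mirnas") <-
    data.frame(mirna = prog,
               direction = ifelse(config$hazard_log_hr >= 0, "risk",
                                  "protective"),
               stringsAsFactors = FALSE)
  out
}

#' Simulate the complete input bundle for the pipeline
#'
#' Runs every sub-generator under one config: gene and miRNA counts (shared
#' sample metadata), the miRNA-target map, the interaction edge table, and
#' survival outcomes, returning them with the truth tables needed to score
#' recovery downstream.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_bundle` with elements `genes`, `mirnas`
#'   (sim_counts), `target_map`, `ppi` (sim_ppi), `survival`, and `config`.
#' @export
simulate_all <- function(config) {
  genes <- simulate_counts(config, "gene")
  mirnas <- simulate_counts(config, "mirna")
  target_map <- simulate_target_map(config, genes, mirnas)
  ppi <- simulate_ppi(config, genes$features)
  surv <- simulate_survival(config, mirnas)
  meta <- genes$samples
  meta <- merge(meta, surv, by = "sample_id", all.x = TRUE, sort = FALSE)
  meta <- meta[match(genes$samples$sample_id, meta$sample_id), ]
  rownames(meta) <- NULL
  structure(list(genes = genes, mirnas = mirnas, target_map = target_map,
                 ppi = ppi, survival = surv, samples = meta, config = config),
            class = "sim_bundle")
}

#' Write a simulated input bundle as plain-text tables
#'
#' Emits the five delimited tables the pipeline reads: gene and miRNA counts,
#' sample metadata (with survival columns), the target map, the interaction
#' edge table, and the truth tables, all regenerable from the config and
#' seed alone.
#'
#' @param bundle Result of [simulate_all()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_sim_inputs <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(gene_counts = file.path(dir, "gene_counts.tsv"),
             mirna_counts = file.path(dir, "mirna_counts.tsv"),
             samples = file.path(dir, "samples.tsv"),
             target_map = file.path(dir, "target_map.tsv"),
             ppi_edges = file.path(dir, "ppi_edges.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_counts(bundle$genes$counts, paths["gene_counts"])
  write_counts(bundle$mirnas$counts, paths["mirna_counts"])
  write_tsv(bundle$samples, paths["samples"])
  write_tsv(bundle$target_map, paths["target_map"])
  write_tsv(bundle$ppi$edges, paths["ppi_edges"])
  truth_block <- function(kind, id, value = rep(NA_real_, length(id))) {
    data.frame(kind = rep(kind, length(id)), id = id, value = value,
               stringsAsFactors = FALSE)
  }
  truth <- rbind(
    truth_block("de_gene", bundle$genes$truth$feature,
                bundle$genes$truth$log2fc),
    truth_block("de_mirna", bundle$mirnas$truth$feature,
                bundle$mirnas$truth$log2fc),
    truth_block("planted_hub", bundle$ppi$planted_hubs),
    truth_block("prognostic_mirna",
                attr(bundle$survival, "prognostic_mirnas")$mirna))
  write_tsv(truth, paths["truth"])
  invisible(paths)
}
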