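# Synthetic cohort generator: determinism, bookkeeping, planted structure.

small_cfg <- function(...) {
  args <- list(...)
  base <- list(n_genes = 300, n_mirnas = 60, n_tumor = 40, n_control = 40,
               seed = 1)
  do.call(sim_config, utils::modifyList(base, args))
}

test_that("regeneration with the same seed is byte-identical", {
  b1 <- simulate_all(small_cfg())
  b2 <- simulate_all(small_cfg())
  expect_identical(b1$genes$counts, b2$genes$counts)
  expect_identical(b1$target_map, b2$target_map)
  expect_identical(b1$ppi$edges, b2$ppi$edges)
  expect_identical(b1$survival, b2$survival)
  b3 <- simulate_all(small_cfg(seed = 2))
  expect_false(identical(b1$genes$counts, b3$genes$counts))
})

test_that("configuration validation rejects bad inputs", {
  expect_error(sim_config(n_genes = 0), "positive")
  expect_error(sim_config(stage_proportions = c(I = 0.5, II = 0.5, III = 0,
                                                IVa = 0, IVb = 0.1)),
               "sum to 1")
  expect_error(sim_config(repression_enrichment = 0.5), ">= 1")
})

test_that("planted DE bookkeeping is exact: half up, half down", {
  cfg <- sim_config(n_genes = 2000, frac_de_genes = 0.1, planted_log2fc = 2,
                    n_tumor = 10, n_control = 10, seed = 1)
  sim <- simulate_counts(cfg, "gene")
  expect_equal(nrow(sim$truth), 200)
  expect_equal(sum(sim$truth$log2fc > 0), 100)
  expect_equal(sum(sim$truth$log2fc < 0), 100)
  # ties to positive for an odd DE count
  cfg2 <- sim_config(n_genes = 30, frac_de_genes = 0.1, n_tumor = 5,
                     n_control = 5, seed = 1)
  tr <- simulate_counts(cfg2, "gene")$truth
  expect_equal(sum(tr$log2fc > 0), 2)
  expect_equal(sum(tr$log2fc < 0), 1)
})

test_that("counts are nonnegative integers and planted means scale as 2^lfc", {
  cfg <- small_cfg(frac_de_genes = 0.2, planted_log2fc = 2, libsize_log_sd = 0)
  sim <- simulate_counts(cfg, "gene")
  expect_true(all(sim$counts >= 0))
  expect_true(all(sim$counts == round(sim$counts)))
  tum <- sim$samples$sample_id[sim$samples$condition == "tumor"]
  ctl <- sim$samples$sample_id[sim$samples$condition == "control"]
  up <- sim$truth$feature[sim$truth$log2fc > 0]
  ratio <- rowMeans(sim$counts[up, tum]) / rowMeans(sim$counts[up, ctl])
  # Monte-Carlo check of the generating mean ratio 2^2 = 4 at n = 40 + 40
  expect_equal(mean(ratio), 4, tolerance = 0.15)
})

test_that("gene and miRNA runs share identical sample metadata", {
  cfg <- small_cfg()
  expect_identical(simulate_counts(cfg, "gene")$samples,
                   simulate_counts(cfg, "mirna")$samples)
  meta <- simulate_counts(cfg, "gene")$samples
  expect_true(all(!is.na(meta$stage[meta$condition == "tumor"])))
  expect_true(all(is.na(meta$stage[meta$condition == "control"])))
})

test_that("target map pairs are unique, reference real ids, and carry the enrichment", {
  cfg <- small_cfg(repression_enrichment = 5)
  gs <- simulate_counts(cfg, "gene")
  ms <- simulate_counts(cfg, "mirna")
  map <- simulate_target_map(cfg, gs, ms)
  expect_equal(anyDuplicated(map[c("mirna_id", "gene_id")]), 0)
  expect_true(all(map$gene_id %in% gs$features))
  expect_true(all(map$mirna_id %in% ms$features))
  # enriched cell: down-miRNA -> up-gene pairs denser than baseline
  up_g <- gs$truth$feature[gs$truth$log2fc > 0]
  down_m <- ms$truth$feature[ms$truth$log2fc < 0]
  enr <- map$mirna_id %in% down_m & map$gene_id %in% up_g
  p_enr <- sum(enr) / (length(up_g) * length(down_m))
  base <- map$mirna_id %in% setdiff(ms$features, down_m)
  p_base <- sum(base) / ((length(ms$features) - length(down_m)) * length(gs$features))
  expect_gt(p_enr / p_base, 2)
})

test_that("interaction edge table is simple with scores in [0, 1]", {
  cfg <- small_cfg()
  ppi <- simulate_ppi(cfg, sprintf("gene%04d", 1:300))
  e <- ppi$edges
  expect_true(all(e$gene_a != e$gene_b))
  key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
  expect_equal(anyDuplicated(key), 0)
  expect_true(all(e$experimental_score >= 0 & e$experimental_score <= 1))
  expect_true(all(e$database_score >= 0 & e$database_score <= 1))
  expect_length(ppi$planted_hubs, cfg$n_planted_hubs)
})

test_that("planted hubs are top-decile by degree across seeds", {
  hits <- sapply(1:10, function(s) {
    cfg <- sim_config(n_genes = 300, seed = s)
    ids <- sprintf("g%03d", 1:300)
    ppi <- simulate_ppi(cfg, ids)
    g <- igraph::graph_from_data_frame(ppi$edges[1:2], directed = FALSE)
    deg <- igraph::degree(g)
    mean(deg[ppi$planted_hubs] >= quantile(deg, 0.9))
  })
  expect_gte(mean(hits), 0.95)
})

test_that("survival times are positive with 0/1 events and planted hazard", {
  cfg <- small_cfg(n_tumor = 200, hazard_log_hr = 1)
  ms <- simulate_counts(cfg, "mirna")
  sv <- simulate_survival(cfg, ms)
  expect_true(all(sv$time > 0))
  expect_true(all(sv$event %in% c(0, 1)))
  expect_equal(nrow(sv), 200)
  prog <- attr(sv, "prognostic_mirnas")
  expect_equal(nrow(prog), 1)
  expect_true(prog$mirna %in% ms$features)
  # censoring fraction is moderate under the defaults
  expect_gt(mean(sv$event), 0.4)
})

test_that("written input bundle round-trips through the readers", {
  dir <- tempfile("simio")
  b <- simulate_all(small_cfg())
  paths <- write_sim_inputs(b, dir)
  expect_identical(read_counts(paths["gene_counts"]), b$genes$counts * 1)
  meta <- read_sample_metadata(paths["samples"])
  expect_equal(meta$sample_id, b$samples$sample_id)
  map <- read_target_map(paths["target_map"])
  expect_equal(nrow(map), nrow(b$target_map))
  edges <- read_ppi_edges(paths["ppi_edges"])
  expect_equal(nrow(edges), nrow(b$ppi$edges))
  unlink(dir, recursive = TRUE)
})
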