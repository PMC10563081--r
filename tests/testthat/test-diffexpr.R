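# Normalization, NB Wald test, stage ANOVA and threshold filters.

toy_counts <- function(vals, nf, ns, fnames = NULL, snames = NULL) {
  matrix(vals, nf, ns,
         dimnames = list(fnames %||% sprintf("f%02d", seq_len(nf)),
                         snames %||% sprintf("s%02d", seq_len(ns))))
}

test_that("median-of-ratios reproduces the hand-computed example", {
  m <- toy_counts(c(2, 8, 4, 16), 2, 2)
  # geometric means (2.83, 11.31); ratios per column constant -> s = (1/sqrt(2), sqrt(2))
  s <- median_of_ratios(m)$size_factors
  expect_equal(unname(s), c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
})

test_that("median-of-ratios is symmetric and scale-equivariant", {
  m <- toy_counts(rep(c(5, 9, 2, 14), 3), 4, 3)
  expect_equal(unname(median_of_ratios(m)$size_factors), rep(1, 3))
  m2 <- cbind(m, 2 * m[, 1])
  colnames(m2)[4] <- "s04"
  s <- median_of_ratios(m2)$size_factors
  expect_equal(unname(s["s04"] / s["s01"]), 2)
  # invariant to per-feature scaling shared by all samples
  m3 <- m2 * c(1, 10, 100, 3)
  expect_equal(median_of_ratios(m3)$size_factors,
               median_of_ratios(m2)$size_factors)
})

test_that("median-of-ratios agrees with the standard DE-package estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(9)
  # all-positive rows, odd row count, so the median feature is unique and
  # the arithmetic- and log-scale medians coincide exactly
  m <- matrix(rnbinom(201 * 8, mu = 50, size = 5) + 1, 201,
              dimnames = list(sprintf("g%03d", 1:201), sprintf("s%d", 1:8)))
  expect_equal(unname(median_of_ratios(m)$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-12)
})

test_that("normalization errors without an all-positive feature", {
  m <- toy_counts(c(0, 1, 1, 0), 2, 2)
  expect_error(median_of_ratios(m), "geometric mean")
})

test_that("a feature with identical group means is a null feature", {
  set.seed(1)
  m <- toy_counts(rep(20, 40), 2, 20)
  m[2, ] <- rep(c(10, 30), 10)  # same mean both groups by construction
  norm <- list(size_factors = rep(1, 20), normalized = m)
  r <- nb_wald_test(m, norm, colnames(m)[1:10], colnames(m)[11:20])
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$p[1], 1)
})

test_that("BH adjustment matches a brute-force step-up implementation", {
  for (s in 1:10) {
    set.seed(s)
    p <- runif(sample(5:100, 1))^2
    expect_equal(p.adjust(p, "BH"), oracle_bh(p))
  }
})

test_that("planted effects are recovered and the null is calibrated", {
  # one seed here; the acceptance suite runs the multi-seed calibration
  cfg <- sim_config(n_genes = 800, n_tumor = 40, n_control = 40,
                    frac_de_genes = 0.1, planted_log2fc = 2, seed = 77)
  sim <- simulate_counts(cfg, "gene")
  de <- de_analysis(sim$counts, sim$samples, de_thresholds(stage_min_n = 1e9))
  sel <- apply_thresholds(de$records, de_thresholds(), "gene_list")
  tp <- sum(sel$feature %in% sim$truth$feature)
  expect_gte(tp / nrow(sim$truth), 0.9)
  expect_lte((nrow(sel) - tp) / max(nrow(sel), 1), 0.05)
  # direction labels follow the planted sign
  up_true <- sim$truth$feature[sim$truth$log2fc > 0]
  expect_true(all(sel$direction[sel$feature %in% up_true] == "up"))
})

test_that("stage ANOVA drops small stages and reduces to t-test for 2 groups", {
  cfg <- sim_config(n_genes = 60, n_tumor = 80, n_control = 10,
                    stage_proportions = c(I = 0.45, II = 0.45, III = 0,
                                          IVa = 0, IVb = 0.1),
                    frac_de_genes = 0, seed = 5)
  sim <- simulate_counts(cfg, "gene")
  # force a stage IVb group of exactly 10 (below the 15 cutoff)
  meta <- sim$samples
  tum <- which(meta$condition == "tumor")
  meta$stage[tum] <- rep(c("I", "II", "IVb"), c(40, 30, 10))
  norm <- median_of_ratios(sim$counts)
  an <- stage_anova(sim$counts, norm, meta, stage_min_n = 15)
  expect_setequal(attr(an, "stages_used"), c("I", "II"))

  # two retained groups: F = t^2, so p equals the equal-variance t-test p
  ids <- meta$sample_id[meta$condition == "tumor" & meta$stage %in% c("I", "II")]
  x <- log2(norm$normalized[1, ids] + 1)
  g <- factor(meta$stage[match(ids, meta$sample_id)])
  expect_equal(an$anova_p[1], t.test(x ~ g, var.equal = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("threshold filters apply the exact stated rules", {
  rec <- data.frame(
    feature = sprintf("f%d", 1:6),
    log2fc = c(1, 1.2, -1.2, 0.4, 5, -0.1),
    fc = c(2, 2.3, -2.3, 1.32, 32, -1.07),
    p = c(1e-8, 0.2, 1e-9, 1e-6, 2e-6, 1e-7),
    adjp = c(0.005, 0.011, 0.002, 0.009, 0.02, 0.005))
  th <- de_thresholds()
  # gene_list: adjP <= 0.01 & |FC| >= 1.5 -> f1, f3
  expect_setequal(apply_thresholds(rec, th, "gene_list")$feature,
                  c("f1", "f3"))
  # adjP = 0.011 excluded by the strict <= 0.01 rule
  expect_false("f2" %in% apply_thresholds(rec, th, "gene_list")$feature)
  # gene_network: |FC| >= 2 as well
  expect_setequal(apply_thresholds(rec, th, "gene_network")$feature,
                  c("f1", "f3"))
  # mirna volcano: |FC| >= 2 & raw p <= 1e-5 -> f1, f3, f5
  sel <- apply_thresholds(rec, th, "mirna")
  expect_setequal(sel$feature, c("f1", "f3", "f5"))
  expect_equal(sel$direction[sel$feature == "f3"], "down")
  # empty input -> empty selection
  expect_equal(nrow(apply_thresholds(rec[0, ], th, "gene_list")), 0)
})
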