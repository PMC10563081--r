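# Bipartite miRNA-target networks: construction, degree selection rules and
# the cross-class filter.

test_that("construction bookkeeping and the bipartite handshake hold", {
  de <- data.frame(feature = c("mir-a", "mir-b", "mir-c"),
                   direction = c("up", "up", "down"))
  map <- data.frame(mirna_id = c("mir-a", "mir-a", "mir-b", "mir-b", "mir-c"),
                    gene_id = c("g1", "g2", "g3", "g4", "g1"))
  nets <- build_bipartite(de, map)
  expect_length(nets$up$mirnas, 2)
  expect_length(nets$up$genes, 4)
  expect_equal(nrow(nets$up$edges), 4)
  # g1 targeted by both classes appears in both networks
  expect_true("g1" %in% nets$up$genes && "g1" %in% nets$down$genes)
  # handshake: sum of out-degrees = sum of in-degrees = |E|
  for (net in nets) {
    expect_equal(sum(net$out_degree), nrow(net$edges))
    expect_equal(sum(net$in_degree), nrow(net$edges))
  }
})

test_that("miRNA ids are matched across naming styles", {
  de <- data.frame(feature = "hsa-miR-99a", direction = "up")
  map <- data.frame(mirna_id = "MIR-99A", gene_id = "TP53")
  nets <- build_bipartite(de, map)
  expect_equal(nrow(nets$up$edges), 1)
})

test_that("isolated miRNAs are retained with degree zero", {
  de <- data.frame(feature = c("mir-a", "mir-x"), direction = "up")
  map <- data.frame(mirna_id = "mir-a", gene_id = "g1")
  nets <- build_bipartite(de, map)
  expect_equal(unname(nets$up$out_degree["mir-x"]), 0)
})

test_that("degree selection uses strict > for miRNAs, >= multiplier for genes", {
  # uniform out-degrees: nothing strictly above average
  de <- data.frame(feature = c("m1", "m2"), direction = "up")
  map <- data.frame(mirna_id = c("m1", "m2"), gene_id = c("g1", "g2"))
  sel <- rank_and_select(build_bipartite(de, map)$up)
  expect_length(sel$selected_mirnas, 0)

  # in-degrees (1,1,1,5): average 2, multiplier 2 -> only the degree-5 gene
  de2 <- data.frame(feature = sprintf("m%d", 1:5), direction = "up")
  map2 <- data.frame(
    mirna_id = c("m1", "m2", "m3", sprintf("m%d", 1:5)),
    gene_id = c("g1", "g2", "g3", rep("g4", 5)))
  sel2 <- rank_and_select(build_bipartite(de2, map2)$up)
  expect_equal(sel2$avg_in, 2)
  expect_equal(sel2$selected_genes, "g4")
})

test_that("cross-class filter reproduces the printed threshold behavior", {
  # with average in-degrees 4 (up) and 5 (down), multiplier 2: the rule is
  # up-degree >= 8 & down-degree < 5, or up-degree < 4 & down-degree >= 10
  fake_net <- function(in_deg, cls) {
    structure(list(mirnas = character(0), genes = names(in_deg),
                   edges = data.frame(), out_degree = numeric(0),
                   in_degree = in_deg, class = cls),
              class = "bipartite_net")
  }
  up <- fake_net(c(gA = 8, gB = 3, gC = 8, gD = 2, gE = 1, gF = 2), "up")
  down <- fake_net(c(gA = 4, gB = 10, gC = 10, gD = 2, gE = 8, gF = 6), "down")
  ccf <- cross_class_filter(up, down, 2, avg_up = 4, avg_down = 5)
  expect_equal(ccf$up_specific, "gA")     # 8 >= 8 and 4 < 5
  expect_equal(ccf$down_specific, "gB")   # 3 < 4 and 10 >= 10
  expect_false("gC" %in% c(ccf$up_specific, ccf$down_specific))  # high both
  expect_true(length(intersect(ccf$up_specific, ccf$down_specific)) == 0)
})

test_that("cross-class filter hand fixture partitions 12 genes exactly", {
  up_deg <- c(a = 9, b = 8, c = 7, d = 4, e = 0, f = 3, g = 12, h = 2,
              i = 8, j = 1, k = 0, l = 5)
  down_deg <- c(a = 2, b = 5, c = 1, d = 12, e = 10, f = 11, g = 11, h = 3,
                i = 4, j = 0, k = 9, l = 4)
  up <- structure(list(genes = names(up_deg)[up_deg > 0],
                       in_degree = up_deg[up_deg > 0]),
                  class = "bipartite_net")
  down <- structure(list(genes = names(down_deg)[down_deg > 0],
                         in_degree = down_deg[down_deg > 0]),
                    class = "bipartite_net")
  ccf <- cross_class_filter(up, down, 2, avg_up = 4, avg_down = 5)
  # hand enumeration: up-specific needs up >= 8 & down < 5 -> a, i
  #   (b has down 5, g has down 11, both fail)
  expect_setequal(ccf$up_specific, c("a", "i"))
  # down-specific needs up < 4 & down >= 10 -> e, f
  #   (d has up 4, k has down 9: fail)
  expect_setequal(ccf$down_specific, c("e", "f"))
})

test_that("selection is deterministic and invariant to relabeling", {
  set.seed(4)
  cfg <- sim_config(n_genes = 150, n_mirnas = 40, n_tumor = 20,
                    n_control = 10, seed = 4)
  gs <- simulate_counts(cfg, "gene")
  ms <- simulate_counts(cfg, "mirna")
  map <- simulate_target_map(cfg, gs, ms)
  de <- data.frame(feature = ms$truth$feature,
                   direction = ifelse(ms$truth$log2fc > 0, "up", "down"))
  nets1 <- build_bipartite(de, map)
  nets2 <- build_bipartite(de, map)
  expect_identical(nets1, nets2)
  # node and edge counts equal a direct recount of the filtered input pairs
  up_m <- normalize_mirna_ids(de$feature[de$direction == "up"])
  pairs_up <- map[normalize_mirna_ids(map$mirna_id) %in% up_m, ]
  expect_equal(nrow(nets1$up$edges), nrow(unique(pairs_up)))
  expect_equal(length(nets1$up$genes), length(unique(pairs_up$gene_id)))
})
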