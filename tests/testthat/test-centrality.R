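# Closed-form and oracle checks for the centrality suite.

star4 <- function() {
  named_graph(cbind(rep("c", 3), c("l1", "l2", "l3")))
}

test_that("star and path closed forms hold for the path centralities", {
  g <- star4()
  btw <- betweenness_centrality(g)
  expect_equal(unname(btw["c"]), 3)  # (n-1)(n-2)/2 for n = 4
  expect_equal(unname(btw[c("l1", "l2", "l3")]), c(0, 0, 0))
  # stress equals betweenness on trees (all geodesics unique)
  expect_equal(stress_centrality(g), btw)

  p4 <- named_graph(cbind(c("a", "b", "c"), c("b", "c", "d")))
  expect_equal(unname(betweenness_centrality(p4)), c(0, 2, 2, 0))

  # C4: two geodesics between opposite corners
  c4 <- named_graph(cbind(c("a", "b", "c", "d"), c("b", "c", "d", "a")))
  sp <- shortest_path_stats(c4)
  expect_equal(sp$sigma["a", "c"], 2)
  expect_equal(sp$dist["a", "c"], 2)
})

test_that("distance centralities match hand values on stars and cliques", {
  g <- star4()
  cl <- closeness_centrality(g)
  expect_equal(unname(cl["c"]), 1 / 3)
  expect_equal(unname(cl["l1"]), 1 / 5)
  ec <- eccentricity_centrality(g)
  expect_equal(unname(ec["c"]), 1)
  expect_equal(unname(ec["l1"]), 1 / 2)

  kn <- igraph::make_full_graph(6)
  igraph::V(kn)$name <- letters[1:6]
  expect_equal(unname(closeness_centrality(kn)), rep(1 / 5, 6))
  expect_equal(unname(eccentricity_centrality(kn)), rep(1, 6))
  expect_equal(unname(radiality_centrality(kn)), rep(1, 6))
})

test_that("centroid gives +2/-2 on the star and is constant on K_n and C_n", {
  cen <- centroid_centrality(star4())
  expect_equal(unname(cen["c"]), 2)
  expect_equal(unname(cen[c("l1", "l2", "l3")]), rep(-2, 3))

  kn <- igraph::make_full_graph(5)
  igraph::V(kn)$name <- letters[1:5]
  expect_length(unique(centroid_centrality(kn)), 1)
  cn <- named_graph(cbind(letters[1:5], letters[c(2:5, 1)]))
  expect_length(unique(round(centroid_centrality(cn), 9)), 1)
})

test_that("eigenvector centrality matches symmetry closed forms", {
  kn <- igraph::make_full_graph(4)
  igraph::V(kn)$name <- letters[1:4]
  expect_equal(unname(eigenvector_centrality(kn)), rep(1 / 2, 4),
               tolerance = 1e-10)
  ev <- eigenvector_centrality(star4())
  expect_equal(unname(ev["c"] / ev["l1"]), sqrt(3), tolerance = 1e-9)
})

test_that("bridging centrality matches hand computations", {
  p3 <- named_graph(cbind(c("a", "b"), c("b", "c")))
  br <- bridging_centrality(p3)
  expect_equal(unname(br["b"]), 0.25)  # BC = (1/2)/2, betweenness 1
  expect_equal(unname(br[c("a", "c")]), c(0, 0))
  br4 <- bridging_centrality(star4())
  expect_equal(unname(br4["c"]), 1 / 3)  # 3 * (1/3)/3
})

test_that("all centralities match brute-force oracles on random graphs", {
  for (s in 1:12) {
    g <- random_connected_graph(n = sample(6:18, 1), p = 0.25, seed = 200 + s)
    tab <- centrality_table(g)
    o <- oracle_path_centralities(g)
    expect_equal(setNames(tab$betweenness, tab$node), o$betweenness,
                 tolerance = 1e-9)
    expect_equal(setNames(tab$stress, tab$node), o$stress, tolerance = 1e-9)
    eb <- attr(tab, "edge_betweenness")
    key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
    m <- match(key(eb), key(o$edge_betweenness))
    expect_equal(eb$edge_betweenness, o$edge_betweenness$value[m],
                 tolerance = 1e-9)
    oc <- oracle_distance_centralities(g)
    expect_equal(setNames(tab$closeness, tab$node), oc$closeness)
    expect_equal(setNames(tab$eccentricity, tab$node), oc$eccentricity)
    expect_equal(setNames(tab$radiality, tab$node), oc$radiality)
    expect_equal(attr(tab, "diameter"), oc$diameter)
    expect_equal(attr(tab, "average_distance"), oc$average_distance)
    expect_equal(setNames(tab$centroid, tab$node), oracle_centroid(g))
    expect_equal(setNames(tab$eigenvector, tab$node), oracle_eigenvector(g),
                 tolerance = 1e-9)
    expect_equal(setNames(tab$bridging, tab$node), oracle_bridging(g),
                 tolerance = 1e-9)
  }
})

test_that("geodesic counts match exhaustive enumeration", {
  for (s in 1:5) {
    g <- random_connected_graph(n = 12, p = 0.3, seed = 300 + s)
    sp <- shortest_path_stats(g)
    o <- oracle_path_centralities(g)
    expect_equal(unname(sp$sigma), unname(o$sigma))
    expect_true(all(sp$dist == o$dist))
  }
})

test_that("centralities are equivariant under node relabeling", {
  g <- random_connected_graph(n = 12, p = 0.3, seed = 42)
  tab <- centrality_table(g)
  perm <- setNames(sprintf("z%02d", sample(12)), igraph::V(g)$name)
  g2 <- igraph::set_vertex_attr(g, "name",
                                value = unname(perm[igraph::V(g)$name]))
  tab2 <- centrality_table(g2)
  m <- match(unname(perm[tab$node]), tab2$node)
  for (col in c("degree", "betweenness", "stress", "closeness", "centroid",
                "eigenvector", "bridging")) {
    expect_equal(tab2[[col]][m], tab[[col]], tolerance = 1e-12, info = col)
  }
})

test_that("node-averaged radiality equals diameter + 1 - average distance", {
  for (s in 1:10) {
    g <- random_connected_graph(n = sample(8:20, 1), p = 0.3, seed = 400 + s)
    tab <- centrality_table(g)
    expect_equal(mean(tab$radiality),
                 attr(tab, "diameter") + 1 - attr(tab, "average_distance"),
                 tolerance = 1e-9)
  }
})

test_that("betweenness sums are consistent with pair-level path accounting", {
  g <- random_connected_graph(n = 14, p = 0.3, seed = 7)
  o <- oracle_path_centralities(g)
  # sum of node betweenness = sum over pairs of mean interior-vertex count
  D <- o$dist
  pair_sum <- sum(D[upper.tri(D)] - 1)  # each geodesic has d-1 interior nodes
  expect_equal(sum(o$betweenness), pair_sum)
  expect_equal(sum(setNames(betweenness_centrality(g), NULL)), pair_sum)
})
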