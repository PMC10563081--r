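# Brute-force oracles for the centrality suite, kept deliberately independent
# of the package's BFS/Brandes implementation: Floyd-Warshall distances,
# exhaustive geodesic enumeration by DFS, a cubic centroid loop, and a dense
# eigendecomposition.

random_connected_graph <- function(n, p = 0.2, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && igraph::ecount(g) >= 1) break
    p <- min(1, p * 1.25)
  }
  igraph::set_vertex_attr(g, "name", value = sprintf("n%03d", seq_len(n)))
}

named_graph <- function(el) {
  igraph::graph_from_edgelist(el, directed = FALSE)
}

oracle_arrays <- function(g) {
  nodes <- sort(igraph::V(g)$name)
  el <- igraph::as_edgelist(g)
  m <- cbind(match(el[, 1], nodes), match(el[, 2], nodes))
  adj <- rep(list(integer(0)), length(nodes))
  for (k in seq_len(nrow(m))) {
    adj[[m[k, 1]]] <- c(adj[[m[k, 1]]], m[k, 2])
    adj[[m[k, 2]]] <- c(adj[[m[k, 2]]], m[k, 1])
  }
  list(nodes = nodes, adj = adj,
       edges = cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
}

# Floyd-Warshall all-pairs distances
oracle_distances <- function(arr) {
  n <- length(arr$nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (k in seq_len(nrow(arr$edges))) {
    D[arr$edges[k, 1], arr$edges[k, 2]] <- 1
    D[arr$edges[k, 2], arr$edges[k, 1]] <- 1
  }
  for (k in seq_len(n)) for (i in seq_len(n)) {
    nd <- D[i, k] + D[k, ]
    upd <- nd < D[i, ]
    D[i, upd] <- nd[upd]
  }
  D
}

# every shortest path from s to t, as a list of vertex index vectors
all_geodesics <- function(arr, D, s, t) {
  if (s == t) return(list(s))
  out <- list()
  for (u in arr$adj[[s]]) {
    if (D[u, t] == D[s, t] - 1) {
      out <- c(out, lapply(all_geodesics(arr, D, u, t),
                           function(p) c(s, p)))
    }
  }
  out
}

# betweenness, stress, edge betweenness and geodesic counts by exhaustive
# enumeration over unordered pairs
oracle_path_centralities <- function(g) {
  arr <- oracle_arrays(g)
  D <- oracle_distances(arr)
  n <- length(arr$nodes)
  btw <- setNames(numeric(n), arr$nodes)
  stress <- btw
  sigma <- matrix(0, n, n)
  diag(sigma) <- 1
  ekey <- paste(arr$edges[, 1], arr$edges[, 2])
  eb <- setNames(numeric(nrow(arr$edges)), ekey)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- all_geodesics(arr, D, s, t)
    np <- length(paths)
    sigma[s, t] <- sigma[t, s] <- np
    for (p in paths) {
      inner <- p[-c(1, length(p))]
      stress[inner] <- stress[inner] + 1
      btw[inner] <- btw[inner] + 1 / np
      for (i in seq_len(length(p) - 1)) {
        k <- paste(min(p[i], p[i + 1]), max(p[i], p[i + 1]))
        eb[k] <- eb[k] + 1 / np
      }
    }
  }
  list(nodes = arr$nodes, dist = D, sigma = sigma, betweenness = btw,
       stress = stress,
       edge_betweenness = data.frame(from = arr$nodes[arr$edges[, 1]],
                                     to = arr$nodes[arr$edges[, 2]],
                                     value = unname(eb)))
}

# cubic triple loop, straight from the definition
oracle_centroid <- function(g) {
  arr <- oracle_arrays(g)
  D <- oracle_distances(arr)
  n <- length(arr$nodes)
  out <- setNames(numeric(n), arr$nodes)
  for (v in seq_len(n)) {
    best <- Inf
    for (w in seq_len(n)) {
      if (w == v) next
      f <- 0
      for (u in seq_len(n)) {
        if (u == v || u == w) next
        if (D[u, v] < D[u, w]) f <- f + 1
        if (D[u, w] < D[u, v]) f <- f - 1
      }
      if (f < best) best <- f
    }
    out[v] <- best
  }
  out
}

oracle_distance_centralities <- function(g) {
  arr <- oracle_arrays(g)
  D <- oracle_distances(arr)
  n <- length(arr$nodes)
  delta <- max(D)
  list(closeness = setNames(1 / rowSums(D), arr$nodes),
       eccentricity = setNames(1 / apply(D, 1, max), arr$nodes),
       radiality = setNames((rowSums(delta + 1 - D) - (delta + 1)) / (n - 1),
                            arr$nodes),
       diameter = delta,
       average_distance = mean(D[upper.tri(D)]))
}

# dense eigensolver oracle for eigenvector centrality
oracle_eigenvector <- function(g) {
  arr <- oracle_arrays(g)
  n <- length(arr$nodes)
  A <- matrix(0, n, n)
  for (k in seq_len(nrow(arr$edges))) {
    A[arr$edges[k, 1], arr$edges[k, 2]] <- 1
    A[arr$edges[k, 2], arr$edges[k, 1]] <- 1
  }
  e <- eigen(A, symmetric = TRUE)
  v <- abs(e$vectors[, which.max(e$values)])
  setNames(v / sqrt(sum(v^2)), arr$nodes)
}

oracle_bridging <- function(g) {
  arr <- oracle_arrays(g)
  n <- length(arr$nodes)
  deg <- vapply(arr$adj, length, 0L)
  bc <- vapply(seq_len(n), function(v)
    (1 / deg[v]) / sum(1 / deg[arr$adj[[v]]]), 0)
  oracle_path_centralities(g)$betweenness * bc
}

# brute-force two-sample KS statistic: sup over pooled points of the ECDF gap
oracle_ks_D <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(t) mean(x <= t) - mean(y <= t), 0)))
}

# brute-force Benjamini-Hochberg step-up adjustment
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(ord)]
}

# hand log-rank: O/E/V accumulated over distinct event times
oracle_logrank <- function(time, event, group) {
  group <- as.integer(factor(group))
  ts <- sort(unique(time[event == 1]))
  O1 <- E1 <- V <- 0
  for (t in ts) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == 1)
    O1 <- O1 + d1
    E1 <- E1 + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- (O1 - E1)^2 / V
  list(chisq = chisq, p = pchisq(chisq, 1, lower.tail = FALSE))
}
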