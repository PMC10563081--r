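#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <unordered_set>
using namespace Rcpp;

// Shared substrate for the path-based centralities: breadth-first search from
// every node with Brandes-style dependency accumulation. Graphs are simple,
// undirected and unweighted; edges arrive as a 0-based m x 2 matrix.

static std::vector<std::vector<int> > build_adj(int n, const IntegerMatrix& edges) {
  std::vector<std::vector<int> > adj(n);
  for (int e = 0; e < edges.nrow(); ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    adj[a].push_back(b);
    adj[b].push_back(a);
  }
  return adj;
}

// Distances, geodesic counts, node betweenness and edge betweenness in one
// pass. Unordered-pair convention: ordered accumulations are halved at the
// end. Unreachable pairs carry distance -1 and sigma 0.
// [[Rcpp::export]]
List brandes_cpp(int n, IntegerMatrix edges) {
  int m = edges.nrow();
  std::vector<std::vector<int> > adj = build_adj(n, edges);

  // edge id lookup for edge betweenness
  std::unordered_map<long long, int> eid;
  eid.reserve(m * 2);
  for (int e = 0; e < m; ++e) {
    int a = edges(e, 0), b = edges(e, 1);
    long long key = (long long)std::min(a, b) * n + std::max(a, b);
    eid[key] = e;
  }

  IntegerMatrix dist(n, n);
  NumericMatrix sigma(n, n);
  std::fill(dist.begin(), dist.end(), -1);
  NumericVector btw(n), ebtw(m);

  std::vector<int> stack(n), d(n);
  std::vector<double> sig(n), delta(n);
  std::vector<std::vector<int> > pred(n);

  for (int s = 0; s < n; ++s) {
    std::fill(d.begin(), d.end(), -1);
    std::fill(sig.begin(), sig.end(), 0.0);
    std::fill(delta.begin(), delta.end(), 0.0);
    for (int i = 0; i < n; ++i) pred[i].clear();
    int top = 0;
    std::queue<int> q;
    d[s] = 0; sig[s] = 1.0; q.push(s);
    while (!q.empty()) {
      int v = q.front(); q.pop();
      stack[top++] = v;
      for (size_t k = 0; k < adj[v].size(); ++k) {
        int w = adj[v][k];
        if (d[w] < 0) { d[w] = d[v] + 1; q.push(w); }
        if (d[w] == d[v] + 1) { sig[w] += sig[v]; pred[w].push_back(v); }
      }
    }
    for (int i = 0; i < n; ++i) { dist(s, i) = d[i]; sigma(s, i) = sig[i]; }
    // dependency accumulation in reverse BFS order
    for (int i = top - 1; i > 0; --i) {
      int w = stack[i];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int v = pred[w][k];
        double c = sig[v] / sig[w] * (1.0 + delta[w]);
        delta[v] += c;
        long long key = (long long)std::min(v, w) * n + std::max(v, w);
        ebtw[eid[key]] += c;
      }
      if (w != s) btw[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) btw[i] /= 2.0;
  for (int e = 0; e < m; ++e) ebtw[e] /= 2.0;
  return List::create(_["dist"] = dist, _["sigma"] = sigma,
                      _["betweenness"] = btw, _["edge_betweenness"] = ebtw);
}

// stress(v) = number of geodesics through v, summed over unordered pairs
// {s,t} with s,t != v: sigma_sv * sigma_vt when d(s,v)+d(v,t)=d(s,t).
// [[Rcpp::export]]
NumericVector stress_cpp(IntegerMatrix dist, NumericMatrix sigma) {
  int n = dist.nrow();
  NumericVector stress(n);
  for (int s = 0; s < n; ++s)
    for (int t = s + 1; t < n; ++t) {
      if (dist(s, t) < 0) continue;
      for (int v = 0; v < n; ++v) {
        if (v == s || v == t) continue;
        if (dist(s, v) >= 0 && dist(v, t) >= 0 &&
            dist(s, v) + dist(v, t) == dist(s, t))
          stress[v] += sigma(s, v) * sigma(v, t);
      }
    }
  return stress;
}

// centroid(v) = min over w != v of f(v,w), with f(v,w) = gamma_v(w) -
// gamma_w(v) and gamma_v(w) = #{u not in {v,w} : d(u,v) < d(u,w)}.
// Tie distances contribute to neither side.
// [[Rcpp::export]]
NumericVector centroid_cpp(IntegerMatrix dist) {
  int n = dist.nrow();
  NumericVector cen(n);
  for (int v = 0; v < n; ++v) {
    double best = R_PosInf;
    for (int w = 0; w < n; ++w) {
      if (w == v) continue;
      int f = 0;
      for (int u = 0; u < n; ++u) {
        if (u == v || u == w) continue;
        if (dist(u, v) < dist(u, w)) ++f;
        else if (dist(u, w) < dist(u, v)) --f;
      }
      if (f < best) best = f;
    }
    cen[v] = best;
  }
  return cen;
}

// Degree-preserving randomization by double edge swaps: pick two edges
// (a,b),(c,d), rewire to (a,d),(c,b) unless that creates a self-loop or a
// duplicate. Runs until n_swaps successes or max_tries attempts. Uses R's
// RNG so results follow set.seed().
// [[Rcpp::export]]
List double_edge_swap_cpp(IntegerMatrix edges, int n, int n_swaps,
                          double max_tries) {
  int m = edges.nrow();
  IntegerMatrix out = clone(edges);
  std::unordered_set<long long> eset;
  eset.reserve(m * 2);
  for (int e = 0; e < m; ++e) {
    int a = out(e, 0), b = out(e, 1);
    eset.insert((long long)std::min(a, b) * n + std::max(a, b));
  }
  int done = 0;
  double tries = 0;
  while (done < n_swaps && tries < max_tries) {
    ++tries;
    int i = (int)(unif_rand() * m), j = (int)(unif_rand() * m);
    if (i == j) continue;
    int a = out(i, 0), b = out(i, 1);
    int c = out(j, 0), d = out(j, 1);
    if (unif_rand() < 0.5) std::swap(c, d);
    if (a == d || c == b) continue;
    long long k1 = (long long)std::min(a, d) * n + std::max(a, d);
    long long k2 = (long long)std::min(c, b) * n + std::max(c, b);
    if (eset.count(k1) || eset.count(k2)) continue;
    long long o1 = (long long)std::min(a, b) * n + std::max(a, b);
    long long o2 = (long long)std::min(c, d) * n + std::max(c, d);
    eset.erase(o1); eset.erase(o2);
    eset.insert(k1); eset.insert(k2);
    out(i, 0) = a; out(i, 1) = d;
    out(j, 0) = c; out(j, 1) = b;
    ++done;
  }
  return List::create(_["edges"] = out, _["swaps"] = done,
                      _["tries"] = tries);
}
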