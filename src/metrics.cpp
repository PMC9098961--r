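#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <utility>
using namespace Rcpp;

// Adjacency-list view of a 0/1 symmetric matrix.
static std::vector<std::vector<int> > build_adj(const IntegerMatrix& a) {
  int n = a.nrow();
  std::vector<std::vector<int> > nb(n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j)
      if (i != j && a(i, j) != 0) nb[i].push_back(j);
  return nb;
}

// All-pairs BFS hop distances; unreachable pairs are +Inf.
// [[Rcpp::export]]
NumericMatrix cpp_bfs_distances(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int> > nb = build_adj(adj);
  NumericMatrix d(n, n);
  std::fill(d.begin(), d.end(), R_PosInf);
  std::vector<int> q(n), dist(n);
  for (int s = 0; s < n; ++s) {
    std::fill(dist.begin(), dist.end(), -1);
    int head = 0, tail = 0;
    q[tail++] = s;
    dist[s] = 0;
    while (head < tail) {
      int u = q[head++];
      for (size_t k = 0; k < nb[u].size(); ++k) {
        int v = nb[u][k];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
      }
    }
    for (int v = 0; v < n; ++v)
      if (dist[v] >= 0) d(s, v) = dist[v];
  }
  return d;
}

// Exact unnormalized betweenness (Brandes); undirected, so halved at the end.
// [[Rcpp::export]]
NumericVector cpp_betweenness(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int> > nb = build_adj(adj);
  NumericVector bc(n);
  std::vector<int> dist(n), stack_(n), q(n);
  std::vector<double> sigma(n), delta(n);
  std::vector<std::vector<int> > pred(n);
  for (int s = 0; s < n; ++s) {
    for (int i = 0; i < n; ++i) {
      dist[i] = -1; sigma[i] = 0.0; delta[i] = 0.0; pred[i].clear();
    }
    int head = 0, tail = 0, sp = 0;
    dist[s] = 0; sigma[s] = 1.0; q[tail++] = s;
    while (head < tail) {
      int u = q[head++];
      stack_[sp++] = u;
      for (size_t k = 0; k < nb[u].size(); ++k) {
        int v = nb[u][k];
        if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
        if (dist[v] == dist[u] + 1) { sigma[v] += sigma[u]; pred[v].push_back(u); }
      }
    }
    while (sp > 0) {
      int w = stack_[--sp];
      for (size_t k = 0; k < pred[w].size(); ++k) {
        int u = pred[w][k];
        delta[u] += sigma[u] / sigma[w] * (1.0 + delta[w]);
      }
      if (w != s) bc[w] += delta[w];
    }
  }
  for (int i = 0; i < n; ++i) bc[i] /= 2.0;
  return bc;
}

// Nodal local efficiency: global efficiency of the neighbour-induced
// subgraph (the node itself excluded); degree < 2 gives 0.
// [[Rcpp::export]]
NumericVector cpp_local_efficiency(const IntegerMatrix& adj) {
  int n = adj.nrow();
  std::vector<std::vector<int> > nb = build_adj(adj);
  NumericVector eloc(n);
  std::vector<int> idx(n, -1);
  for (int i = 0; i < n; ++i) {
    int k = (int) nb[i].size();
    if (k < 2) { eloc[i] = 0.0; continue; }
    for (int a = 0; a < k; ++a) idx[nb[i][a]] = a;
    std::vector<std::vector<int> > sub(k);
    for (int a = 0; a < k; ++a) {
      int u = nb[i][a];
      for (size_t t = 0; t < nb[u].size(); ++t) {
        int v = nb[u][t];
        if (idx[v] >= 0) sub[a].push_back(idx[v]);
      }
    }
    double tot = 0.0;
    std::vector<int> dist(k), q(k);
    for (int s = 0; s < k; ++s) {
      std::fill(dist.begin(), dist.end(), -1);
      int head = 0, tail = 0;
      dist[s] = 0; q[tail++] = s;
      while (head < tail) {
        int u = q[head++];
        for (size_t t = 0; t < sub[u].size(); ++t) {
          int v = sub[u][t];
          if (dist[v] < 0) { dist[v] = dist[u] + 1; q[tail++] = v; }
        }
      }
      for (int t = 0; t < k; ++t)
        if (t != s && dist[t] > 0) tot += 1.0 / dist[t];
    }
    eloc[i] = tot / (double) (k * (double) (k - 1));
    for (int a = 0; a < k; ++a) idx[nb[i][a]] = -1;
  }
  return eloc;
}

// Degree-preserving Maslov-Sneppen double-edge swaps. `attempts` proposals
// are drawn from R's RNG; swaps creating self-loops or multi-edges are
// rejected. Returns the rewired adjacency and the realized swap count.
// [[Rcpp::export]]
List cpp_rewire(const IntegerMatrix& adj, int attempts) {
  int n = adj.nrow();
  IntegerMatrix a = clone(adj);
  std::vector<std::pair<int, int> > edges;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (a(i, j) != 0) edges.push_back(std::make_pair(i, j));
  int m = (int) edges.size();
  int success = 0;
  if (m >= 2) {
    for (int t = 0; t < attempts; ++t) {
      int e1 = (int) (unif_rand() * m);
      int e2 = (int) (unif_rand() * m);
      if (e1 >= m) e1 = m - 1;
      if (e2 >= m) e2 = m - 1;
      if (e1 == e2) continue;
      int a1 = edges[e1].first, b1 = edges[e1].second;
      int a2 = edges[e2].first, b2 = edges[e2].second;
      if (unif_rand() < 0.5) std::swap(a2, b2);
      if (a1 == a2 || a1 == b2 || b1 == a2 || b1 == b2) continue;
      if (a(a1, b2) != 0 || a(a2, b1) != 0) continue;
      a(a1, b1) = a(b1, a1) = 0;
      a(a2, b2) = a(b2, a2) = 0;
      a(a1, b2) = a(b2, a1) = 1;
      a(a2, b1) = a(b1, a2) = 1;
      edges[e1] = std::make_pair(std::min(a1, b2), std::max(a1, b2));
      edges[e2] = std::make_pair(std::min(a2, b1), std::max(a2, b1));
      ++success;
    }
  }
  return List::create(_["adjacency"] = a, _["n_swaps"] = success);
}
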