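#include <Rcpp.h>
#include <algorithm>
#include <map>
#include <random>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

// Weighted undirected graph; self-loops (from aggregation) stored separately.
struct Graph {
  int n;
  std::vector<std::vector<std::pair<int, double> > > adj;
  std::vector<double> selfw;  // self-loop weight, counted once
  std::vector<double> deg;    // weighted degree, self-loops count twice
  double W;                   // total weight, each edge once
};

static Graph make_graph(const std::vector<int>& u, const std::vector<int>& v,
                        const std::vector<double>& w, int n) {
  Graph g;
  g.n = n;
  g.adj.assign(n, std::vector<std::pair<int, double> >());
  g.selfw.assign(n, 0.0);
  g.deg.assign(n, 0.0);
  g.W = 0.0;
  for (size_t e = 0; e < u.size(); ++e) {
    if (u[e] == v[e]) {
      g.selfw[u[e]] += w[e];
      g.deg[u[e]] += 2.0 * w[e];
    } else {
      g.adj[u[e]].push_back(std::make_pair(v[e], w[e]));
      g.adj[v[e]].push_back(std::make_pair(u[e], w[e]));
      g.deg[u[e]] += w[e];
      g.deg[v[e]] += w[e];
    }
    g.W += w[e];
  }
  return g;
}

static double modularity_of(const Graph& g, const std::vector<int>& comm) {
  std::vector<double> in(g.n, 0.0), tot(g.n, 0.0);
  for (int i = 0; i < g.n; ++i) {
    tot[comm[i]] += g.deg[i];
    in[comm[i]] += g.selfw[i];
  }
  for (int i = 0; i < g.n; ++i)
    for (size_t a = 0; a < g.adj[i].size(); ++a) {
      int j = g.adj[i][a].first;
      if (j > i && comm[j] == comm[i]) in[comm[i]] += g.adj[i][a].second;
    }
  double q = 0.0;
  for (int c = 0; c < g.n; ++c)
    if (tot[c] > 0.0) {
      double frac = tot[c] / (2.0 * g.W);
      q += in[c] / g.W - frac * frac;
    }
  return q;
}

// Phase 1: local moving. Sweep order shuffled by rng; ties in gain go to the
// lowest community id. Returns the (non-dense) community labels.
static void one_level(const Graph& g, std::vector<int>& comm, std::mt19937& rng) {
  comm.assign(g.n, 0);
  std::vector<double> tot(g.n, 0.0);
  for (int i = 0; i < g.n; ++i) {
    comm[i] = i;
    tot[i] = g.deg[i];
  }
  const double twoW = 2.0 * g.W;
  const double eps = 1e-12;
  std::vector<int> order(g.n);
  for (int i = 0; i < g.n; ++i) order[i] = i;
  std::vector<double> w2c(g.n, 0.0);
  std::vector<char> seen(g.n, 0);
  std::vector<int> touched;
  bool moved = true;
  while (moved) {
    moved = false;
    std::shuffle(order.begin(), order.end(), rng);
    for (int oi = 0; oi < g.n; ++oi) {
      int i = order[oi];
      touched.clear();
      for (size_t a = 0; a < g.adj[i].size(); ++a) {
        int c = comm[g.adj[i][a].first];
        if (!seen[c]) {
          seen[c] = 1;
          touched.push_back(c);
        }
        w2c[c] += g.adj[i][a].second;
      }
      int old_c = comm[i];
      if (!seen[old_c]) {
        seen[old_c] = 1;
        touched.push_back(old_c);
      }
      tot[old_c] -= g.deg[i];
      std::sort(touched.begin(), touched.end());
      int best = old_c;
      double bestgain = w2c[old_c] - g.deg[i] * tot[old_c] / twoW;
      for (size_t a = 0; a < touched.size(); ++a) {
        int c = touched[a];
        double gain = w2c[c] - g.deg[i] * tot[c] / twoW;
        if (gain > bestgain + eps || (gain > bestgain - eps && c < best)) {
          best = c;
          bestgain = gain;
        }
      }
      if (best != old_c) moved = true;
      comm[i] = best;
      tot[best] += g.deg[i];
      for (size_t a = 0; a < touched.size(); ++a) {
        w2c[touched[a]] = 0.0;
        seen[touched[a]] = 0;
      }
    }
  }
}

// Dense renumbering in order of first appearance by node index.
static int densify(std::vector<int>& comm) {
  std::vector<int> map(comm.size(), -1);
  int next = 0;
  for (size_t i = 0; i < comm.size(); ++i) {
    if (map[comm[i]] < 0) map[comm[i]] = next++;
    comm[i] = map[comm[i]];
  }
  return next;
}

// [[Rcpp::export]]
IntegerVector cpp_louvain(IntegerVector ei, IntegerVector ej, NumericVector ew,
                          int n_nodes, int seed, double tol) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::vector<int> u(ei.begin(), ei.end()), v(ej.begin(), ej.end());
  std::vector<double> w(ew.begin(), ew.end());
  Graph g = make_graph(u, v, w, n_nodes);
  if (g.W <= 0.0) stop("graph has no edges");

  std::vector<int> node2comm(n_nodes);  // original node -> current coarse node
  for (int i = 0; i < n_nodes; ++i) node2comm[i] = i;

  std::vector<int> single(g.n);
  for (int i = 0; i < g.n; ++i) single[i] = i;
  double q_cur = modularity_of(g, single);

  while (true) {
    std::vector<int> comm;
    one_level(g, comm, rng);
    double q_new = modularity_of(g, comm);
    int ncomm = densify(comm);
    for (int i = 0; i < n_nodes; ++i) node2comm[i] = comm[node2comm[i]];
    if (q_new - q_cur < tol || ncomm == g.n) break;
    q_cur = q_new;
    // Phase 2: aggregate communities into nodes.
    std::vector<int> nu, nv;
    std::vector<double> nw;
    std::vector<std::vector<double> > acc;  // dense accumulate per pair
    // collect edges via map on pair key
    std::vector<double> selfacc(ncomm, 0.0);
    std::map<std::pair<int, int>, double> em;
    for (int i = 0; i < g.n; ++i) {
      if (g.selfw[i] > 0.0) selfacc[comm[i]] += g.selfw[i];
      for (size_t a = 0; a < g.adj[i].size(); ++a) {
        int j = g.adj[i][a].first;
        if (j < i) continue;  // each edge once
        int ci = comm[i], cj = comm[j];
        if (ci == cj)
          selfacc[ci] += g.adj[i][a].second;
        else {
          std::pair<int, int> key(std::min(ci, cj), std::max(ci, cj));
          em[key] += g.adj[i][a].second;
        }
      }
    }
    for (int c = 0; c < ncomm; ++c)
      if (selfacc[c] > 0.0) {
        nu.push_back(c);
        nv.push_back(c);
        nw.push_back(selfacc[c]);
      }
    for (std::map<std::pair<int, int>, double>::iterator it = em.begin();
         it != em.end(); ++it) {
      nu.push_back(it->first.first);
      nv.push_back(it->first.second);
      nw.push_back(it->second);
    }
    g = make_graph(nu, nv, nw, ncomm);
  }
  return IntegerVector(node2comm.begin(), node2comm.end());
}

// Degree-preserving double-edge swaps. Each attempt picks two distinct edges
// (a,b),(c,d), randomizes the orientation of the second, and proposes
// (a,d),(c,b); rejected if it would create a self-loop or duplicate edge.
// [[Rcpp::export]]
List cpp_edge_swap(IntegerVector ei, IntegerVector ej, int n_nodes,
                   int n_swaps, int seed) {
  std::mt19937 rng(static_cast<unsigned int>(seed));
  int m = ei.size();
  std::vector<int> a(ei.begin(), ei.end()), b(ej.begin(), ej.end());
  std::unordered_set<long long> have;
  const long long N = n_nodes;
  for (int e = 0; e < m; ++e) {
    long long x = a[e], y = b[e];
    have.insert(std::min(x, y) * N + std::max(x, y));
  }
  if (m >= 2) {
    for (int s = 0; s < n_swaps; ++s) {
      int e1 = static_cast<int>(rng() % m);
      int e2 = static_cast<int>(rng() % m);
      if (e1 == e2) continue;
      int x1 = a[e1], y1 = b[e1], x2 = a[e2], y2 = b[e2];
      if (rng() & 1u) std::swap(x2, y2);
      if (x1 == y2 || x2 == y1) continue;
      long long k1 = std::min((long long)x1, (long long)y2) * N +
                     std::max((long long)x1, (long long)y2);
      long long k2 = std::min((long long)x2, (long long)y1) * N +
                     std::max((long long)x2, (long long)y1);
      if (k1 == k2 || have.count(k1) || have.count(k2)) continue;
      long long o1 = std::min((long long)x1, (long long)y1) * N +
                     std::max((long long)x1, (long long)y1);
      long long o2 = std::min((long long)x2, (long long)y2) * N +
                     std::max((long long)x2, (long long)y2);
      have.erase(o1);
      have.erase(o2);
      have.insert(k1);
      have.insert(k2);
      a[e1] = x1; b[e1] = y2;
      a[e2] = x2; b[e2] = y1;
    }
  }
  return List::create(_["a"] = IntegerVector(a.begin(), a.end()),
                      _["b"] = IntegerVector(b.begin(), b.end()));
}
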