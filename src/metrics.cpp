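#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Relative tolerance for shortest-path ties (weights are continuous; exact
// ties occur mainly on unit-weight graphs, where sums are exact anyway).
static inline bool close_to(double a, double b) {
  if (!R_finite(a) || !R_finite(b)) return false;
  return std::fabs(a - b) <= 1e-9 * std::max(1.0, std::fabs(b));
}

// O(k^2) Dijkstra from `src` on edge lengths 1/W (W > 0), with counts of
// tied shortest paths accumulated in `cnt`.
static void dijkstra_counts(const NumericMatrix& W, int src,
                            std::vector<double>& d, std::vector<double>& cnt) {
  const int k = W.nrow();
  std::vector<bool> done(k, false);
  std::fill(d.begin(), d.end(), R_PosInf);
  std::fill(cnt.begin(), cnt.end(), 0.0);
  d[src] = 0.0;
  cnt[src] = 1.0;
  for (int it = 0; it < k; ++it) {
    int u = -1;
    double best = R_PosInf;
    for (int v = 0; v < k; ++v)
      if (!done[v] && d[v] < best) { best = d[v]; u = v; }
    if (u < 0) break;
    done[u] = true;
    for (int v = 0; v < k; ++v) {
      if (done[v] || W(u, v) <= 0.0) continue;
      double nd = d[u] + 1.0 / W(u, v);
      if (nd < d[v] && !close_to(nd, d[v])) {
        d[v] = nd;
        cnt[v] = cnt[u];
      } else if (close_to(nd, d[v])) {
        cnt[v] += cnt[u];
      }
    }
  }
}

// [[Rcpp::export(name = ".dist_counts_cpp")]]
List dist_counts_cpp(NumericMatrix W) {
  const int k = W.nrow();
  NumericMatrix D(k, k), C(k, k);
  std::vector<double> d(k), cnt(k);
  for (int s = 0; s < k; ++s) {
    dijkstra_counts(W, s, d, cnt);
    for (int v = 0; v < k; ++v) { D(s, v) = d[v]; C(s, v) = cnt[v]; }
  }
  return List::create(_["d"] = D, _["n_paths"] = C);
}

// Edge betweenness as raw shortest-path counts: eb(u,v) = number of
// shortest directed paths, over all ordered source-target pairs and
// including all ties, that traverse edge (u,v).
// [[Rcpp::export(name = ".edge_betweenness_cpp")]]
NumericMatrix edge_betweenness_cpp(NumericMatrix W, NumericMatrix D,
                                   NumericMatrix C) {
  const int k = W.nrow();
  NumericMatrix EB(k, k);
  for (int u = 0; u < k; ++u) {
    for (int v = 0; v < k; ++v) {
      if (u == v || W(u, v) <= 0.0) continue;
      const double len = 1.0 / W(u, v);
      double total = 0.0;
      for (int s = 0; s < k; ++s) {
        const double dsu = D(s, u);
        if (!R_finite(dsu)) continue;
        const double csu = C(s, u);
        for (int t = 0; t < k; ++t) {
          if (t == s) continue;
          const double dvt = D(v, t);
          if (!R_finite(dvt)) continue;
          if (close_to(dsu + len + dvt, D(s, t)))
            total += csu * C(v, t);
        }
      }
      EB(u, v) = total;
    }
  }
  return EB;
}

// Directed weighted clustering (Fagiolo): cube-root weights, triangle
// intensity t_i = 0.5 * sum_{j!=h, both != i} of the products of the three
// symmetrized cube-rooted couplings; normalized by the number of possible
// directed triangles dtot_i*(dtot_i-1) - 2*dbi_i.
// [[Rcpp::export(name = ".clustering_cpp")]]
List clustering_cpp(NumericMatrix W) {
  const int k = W.nrow();
  NumericMatrix Wc(k, k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      Wc(i, j) = std::cbrt(W(i, j));
  NumericVector cc(k), ti(k), denom(k);
  for (int i = 0; i < k; ++i) {
    double dtot = 0.0, dbi = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      dtot += (W(i, j) > 0.0) + (W(j, i) > 0.0);
      dbi += (W(i, j) > 0.0) && (W(j, i) > 0.0);
    }
    double t = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      for (int h = 0; h < k; ++h) {
        if (h == i || h == j) continue;
        t += (Wc(i, j) + Wc(j, i)) * (Wc(i, h) + Wc(h, i)) *
             (Wc(j, h) + Wc(h, j));
      }
    }
    ti[i] = 0.5 * t;
    denom[i] = dtot * (dtot - 1.0) - 2.0 * dbi;
    cc[i] = denom[i] > 0.0 ? ti[i] / denom[i] : 0.0;
  }
  double sd = 0.0, st = 0.0;
  for (int i = 0; i < k; ++i) { sd += denom[i]; st += ti[i]; }
  double trans = (k < 3 || sd <= 0.0) ? NA_REAL : st / sd;
  return List::create(_["cc"] = cc, _["transitivity"] = trans);
}

static double global_eff_from_D(const NumericMatrix& D) {
  const int k = D.nrow();
  if (k < 2) return 0.0;
  double s = 0.0;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j && R_finite(D(i, j)) && D(i, j) > 0.0)
        s += 1.0 / D(i, j);
  return s / (double(k) * (k - 1));
}

// [[Rcpp::export(name = ".global_efficiency_cpp")]]
double global_efficiency_cpp(NumericMatrix D) {
  return global_eff_from_D(D);
}

// Local efficiency: global efficiency of each node's neighborhood
// subgraph (union of in- and out-neighbors, node itself excluded).
// [[Rcpp::export(name = ".local_efficiency_cpp")]]
NumericVector local_efficiency_cpp(NumericMatrix W) {
  const int k = W.nrow();
  NumericVector eff(k);
  for (int i = 0; i < k; ++i) {
    std::vector<int> nb;
    for (int j = 0; j < k; ++j)
      if (j != i && (W(i, j) > 0.0 || W(j, i) > 0.0)) nb.push_back(j);
    const int m = nb.size();
    if (m < 2) { eff[i] = 0.0; continue; }
    NumericMatrix S(m, m);
    for (int a = 0; a < m; ++a)
      for (int b = 0; b < m; ++b)
        S(a, b) = W(nb[a], nb[b]);
    NumericMatrix D(m, m);
    std::vector<double> d(m), cnt(m);
    for (int s = 0; s < m; ++s) {
      dijkstra_counts(S, s, d, cnt);
      for (int v = 0; v < m; ++v) D(s, v) = d[v];
    }
    eff[i] = global_eff_from_D(D);
  }
  return eff;
}
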