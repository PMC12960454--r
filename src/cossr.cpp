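#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Nearest-neighbour distance and index (1-based) for every point. O(n^2),
// no n x n matrix is materialised.
// [[Rcpp::export]]
List cpp_nn(NumericVector x, NumericVector y) {
  int n = x.size();
  NumericVector nnd(n);
  IntegerVector nni(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    int bi = -1;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j];
      double d2 = dx * dx + dy * dy;
      if (d2 < best) { best = d2; bi = j; }
    }
    nnd[i] = std::sqrt(best);
    nni[i] = bi + 1;
  }
  return List::create(_["dist"] = nnd, _["index"] = nni);
}

// All ordered pairs (i, j), i != j, with distance <= r. Returns both
// directions so bearing histograms see each displacement twice (once per
// orientation). Columns: i, j (1-based), dx, dy.
// [[Rcpp::export]]
NumericMatrix cpp_pairs_within(NumericVector x, NumericVector y, double r) {
  int n = x.size();
  double r2 = r * r;
  std::vector<double> out;
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[j] - x[i], dy = y[j] - y[i];
      if (dx * dx + dy * dy <= r2) {
        out.push_back(i + 1); out.push_back(j + 1);
        out.push_back(dx); out.push_back(dy);
      }
    }
  }
  int m = out.size() / 4;
  NumericMatrix res(m, 4);
  for (int k = 0; k < m; ++k)
    for (int c = 0; c < 4; ++c) res(k, c) = out[4 * k + c];
  colnames(res) = CharacterVector::create("i", "j", "dx", "dy");
  return res;
}

// Row p holds the 1-based indices of all wells ordered by Euclidean distance
// to well p (p itself first); ties broken by ascending well index. group_end
// marks sorted positions that close a tie group: squared distances within
// eps2 of each other belong to one group (on an exact lattice a group is a
// distance shell). The dtm accumulation only tests the mass threshold at
// group ends, which makes the result invariant under well relabeling and
// rigid motions even in the presence of ties.
// [[Rcpp::export]]
List cpp_distance_order(NumericVector x, NumericVector y, double eps2) {
  int n = x.size();
  IntegerMatrix ord(n, n);
  LogicalMatrix grp(n, n);
  std::vector<int> idx(n);
  std::vector<double> d2(n);
  for (int p = 0; p < n; ++p) {
    for (int j = 0; j < n; ++j) {
      double dx = x[p] - x[j], dy = y[p] - y[j];
      d2[j] = dx * dx + dy * dy;
      idx[j] = j;
    }
    std::stable_sort(idx.begin(), idx.end(),
                     [&](int a, int b) {
                       if (d2[a] != d2[b]) return d2[a] < d2[b];
                       return a < b;
                     });
    for (int j = 0; j < n; ++j) {
      ord(p, j) = idx[j] + 1;
      grp(p, j) = (j == n - 1) || (d2[idx[j + 1]] - d2[idx[j]] > eps2);
    }
  }
  return List::create(_["order"] = ord, _["group_end"] = grp);
}

// Weighted distance-to-measure over all wells for a matrix of features.
// ord: n x n distance ordering (1-based, from cpp_distance_order);
// W: nf x n nonnegative weights, every row summing to 1;
// cumd2: cumulative sums of squared idealized network distances d_i^2;
// m: mass fraction in (0, 1).
// For each well p, weights are accumulated in actual-distance order until
// they first reach m (tolerance 1e-12 against float accumulation), giving k;
// dtm = cumd2[k] / k uses the idealized lattice distances, not the data.
// Wells at equal distance from p (a tie group; a whole shell on an exact
// lattice) are accumulated in ascending weight order, a symmetric function
// of the group, so k is invariant under well relabeling and rigid motions;
// whenever no tie group straddles the mass threshold this reduces to the
// plain sequential rule.
// [[Rcpp::export]]
NumericMatrix cpp_dtm_matrix(IntegerMatrix ord, LogicalMatrix grp,
                             NumericMatrix W, NumericVector cumd2, double m) {
  int n = ord.nrow(), nf = W.nrow();
  if (W.ncol() != n) stop("weight matrix width does not match well count");
  if (cumd2.size() < n) stop("cumd2 shorter than well count");
  NumericMatrix out(nf, n);
  const double tol = 1e-12;
  std::vector<double> gw;
  for (int f = 0; f < nf; ++f) {
    for (int p = 0; p < n; ++p) {
      double acc = 0.0;
      int k = n;
      int i = 0;
      while (i < n) {
        int e = i;                       // find end of the tie group
        while (!grp(p, e)) ++e;
        double gsum = 0.0;
        for (int t = i; t <= e; ++t) gsum += W(f, ord(p, t) - 1);
        if (acc + gsum >= m - tol) {
          if (e == i) {
            k = i + 1;
          } else {
            gw.clear();
            for (int t = i; t <= e; ++t) gw.push_back(W(f, ord(p, t) - 1));
            std::sort(gw.begin(), gw.end());
            int cnt = 0;
            for (size_t t = 0; t < gw.size(); ++t) {
              acc += gw[t];
              ++cnt;
              if (acc >= m - tol) break;
            }
            k = i + cnt;
          }
          break;
        }
        acc += gsum;
        i = e + 1;
      }
      out(f, p) = cumd2[k - 1] / k;
    }
  }
  return out;
}

static int uf_find(std::vector<int>& parent, int v) {
  while (parent[v] != v) {
    parent[v] = parent[parent[v]];
    v = parent[v];
  }
  return v;
}

// 0-dimensional persistence of the upper star filtration by a union-find
// sweep in decreasing filtration order (vertices before edges at equal
// index). Elder rule: at a merge the component with the lower birth dies at
// the edge index; birth ties are broken by the smaller creating-vertex index
// surviving. With kill = true every surviving component receives
// death = global minimum vertex value; with kill = false survivors are
// dropped. Returns a (birth, death) matrix.
// [[Rcpp::export]]
NumericMatrix cpp_persistence(NumericVector z, IntegerVector ei,
                              IntegerVector ej, bool kill) {
  int n = z.size();
  if (n == 0) return NumericMatrix(0, 2);
  int ne = ei.size();
  // adjacency lists
  std::vector<int> deg(n, 0);
  for (int e = 0; e < ne; ++e) { deg[ei[e] - 1]++; deg[ej[e] - 1]++; }
  std::vector<int> start(n + 1, 0);
  for (int i = 0; i < n; ++i) start[i + 1] = start[i] + deg[i];
  std::vector<int> adj(2 * ne);
  std::vector<int> fill(start.begin(), start.end() - 1);
  for (int e = 0; e < ne; ++e) {
    int a = ei[e] - 1, b = ej[e] - 1;
    adj[fill[a]++] = b;
    adj[fill[b]++] = a;
  }
  // vertices in decreasing z, ties by ascending index (stable sort keeps it)
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  std::stable_sort(order.begin(), order.end(),
                   [&](int a, int b) { return z[a] > z[b]; });
  std::vector<int> parent(n), creator(n);
  std::vector<double> birth(n);
  std::vector<bool> added(n, false);
  std::vector<double> bars_b, bars_d;
  double zmin = z[0];
  for (int i = 1; i < n; ++i) if (z[i] < zmin) zmin = z[i];
  for (int oi = 0; oi < n; ++oi) {
    int v = order[oi];
    parent[v] = v; birth[v] = z[v]; creator[v] = v; added[v] = true;
    for (int t = start[v]; t < start[v + 1]; ++t) {
      int u = adj[t];
      if (!added[u]) continue;
      int ru = uf_find(parent, u), rv = uf_find(parent, v);
      if (ru == rv) continue;
      int winner, loser;
      if (birth[ru] > birth[rv]) { winner = ru; loser = rv; }
      else if (birth[ru] < birth[rv]) { winner = rv; loser = ru; }
      else if (creator[ru] < creator[rv]) { winner = ru; loser = rv; }
      else { winner = rv; loser = ru; }
      // a component paired at its own birth index never was a homology
      // class; only strictly positive-lifetime merge bars are emitted
      if (birth[loser] > z[v]) {
        bars_b.push_back(birth[loser]);
        bars_d.push_back(z[v]);  // edge index = min(z_u, z_v) = z[v] here
      }
      parent[loser] = winner;
    }
  }
  if (kill) {
    for (int v = 0; v < n; ++v) {
      if (uf_find(parent, v) == v) {
        bars_b.push_back(birth[v]);
        bars_d.push_back(zmin);
      }
    }
  }
  int nb = bars_b.size();
  NumericMatrix bars(nb, 2);
  for (int k = 0; k < nb; ++k) { bars(k, 0) = bars_b[k]; bars(k, 1) = bars_d[k]; }
  colnames(bars) = CharacterVector::create("birth", "death");
  return bars;
}
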