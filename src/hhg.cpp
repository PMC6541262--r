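// Heller-Heller-Gorfine distance-based dependence statistics and their
// permutation null. For every ordered pair (i, j) the remaining n-2 points
// are cross-classified by d(i,k) <= d(i,j) in each space; Pearson chi-squared
// and likelihood-ratio (G) statistics of the 2x2 tables are summed and
// maximized. Permutations relabel the second space; the identity
// S(dx, dy[p,p]) = S(dx[q,q], dy) with q = p^{-1} lets all sort orders be
// precomputed once, and a bitset dominance counter yields each table in
// near-constant time.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
#include <cmath>
using namespace Rcpp;

namespace {

struct CenterX {
  std::vector<int> order;      // other indices sorted by dx[center][.]
  std::vector<int> grp_end;    // for each position, end (exclusive) of its tie run
  std::vector<int> cntx;       // per other index b: #{k != a : dx[a][k] <= dx[a][b]}
};

struct CenterY {
  std::vector<int> upos;       // unique bitset position per other index
  std::vector<int> qpos;       // inclusive upper tie boundary per other index
  std::vector<int> cnty;       // per other index b: #{k != i : dy[i][k] <= dy[i][b]}
};

void build_center_x(const NumericMatrix& d, int a, CenterX& cx) {
  int n = d.nrow();
  cx.order.clear();
  cx.order.reserve(n - 1);
  for (int k = 0; k < n; ++k) if (k != a) cx.order.push_back(k);
  std::stable_sort(cx.order.begin(), cx.order.end(),
                   [&](int u, int v) { return d(a, u) < d(a, v); });
  int m = n - 1;
  cx.grp_end.assign(m, 0);
  cx.cntx.assign(n, 0);
  int i = 0;
  while (i < m) {
    int j = i + 1;
    while (j < m && d(a, cx.order[j]) == d(a, cx.order[i])) ++j;
    for (int t = i; t < j; ++t) {
      cx.grp_end[t] = j;
      cx.cntx[cx.order[t]] = j;   // ties all count; 1-based inclusive count
    }
    i = j;
  }
}

void build_center_y(const NumericMatrix& d, int i0, CenterY& cy) {
  int n = d.nrow();
  std::vector<int> order;
  order.reserve(n - 1);
  for (int k = 0; k < n; ++k) if (k != i0) order.push_back(k);
  std::stable_sort(order.begin(), order.end(),
                   [&](int u, int v) { return d(i0, u) < d(i0, v); });
  int m = n - 1;
  cy.upos.assign(n, 0);
  cy.qpos.assign(n, 0);
  cy.cnty.assign(n, 0);
  int i = 0;
  while (i < m) {
    int j = i + 1;
    while (j < m && d(i0, order[j]) == d(i0, order[i])) ++j;
    for (int t = i; t < j; ++t) {
      int b = order[t];
      cy.upos[b] = t;
      cy.qpos[b] = j - 1;
      cy.cnty[b] = j;
    }
    i = j;
  }
}

struct Bitset {
  std::vector<uint64_t> w;
  void init(int nbits) { w.assign((nbits + 63) / 64, 0ULL); }
  void reset() { std::fill(w.begin(), w.end(), 0ULL); }
  inline void set(int pos) { w[pos >> 6] |= (1ULL << (pos & 63)); }
  inline int prefix_count(int pos) const {   // inclusive
    int word = pos >> 6;
    int cnt = 0;
    for (int t = 0; t < word; ++t) cnt += __builtin_popcountll(w[t]);
    uint64_t mask = (pos & 63) == 63 ? ~0ULL : ((1ULL << ((pos & 63) + 1)) - 1);
    cnt += __builtin_popcountll(w[word] & mask);
    return cnt;
  }
};

// Accumulate the four statistics for labelling sigma (sigma = identity gives
// the observed value). xlx[v] = v * log(v).
void hhg_stats_sigma(const std::vector<CenterX>& cxs,
                     const std::vector<CenterY>& cys,
                     const int* sigma, const int* pi, int n,
                     const std::vector<double>& xlx, double out[4]) {
  double sum_chi = 0.0, sum_lr = 0.0, max_chi = 0.0, max_lr = 0.0;
  int m = n - 2;
  Bitset bs;
  bs.init(n - 1);
  for (int i = 0; i < n; ++i) {
    int a = sigma[i];
    const CenterX& cx = cxs[a];
    const CenterY& cy = cys[i];
    bs.reset();
    int pos = 0;
    int nm1 = n - 1;
    while (pos < nm1) {
      int end = cx.grp_end[pos];
      for (int t = pos; t < end; ++t)
        bs.set(cy.upos[pi[cx.order[t]]]);
      for (int t = pos; t < end; ++t) {
        int b = cx.order[t];
        int j = pi[b];
        int nx = cx.cntx[b] - 1;          // exclude j itself
        int ny = cy.cnty[j] - 1;
        if (nx == 0 || nx == m || ny == 0 || ny == m) continue;
        int a11 = bs.prefix_count(cy.qpos[j]) - 1;
        int a12 = nx - a11;
        int a21 = ny - a11;
        int a22 = m - nx - ny + a11;
        double det = (double)a11 * a22 - (double)a12 * a21;
        double chi = (double)m * det * det /
          ((double)nx * (m - nx) * ny * (m - ny));
        double g = 2.0 * (xlx[a11] + xlx[a12] + xlx[a21] + xlx[a22]
                          - xlx[nx] - xlx[m - nx] - xlx[ny] - xlx[m - ny]
                          + xlx[m]);
        sum_chi += chi;
        sum_lr += g;
        if (chi > max_chi) max_chi = chi;
        if (g > max_lr) max_lr = g;
      }
      pos = end;
    }
  }
  out[0] = sum_chi;
  out[1] = sum_lr;
  out[2] = max_chi;
  out[3] = max_lr;
}

}  // namespace

// [[Rcpp::export]]
List hhg_engine_cpp(NumericMatrix dx, NumericMatrix dy, IntegerMatrix sigmas) {
  int n = dx.nrow();
  if (dx.ncol() != n || dy.nrow() != n || dy.ncol() != n)
    stop("distance matrices must be square and of equal size");
  if (n < 3) stop("need at least 3 points");
  std::vector<CenterX> cxs(n);
  std::vector<CenterY> cys(n);
  for (int a = 0; a < n; ++a) build_center_x(dx, a, cxs[a]);
  for (int i = 0; i < n; ++i) build_center_y(dy, i, cys[i]);
  std::vector<double> xlx(n + 1, 0.0);
  for (int v = 1; v <= n; ++v) xlx[v] = v * std::log((double)v);

  std::vector<int> ident(n), pi(n);
  for (int i = 0; i < n; ++i) ident[i] = i;
  double obs[4];
  hhg_stats_sigma(cxs, cys, ident.data(), ident.data(), n, xlx, obs);

  int nperm = sigmas.ncol();
  IntegerVector geq(4, 0);
  std::vector<int> sig(n);
  double st[4];
  for (int p = 0; p < nperm; ++p) {
    for (int i = 0; i < n; ++i) {
      sig[i] = sigmas(i, p) - 1;
      if (sig[i] < 0 || sig[i] >= n) stop("invalid permutation entry");
    }
    for (int i = 0; i < n; ++i) pi[sig[i]] = i;
    hhg_stats_sigma(cxs, cys, sig.data(), pi.data(), n, xlx, st);
    for (int s = 0; s < 4; ++s) if (st[s] >= obs[s]) geq[s]++;
  }
  return List::create(
    _["statistics"] = NumericVector(obs, obs + 4),
    _["n_geq"] = geq,
    _["n_perm"] = nperm
  );
}
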