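// Maximal Information Coefficient via the MINE characteristic matrix:
// dynamic-programming optimization of one axis against an equipartition of the
// other, over all grids (k columns x q rows) with k*q < B(n) = n^alpha, with
// the clump/superclump restriction controlled by the factor c.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
#include <limits>
using namespace Rcpp;

namespace {

// Assign sorted values to up to q bins of roughly equal size, never splitting
// tied values. Returns the number of bins actually used.
int equipartition(const std::vector<double>& vals, int q, std::vector<int>& bins) {
  int n = (int)vals.size();
  bins.assign(n, 0);
  int i = 0, curr = 0;
  double h = 0.0;
  double rowsize = (double)n / (double)q;
  while (i < n) {
    int s = 1;
    while (i + s < n && vals[i + s] == vals[i]) ++s;
    double t1 = std::fabs(h + s - rowsize);
    double t2 = std::fabs(h - rowsize);
    if (h != 0.0 && t1 >= t2) {
      ++curr;
      h = 0.0;
      rowsize = (double)(n - i) / (double)(q - curr);
    }
    for (int j = i; j < i + s; ++j) bins[j] = curr;
    i += s;
    h += s;
  }
  return curr + 1;
}

// Clumps: maximal runs (in x order) of consecutive points lying in the same
// y row; groups of tied x values that span several rows are fused into a
// clump of their own. Optimal x partitions only cut between clumps.
int get_clumps(const std::vector<double>& x, const std::vector<int>& q_map,
               std::vector<int>& p_map) {
  int n = (int)x.size();
  std::vector<int> qt(q_map);
  int i = 0, c = -1;
  while (i < n) {
    int s = 1;
    bool flag = false;
    for (int j = i + 1; j < n && x[j] == x[i]; ++j) {
      if (qt[j] != qt[i]) flag = true;
      ++s;
    }
    if (s > 1 && flag) {
      for (int j = i; j < i + s; ++j) qt[j] = c;
      --c;
    }
    i += s;
  }
  p_map.assign(n, 0);
  int p = 0;
  for (int j = 1; j < n; ++j) {
    if (qt[j] != qt[j - 1]) ++p;
    p_map[j] = p;
  }
  return p + 1;
}

int get_superclumps(const std::vector<double>& x, const std::vector<int>& q_map,
                    int k_hat, std::vector<int>& p_map) {
  int np = get_clumps(x, q_map, p_map);
  if (np > k_hat) {
    std::vector<double> dp(p_map.begin(), p_map.end());
    std::vector<int> sp;
    int k = equipartition(dp, k_hat, sp);
    p_map = sp;
    return k;
  }
  return np;
}

// DP over clump boundaries: scores[l-2] = max mutual information (nats) of an
// x partition with at most l columns against the fixed y partition.
// Recurrence on G(P) = H(P) - H(P,Q), which adds H(Q) back at the end.
void optimize_x_axis(int n, const std::vector<int>& p_map, int m,
                     const std::vector<int>& q_map, int q,
                     int kmax, std::vector<double>& scores) {
  const double NEG = -std::numeric_limits<double>::infinity();
  std::vector<int> csum(m + 1, 0);
  std::vector<std::vector<int> > cnt(q, std::vector<int>(m + 1, 0));
  for (int t = 0; t < n; ++t) {
    csum[p_map[t] + 1]++;
    cnt[q_map[t]][p_map[t] + 1]++;
  }
  for (int i = 1; i <= m; ++i) {
    csum[i] += csum[i - 1];
    for (int r = 0; r < q; ++r) cnt[r][i] += cnt[r][i - 1];
  }
  double hq = 0.0;
  for (int r = 0; r < q; ++r) {
    double pr = (double)cnt[r][m] / n;
    if (pr > 0) hq -= pr * std::log(pr);
  }
  int L = std::min(kmax, m);
  std::vector<std::vector<double> > F(m + 1, std::vector<double>(L + 1, NEG));
  for (int s = 1; s <= m; ++s) {
    double f = 0.0;
    for (int r = 0; r < q; ++r) {
      double nr = cnt[r][s];
      if (nr > 0) f += nr / (double)csum[s] * std::log(nr / (double)csum[s]);
    }
    F[s][1] = f;
  }
  for (int l = 2; l <= L; ++l) {
    for (int t = l; t <= m; ++t) {
      double best = NEG;
      double ct = csum[t];
      for (int s = l - 1; s < t; ++s) {
        double d = ct - csum[s];
        double val = csum[s] / ct * F[s][l - 1] - d / ct * std::log(d / ct);
        for (int r = 0; r < q; ++r) {
          double dr = cnt[r][t] - cnt[r][s];
          if (dr > 0) val += dr / ct * std::log(dr / ct);
        }
        if (val > best) best = val;
      }
      F[t][l] = best;
    }
  }
  scores.assign(kmax - 1, 0.0);
  double running = NEG;
  for (int l = 2; l <= kmax; ++l) {
    int ll = std::min(l, L);
    double v = hq + F[m][ll];
    if (v > running) running = v;   // MI over <= l columns is non-decreasing
    scores[l - 2] = std::max(running, 0.0);
  }
}

// One orientation: equipartition the secondary axis, optimize the primary.
// Updates best normalized score in-place.
void scan_orientation(const std::vector<double>& primary,
                      const std::vector<double>& secondary,
                      double B, double c, double& mic) {
  int n = (int)primary.size();
  std::vector<int> ord(n);
  for (int i = 0; i < n; ++i) ord[i] = i;
  std::stable_sort(ord.begin(), ord.end(),
                   [&](int a, int b) { return primary[a] < primary[b]; });
  std::vector<double> px(n);
  for (int i = 0; i < n; ++i) px[i] = primary[ord[i]];

  std::vector<int> ord_y(n);
  for (int i = 0; i < n; ++i) ord_y[i] = i;
  std::stable_sort(ord_y.begin(), ord_y.end(),
                   [&](int a, int b) { return secondary[a] < secondary[b]; });
  std::vector<double> sy(n);
  for (int i = 0; i < n; ++i) sy[i] = secondary[ord_y[i]];

  int qmax = (int)std::floor(B / 2.0);
  for (int q = 2; q <= qmax; ++q) {
    int kmax = (int)std::floor(B / (double)q);
    if (kmax < 2) break;
    std::vector<int> ybin_sorted;
    equipartition(sy, q, ybin_sorted);
    std::vector<int> ybin(n);
    for (int i = 0; i < n; ++i) ybin[ord_y[i]] = ybin_sorted[i];
    std::vector<int> q_map(n);
    for (int i = 0; i < n; ++i) q_map[i] = ybin[ord[i]];
    int qa = 1 + *std::max_element(ybin_sorted.begin(), ybin_sorted.end());

    int k_hat = std::max((int)(c * kmax), 1);
    std::vector<int> p_map;
    int m = get_superclumps(px, q_map, k_hat, p_map);

    std::vector<double> scores;
    optimize_x_axis(n, p_map, m, q_map, qa, kmax, scores);
    for (int k = 2; k <= kmax; ++k) {
      double norm = std::log((double)std::min(k, q));
      double v = scores[k - 2] / norm;
      if (v > mic) mic = v;
    }
  }
}

}  // namespace

// [[Rcpp::export]]
double mine_mic_cpp(NumericVector x, NumericVector y, double alpha, double c) {
  int n = x.size();
  if (y.size() != n) stop("x and y must have equal length");
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> yv(y.begin(), y.end());
  double B = std::max(std::pow((double)n, alpha), 4.0);
  if (B > (double)n) B = (double)n;
  double mic = 0.0;
  scan_orientation(xv, yv, B, c, mic);
  scan_orientation(yv, xv, B, c, mic);
  if (mic > 1.0) mic = 1.0;   // guard against rounding at the boundary
  return mic;
}
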