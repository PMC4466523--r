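#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Banded dynamic time warping on two feature sequences with squared
// difference local cost and step set {(1,1),(1,0),(0,1)}. The band is a
// Sakoe-Chiba corridor of half-width `w` around the rescaled diagonal,
// always wide enough to keep the corner-to-corner path feasible.
// Tie-break among equal-cost predecessors: diagonal, then (i-1,j), then
// (i,j-1) — fixed for determinism.
// [[Rcpp::export(name = ".dtw_core")]]
List dtw_core(NumericVector a, NumericVector b, double band_frac) {
  const int n = a.size(), m = b.size();
  if (n < 1 || m < 1) stop("empty feature sequence");
  const double INF = std::numeric_limits<double>::infinity();

  int w = (int)std::ceil(band_frac * std::max(n, m));
  w = std::max(w, std::abs(n - m) + 2);
  // corridor |i*(m-1) - j*(n-1)| <= W: symmetric in the two sequences,
  // so swapping the arguments leaves the reachable cell set unchanged
  double W = (double)w * std::max(std::max(n - 1, m - 1), 1);

  std::vector<int> lo(n), hi(n);
  for (int i = 0; i < n; ++i) {
    if (m == 1) { lo[i] = hi[i] = 0; continue; }
    double num = (double)i * (m - 1);
    lo[i] = std::max(0, (int)std::ceil((num - W) / (n - 1 > 0 ? n - 1 : 1)));
    hi[i] = std::min(m - 1,
                     (int)std::floor((num + W) / (n - 1 > 0 ? n - 1 : 1)));
    if (lo[i] > hi[i]) { lo[i] = std::max(0, std::min(m - 1, (int)(num / std::max(n - 1, 1)))); hi[i] = lo[i]; }
  }
  // row-major banded storage
  std::vector<int> off(n + 1, 0);
  for (int i = 0; i < n; ++i) off[i + 1] = off[i] + (hi[i] - lo[i] + 1);
  std::vector<double> D(off[n], INF);
  std::vector<signed char> bp(off[n], -1); // 0=diag,1=up,2=left

  auto at = [&](int i, int j) -> int { return off[i] + (j - lo[i]); };
  auto get = [&](int i, int j) -> double {
    if (i < 0 || j < 0 || j < lo[i] || j > hi[i]) return INF;
    return D[at(i, j)];
  };

  for (int i = 0; i < n; ++i) {
    for (int j = lo[i]; j <= hi[i]; ++j) {
      double d = a[i] - b[j];
      double cost = d * d;
      if (i == 0 && j == 0) {
        D[at(i, j)] = cost;
        continue;
      }
      double cd = get(i - 1, j - 1), cu = get(i - 1, j), cl = get(i, j - 1);
      double best = cd;
      signed char arg = 0;
      if (cu < best) { best = cu; arg = 1; }
      if (cl < best) { best = cl; arg = 2; }
      if (best == INF) continue; // unreachable cell
      D[at(i, j)] = best + cost;
      bp[at(i, j)] = arg;
    }
  }

  double total = D[at(n - 1, m - 1)];
  if (!R_FINITE(total)) stop("DTW: no feasible path inside the band");

  // backtrack
  std::vector<int> pi, pj;
  int i = n - 1, j = m - 1;
  while (true) {
    pi.push_back(i);
    pj.push_back(j);
    if (i == 0 && j == 0) break;
    signed char s = bp[at(i, j)];
    if (s == 0) { --i; --j; }
    else if (s == 1) { --i; }
    else { --j; }
  }
  int L = pi.size();
  IntegerMatrix path(L, 2);
  for (int k = 0; k < L; ++k) {
    path(k, 0) = pi[L - 1 - k];
    path(k, 1) = pj[L - 1 - k];
  }
  return List::create(_["path"] = path, _["cost"] = total);
}
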