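#include <Rcpp.h>
using namespace Rcpp;

// Exact two-sided permutation p-value for the Spearman correlation.
// xr, yr are midrank vectors (ties allowed). Enumerates all n! permutations
// of yr; since the rank correlation is affine increasing in the dot product
// S = sum(xr[i] * yr[perm[i]]), the tail count only needs S. Two-sided by
// |r| >= |r_obs| - eps, i.e. counting permutations whose |centred S| is at
// least the observed one.

static void perm_rec(const std::vector<double>& xr,
                     const std::vector<double>& yr,
                     std::vector<bool>& used,
                     int depth, double s,
                     double lo, double hi,
                     long long& count) {
  const int n = (int) xr.size();
  if (depth == n) {
    if (s <= lo || s >= hi) ++count;
    return;
  }
  for (int j = 0; j < n; ++j) {
    if (used[j]) continue;
    used[j] = true;
    perm_rec(xr, yr, used, depth + 1, s + xr[depth] * yr[j], lo, hi, count);
    used[j] = false;
  }
}

// [[Rcpp::export(name = ".spearman_perm_pvalue")]]
double spearman_perm_pvalue(NumericVector xr_, NumericVector yr_) {
  const int n = xr_.size();
  if (n != yr_.size()) stop("length mismatch");
  if (n > 10) stop("exact permutation enumeration supported only for n <= 10");
  std::vector<double> xr(xr_.begin(), xr_.end());
  std::vector<double> yr(yr_.begin(), yr_.end());
  double mx = 0.0, my = 0.0;
  for (int i = 0; i < n; ++i) { mx += xr[i]; my += yr[i]; }
  mx /= n; my /= n;
  double s_obs = 0.0;
  for (int i = 0; i < n; ++i) s_obs += xr[i] * yr[i];
  const double centre = n * mx * my;            // S under perfect independence
  const double dev = std::fabs(s_obs - centre); // |centred S| observed
  const double eps = 1e-9 * (std::fabs(centre) + 1.0);
  const double lo = centre - dev + eps;
  const double hi = centre + dev - eps;
  std::vector<bool> used(n, false);
  long long count = 0;
  perm_rec(xr, yr, used, 0, 0.0, lo, hi, count);
  double total = 1.0;
  for (int i = 2; i <= n; ++i) total *= i;
  return (double) count / total;
}
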