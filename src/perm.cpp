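#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Statistic codes shared with the R wrappers:
//   0 = |mean(a) - mean(b)|
//   1 = |log(var(a) / var(b))|   (sample variances, n-1 denominator)
//   2 = |Welch t|                (studentized option)
// Degenerate variances map to +Inf so they always land in the tail;
// the R wrappers intercept the all-degenerate observed case.

static double group_stat(double sum_a, double ssq_a, int n_a,
                         double sum_b, double ssq_b, int n_b,
                         int stat) {
  const double mean_a = sum_a / n_a, mean_b = sum_b / n_b;
  if (stat == 0) return std::fabs(mean_a - mean_b);
  const double var_a = (ssq_a - sum_a * mean_a) / (n_a - 1);
  const double var_b = (ssq_b - sum_b * mean_b) / (n_b - 1);
  if (stat == 1) {
    if (var_a <= 0.0 || var_b <= 0.0) return R_PosInf;
    return std::fabs(std::log(var_a / var_b));
  }
  const double se2 = var_a / n_a + var_b / n_b;
  if (se2 <= 0.0) return R_PosInf;
  return std::fabs(mean_a - mean_b) / std::sqrt(se2);
}

// [[Rcpp::export]]
double perm_stat_cpp(NumericVector x, int n_a, int stat) {
  const int n = x.size();
  double sum_a = 0, ssq_a = 0, sum = 0, ssq = 0;
  for (int i = 0; i < n; ++i) {
    sum += x[i];
    ssq += x[i] * x[i];
    if (i < n_a) { sum_a += x[i]; ssq_a += x[i] * x[i]; }
  }
  return group_stat(sum_a, ssq_a, n_a, sum - sum_a, ssq - ssq_a, n - n_a, stat);
}

// Number of label permutations whose statistic reaches the observed value.
// Uses partial Fisher-Yates: after each pass the first n_a slots hold a
// uniformly random subset, so no re-initialisation is needed between
// iterations.  Draws come from R's RNG (set.seed() upstream governs them).
// [[Rcpp::export]]
double perm_count_cpp(NumericVector x, int n_a, double t_obs,
                      double n_iter, int stat) {
  const int n = x.size();
  std::vector<double> v(x.begin(), x.end());
  double sum = 0, ssq = 0;
  for (int i = 0; i < n; ++i) { sum += v[i]; ssq += v[i] * v[i]; }
  // infinite observed statistic (degenerate variance): count the
  // permutations that are themselves degenerate
  const double thresh = std::isfinite(t_obs)
    ? t_obs - 1e-12 * (1.0 + std::fabs(t_obs)) : t_obs;
  double count = 0;
  const long long iters = (long long)n_iter;
  for (long long it = 0; it < iters; ++it) {
    double sum_a = 0, ssq_a = 0;
    for (int i = 0; i < n_a; ++i) {
      int j = i + (int)(unif_rand() * (n - i));
      if (j >= n) j = n - 1;  // guard against unif_rand() == 1
      std::swap(v[i], v[j]);
      sum_a += v[i];
      ssq_a += v[i] * v[i];
    }
    const double t = group_stat(sum_a, ssq_a, n_a,
                                sum - sum_a, ssq - ssq_a, n - n_a, stat);
    if (t >= thresh) count += 1;
  }
  return count;
}
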