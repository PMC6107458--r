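#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Grid threshold search. Must reproduce the R reference (threshold_search)
// exactly: grid t_k = k * increment with the pooled range rounded outward,
// strict ">" / "<" comparators, tie set averaged, orientation tie broken
// toward positive_high, sensitivity/specificity re-evaluated at the averaged
// threshold.
//
// Instead of binary-searching the class vectors at every grid point, each
// data value v is bucketed once at the first grid index whose threshold
// satisfies t_k >= v (resp. t_k > v); running prefix sums over the buckets
// then give #{v <= t_k} and #{v < t_k} at every k. The bucket boundaries are
// fixed up against the actual double comparisons, so the sweep is
// bit-identical to evaluating every grid point directly.
struct SearchResult {
  int orientation;      // 0 = positive_high, 1 = positive_low
  double best_threshold;
  double tie_min, tie_max;
  double sensitivity, specificity;
  double optimum;
};

static inline int count_le(const std::vector<double>& v, double t) {
  return (int)(std::upper_bound(v.begin(), v.end(), t) - v.begin());
}
static inline int count_lt(const std::vector<double>& v, double t) {
  return (int)(std::lower_bound(v.begin(), v.end(), t) - v.begin());
}

// smallest k in [k_lo, k_hi + 1] with (double)k * inc >= v; k_hi + 1 acts as
// an "off the grid" sentinel
static inline long long first_ge(double v, double inc, long long k_lo,
                                 long long k_hi) {
  long long k = (long long)std::ceil(v / inc - 1e-9);
  if (k < k_lo) k = k_lo;
  if (k > k_hi + 1) k = k_hi + 1;
  while (k <= k_hi && (double)k * inc < v) ++k;
  while (k > k_lo && (double)(k - 1) * inc >= v) --k;
  return k;
}

static SearchResult grid_search(const std::vector<double>& pos,
                                const std::vector<double>& neg,
                                double increment) {
  const int np = (int)pos.size(), nn = (int)neg.size();
  double lo = pos[0], hi = pos[0];
  for (double v : pos) { if (v < lo) lo = v; if (v > hi) hi = v; }
  for (double v : neg) { if (v < lo) lo = v; if (v > hi) hi = v; }
  const long long k_lo = (long long)std::floor(lo / increment + 1e-9);
  const long long k_hi = (long long)std::ceil(hi / increment - 1e-9);
  const int G = (int)(k_hi - k_lo + 1);

  // bucket increments: at index k - k_lo, how many values start counting as
  // "<= t_k" (ge buckets) and as "< t_k" (gt buckets)
  static std::vector<int> ge_p, gt_p, ge_n, gt_n;
  ge_p.assign(G + 1, 0); gt_p.assign(G + 1, 0);
  ge_n.assign(G + 1, 0); gt_n.assign(G + 1, 0);
  for (double v : pos) {
    long long k = first_ge(v, increment, k_lo, k_hi);
    ge_p[k - k_lo]++;
    // first k with t_k > v: one past k if t_k == v exactly
    if (k <= k_hi && (double)k * increment == v) ++k;
    gt_p[k - k_lo]++;
  }
  for (double v : neg) {
    long long k = first_ge(v, increment, k_lo, k_hi);
    ge_n[k - k_lo]++;
    if (k <= k_hi && (double)k * increment == v) ++k;
    gt_n[k - k_lo]++;
  }

  double best_sum[2] = {-1.0, -1.0};
  long double tie_sum[2] = {0.0L, 0.0L};
  long long tie_n[2] = {0, 0};
  double tie_min[2] = {0, 0}, tie_max[2] = {0, 0};
  int le_p = 0, lt_p = 0, le_n = 0, lt_n = 0;

  for (int g = 0; g < G; ++g) {
    const double t = (double)(k_lo + g) * increment;
    le_p += ge_p[g]; lt_p += gt_p[g];
    le_n += ge_n[g]; lt_n += gt_n[g];
    const double sums[2] = {
      (double)(np - le_p) / np + (double)le_n / nn,   // positive_high
      (double)lt_p / np + (double)(nn - lt_n) / nn    // positive_low
    };
    for (int o = 0; o < 2; ++o) {
      if (sums[o] > best_sum[o]) {
        best_sum[o] = sums[o];
        tie_sum[o] = t; tie_n[o] = 1; tie_min[o] = t; tie_max[o] = t;
      } else if (sums[o] == best_sum[o]) {
        tie_sum[o] += t; tie_n[o] += 1; tie_max[o] = t;
      }
    }
  }

  const int o = (best_sum[0] >= best_sum[1]) ? 0 : 1;
  SearchResult r;
  r.orientation = o;
  r.best_threshold = (double)(tie_sum[o] / tie_n[o]);
  r.tie_min = tie_min[o];
  r.tie_max = tie_max[o];
  r.optimum = best_sum[o];
  std::vector<double> sp(pos), sn(neg);
  std::sort(sp.begin(), sp.end());
  std::sort(sn.begin(), sn.end());
  if (o == 0) {
    r.sensitivity = (double)(np - count_le(sp, r.best_threshold)) / np;
    r.specificity = (double)count_le(sn, r.best_threshold) / nn;
  } else {
    r.sensitivity = (double)count_lt(sp, r.best_threshold) / np;
    r.specificity = (double)(nn - count_lt(sn, r.best_threshold)) / nn;
  }
  return r;
}

// [[Rcpp::export]]
List cpp_threshold_search(NumericVector values, LogicalVector labels,
                          double increment) {
  std::vector<double> pos, neg;
  for (int i = 0; i < values.size(); ++i) {
    if (labels[i]) pos.push_back(values[i]); else neg.push_back(values[i]);
  }
  SearchResult r = grid_search(pos, neg, increment);
  return List::create(
    _["orientation"] = r.orientation, _["best_threshold"] = r.best_threshold,
    _["tie_min"] = r.tie_min, _["tie_max"] = r.tie_max,
    _["sensitivity"] = r.sensitivity, _["specificity"] = r.specificity,
    _["optimum"] = r.optimum);
}

// Streamed exhaustive ordered-pair screen. Rows of `logareas` are ions
// (pre-sorted lexicographically by (mz, rt)); columns are the comparison
// samples. method_code: 0 = log_of_ratio (difference of log areas),
// 1 = ratio_of_logs. zero_policy (ratio only): 0 = skip the ordered pair
// when the denominator has a zero log area, 1 = drop those samples.
// [[Rcpp::export]]
List cpp_screen_pairs(NumericMatrix logareas, LogicalVector is_pos,
                      int method_code, double min_sens, double min_spec,
                      double increment, int zero_policy) {
  const int n_ions = logareas.nrow();
  const int n_samp = logareas.ncol();

  std::vector<int> out_a, out_b, out_orient;
  std::vector<double> out_thr, out_sens, out_spec, out_opt;
  double n_screened = 0, n_skipped = 0;

  std::vector<double> pos, neg;
  pos.reserve(n_samp); neg.reserve(n_samp);

  for (int a = 0; a < n_ions; ++a) {
    for (int b = 0; b < n_ions; ++b) {
      if (a == b) continue;
      pos.clear(); neg.clear();
      bool skip = false;
      if (method_code == 1) {
        for (int s = 0; s < n_samp; ++s) {
          const double lb = logareas(b, s);
          if (lb == 0.0) {
            if (zero_policy == 0) { skip = true; break; }
            continue;  // drop_sample
          }
          const double sc = logareas(a, s) / lb;
          if (is_pos[s]) pos.push_back(sc); else neg.push_back(sc);
        }
        if (!skip && (pos.empty() || neg.empty())) skip = true;
      } else {
        for (int s = 0; s < n_samp; ++s) {
          const double sc = logareas(a, s) - logareas(b, s);
          if (is_pos[s]) pos.push_back(sc); else neg.push_back(sc);
        }
      }
      if (skip) { n_skipped += 1; continue; }
      n_screened += 1;
      SearchResult r = grid_search(pos, neg, increment);
      if (r.sensitivity >= min_sens && r.specificity >= min_spec) {
        out_a.push_back(a + 1);
        out_b.push_back(b + 1);
        out_orient.push_back(r.orientation);
        out_thr.push_back(r.best_threshold);
        out_sens.push_back(r.sensitivity);
        out_spec.push_back(r.specificity);
        out_opt.push_back(r.optimum);
      }
    }
    Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["a"] = wrap(out_a), _["b"] = wrap(out_b),
    _["orientation"] = wrap(out_orient), _["threshold"] = wrap(out_thr),
    _["sensitivity"] = wrap(out_sens), _["specificity"] = wrap(out_spec),
    _["optimum"] = wrap(out_opt),
    _["n_screened"] = n_screened, _["n_skipped"] = n_skipped);
}
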