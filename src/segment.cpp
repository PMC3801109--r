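#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Greedy BIC-penalised merging of adjacent bins for case/control read-depth
// segmentation. Within a segment each read is a case read with segment
// probability p; the segment log-likelihood is the binomial maximum
// ka*log(p^) + kb*log(1-p^). Total BIC = -2*sum(logL) + lambda*k*log(N).
// Adjacent segments are merged greedily, always taking the merge with the
// largest BIC decrease, until no merge decreases the BIC.

static inline double seg_ll(double ka, double kb) {
  double t = ka + kb;
  if (t <= 0) return 0.0;
  double ll = 0.0;
  if (ka > 0) ll += ka * std::log(ka / t);
  if (kb > 0) ll += kb * std::log(kb / t);
  return ll;
}

struct Cand {
  double delta;
  int left;
  long version;
};
struct CandCmp {
  bool operator()(const Cand &a, const Cand &b) const {
    return a.delta > b.delta;  // min-heap on delta
  }
};

// [[Rcpp::export(name = ".segment_bins")]]
List segment_bins(NumericVector case_counts, NumericVector control_counts,
                  double lambda, double total_reads) {
  int n = case_counts.size();
  if (n == 0) {
    return List::create(_["start"] = IntegerVector(0),
                        _["end"] = IntegerVector(0),
                        _["case_count"] = NumericVector(0),
                        _["control_count"] = NumericVector(0),
                        _["bic_trace"] = NumericVector(0));
  }
  double logN = std::log(std::max(total_reads, 2.0));
  double penalty = lambda * logN;  // BIC cost of one extra segment

  std::vector<double> ka(case_counts.begin(), case_counts.end());
  std::vector<double> kb(control_counts.begin(), control_counts.end());
  std::vector<int> start(n), end(n), prev(n), next(n);
  std::vector<long> version(n, 0);
  std::vector<bool> alive(n, true);
  for (int i = 0; i < n; i++) {
    start[i] = i;
    end[i] = i;
    prev[i] = i - 1;
    next[i] = (i + 1 < n) ? i + 1 : -1;
  }

  std::priority_queue<Cand, std::vector<Cand>, CandCmp> heap;
  auto push_cand = [&](int i) {
    int j = next[i];
    if (j < 0) return;
    double d = -2.0 * (seg_ll(ka[i] + ka[j], kb[i] + kb[j]) -
                       seg_ll(ka[i], kb[i]) - seg_ll(ka[j], kb[j])) -
               penalty;
    heap.push({d, i, version[i] + version[j]});
  };
  for (int i = 0; i < n; i++) push_cand(i);

  std::vector<double> trace;
  while (!heap.empty()) {
    Cand c = heap.top();
    heap.pop();
    int i = c.left;
    if (!alive[i]) continue;
    int j = next[i];
    if (j < 0 || !alive[j]) continue;
    if (c.version != version[i] + version[j]) continue;  // stale
    if (c.delta >= 0) break;
    // merge j into i
    ka[i] += ka[j];
    kb[i] += kb[j];
    end[i] = end[j];
    alive[j] = false;
    next[i] = next[j];
    if (next[i] >= 0) prev[next[i]] = i;
    version[i]++;
    trace.push_back(c.delta);
    push_cand(i);
    if (prev[i] >= 0) push_cand(prev[i]);
  }

  std::vector<int> s_out, e_out;
  std::vector<double> a_out, b_out;
  for (int i = 0; i >= 0; i = next[i]) {
    s_out.push_back(start[i] + 1);  // 1-based bin indices
    e_out.push_back(end[i] + 1);
    a_out.push_back(ka[i]);
    b_out.push_back(kb[i]);
  }
  return List::create(
    _["start"] = wrap(s_out), _["end"] = wrap(e_out),
    _["case_count"] = wrap(a_out), _["control_count"] = wrap(b_out),
    _["bic_trace"] = wrap(trace)
  );
}
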