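#include <Rcpp.h>
using namespace Rcpp;

// Partitioning around medoids over a precomputed dissimilarity matrix.
// Classical BUILD (greedy) + SWAP (best improvement). All ties broken by
// lowest index so results are fully deterministic; randomness enters the
// pipeline only through subsampling. Core routines work on raw column-major
// buffers so the consensus engine can run thousands of subsampled fits
// without R-level overhead.

namespace {

inline const double* col(const double* D, int n, int j) {
  return D + (size_t)j * n;
}

void nearest_two(const double* D, int n, const std::vector<int>& med,
                 std::vector<double>& d1, std::vector<double>& d2,
                 std::vector<int>& m1) {
  const int k = med.size();
  for (int i = 0; i < n; ++i) {
    d1[i] = R_PosInf;
    d2[i] = R_PosInf;
    m1[i] = -1;
  }
  for (int c = 0; c < k; ++c) {       // medoids ascending: lowest index
    const double* dc = col(D, n, med[c]);  // wins ties via strict <
    for (int i = 0; i < n; ++i) {
      const double d = dc[i];
      if (d < d1[i]) {
        d2[i] = d1[i];
        d1[i] = d;
        m1[i] = med[c];
      } else if (d < d2[i]) {
        d2[i] = d;
      }
    }
  }
}

// greedy BUILD: first medoid minimizes total dissimilarity, each further
// medoid maximizes the total decrease in cost; ties -> lowest index
void pam_build_core(const double* D, int n, int k, std::vector<int>& med) {
  med.clear();
  med.reserve(k);
  std::vector<bool> is_med(n, false);
  std::vector<double> nearest(n);

  int best = -1;
  double best_sum = R_PosInf;
  for (int j = 0; j < n; ++j) {
    const double* dj = col(D, n, j);
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += dj[i];
    if (s < best_sum) { best_sum = s; best = j; }
  }
  med.push_back(best);
  is_med[best] = true;
  const double* db = col(D, n, best);
  for (int i = 0; i < n; ++i) nearest[i] = db[i];

  while ((int)med.size() < k) {
    int pick = -1;
    double best_gain = -1.0;
    for (int c = 0; c < n; ++c) {
      if (is_med[c]) continue;
      const double* dc = col(D, n, c);
      double gain = 0.0;
      for (int i = 0; i < n; ++i) {
        const double g = nearest[i] - dc[i];
        if (g > 0) gain += g;
      }
      if (gain > best_gain) { best_gain = gain; pick = c; }
    }
    med.push_back(pick);
    is_med[pick] = true;
    const double* dp = col(D, n, pick);
    for (int i = 0; i < n; ++i)
      if (dp[i] < nearest[i]) nearest[i] = dp[i];
  }
  std::sort(med.begin(), med.end());
}

// best-improvement SWAP until local optimum; ties -> first (m, h) in
// ascending order; returns final cost and appends accepted costs to trace
double pam_swap_core(const double* D, int n, std::vector<int>& med,
                     std::vector<int>& m1, double& cost,
                     std::vector<double>* trace, int max_iter = 1000) {
  const int k = med.size();
  std::sort(med.begin(), med.end());
  std::vector<bool> is_med(n, false);
  for (int c = 0; c < k; ++c) is_med[med[c]] = true;

  std::vector<double> d1(n), d2(n);
  nearest_two(D, n, med, d1, d2, m1);
  cost = 0.0;
  for (int i = 0; i < n; ++i) cost += d1[i];
  if (trace) trace->push_back(cost);

  const double eps = 1e-12;
  for (int iter = 0; iter < max_iter; ++iter) {
    double best_delta = -eps;
    int best_m = -1, best_h = -1;
    for (int c = 0; c < k; ++c) {
      const int m = med[c];
      for (int h = 0; h < n; ++h) {
        if (is_med[h]) continue;
        const double* dh = col(D, n, h);
        double delta = 0.0;
        for (int i = 0; i < n; ++i) {
          const double dih = dh[i];
          if (m1[i] == m) {
            const double repl = (dih < d2[i]) ? dih : d2[i];
            delta += repl - d1[i];
          } else if (dih < d1[i]) {
            delta += dih - d1[i];
          }
        }
        if (delta < best_delta) { best_delta = delta; best_m = m; best_h = h; }
      }
    }
    if (best_m < 0) break;  // local optimum
    is_med[best_m] = false;
    is_med[best_h] = true;
    for (int c = 0; c < k; ++c) if (med[c] == best_m) med[c] = best_h;
    std::sort(med.begin(), med.end());
    nearest_two(D, n, med, d1, d2, m1);
    cost = 0.0;
    for (int i = 0; i < n; ++i) cost += d1[i];
    if (trace) trace->push_back(cost);
  }
  return cost;
}

// cluster index = rank of the assigned medoid in the sorted medoid set
void labels_from(const std::vector<int>& med, const std::vector<int>& m1,
                 std::vector<int>& labels) {
  const int n = m1.size();
  labels.resize(n);
  for (int i = 0; i < n; ++i) {
    const int pos = std::lower_bound(med.begin(), med.end(), m1[i]) - med.begin();
    labels[i] = pos + 1;
  }
}

}  // namespace

// [[Rcpp::export]]
List pam_build_cpp(NumericMatrix D, int k) {
  const int n = D.nrow();
  if (k < 1 || k > n) stop("k must lie in 1..n");
  std::vector<int> med;
  pam_build_core(REAL(D), n, k, med);
  return List::create(_["medoids"] = IntegerVector(med.begin(), med.end()));
}

// [[Rcpp::export]]
List pam_swap_cpp(NumericMatrix D, IntegerVector medoids0, int max_iter = 1000) {
  const int n = D.nrow();
  std::vector<int> med(medoids0.begin(), medoids0.end());
  for (size_t c = 0; c < med.size(); ++c)
    if (med[c] < 0 || med[c] >= n) stop("medoid index out of range");
  std::vector<int> m1(n), labels;
  std::vector<double> trace;
  double cost = 0.0;
  pam_swap_core(REAL(D), n, med, m1, cost, &trace, max_iter);
  labels_from(med, m1, labels);
  return List::create(_["medoids"] = IntegerVector(med.begin(), med.end()),
                      _["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["cost"] = cost,
                      _["cost_trace"] = NumericVector(trace.begin(), trace.end()));
}

// [[Rcpp::export]]
List assign_to_medoids_cpp(NumericMatrix D, IntegerVector medoids) {
  const int n = D.nrow();
  std::vector<int> med(medoids.begin(), medoids.end());
  std::sort(med.begin(), med.end());
  std::vector<double> d1(n), d2(n);
  std::vector<int> m1(n), labels;
  nearest_two(REAL(D), n, med, d1, d2, m1);
  double cost = 0.0;
  for (int i = 0; i < n; ++i) cost += d1[i];
  labels_from(med, m1, labels);
  return List::create(_["medoids"] = IntegerVector(med.begin(), med.end()),
                      _["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["cost"] = cost);
}

// One full consensus accumulation: for each repetition (row of idx,
// 1-based indices into D), slice the dissimilarity matrix, run BUILD+SWAP
// PAM with k clusters, and increment pairwise co-sampling / co-clustering
// counters. Only counting lives here; subsample draws stay in R.
// [[Rcpp::export]]
List consensus_counts_cpp(NumericMatrix D, int k, IntegerMatrix idx) {
  const int n = D.nrow();
  const int reps = idx.nrow();
  const int m = idx.ncol();
  if (k < 2 || k > m) stop("need 2 <= k <= subsample size");
  NumericMatrix cosample(n, n), cocluster(n, n);
  std::vector<double> sub((size_t)m * m);
  std::vector<int> take(m), med, m1(m), labels;
  const double* Dp = REAL(D);
  double* cs = REAL(cosample);
  double* cc = REAL(cocluster);

  for (int r = 0; r < reps; ++r) {
    for (int j = 0; j < m; ++j) {
      take[j] = idx(r, j) - 1;
      if (take[j] < 0 || take[j] >= n) stop("subsample index out of range");
    }
    for (int j = 0; j < m; ++j) {
      const double* dj = col(Dp, n, take[j]);
      double* sj = &sub[(size_t)j * m];
      for (int i = 0; i < m; ++i) sj[i] = dj[take[i]];
    }
    pam_build_core(sub.data(), m, k, med);
    double cost = 0.0;
    pam_swap_core(sub.data(), m, med, m1, cost, nullptr);
    labels_from(med, m1, labels);
    for (int j = 0; j < m; ++j) {
      const int cj = take[j];
      double* csj = cs + (size_t)cj * n;
      double* ccj = cc + (size_t)cj * n;
      for (int i = 0; i < m; ++i) {
        csj[take[i]] += 1.0;
        if (labels[i] == labels[j]) ccj[take[i]] += 1.0;
      }
    }
  }
  return List::create(_["cosample"] = cosample, _["cocluster"] = cocluster);
}
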