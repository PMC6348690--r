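#include <Rcpp.h>
using namespace Rcpp;

// Local similarity dynamic programming.
//
// Cells (i, j) with |i - j| <= D carry two accumulators,
//   P(i,j) = max(0, P(i-1,j-1) + x_i * y_j)
//   N(i,j) = max(0, N(i-1,j-1) - x_i * y_j),
// and the LS score s_D is the maximum of both over all cells. Because the
// recurrence only moves along a diagonal (constant j - i), each diagonal is
// an independent Kadane-style scan over the product series, so time is
// O(n * (2D+1)) and memory O(1) per diagonal.

namespace {

struct Best {
  double score;
  int delay;    // start_y - start_x (constant along a diagonal)
  int start_x;  // 1-based
  int start_y;  // 1-based
  int len;
  int sign;     // +1 if the max came from P, -1 from N
};

// Lexicographic tie-break on (delay, start_x, length); positive sign
// preferred when everything else ties.
inline bool better(const Best& cand, const Best& cur) {
  if (cand.score != cur.score) return cand.score > cur.score;
  if (cand.delay != cur.delay) return cand.delay < cur.delay;
  if (cand.start_x != cur.start_x) return cand.start_x < cur.start_x;
  if (cand.len != cur.len) return cand.len < cur.len;
  return cand.sign > cur.sign;
}

// Scan one diagonal; z_t = x[i0 + t] * y[j0 + t], t = 0..L-1 (0-based).
void scan_diagonal(const double* x, const double* y, int i0, int j0, int L,
                   int delay, Best& best) {
  double pos = 0.0, neg = 0.0;
  int pos_start = 0, neg_start = 0;  // 0-based run starts within diagonal
  for (int t = 0; t < L; ++t) {
    double z = x[i0 + t] * y[j0 + t];
    pos += z;
    if (pos <= 0.0) {
      pos = 0.0;
      pos_start = t + 1;
    } else {
      Best cand = {pos, delay, i0 + pos_start + 1, j0 + pos_start + 1,
                   t - pos_start + 1, 1};
      if (better(cand, best)) best = cand;
    }
    neg -= z;
    if (neg <= 0.0) {
      neg = 0.0;
      neg_start = t + 1;
    } else {
      Best cand = {neg, delay, i0 + neg_start + 1, j0 + neg_start + 1,
                   t - neg_start + 1, -1};
      if (better(cand, best)) best = cand;
    }
  }
}

Best ls_best(const double* x, const double* y, int n, int D) {
  Best best = {0.0, 0, 1, 1, 0, 1};
  for (int d = -D; d <= D; ++d) {
    // delay d = start_y - start_x; x index range so both stay in 1..n
    int i0 = d >= 0 ? 0 : -d;  // 0-based first x index on the diagonal
    int j0 = d >= 0 ? d : 0;
    int L = n - (d >= 0 ? d : -d);
    scan_diagonal(x, y, i0, j0, L, d, best);
  }
  return best;
}

// Score only: per diagonal the max |interval sum| equals the range of the
// prefix sums (including the empty prefix 0).
double ls_score_val(const double* x, const double* y, int n, int D) {
  double best = 0.0;
  for (int d = -D; d <= D; ++d) {
    int i0 = d >= 0 ? 0 : -d;
    int j0 = d >= 0 ? d : 0;
    int L = n - (d >= 0 ? d : -d);
    double s = 0.0, mx = 0.0, mn = 0.0;
    for (int t = 0; t < L; ++t) {
      s += x[i0 + t] * y[j0 + t];
      if (s > mx) mx = s;
      if (s < mn) mn = s;
    }
    if (mx - mn > best) best = mx - mn;
  }
  return best;
}

}  // namespace

// [[Rcpp::export]]
List cpp_ls_score(NumericVector x, NumericVector y, int max_delay) {
  int n = x.size();
  Best b = ls_best(REAL(x), REAL(y), n, max_delay);
  return List::create(_["score"] = b.score, _["delay"] = b.delay,
                      _["start_x"] = b.start_x, _["start_y"] = b.start_y,
                      _["length"] = b.len, _["sign"] = b.sign);
}

// [[Rcpp::export]]
double cpp_ls_score_only(NumericVector x, NumericVector y, int max_delay) {
  return ls_score_val(REAL(x), REAL(y), x.size(), max_delay);
}

// Permutation null distribution of the LS score: y fixed, x reshuffled
// n_perm times with R's RNG (so set.seed() makes it reproducible).
// [[Rcpp::export]]
NumericVector cpp_perm_scores(NumericVector x, NumericVector y, int max_delay,
                              int n_perm) {
  int n = x.size();
  NumericVector out(n_perm);
  std::vector<double> xs(REAL(x), REAL(x) + n);
  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates with R's uniform RNG
    for (int i = n - 1; i > 0; --i) {
      int j = static_cast<int>(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(xs[i], xs[j]);
    }
    out[b] = ls_score_val(xs.data(), REAL(y), n, max_delay);
  }
  return out;
}
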