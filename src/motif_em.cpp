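#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// ZOOPS (zero-or-one occurrence per sequence) EM refinement of a PWM.
//
// windows: nwin x w integer matrix of base codes 0..3 (both strands of every
//          promoter, pre-expanded by the caller)
// prom:    0-based promoter index per window
// n_prom:  number of promoters
// pwm0:    4 x w starting PWM (probabilities)
// bg:      background base probabilities (length 4)
// pseudo:  total pseudocount added per column, split by bg
//
// Each pass scores every window with the current log2-odds PWM, takes the
// best-scoring window per promoter, keeps it as a site when its score is
// positive, and re-estimates the PWM from the kept sites. Stops when the
// summed site score changes by less than tol or after max_iter passes.
// [[Rcpp::export]]
List cpp_zoops_em(const IntegerMatrix& windows, const IntegerVector& prom,
                  int n_prom, NumericMatrix pwm0, const NumericVector& bg,
                  double pseudo, int max_iter, double tol) {
  const int nwin = windows.nrow(), w = windows.ncol();
  NumericMatrix pwm(4, w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b) pwm(b, j) = pwm0(b, j);

  std::vector<double> lo(4 * w);
  std::vector<int> best_win(n_prom);
  std::vector<double> best_score(n_prom);
  double prev_ll = -1e300, ll = 0.0;
  int iter = 0, n_sites = 0;

  for (iter = 1; iter <= max_iter; ++iter) {
    for (int j = 0; j < w; ++j)
      for (int b = 0; b < 4; ++b)
        lo[j * 4 + b] = std::log2(pwm(b, j) / bg[b]);

    std::fill(best_score.begin(), best_score.end(), -1e300);
    std::fill(best_win.begin(), best_win.end(), -1);
    for (int i = 0; i < nwin; ++i) {
      double s = 0.0;
      for (int j = 0; j < w; ++j) s += lo[j * 4 + windows(i, j)];
      const int p = prom[i];
      if (s > best_score[p]) { best_score[p] = s; best_win[p] = i; }
    }

    ll = 0.0; n_sites = 0;
    NumericMatrix counts(4, w);
    for (int p = 0; p < n_prom; ++p) {
      if (best_win[p] >= 0 && best_score[p] > 0.0) {
        ++n_sites;
        ll += best_score[p];
        for (int j = 0; j < w; ++j) counts(windows(best_win[p], j), j) += 1.0;
      }
    }
    if (n_sites < 2) break;
    for (int j = 0; j < w; ++j) {
      double tot = n_sites + pseudo;
      for (int b = 0; b < 4; ++b)
        pwm(b, j) = (counts(b, j) + pseudo * bg[b]) / tot;
    }
    if (std::fabs(ll - prev_ll) < tol) break;
    prev_ll = ll;
  }

  IntegerVector site_win(n_prom);
  for (int p = 0; p < n_prom; ++p)
    site_win[p] = (best_win[p] >= 0 && best_score[p] > 0.0)
      ? best_win[p] + 1 : NA_INTEGER;  // 1-based for R

  return List::create(_["pwm"] = pwm, _["site_window"] = site_win,
                      _["loglik"] = ll, _["n_sites"] = n_sites,
                      _["iterations"] = iter);
}

// Exact tail probability P(score >= threshold) of the PWM log2-odds score of
// a single background-distributed window, by dynamic programming on a
// discretized score grid (grid step `delta` bits).
// [[Rcpp::export]]
double cpp_score_tail(const NumericMatrix& pwm, const NumericVector& bg,
                      double threshold, double delta) {
  const int w = pwm.ncol();
  std::vector<std::vector<int>> v(w, std::vector<int>(4));
  std::vector<std::vector<double>> pr(w, std::vector<double>(4));
  long lo_sum = 0, hi_sum = 0;
  for (int j = 0; j < w; ++j) {
    int lo = 0, hi = 0;
    for (int b = 0; b < 4; ++b) {
      double val = std::log2(std::max(pwm(b, j), 1e-12) / bg[b]);
      v[j][b] = (int)std::lround(val / delta);
      pr[j][b] = bg[b];
      if (b == 0 || v[j][b] < lo) lo = v[j][b];
      if (b == 0 || v[j][b] > hi) hi = v[j][b];
    }
    lo_sum += lo; hi_sum += hi;
  }
  const long span = hi_sum - lo_sum + 1;
  std::vector<double> dp(span, 0.0), nxt(span, 0.0);
  // running support offset: minimal achievable sum so far
  long off = 0;
  dp[0] = 1.0;
  long cur_lo = 0, cur_hi = 0;
  for (int j = 0; j < w; ++j) {
    int lo = v[j][0], hi = v[j][0];
    for (int b = 1; b < 4; ++b) { lo = std::min(lo, v[j][b]); hi = std::max(hi, v[j][b]); }
    long new_lo = cur_lo + lo, new_hi = cur_hi + hi;
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (long k = cur_lo; k <= cur_hi; ++k) {
      double p = dp[k - off];
      if (p == 0.0) continue;
      for (int b = 0; b < 4; ++b)
        nxt[k + v[j][b] - new_lo] += p * pr[j][b];
    }
    dp.swap(nxt);
    off = new_lo; cur_lo = new_lo; cur_hi = new_hi;
  }
  const long thr = (long)std::ceil(threshold / delta - 1e-9);
  double tail = 0.0;
  for (long k = std::max(thr, cur_lo); k <= cur_hi; ++k) tail += dp[k - off];
  return tail;
}

// Tail probabilities P(score >= t) for several thresholds from one DP pass
// (same computation as cpp_score_tail, shared across thresholds).
// [[Rcpp::export]]
NumericVector cpp_score_tail_multi(const NumericMatrix& pwm,
                                   const NumericVector& bg,
                                   const NumericVector& thresholds,
                                   double delta) {
  const int w = pwm.ncol();
  std::vector<std::vector<int>> v(w, std::vector<int>(4));
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b)
      v[j][b] = (int)std::lround(
        std::log2(std::max(pwm(b, j), 1e-12) / bg[b]) / delta);
  long lo_sum = 0, hi_sum = 0;
  for (int j = 0; j < w; ++j) {
    int lo = v[j][0], hi = v[j][0];
    for (int b = 1; b < 4; ++b) { lo = std::min(lo, v[j][b]); hi = std::max(hi, v[j][b]); }
    lo_sum += lo; hi_sum += hi;
  }
  const long span = hi_sum - lo_sum + 1;
  std::vector<double> dp(span, 0.0), nxt(span, 0.0);
  long off = 0, cur_lo = 0, cur_hi = 0;
  dp[0] = 1.0;
  for (int j = 0; j < w; ++j) {
    int lo = v[j][0], hi = v[j][0];
    for (int b = 1; b < 4; ++b) { lo = std::min(lo, v[j][b]); hi = std::max(hi, v[j][b]); }
    long new_lo = cur_lo + lo, new_hi = cur_hi + hi;
    std::fill(nxt.begin(), nxt.end(), 0.0);
    for (long k = cur_lo; k <= cur_hi; ++k) {
      double p = dp[k - off];
      if (p == 0.0) continue;
      for (int b = 0; b < 4; ++b)
        nxt[k + v[j][b] - new_lo] += p * bg[b];
    }
    dp.swap(nxt);
    off = new_lo; cur_lo = new_lo; cur_hi = new_hi;
  }
  // suffix sums once, then lookup per threshold
  std::vector<double> suffix(span + 1, 0.0);
  for (long k = cur_hi; k >= cur_lo; --k)
    suffix[k - off] = suffix[k - off + 1] + dp[k - off];
  NumericVector out(thresholds.size());
  for (int t = 0; t < thresholds.size(); ++t) {
    long thr = (long)std::ceil(thresholds[t] / delta - 1e-9);
    if (thr <= cur_lo) out[t] = 1.0;
    else if (thr > cur_hi) out[t] = 0.0;
    else out[t] = suffix[thr - off];
  }
  return out;
}

// Number of promoters containing at least one window within `max_mismatch`
// of the given word (windows span both strands, so the reverse complement is
// covered).
// [[Rcpp::export]]
int cpp_near_match_promoters(const IntegerMatrix& windows,
                             const IntegerVector& prom, int n_prom,
                             const IntegerVector& word, int max_mismatch) {
  std::vector<char> hit(n_prom, 0);
  const int w = windows.ncol();
  for (int i = 0; i < windows.nrow(); ++i) {
    if (hit[prom[i]]) continue;
    int mm = 0;
    for (int j = 0; j < w; ++j) {
      mm += (windows(i, j) != word[j]);
      if (mm > max_mismatch) break;
    }
    if (mm <= max_mismatch) hit[prom[i]] = 1;
  }
  int k = 0;
  for (int p = 0; p < n_prom; ++p) k += hit[p];
  return k;
}

// Log2-odds score of every window under a PWM (used for strand-symmetry and
// invariance checks from R).
// [[Rcpp::export]]
NumericVector cpp_score_windows(const IntegerMatrix& windows,
                                const NumericMatrix& pwm,
                                const NumericVector& bg) {
  const int nwin = windows.nrow(), w = windows.ncol();
  std::vector<double> lo(4 * w);
  for (int j = 0; j < w; ++j)
    for (int b = 0; b < 4; ++b)
      lo[j * 4 + b] = std::log2(pwm(b, j) / bg[b]);
  NumericVector out(nwin);
  for (int i = 0; i < nwin; ++i) {
    double s = 0.0;
    for (int j = 0; j < w; ++j) s += lo[j * 4 + windows(i, j)];
    out[i] = s;
  }
  return out;
}
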