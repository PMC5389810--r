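#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Joint mean+variance GLR for a split after k of n observations, computed
// from partial sums.  MLE (1/n) variance estimates, floored at 1e-12 so
// noiseless fixtures do not blow up.
static inline double glr_from_sums(double Sl, double Ql, double Sn, double Qn,
                                   int k, int n) {
  const double vfloor = 1e-12;
  int m = n - k;
  double vl = (Ql - Sl * Sl / k) / k;
  double Sr = Sn - Sl, Qr = Qn - Ql;
  double vr = (Qr - Sr * Sr / m) / m;
  double vf = (Qn - Sn * Sn / n) / n;
  if (vl < vfloor) vl = vfloor;
  if (vr < vfloor) vr = vfloor;
  if (vf < vfloor) vf = vfloor;
  return n * std::log(vf) - k * std::log(vl) - m * std::log(vr);
}

// GLR statistic at every admissible split of a window.
// Returns a vector of length n-1 whose element k (1-based) is the statistic
// for a split after k observations; NA outside [min_side, n-min_side].
// [[Rcpp::export]]
NumericVector cpp_glr_scan(NumericVector x, int min_side) {
  int n = x.size();
  NumericVector out(std::max(n - 1, 0), NA_REAL);
  if (n < 2 * min_side) return out;
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    Q[i + 1] = Q[i] + x[i] * x[i];
  }
  for (int k = min_side; k <= n - min_side; ++k)
    out[k - 1] = glr_from_sums(S[k], Q[k], S[n], Q[n], k, n);
  return out;
}

// Threshold for run length t: h[t-1], holding the last value beyond the
// calibrated horizon.  Entries below the calibration start are +Inf.
static inline double h_at(const NumericVector& h, int t) {
  int nh = h.size();
  return (t <= nh) ? h[t - 1] : h[nh - 1];
}

// Sequential GLR monitor over a full stream.  Detection allowed once the
// current run holds at least max(startup, 2*min_side) observations; on
// detection the boundary is the argmax split and monitoring restarts there,
// re-consuming the detection-delay samples.
// [[Rcpp::export]]
List cpp_monitor(NumericVector x, NumericVector h, int startup, int min_side) {
  int n = x.size();
  std::vector<double> S(n + 1, 0.0), Q(n + 1, 0.0);
  for (int i = 0; i < n; ++i) {
    S[i + 1] = S[i] + x[i];
    Q[i + 1] = Q[i] + x[i] * x[i];
  }
  std::vector<int> bnd, delay, dettime;
  int tmin = std::max(startup, 2 * min_side);
  int run_start = 0;
  while (true) {
    bool detected = false;
    for (int e = run_start + tmin; e <= n; ++e) {
      int t = e - run_start;
      double Sn = S[e] - S[run_start], Qn = Q[e] - Q[run_start];
      double best = -1e300;
      int bestk = -1;
      for (int k = min_side; k <= t - min_side; ++k) {
        double Sl = S[run_start + k] - S[run_start];
        double Ql = Q[run_start + k] - Q[run_start];
        double g = glr_from_sums(Sl, Ql, Sn, Qn, k, t);
        if (g > best) { best = g; bestk = k; }
      }
      if (best > h_at(h, t)) {
        bnd.push_back(run_start + bestk);
        delay.push_back(t - bestk);
        dettime.push_back(e);
        run_start += bestk;  // restart at the estimated change point; the
                             // delay samples are re-consumed by the new run
        detected = true;
        break;
      }
    }
    if (!detected) break;
  }
  return List::create(_["boundaries"] = wrap(bnd),
                      _["delays"] = wrap(delay),
                      _["detection_times"] = wrap(dettime));
}

// Exponential-tail (peaks-over-threshold) estimate of the 1-alpha quantile
// of d (alive-stream statistics).  Stable even when alpha is far beyond the
// empirical range.
static double tail_quantile(std::vector<double> d, double alpha,
                            double tail_frac) {
  int n = d.size();
  std::sort(d.begin(), d.end());
  if (n * alpha >= 2.0) {        // tail well sampled: empirical quantile
    double pos = (1.0 - alpha) * (n - 1);
    int lo = (int)std::floor(pos);
    double w = pos - lo;
    return (1.0 - w) * d[lo] + w * d[std::min(lo + 1, n - 1)];
  }
  int m = std::max(20, (int)std::ceil(tail_frac * n));
  if (m >= n) m = std::max(1, n / 2);
  double u = d[n - m - 1 >= 0 ? n - m - 1 : 0];
  double excess = 0.0;
  for (int i = n - m; i < n; ++i) excess += d[i] - u;
  excess /= m;
  double ratio = (double)m / (n * alpha);
  if (ratio < 1e-12) ratio = 1e-12;
  return u + excess * std::log(ratio);
}

// Constant-hazard Monte-Carlo calibration of the threshold sequence h_t:
// simulate `reps` i.i.d. N(0,1) null streams, and at every run length
// t >= t_start set h_t to the estimated (1 - alpha) conditional quantile of
// the max-GLR statistic among streams not yet killed, then kill exceeders.
// Stops once fewer than `min_alive` streams survive (the tail of the curve
// is held constant by callers).  Uses the R RNG.
// [[Rcpp::export]]
List cpp_calibrate(int reps, int horizon, int min_side, double alpha,
                   int t_start, double tail_frac, int min_alive,
                   int pool_start) {
  RNGScope scope;
  NumericMatrix CS(reps, horizon + 1), CQ(reps, horizon + 1);
  std::vector<char> alive(reps, 1);
  std::vector<double> hs, pool;
  std::vector<int> ts, nal, pool_t;
  int n_alive = reps;
  if (t_start < 2 * min_side) t_start = 2 * min_side;
  for (int t = 1; t <= horizon; ++t) {
    for (int s = 0; s < reps; ++s) {
      if (!alive[s]) continue;
      double v = R::norm_rand();
      CS(s, t) = CS(s, t - 1) + v;
      CQ(s, t) = CQ(s, t - 1) + v * v;
    }
    if (t < t_start) continue;
    if (n_alive < min_alive) break;
    std::vector<double> d;
    d.reserve(n_alive);
    std::vector<int> idx;
    idx.reserve(n_alive);
    for (int s = 0; s < reps; ++s) {
      if (!alive[s]) continue;
      double Sn = CS(s, t), Qn = CQ(s, t);
      double best = -1e300;
      for (int k = min_side; k <= t - min_side; ++k) {
        double g = glr_from_sums(CS(s, k), CQ(s, k), Sn, Qn, k, t);
        if (g > best) best = g;
      }
      d.push_back(best);
      idx.push_back(s);
    }
    double h = tail_quantile(d, alpha, tail_frac);
    for (size_t j = 0; j < d.size(); ++j) {
      if (d[j] > h) { alive[idx[j]] = 0; --n_alive; }
    }
    if (t >= pool_start) {
      pool.insert(pool.end(), d.begin(), d.end());
      pool_t.insert(pool_t.end(), d.size(), t);
    }
    ts.push_back(t);
    hs.push_back(h);
    nal.push_back((int)d.size());
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["t"] = wrap(ts), _["h"] = wrap(hs),
                      _["n_alive"] = wrap(nal), _["pool"] = wrap(pool),
                      _["pool_t"] = wrap(pool_t));
}

// Run lengths to first alarm on fresh N(0,1) null streams under a given
// threshold sequence; censored at `cap`.  Uses the R RNG.
// [[Rcpp::export]]
List cpp_null_run_lengths(NumericVector h, int startup, int min_side,
                          int n_streams, int cap) {
  RNGScope scope;
  IntegerVector out(n_streams);
  LogicalVector censored(n_streams);
  int tmin = std::max(startup, 2 * min_side);
  std::vector<double> S(cap + 1), Q(cap + 1);
  for (int s = 0; s < n_streams; ++s) {
    S[0] = 0.0; Q[0] = 0.0;
    int alarm = -1;
    for (int t = 1; t <= cap; ++t) {
      double v = R::norm_rand();
      S[t] = S[t - 1] + v;
      Q[t] = Q[t - 1] + v * v;
      if (t < tmin) continue;
      double best = -1e300;
      for (int k = min_side; k <= t - min_side; ++k) {
        double g = glr_from_sums(S[k], Q[k], S[t], Q[t], k, t);
        if (g > best) best = g;
      }
      if (best > h_at(h, t)) { alarm = t; break; }
    }
    out[s] = (alarm > 0) ? alarm : cap;
    censored[s] = (alarm <= 0);
    Rcpp::checkUserInterrupt();
  }
  return List::create(_["run_length"] = out, _["censored"] = censored);
}

// K nearest training rows for every test row under Euclidean distance.
// Ties in distance are broken by training order (stable), so results are
// deterministic.  Returns a m x kmax matrix of 1-based training indices.
// [[Rcpp::export]]
IntegerMatrix cpp_knn_neighbors(NumericMatrix train, NumericMatrix test,
                                int kmax) {
  int n = train.nrow(), m = test.nrow(), p = train.ncol();
  if (kmax > n) stop("kmax exceeds the number of training rows");
  IntegerMatrix out(m, kmax);
  std::vector<double> d(n);
  std::vector<int> ord(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j) {
      double acc = 0.0;
      for (int c = 0; c < p; ++c) {
        double diff = test(i, c) - train(j, c);
        acc += diff * diff;
      }
      d[j] = acc;
      ord[j] = j;
    }
    std::partial_sort(ord.begin(), ord.begin() + kmax, ord.end(),
                      [&](int a, int b) {
                        if (d[a] != d[b]) return d[a] < d[b];
                        return a < b;
                      });
    for (int k = 0; k < kmax; ++k) out(i, k) = ord[k] + 1;
    if ((i & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// Majority vote over the first k neighbour labels; vote ties go to the
// smallest class index.  Labels are 1-based class indices.
// [[Rcpp::export]]
IntegerVector cpp_knn_vote(IntegerMatrix nbrs, IntegerVector train_labels,
                           int k, int n_classes) {
  int m = nbrs.nrow();
  if (k > nbrs.ncol()) stop("k exceeds stored neighbour count");
  IntegerVector out(m);
  std::vector<int> cnt(n_classes);
  for (int i = 0; i < m; ++i) {
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int j = 0; j < k; ++j) cnt[train_labels[nbrs(i, j) - 1] - 1]++;
    int best = 0;
    for (int c = 1; c < n_classes; ++c)
      if (cnt[c] > cnt[best]) best = c;
    out[i] = best + 1;
  }
  return out;
}
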