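#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Circular binary segmentation core.
//
// The candidate changepoints of a segment x[0..n-1], viewed as a circle,
// are arcs [i, j) (0-based half-open, 1 <= j - i <= n - 1).  For an arc of
// length k the statistic is
//   Z = (mean_in - mean_out) / (s * sqrt(1/k + 1/(n-k)))
// with s the two-group pooled SD.  We maximise Z^2 over all arcs; wrap-
// around arcs need not be enumerated because an arc and its complement
// give the same |Z|.  Ties are broken toward the smallest i, then the
// smallest j (the scan order below with a strict improvement test).
//
// Z^2 is evaluated as num/den with
//   num = (s_in/k - (T - s_in)/(n-k))^2
//   den = (Q - s_in^2/k - (T - s_in)^2/(n-k)) * (1/k + 1/(n-k)) / (n-2)
// so permutation scans can compare num >= thr * den without dividing.

struct ArcMax {
  double z2;   // maximal Z^2 (may be +Inf for noiseless steps)
  int i, j;    // arc [i, j), 0-based; -1 if no arc evaluated
};

// Complementary edge arcs ([0,k) vs [k,n)) have exactly equal |Z|; a
// strict floating-point comparison would break such ties arbitrarily.
// An improvement must beat the incumbent by this relative margin, so
// exact ties always resolve to the earliest (i, j) in scan order.
static const double TIE_REL = 1e-12;

static inline bool improves(double z2, double best) {
  if (best <= 0) return z2 > best;
  return z2 > best * (1 + TIE_REL);
}

static ArcMax scan_arcs(const double *xraw, int n, int min_width) {
  ArcMax best;
  best.z2 = -1.0;
  best.i = best.j = -1;

  bool constant = true;
  for (int t = 1; t < n; ++t)
    if (xraw[t] != xraw[0]) { constant = false; break; }
  if (constant) { best.z2 = 0.0; return best; }

  // center: the statistic is shift-invariant and centering improves the
  // conditioning of the sum-of-squares cancellation
  double m = 0.0;
  for (int t = 0; t < n; ++t) m += xraw[t];
  m /= n;
  std::vector<double> xc(n);
  for (int t = 0; t < n; ++t) xc[t] = xraw[t] - m;
  const double *x = xc.data();

  double total = 0.0, q = 0.0;
  for (int t = 0; t < n; ++t) {
    total += x[t];
    q += x[t] * x[t];
  }
  const double inv_nm2 = 1.0 / (n - 2 > 0 ? n - 2 : 1);
  std::vector<double> inv(n + 1);
  for (int k = 1; k <= n; ++k) inv[k] = 1.0 / k;

  for (int i = 0; i < n; ++i) {
    if (i != 0 && i < min_width) continue;  // left piece [0, i)
    double s_in = 0.0;
    for (int j = i + 1; j <= n; ++j) {
      s_in += x[j - 1];
      int k = j - i;
      if (k == n) continue;                       // arc must leave something out
      if (k < min_width) continue;                // middle piece
      if (j != n && n - j < min_width) continue;  // right piece
      double s_out = total - s_in;
      double m_in = s_in * inv[k];
      double m_out = s_out * inv[n - k];
      double ss = q - s_in * m_in - s_out * m_out;
      if (ss < 0) ss = 0;
      double diff = m_in - m_out;
      double denom = ss * inv_nm2 * (inv[k] + inv[n - k]);
      double z2;
      if (denom <= 0)
        z2 = (diff != 0.0) ? R_PosInf : 0.0;
      else
        z2 = diff * diff / denom;
      if (improves(z2, best.z2)) {
        best.z2 = z2;
        best.i = i;
        best.j = j;
      }
    }
  }
  if (best.z2 < 0) best.z2 = 0;  // nothing evaluated (constraints too tight)
  return best;
}

// Does any arc reach Z^2 >= thr?  Division-free inner loop with early
// exit; the exceed decision is identical to a full scan.
static bool scan_exceeds(const double *xraw, int n, double thr) {
  double m = 0.0;
  for (int t = 0; t < n; ++t) m += xraw[t];
  m /= n;
  std::vector<double> xc(n);
  for (int t = 0; t < n; ++t) xc[t] = xraw[t] - m;
  const double *x = xc.data();

  double total = 0.0, q = 0.0;
  for (int t = 0; t < n; ++t) {
    total += x[t];
    q += x[t] * x[t];
  }
  const double inv_nm2 = 1.0 / (n - 2 > 0 ? n - 2 : 1);
  std::vector<double> inv(n + 1), w(n + 1);
  for (int k = 1; k <= n; ++k) inv[k] = 1.0 / k;
  for (int k = 1; k < n; ++k) w[k] = (inv[k] + inv[n - k]) * inv_nm2;

  const bool thr_inf = (thr == R_PosInf);
  for (int i = 0; i < n; ++i) {
    double s_in = 0.0;
    const int j_max = (i == 0) ? n - 1 : n;  // skip k == n
    for (int j = i + 1; j <= j_max; ++j) {
      s_in += x[j - 1];
      int k = j - i;
      double s_out = total - s_in;
      double m_in = s_in * inv[k];
      double m_out = s_out * inv[n - k];
      double diff = m_in - m_out;
      double num = diff * diff;
      double ss = q - s_in * m_in - s_out * m_out;
      if (ss < 0) ss = 0;
      if (thr_inf) {
        if (ss * w[k] <= 0 && num > 0) return true;
      } else if (num >= thr * ss * w[k]) {
        return true;
      }
    }
  }
  return false;
}

// [[Rcpp::export(name = ".cbs_tmax_cpp")]]
List cbs_tmax_cpp(NumericVector x, int min_width = 1) {
  int n = x.size();
  if (n < 4) stop("need at least 4 values");
  ArcMax best = scan_arcs(REAL(x), n, min_width);
  double t = (best.z2 == R_PosInf) ? R_PosInf : std::sqrt(best.z2);
  return List::create(_["t_max"] = t,
                      _["i"] = best.i,   // 0-based arc start (-1: none)
                      _["j"] = best.j);  // 0-based arc end (exclusive)
}

// Permutation significance of the maximal arc.  p is the fraction of
// shuffles whose (unconstrained) T_max is >= the observed one.  Stops
// early once the exceedance count guarantees p > alpha: the split/no-split
// decision is then identical to the full n_perm run, and the RNG stream
// is consumed deterministically.
// [[Rcpp::export(name = ".cbs_perm_cpp")]]
List cbs_perm_cpp(NumericVector x, int n_perm, double alpha) {
  int n = x.size();
  if (n < 4) stop("need at least 4 values");
  ArcMax obs = scan_arcs(REAL(x), n, 1);

  if (obs.z2 <= 0) {  // constant segment: nothing to split
    return List::create(_["t_max"] = 0.0, _["i"] = obs.i, _["j"] = obs.j,
                        _["p"] = 1.0, _["n_perm_done"] = 0);
  }

  std::vector<double> perm(REAL(x), REAL(x) + n);
  int exceed = 0, done = 0;
  const double stop_count = alpha * n_perm;  // p > alpha certain once exceeded

  for (int b = 0; b < n_perm; ++b) {
    // Fisher-Yates using R's RNG so set.seed() governs everything
    for (int t = n - 1; t > 0; --t) {
      int idx = (int)(unif_rand() * (t + 1));
      if (idx > t) idx = t;
      std::swap(perm[t], perm[idx]);
    }
    ++done;
    if (scan_exceeds(perm.data(), n, obs.z2)) {
      ++exceed;
      if (exceed > stop_count) break;
    }
  }
  double t = (obs.z2 == R_PosInf) ? R_PosInf : std::sqrt(obs.z2);
  return List::create(_["t_max"] = t, _["i"] = obs.i, _["j"] = obs.j,
                      _["p"] = (double)exceed / done,
                      _["n_perm_done"] = done);
}
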