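// Permutation nulls for the cluster-corrected sliding-window test and the
// lag-constrained cross-correlation test.  Uses R's RNG so results are
// reproducible under set.seed().

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

static void fy_shuffle(std::vector<double>& v) {
  int n = (int)v.size();
  for (int i = n - 1; i > 0; --i) {
    int j = (int)std::floor(unif_rand() * (i + 1));
    if (j > i) j = i;
    std::swap(v[i], v[j]);
  }
}

// one-sample t per column, NA-aware; sd == 0 -> t = 0
static void col_t(const std::vector<std::vector<double>>& rows, int W,
                  std::vector<double>& t) {
  int S = (int)rows.size();
  for (int w = 0; w < W; ++w) {
    double s = 0, s2 = 0;
    int n = 0;
    for (int i = 0; i < S; ++i) {
      double v = rows[i][w];
      if (!ISNAN(v)) { s += v; s2 += v * v; ++n; }
    }
    if (n < 2) { t[w] = 0; continue; }
    double m = s / n;
    double var = (s2 - n * m * m) / (n - 1);
    if (var <= 0) {  // zero spread: perfect deviation unless mean is 0 too
      t[w] = (m == 0) ? 0 : (m > 0 ? 1e6 : -1e6);
      continue;
    }
    t[w] = m / std::sqrt(var / n);
  }
}

// max positive and max |negative| cluster mass of a thresholded t map
static void max_masses(const std::vector<double>& t, double tcrit,
                       double& maxpos, double& maxneg) {
  maxpos = 0;
  maxneg = 0;
  int W = (int)t.size();
  double mass = 0;
  int sign = 0;
  for (int w = 0; w <= W; ++w) {
    int s = 0;
    if (w < W) {
      if (t[w] > tcrit) s = 1;
      else if (t[w] < -tcrit) s = -1;
    }
    if (s != sign) {
      if (sign == 1 && mass > maxpos) maxpos = mass;
      if (sign == -1 && -mass > maxneg) maxneg = -mass;
      mass = 0;
      sign = s;
    }
    if (w < W && s != 0) mass += t[w];
  }
}

// scheme 0: random per-subject sign flips (preserves each subject's
// temporal autocorrelation; exact under a symmetric null).
// scheme 1: independent per-subject shuffles of the window labels.
//' @noRd
// [[Rcpp::export(name = ".cpp_cluster_perm_null")]]
NumericMatrix cpp_cluster_perm_null(NumericMatrix X, double tcrit, int nperm,
                                    int scheme) {
  int S = X.nrow(), W = X.ncol();
  std::vector<std::vector<double>> rows(S, std::vector<double>(W));
  for (int i = 0; i < S; ++i)
    for (int w = 0; w < W; ++w) rows[i][w] = X(i, w);
  std::vector<double> t(W);
  NumericMatrix out(nperm, 2);
  for (int p = 0; p < nperm; ++p) {
    if (scheme == 1) {
      for (int i = 0; i < S; ++i) fy_shuffle(rows[i]);
    } else {
      for (int i = 0; i < S; ++i) {
        if (unif_rand() < 0.5)
          for (int w = 0; w < W; ++w) rows[i][w] = -rows[i][w];
      }
    }
    col_t(rows, W, t);
    double mp, mn;
    max_masses(t, tcrit, mp, mn);
    out(p, 0) = mp;
    out(p, 1) = mn;
  }
  return out;
}

// Pearson r between a[0..n-1] and b[off..off+n-1]
static double pearson(const std::vector<double>& a,
                      const std::vector<double>& b, int off, int n) {
  double sx = 0, sy = 0, sxx = 0, syy = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    double x = a[i];
    double y = b[off + i];
    sx += x; sy += y; sxx += x * x; syy += y * y; sxy += x * y;
  }
  double vx = sxx - sx * sx / n, vy = syy - sy * sy / n;
  if (vx <= 0 || vy <= 0) return 0;
  return (sxy - sx * sy / n) / std::sqrt(vx * vy);
}

static double r_to_t(double r, int n) {
  double d = 1.0 - r * r;
  if (d < 1e-12) return (r > 0 ? 1.0 : -1.0) * 1e6;
  return r * std::sqrt((n - 2) / d);
}

// lag maps for both directions; K = max lag index
// dir1[k] = cor(a[0:n], b[k:k+n])   ("a precedes b", reported at -k)
// dir2[k] = cor(b[0:n], a[k:k+n])
static void lag_maps(const std::vector<double>& a, const std::vector<double>& b,
                     int K, std::vector<double>& d1, std::vector<double>& d2) {
  int N = (int)a.size();
  for (int k = 0; k <= K; ++k) {
    int n = N - k;
    d1[k] = pearson(a, b, k, n);  // cor(a[0:n], b[k:k+n])
    d2[k] = pearson(b, a, k, n);  // cor(b[0:n], a[k:k+n])
  }
}

//' @noRd
// [[Rcpp::export(name = ".cpp_xcorr_perm_null")]]
NumericMatrix cpp_xcorr_perm_null(NumericVector a, NumericVector b,
                                  int K, NumericVector tcrit, int nperm) {
  int N = a.size();
  if (b.size() != N) stop("traces differ in length");
  if (tcrit.size() != K + 1) stop("tcrit must have K+1 values");
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> d1(K + 1), d2(K + 1), t1(K + 1), t2(K + 1);
  NumericMatrix out(nperm, 4); // pos1, neg1, pos2, neg2
  for (int p = 0; p < nperm; ++p) {
    fy_shuffle(bv);
    lag_maps(av, bv, K, d1, d2);
    for (int k = 0; k <= K; ++k) {
      int n = N - k;
      double tt1 = r_to_t(d1[k], n), tt2 = r_to_t(d2[k], n);
      t1[k] = std::fabs(tt1) > tcrit[k] ? tt1 : 0;
      t2[k] = std::fabs(tt2) > tcrit[k] ? tt2 : 0;
    }
    double mp, mn;
    // reuse max_masses with tcrit 0 on pre-thresholded maps
    max_masses(t1, 0.0, mp, mn);
    out(p, 0) = mp;
    out(p, 1) = mn;
    max_masses(t2, 0.0, mp, mn);
    out(p, 2) = mp;
    out(p, 3) = mn;
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".cpp_lag_maps")]]
List cpp_lag_maps(NumericVector a, NumericVector b, int K) {
  int N = a.size();
  if (b.size() != N) stop("traces differ in length");
  std::vector<double> av(a.begin(), a.end()), bv(b.begin(), b.end());
  std::vector<double> d1(K + 1), d2(K + 1);
  lag_maps(av, bv, K, d1, d2);
  return List::create(_["ab"] = NumericVector(d1.begin(), d1.end()),
                      _["ba"] = NumericVector(d2.begin(), d2.end()));
}
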