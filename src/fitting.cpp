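// Levenberg-Marquardt fitting of MRS peak models over a ppm window.
//
// Models are evaluated analytically; the Jacobian is forward-difference.
// All fits include a linear baseline parameterised about the window centre
// so the normal equations stay well conditioned.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>

using namespace Rcpp;

// model ids (keep in sync with R/quantify.R)
// 1 lorentzian, 2 gaussian, 3 double_gaussian, 4 inverse_lorentzian

static void eval_real_model(int model, const double* p, const double* x,
                            double xmid, int n, double* out) {
  switch (model) {
  case 1: { // A, f0, g, b0, b1
    double A = p[0], f0 = p[1], g = std::fabs(p[2]);
    if (g < 1e-8) g = 1e-8;
    for (int i = 0; i < n; ++i) {
      double u = (x[i] - f0) / g;
      out[i] = A / (1.0 + u * u) + p[3] + p[4] * (x[i] - xmid);
    }
    break;
  }
  case 4: { // inverse lorentzian: negative lobe, A stored positive
    double A = p[0], f0 = p[1], g = std::fabs(p[2]);
    if (g < 1e-8) g = 1e-8;
    for (int i = 0; i < n; ++i) {
      double u = (x[i] - f0) / g;
      out[i] = -A / (1.0 + u * u) + p[3] + p[4] * (x[i] - xmid);
    }
    break;
  }
  case 2: { // A, f0, s, b0, b1
    double A = p[0], f0 = p[1], s = std::fabs(p[2]);
    if (s < 1e-8) s = 1e-8;
    for (int i = 0; i < n; ++i) {
      double u = (x[i] - f0) / s;
      out[i] = A * std::exp(-0.5 * u * u) + p[3] + p[4] * (x[i] - xmid);
    }
    break;
  }
  case 3: { // A1, A2, f01, f02, s, b0, b1  (shared width)
    double A1 = p[0], A2 = p[1], f1 = p[2], f2 = p[3], s = std::fabs(p[4]);
    if (s < 1e-8) s = 1e-8;
    for (int i = 0; i < n; ++i) {
      double u1 = (x[i] - f1) / s, u2 = (x[i] - f2) / s;
      out[i] = A1 * std::exp(-0.5 * u1 * u1) + A2 * std::exp(-0.5 * u2 * u2) +
        p[5] + p[6] * (x[i] - xmid);
    }
    break;
  }
  default:
    stop("unknown model id");
  }
}

// Generic damped Gauss-Newton (Levenberg-Marquardt) with numeric Jacobian.
// resid(p, r) fills the n-vector of residuals. Returns true on convergence.
static bool lm_minimise(std::function<void(const double*, double*)> resid,
                        std::vector<double>& p, int n, int maxit = 200) {
  const int np = (int)p.size();
  std::vector<double> r(n), rtry(n), J(n * np), g(np), delta(np),
    A(np * np), ptry(np);
  double lambda = 1e-3;

  auto sse = [&](const std::vector<double>& rr) {
    double s = 0;
    for (int i = 0; i < n; ++i) s += rr[i] * rr[i];
    return s;
  };

  resid(p.data(), r.data());
  double f = sse(r);
  if (!std::isfinite(f)) return false;

  for (int it = 0; it < maxit; ++it) {
    // numeric Jacobian of residuals
    for (int j = 0; j < np; ++j) {
      double h = 1e-6 * std::fabs(p[j]);
      if (h < 1e-9) h = 1e-9;
      ptry = p;
      ptry[j] += h;
      resid(ptry.data(), rtry.data());
      for (int i = 0; i < n; ++i) J[i * np + j] = (rtry[i] - r[i]) / h;
    }
    // g = J'r, A = J'J
    for (int j = 0; j < np; ++j) {
      g[j] = 0;
      for (int i = 0; i < n; ++i) g[j] += J[i * np + j] * r[i];
      for (int k = 0; k <= j; ++k) {
        double s = 0;
        for (int i = 0; i < n; ++i) s += J[i * np + j] * J[i * np + k];
        A[j * np + k] = A[k * np + j] = s;
      }
    }
    double gmax = 0;
    for (int j = 0; j < np; ++j) gmax = std::max(gmax, std::fabs(g[j]));
    if (gmax < 1e-14 * (1.0 + f)) return true;

    bool stepped = false;
    for (int tries = 0; tries < 40 && !stepped; ++tries) {
      // solve (A + lambda diag(A)) delta = -g via Cholesky
      std::vector<double> M(A);
      for (int j = 0; j < np; ++j) {
        double d = M[j * np + j];
        M[j * np + j] = d + lambda * (d > 0 ? d : 1.0);
      }
      // Cholesky
      bool ok = true;
      std::vector<double> L(np * np, 0.0);
      for (int j = 0; j < np && ok; ++j) {
        double s = M[j * np + j];
        for (int k = 0; k < j; ++k) s -= L[j * np + k] * L[j * np + k];
        if (s <= 0) { ok = false; break; }
        L[j * np + j] = std::sqrt(s);
        for (int i = j + 1; i < np; ++i) {
          double t = M[i * np + j];
          for (int k = 0; k < j; ++k) t -= L[i * np + k] * L[j * np + k];
          L[i * np + j] = t / L[j * np + j];
        }
      }
      if (!ok) { lambda *= 10; continue; }
      // forward/back solve L L' delta = -g
      std::vector<double> ytmp(np);
      for (int i = 0; i < np; ++i) {
        double s = -g[i];
        for (int k = 0; k < i; ++k) s -= L[i * np + k] * ytmp[k];
        ytmp[i] = s / L[i * np + i];
      }
      for (int i = np - 1; i >= 0; --i) {
        double s = ytmp[i];
        for (int k = i + 1; k < np; ++k) s -= L[k * np + i] * delta[k];
        delta[i] = s / L[i * np + i];
      }
      for (int j = 0; j < np; ++j) ptry[j] = p[j] + delta[j];
      resid(ptry.data(), rtry.data());
      double ftry = sse(rtry);
      if (std::isfinite(ftry) && ftry < f) {
        double rel = (f - ftry) / (f + 1e-300);
        p = ptry;
        r = rtry;
        f = ftry;
        lambda = std::max(lambda / 3.0, 1e-12);
        stepped = true;
        if (rel < 1e-12) return true;
      } else {
        lambda *= 10;
        // no downhill step exists: already at a (local) minimum
        if (lambda > 1e12) return true;
      }
    }
    if (!stepped) return true;
  }
  return true; // hit maxit with steady progress; caller checks residuals
}

// Fit one real-valued peak model + linear baseline.
// init: f0 (length 1 or 2) and width starting values.
static void fit_real_one(int model, const double* x, const double* y, int n,
                         const std::vector<double>& f0_init, double w_init,
                         std::vector<double>& p, bool& conv, double& resid_sd) {
  double xmid = 0.5 * (x[0] + x[n - 1]);
  // crude baseline init from window edges
  int ne = std::max(2, n / 10);
  double b0 = 0;
  for (int i = 0; i < ne; ++i) b0 += y[i] + y[n - 1 - i];
  b0 /= (2.0 * ne);

  if (model == 1 || model == 2 || model == 4) {
    // locate extremum
    int idx = 0;
    double best = model == 4 ? (y[0] - b0) : -(y[0] - b0);
    for (int i = 1; i < n; ++i) {
      double v = y[i] - b0;
      double sc = model == 4 ? v : -v;
      if (sc < best) { best = sc; idx = i; }
    }
    double A = std::fabs(y[idx] - b0);
    if (A < 1e-12) A = 1e-12;
    p = {A, x[idx], w_init, b0, 0.0};
  } else { // double gaussian
    double A = 0;
    for (int i = 0; i < n; ++i) A = std::max(A, y[i] - b0);
    if (A < 1e-12) A = 1e-12;
    p = {A, A, f0_init[0], f0_init[1], w_init, b0, 0.0};
  }

  std::vector<double> m(n);
  auto resid = [&](const double* pp, double* out) {
    eval_real_model(model, pp, x, xmid, n, m.data());
    for (int i = 0; i < n; ++i) out[i] = y[i] - m[i];
  };
  conv = lm_minimise(resid, p, n);
  // widths positive by construction
  if (model == 3) p[4] = std::fabs(p[4]); else p[2] = std::fabs(p[2]);
  std::vector<double> r(n);
  resid(p.data(), r.data());
  double s = 0;
  for (int i = 0; i < n; ++i) s += r[i] * r[i];
  int np = (int)p.size();
  int dof = n - np;
  resid_sd = dof > 0 ? std::sqrt(s / dof) : std::sqrt(s / n);
}

//' @noRd
// [[Rcpp::export(name = ".cpp_fit_peaks")]]
NumericMatrix cpp_fit_peaks(NumericMatrix Y, NumericVector x, int model,
                            NumericVector f0_init, double w_init) {
  int nr = Y.nrow(), n = Y.ncol();
  if (x.size() != n) stop("x length must match ncol(Y)");
  int np = model == 3 ? 7 : 5;
  NumericMatrix out(nr, np + 2); // params..., resid_sd, conv
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> f0v(f0_init.begin(), f0_init.end());
  std::vector<double> yv(n), p;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < n; ++j) yv[j] = Y(i, j);
    bool conv;
    double rsd;
    fit_real_one(model, xv.data(), yv.data(), n, f0v, w_init, p, conv, rsd);
    for (int j = 0; j < np; ++j) out(i, j) = p[j];
    out(i, np) = rsd;
    out(i, np + 1) = conv ? 1.0 : 0.0;
  }
  return out;
}

// Complex Lorentzian reference fit: e^{i phi} * A * (1 - i u)/(1 + u^2)
// + complex linear baseline; u = (x - f0)/g.  Params:
// A, f0, g, phi, br0, br1, bi0, bi1
//' @noRd
// [[Rcpp::export(name = ".cpp_fit_ref")]]
NumericMatrix cpp_fit_ref(NumericMatrix RE, NumericMatrix IM, NumericVector x,
                          double w_init) {
  int nr = RE.nrow(), n = RE.ncol();
  if (IM.nrow() != nr || IM.ncol() != n) stop("RE/IM dims differ");
  double xmid = 0.5 * (x[0] + x[n - 1]);
  NumericMatrix out(nr, 6); // A, f0, g, phi, resid_sd, conv
  std::vector<double> xv(x.begin(), x.end());
  std::vector<double> re(n), im(n);

  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < n; ++j) { re[j] = RE(i, j); im[j] = IM(i, j); }
    int idx = 0;
    double best = -1;
    for (int j = 0; j < n; ++j) {
      double mag = re[j] * re[j] + im[j] * im[j];
      if (mag > best) { best = mag; idx = j; }
    }
    double A0 = std::sqrt(best);
    if (A0 < 1e-12) A0 = 1e-12;
    double phi0 = std::atan2(im[idx], re[idx]);
    std::vector<double> p = {A0, xv[idx], w_init, phi0, 0, 0, 0, 0};

    auto resid = [&](const double* pp, double* outr) {
      double A = pp[0], f0 = pp[1], g = std::fabs(pp[2]), phi = pp[3];
      if (g < 1e-8) g = 1e-8;
      double cp = std::cos(phi), sp = std::sin(phi);
      for (int j = 0; j < n; ++j) {
        double u = (xv[j] - f0) / g;
        double den = 1.0 + u * u;
        double lr = A / den, li = -A * u / den;
        double mr = lr * cp - li * sp + pp[4] + pp[5] * (xv[j] - xmid);
        double mi = lr * sp + li * cp + pp[6] + pp[7] * (xv[j] - xmid);
        outr[j] = re[j] - mr;
        outr[n + j] = im[j] - mi;
      }
    };
    bool conv = lm_minimise(resid, p, 2 * n);
    std::vector<double> r(2 * n);
    resid(p.data(), r.data());
    double s = 0;
    for (int j = 0; j < 2 * n; ++j) s += r[j] * r[j];
    double rsd = std::sqrt(s / std::max(1, 2 * n - 8));
    // wrap phase into (-pi, pi], keep amplitude positive
    double A = p[0], phi = p[3];
    if (A < 0) { A = -A; phi += M_PI; }
    phi = std::atan2(std::sin(phi), std::cos(phi));
    out(i, 0) = A;
    out(i, 1) = p[1];
    out(i, 2) = std::fabs(p[2]);
    out(i, 3) = phi;
    out(i, 4) = rsd;
    out(i, 5) = conv ? 1.0 : 0.0;
  }
  return out;
}
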