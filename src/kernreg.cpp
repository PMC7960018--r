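// 3D kernel regression engines: classical (isotropic Gaussian) order-2 local
// polynomial fits for the initial value/gradient field, gradient-covariance
// estimation with eigenvalue-based regularization, and the adaptive steering
// kernel regression update.  Offsets are in voxel units on the isotropic
// reconstruction grid.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// order-2 design row for offset d: [1, d, vech(d d^T)]
static inline void design_row(double d0, double d1, double d2, double* x) {
  x[0] = 1.0; x[1] = d0; x[2] = d1; x[3] = d2;
  x[4] = d0 * d0; x[5] = d0 * d1; x[6] = d0 * d2;
  x[7] = d1 * d1; x[8] = d1 * d2; x[9] = d2 * d2;
}

// Weighted order-2 local fit from accumulated normal equations; falls back to
// the order-0 weighted mean (zero gradient) when the neighborhood is too
// small or the system is ill-conditioned (rcond < 1e-10, i.e. cond > 1e10).
static inline void solve_or_fallback(const arma::mat& A, const arma::vec& b,
                                     long L, double sw, double swy,
                                     double& beta0, double* grad, bool& fell) {
  fell = true;
  beta0 = (sw > 0.0) ? swy / sw : NA_REAL;
  grad[0] = grad[1] = grad[2] = 0.0;
  if (L < 10 || sw <= 0.0) return;
  if (arma::rcond(A) < 1e-10) return;
  arma::vec beta;
  if (!arma::solve(beta, A, b, arma::solve_opts::no_approx)) return;
  if (!beta.is_finite()) return;
  beta0 = beta(0);
  grad[0] = beta(1); grad[1] = beta(2); grad[2] = beta(3);
  fell = false;
}

// Classical kernel regression over the whole grid: at every voxel, fit the
// known voxels in a kc^3 window with isotropic Gaussian weights
// exp(-|d|^2 / (2 hc^2)), returning the value and gradient fields.
// [[Rcpp::export]]
List cpp_classical_kr_field(const arma::cube& Y, const arma::cube& known,
                            int kc, double hc) {
  const int d0 = Y.n_rows, d1 = Y.n_cols, d2 = Y.n_slices;
  const int r = kc / 2;
  arma::cube beta0(d0, d1, d2, arma::fill::zeros);
  arma::cube gx(d0, d1, d2, arma::fill::zeros);
  arma::cube gy(d0, d1, d2, arma::fill::zeros);
  arma::cube gz(d0, d1, d2, arma::fill::zeros);
  arma::cube est(d0, d1, d2, arma::fill::zeros);
  long n_fallback = 0, n_empty = 0;
  arma::mat A(10, 10);
  arma::vec b(10);
  double x[10];
  const double inv2h2 = 1.0 / (2.0 * hc * hc);
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++) {
        A.zeros(); b.zeros();
        double sw = 0.0, swy = 0.0;
        long L = 0;
        for (int qk = std::max(k - r, 0); qk <= std::min(k + r, d2 - 1); qk++)
          for (int qj = std::max(j - r, 0); qj <= std::min(j + r, d1 - 1); qj++)
            for (int qi = std::max(i - r, 0); qi <= std::min(i + r, d0 - 1); qi++) {
              if (known(qi, qj, qk) == 0.0) continue;
              const double o0 = qi - i, o1 = qj - j, o2 = qk - k;
              const double w = std::exp(-(o0 * o0 + o1 * o1 + o2 * o2) * inv2h2);
              const double y = Y(qi, qj, qk);
              design_row(o0, o1, o2, x);
              for (int a = 0; a < 10; a++) {
                b(a) += w * x[a] * y;
                for (int c = a; c < 10; c++) A(a, c) += w * x[a] * x[c];
              }
              sw += w; swy += w * y;
              L++;
            }
        if (L == 0) { n_empty++; est(i, j, k) = 0.0; continue; }
        A = arma::symmatu(A);
        double b0, g[3]; bool fell;
        solve_or_fallback(A, b, L, sw, swy, b0, g, fell);
        if (fell) n_fallback++;
        beta0(i, j, k) = b0;
        gx(i, j, k) = g[0]; gy(i, j, k) = g[1]; gz(i, j, k) = g[2];
        est(i, j, k) = 1.0;
      }
  return List::create(_["beta0"] = beta0, _["gx"] = gx, _["gy"] = gy,
                      _["gz"] = gz, _["estimated"] = est,
                      _["n_fallback"] = (double)n_fallback,
                      _["n_empty"] = (double)n_empty);
}

// Per-voxel sum of gradient outer products over a w^3 analysis window
// (naive structure-tensor estimate) plus the sample count L per voxel.
// [[Rcpp::export]]
List cpp_covariance_field(const arma::cube& gx, const arma::cube& gy,
                          const arma::cube& gz, int w) {
  const int d0 = gx.n_rows, d1 = gx.n_cols, d2 = gx.n_slices;
  const int r = w / 2;
  arma::cube cxx(d0, d1, d2, arma::fill::zeros), cxy = cxx, cxz = cxx,
             cyy = cxx, cyz = cxx, czz = cxx, Ln = cxx;
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++) {
        double sxx = 0, sxy = 0, sxz = 0, syy = 0, syz = 0, szz = 0;
        long L = 0;
        for (int qk = std::max(k - r, 0); qk <= std::min(k + r, d2 - 1); qk++)
          for (int qj = std::max(j - r, 0); qj <= std::min(j + r, d1 - 1); qj++)
            for (int qi = std::max(i - r, 0); qi <= std::min(i + r, d0 - 1); qi++) {
              const double a = gx(qi, qj, qk), b = gy(qi, qj, qk),
                           c = gz(qi, qj, qk);
              sxx += a * a; sxy += a * b; sxz += a * c;
              syy += b * b; syz += b * c; szz += c * c;
              L++;
            }
        cxx(i, j, k) = sxx; cxy(i, j, k) = sxy; cxz(i, j, k) = sxz;
        cyy(i, j, k) = syy; cyz(i, j, k) = syz; czz(i, j, k) = szz;
        Ln(i, j, k) = (double)L;
      }
  return List::create(_["cxx"] = cxx, _["cxy"] = cxy, _["cxz"] = cxz,
                      _["cyy"] = cyy, _["cyz"] = cyz, _["czz"] = czz,
                      _["L"] = Ln);
}

// Eigenvalue-based regularization of the naive covariances:
//   a_k   = (s_k + lam) / prod_{j != k} (s_j + lam)^{1/2}   (elongation)
//   gamma = (prod_k (s_k + lam)^{1/2} / L)^alpha            (footprint scale)
//   C     = gamma * U diag(a) U^T
// which is SPD for lam > 0, isotropic in flat regions, and scale-insensitive
// at alpha = 0.
// [[Rcpp::export]]
List cpp_regularize_field(const arma::cube& cxx, const arma::cube& cxy,
                          const arma::cube& cxz, const arma::cube& cyy,
                          const arma::cube& cyz, const arma::cube& czz,
                          const arma::cube& Ln, double alpha, double lam) {
  const int d0 = cxx.n_rows, d1 = cxx.n_cols, d2 = cxx.n_slices;
  arma::cube rxx(d0, d1, d2), rxy(d0, d1, d2), rxz(d0, d1, d2),
             ryy(d0, d1, d2), ryz(d0, d1, d2), rzz(d0, d1, d2);
  arma::mat33 C, U, R;
  arma::vec3 s;
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++) {
        C(0, 0) = cxx(i, j, k); C(0, 1) = cxy(i, j, k); C(0, 2) = cxz(i, j, k);
        C(1, 0) = C(0, 1);      C(1, 1) = cyy(i, j, k); C(1, 2) = cyz(i, j, k);
        C(2, 0) = C(0, 2);      C(2, 1) = C(1, 2);      C(2, 2) = czz(i, j, k);
        arma::eig_sym(s, U, C);  // ascending eigenvalues
        double sp[3] = { std::max(s(0), 0.0) + lam, std::max(s(1), 0.0) + lam,
                         std::max(s(2), 0.0) + lam };
        const double L = std::max(Ln(i, j, k), 1.0);
        double a[3];
        a[0] = sp[0] / std::sqrt(sp[1] * sp[2]);
        a[1] = sp[1] / std::sqrt(sp[0] * sp[2]);
        a[2] = sp[2] / std::sqrt(sp[0] * sp[1]);
        const double gamma = std::pow(std::sqrt(sp[0] * sp[1] * sp[2]) / L,
                                      alpha);
        R.zeros();
        for (int e = 0; e < 3; e++)
          for (int rr = 0; rr < 3; rr++)
            for (int cc = 0; cc < 3; cc++)
              R(rr, cc) += gamma * a[e] * U(rr, e) * U(cc, e);
        rxx(i, j, k) = R(0, 0); rxy(i, j, k) = R(0, 1); rxz(i, j, k) = R(0, 2);
        ryy(i, j, k) = R(1, 1); ryz(i, j, k) = R(1, 2); rzz(i, j, k) = R(2, 2);
      }
  return List::create(_["cxx"] = rxx, _["cxy"] = rxy, _["cxz"] = rxz,
                      _["cyy"] = ryy, _["cyz"] = ryz, _["czz"] = rzz);
}

// One steering kernel regression sweep: re-estimate every voxel from the
// known voxels in a ks^3 window with data-adapted weights
//   K_s(d) = sqrt(det C_i) / (2 pi h^2) * exp(-d^T C_i d / (2 h^2)),
// C_i taken at the known sample voxel.  Y holds the known data values; prev
// is the current estimate (kept where a voxel has no known neighbor).  ops
// counts neighbor visits (the arithmetic work of the sweep).
// [[Rcpp::export]]
List cpp_steering_field(const arma::cube& Y, const arma::cube& known,
                        const arma::cube& prev,
                        const arma::cube& cxx, const arma::cube& cxy,
                        const arma::cube& cxz, const arma::cube& cyy,
                        const arma::cube& cyz, const arma::cube& czz,
                        int ks, double hs) {
  const int d0 = Y.n_rows, d1 = Y.n_cols, d2 = Y.n_slices;
  const int r = ks / 2;
  arma::cube beta0 = prev;
  arma::cube gx(d0, d1, d2, arma::fill::zeros), gy = gx, gz = gx;
  arma::cube est(d0, d1, d2, arma::fill::zeros);
  const double inv2h2 = 1.0 / (2.0 * hs * hs);
  const double norm = 1.0 / (2.0 * M_PI * hs * hs);
  long n_unfilled = 0, n_fallback = 0;
  double ops = 0.0;
  arma::mat A(10, 10);
  arma::vec b(10);
  double x[10];
  for (int k = 0; k < d2; k++)
    for (int j = 0; j < d1; j++)
      for (int i = 0; i < d0; i++) {
        A.zeros(); b.zeros();
        double sw = 0.0, swy = 0.0;
        long L = 0;
        for (int qk = std::max(k - r, 0); qk <= std::min(k + r, d2 - 1); qk++)
          for (int qj = std::max(j - r, 0); qj <= std::min(j + r, d1 - 1); qj++)
            for (int qi = std::max(i - r, 0); qi <= std::min(i + r, d0 - 1); qi++) {
              if (known(qi, qj, qk) == 0.0) continue;
              ops += 1.0;
              const double o0 = qi - i, o1 = qj - j, o2 = qk - k;
              const double a11 = cxx(qi, qj, qk), a12 = cxy(qi, qj, qk),
                           a13 = cxz(qi, qj, qk), a22 = cyy(qi, qj, qk),
                           a23 = cyz(qi, qj, qk), a33 = czz(qi, qj, qk);
              const double det = a11 * (a22 * a33 - a23 * a23) -
                                 a12 * (a12 * a33 - a23 * a13) +
                                 a13 * (a12 * a23 - a22 * a13);
              const double quad = a11 * o0 * o0 + a22 * o1 * o1 + a33 * o2 * o2 +
                                  2.0 * (a12 * o0 * o1 + a13 * o0 * o2 +
                                         a23 * o1 * o2);
              const double e = quad * inv2h2;
              if (e > 46.0) continue;   // exp(-e) < 1e-20 of the peak weight
              const double w = norm * std::sqrt(std::max(det, 0.0)) *
                               std::exp(-e);
              if (w < 1e-300) continue;
              const double y = Y(qi, qj, qk);
              design_row(o0, o1, o2, x);
              for (int a = 0; a < 10; a++) {
                b(a) += w * x[a] * y;
                for (int c = a; c < 10; c++) A(a, c) += w * x[a] * x[c];
              }
              sw += w; swy += w * y;
              L++;
            }
        if (L == 0 || sw <= 0.0) { n_unfilled++; continue; }
        A = arma::symmatu(A);
        double b0, g[3]; bool fell;
        solve_or_fallback(A, b, L, sw, swy, b0, g, fell);
        if (fell) n_fallback++;
        beta0(i, j, k) = b0;
        gx(i, j, k) = g[0]; gy(i, j, k) = g[1]; gz(i, j, k) = g[2];
        est(i, j, k) = 1.0;
      }
  return List::create(_["beta0"] = beta0, _["gx"] = gx, _["gy"] = gy,
                      _["gz"] = gz, _["estimated"] = est,
                      _["n_unfilled"] = (double)n_unfilled,
                      _["n_fallback"] = (double)n_fallback, _["ops"] = ops);
}
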