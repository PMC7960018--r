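// Mean structural similarity over all fully-contained cubic windows at
// stride 1, with the standard stabilizers c1 = (k1 L)^2, c2 = (k2 L)^2.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// [[Rcpp::export]]
List cpp_mssim(const arma::cube& z, const arma::cube& g, int win, double L,
               double k1, double k2) {
  const int d0 = z.n_rows, d1 = z.n_cols, d2 = z.n_slices;
  if (win > d0 || win > d1 || win > d2)
    stop("window larger than volume");
  const double c1 = (k1 * L) * (k1 * L), c2 = (k2 * L) * (k2 * L);
  const double n = (double)win * win * win;
  double acc = 0.0;
  long M = 0;
  for (int k = 0; k + win <= d2; k++)
    for (int j = 0; j + win <= d1; j++)
      for (int i = 0; i + win <= d0; i++) {
        double sz = 0, sg = 0, szz = 0, sgg = 0, szg = 0;
        for (int qk = k; qk < k + win; qk++)
          for (int qj = j; qj < j + win; qj++)
            for (int qi = i; qi < i + win; qi++) {
              const double a = z(qi, qj, qk), b = g(qi, qj, qk);
              sz += a; sg += b; szz += a * a; sgg += b * b; szg += a * b;
            }
        const double mz = sz / n, mg = sg / n;
        const double vz = szz / n - mz * mz, vg = sgg / n - mg * mg;
        const double cv = szg / n - mz * mg;
        acc += ((2 * mz * mg + c1) * (2 * cv + c2)) /
               ((mz * mz + mg * mg + c1) * (vz + vg + c2));
        M++;
      }
  return List::create(_["mssim"] = acc / M, _["M"] = (double)M);
}
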