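// Gaussian-PSF scatter/gather between 2D slices and the 3D reconstruction
// grid, plus the NCC similarity kernels used by the rigid registrations.
// Voxel/pixel indices are 0-based; voxel centers sit at integer indices.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Trilinear sample of V at 0-based continuous index (x,y,z).
// Returns false when the sample point falls outside the grid.
static inline bool trilinear(const arma::cube& V, double x, double y, double z,
                             double& out) {
  const int nx = V.n_rows, ny = V.n_cols, nz = V.n_slices;
  if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
        x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0))
    return false;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  if (nx == 1) x0 = 0;
  if (ny == 1) y0 = 0;
  if (nz == 1) z0 = 0;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const int x1 = std::min(x0 + 1, nx - 1), y1 = std::min(y0 + 1, ny - 1),
            z1 = std::min(z0 + 1, nz - 1);
  const double c000 = V(x0, y0, z0), c100 = V(x1, y0, z0),
               c010 = V(x0, y1, z0), c110 = V(x1, y1, z0),
               c001 = V(x0, y0, z1), c101 = V(x1, y0, z1),
               c011 = V(x0, y1, z1), c111 = V(x1, y1, z1);
  out = c000 * (1 - fx) * (1 - fy) * (1 - fz) + c100 * fx * (1 - fy) * (1 - fz) +
        c010 * (1 - fx) * fy * (1 - fz) + c110 * fx * fy * (1 - fz) +
        c001 * (1 - fx) * (1 - fy) * fz + c101 * fx * (1 - fy) * fz +
        c011 * (1 - fx) * fy * fz + c111 * fx * fy * fz;
  return true;
}

// Scatter valid slice pixels into a volume accumulator under the truncated
// separable Gaussian PSF.  For each slice, A maps the homogeneous pixel index
// [i, j, 0, 1] to a continuous voxel coordinate and M maps a voxel-index
// offset to millimetre offsets expressed in the slice frame (in-plane x,
// in-plane y, through-plane z), so the PSF widths apply along their own axes.
// values[[s]] carries the (already corrected, optionally residual-weighted)
// intensities; pixw[[s]] an optional per-pixel multiplier on the PSF weight.
// [[Rcpp::export]]
List cpp_scatter_slices(List values, List masks, List pixw, List A, List M,
                        IntegerVector dim, NumericVector sigma, double support) {
  arma::cube accum(dim[0], dim[1], dim[2], arma::fill::zeros);
  arma::cube wsum(dim[0], dim[1], dim[2], arma::fill::zeros);
  const double sx = sigma[0], sy = sigma[1], sz = sigma[2];
  const double bx = support * sx, by = support * sy, bz = support * sz;
  int n_oob = 0;
  for (int s = 0; s < values.size(); s++) {
    NumericMatrix px = values[s];
    LogicalMatrix mk = masks[s];
    NumericMatrix Am = A[s];
    NumericMatrix Mm = M[s];
    bool has_pw = !Rf_isNull(pixw[s]);
    NumericMatrix pw = has_pw ? NumericMatrix(as<NumericMatrix>(pixw[s]))
                              : NumericMatrix(1, 1);
    // voxel-index search radius per axis (columns of M give mm per voxel step)
    double rad_mm = support * std::max(sx, std::max(sy, sz));
    double step[3], rad[3];
    for (int a = 0; a < 3; a++) {
      step[a] = std::sqrt(Mm(0, a) * Mm(0, a) + Mm(1, a) * Mm(1, a) +
                          Mm(2, a) * Mm(2, a));
      rad[a] = rad_mm / std::max(step[a], 1e-12);
    }
    for (int j = 0; j < px.ncol(); j++) {
      for (int i = 0; i < px.nrow(); i++) {
        if (!mk(i, j)) continue;
        const double v = px(i, j);
        const double pm = has_pw ? pw(i, j) : 1.0;
        // continuous voxel coordinate of this pixel
        const double cx = Am(0, 0) * i + Am(0, 1) * j + Am(0, 3);
        const double cy = Am(1, 0) * i + Am(1, 1) * j + Am(1, 3);
        const double cz = Am(2, 0) * i + Am(2, 1) * j + Am(2, 3);
        const int lo0 = (int)std::ceil(cx - rad[0]), hi0 = (int)std::floor(cx + rad[0]);
        const int lo1 = (int)std::ceil(cy - rad[1]), hi1 = (int)std::floor(cy + rad[1]);
        const int lo2 = (int)std::ceil(cz - rad[2]), hi2 = (int)std::floor(cz + rad[2]);
        bool touched = false;
        for (int q2 = std::max(lo2, 0); q2 <= std::min(hi2, dim[2] - 1); q2++)
          for (int q1 = std::max(lo1, 0); q1 <= std::min(hi1, dim[1] - 1); q1++)
            for (int q0 = std::max(lo0, 0); q0 <= std::min(hi0, dim[0] - 1); q0++) {
              const double o0 = q0 - cx, o1 = q1 - cy, o2 = q2 - cz;
              const double dx = Mm(0, 0) * o0 + Mm(0, 1) * o1 + Mm(0, 2) * o2;
              const double dy = Mm(1, 0) * o0 + Mm(1, 1) * o1 + Mm(1, 2) * o2;
              const double dz = Mm(2, 0) * o0 + Mm(2, 1) * o1 + Mm(2, 2) * o2;
              if (std::abs(dx) > bx || std::abs(dy) > by || std::abs(dz) > bz)
                continue;
              const double w = std::exp(-0.5 * (dx * dx / (sx * sx) +
                                                dy * dy / (sy * sy) +
                                                dz * dz / (sz * sz)));
              accum(q0, q1, q2) += w * pm * v;
              wsum(q0, q1, q2) += w * pm;
              touched = true;
            }
        if (!touched) n_oob++;
      }
    }
  }
  return List::create(_["accum"] = accum, _["wsum"] = wsum, _["n_oob"] = n_oob);
}

// Forward-simulate slices from a volume: each pixel is the PSF-weighted
// average of known voxels in its footprint (the adjoint of the scatter).
// Pixels with an empty footprint come back NA.
// [[Rcpp::export]]
List cpp_simulate_slices(const arma::cube& vol, const arma::cube& known,
                         List shapes, List A, List M, NumericVector sigma,
                         double support) {
  const double sx = sigma[0], sy = sigma[1], sz = sigma[2];
  const double bx = support * sx, by = support * sy, bz = support * sz;
  const int d0 = vol.n_rows, d1 = vol.n_cols, d2 = vol.n_slices;
  List out(shapes.size());
  for (int s = 0; s < shapes.size(); s++) {
    IntegerVector sh = shapes[s];
    NumericMatrix Am = A[s];
    NumericMatrix Mm = M[s];
    NumericMatrix sim(sh[0], sh[1]);
    double rad_mm = support * std::max(sx, std::max(sy, sz));
    double rad[3];
    for (int a = 0; a < 3; a++) {
      double st = std::sqrt(Mm(0, a) * Mm(0, a) + Mm(1, a) * Mm(1, a) +
                            Mm(2, a) * Mm(2, a));
      rad[a] = rad_mm / std::max(st, 1e-12);
    }
    for (int j = 0; j < sh[1]; j++)
      for (int i = 0; i < sh[0]; i++) {
        const double cx = Am(0, 0) * i + Am(0, 1) * j + Am(0, 3);
        const double cy = Am(1, 0) * i + Am(1, 1) * j + Am(1, 3);
        const double cz = Am(2, 0) * i + Am(2, 1) * j + Am(2, 3);
        const int lo0 = (int)std::ceil(cx - rad[0]), hi0 = (int)std::floor(cx + rad[0]);
        const int lo1 = (int)std::ceil(cy - rad[1]), hi1 = (int)std::floor(cy + rad[1]);
        const int lo2 = (int)std::ceil(cz - rad[2]), hi2 = (int)std::floor(cz + rad[2]);
        double num = 0.0, den = 0.0;
        for (int q2 = std::max(lo2, 0); q2 <= std::min(hi2, d2 - 1); q2++)
          for (int q1 = std::max(lo1, 0); q1 <= std::min(hi1, d1 - 1); q1++)
            for (int q0 = std::max(lo0, 0); q0 <= std::min(hi0, d0 - 1); q0++) {
              if (known(q0, q1, q2) == 0.0) continue;
              const double o0 = q0 - cx, o1 = q1 - cy, o2 = q2 - cz;
              const double dx = Mm(0, 0) * o0 + Mm(0, 1) * o1 + Mm(0, 2) * o2;
              const double dy = Mm(1, 0) * o0 + Mm(1, 1) * o1 + Mm(1, 2) * o2;
              const double dz = Mm(2, 0) * o0 + Mm(2, 1) * o1 + Mm(2, 2) * o2;
              if (std::abs(dx) > bx || std::abs(dy) > by || std::abs(dz) > bz)
                continue;
              const double w = std::exp(-0.5 * (dx * dx / (sx * sx) +
                                                dy * dy / (sy * sy) +
                                                dz * dz / (sz * sz)));
              num += w * vol(q0, q1, q2);
              den += w;
            }
        sim(i, j) = (den > 0.0) ? num / den : NA_REAL;
      }
    out[s] = sim;
  }
  return out;
}

// 1 - NCC between a fixed volume and a moving volume resampled through B,
// where B maps 0-based fixed voxel indices to continuous moving indices.
// Out-of-field samples are excluded from the metric.
// [[Rcpp::export]]
List cpp_ncc_volume(const arma::cube& fixedv, const arma::cube& moving,
                    const arma::mat& B) {
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  long n = 0;
  const long ntot = (long)fixedv.n_elem;
  for (arma::uword k = 0; k < fixedv.n_slices; k++)
    for (arma::uword j = 0; j < fixedv.n_cols; j++)
      for (arma::uword i = 0; i < fixedv.n_rows; i++) {
        const double x = B(0, 0) * i + B(0, 1) * j + B(0, 2) * k + B(0, 3);
        const double y = B(1, 0) * i + B(1, 1) * j + B(1, 2) * k + B(1, 3);
        const double z = B(2, 0) * i + B(2, 1) * j + B(2, 2) * k + B(2, 3);
        double mv;
        if (!trilinear(moving, x, y, z, mv)) continue;
        const double fv = fixedv(i, j, k);
        sf += fv; sm += mv; sff += fv * fv; smm += mv * mv; sfm += fv * mv;
        n++;
      }
  double ncc = 0.0;
  if (n > 1) {
    const double vf = sff - sf * sf / n, vm = smm - sm * sm / n;
    if (vf > 1e-12 && vm > 1e-12)
      ncc = (sfm - sf * sm / n) / std::sqrt(vf * vm);
  }
  return List::create(_["ncc"] = ncc, _["n"] = (double)n,
                      _["n_total"] = (double)ntot);
}

// 1 - NCC objective for slice-to-volume registration: simulate one slice from
// the volume at the candidate pose (PSF gather) and correlate it with the
// observed valid pixels.
// [[Rcpp::export]]
List cpp_ncc_slice(const arma::cube& vol, const arma::cube& known,
                   NumericMatrix obs, LogicalMatrix mask, NumericMatrix Am,
                   NumericMatrix Mm, NumericVector sigma, double support) {
  const double sx = sigma[0], sy = sigma[1], sz = sigma[2];
  const double bx = support * sx, by = support * sy, bz = support * sz;
  const int d0 = vol.n_rows, d1 = vol.n_cols, d2 = vol.n_slices;
  double rad_mm = support * std::max(sx, std::max(sy, sz));
  double rad[3];
  for (int a = 0; a < 3; a++) {
    double st = std::sqrt(Mm(0, a) * Mm(0, a) + Mm(1, a) * Mm(1, a) +
                          Mm(2, a) * Mm(2, a));
    rad[a] = rad_mm / std::max(st, 1e-12);
  }
  double sf = 0, sm = 0, sff = 0, smm = 0, sfm = 0;
  long n = 0;
  for (int j = 0; j < obs.ncol(); j++)
    for (int i = 0; i < obs.nrow(); i++) {
      if (!mask(i, j)) continue;
      const double cx = Am(0, 0) * i + Am(0, 1) * j + Am(0, 3);
      const double cy = Am(1, 0) * i + Am(1, 1) * j + Am(1, 3);
      const double cz = Am(2, 0) * i + Am(2, 1) * j + Am(2, 3);
      const int lo0 = (int)std::ceil(cx - rad[0]), hi0 = (int)std::floor(cx + rad[0]);
      const int lo1 = (int)std::ceil(cy - rad[1]), hi1 = (int)std::floor(cy + rad[1]);
      const int lo2 = (int)std::ceil(cz - rad[2]), hi2 = (int)std::floor(cz + rad[2]);
      double num = 0.0, den = 0.0;
      for (int q2 = std::max(lo2, 0); q2 <= std::min(hi2, d2 - 1); q2++)
        for (int q1 = std::max(lo1, 0); q1 <= std::min(hi1, d1 - 1); q1++)
          for (int q0 = std::max(lo0, 0); q0 <= std::min(hi0, d0 - 1); q0++) {
            if (known(q0, q1, q2) == 0.0) continue;
            const double o0 = q0 - cx, o1 = q1 - cy, o2 = q2 - cz;
            const double dx = Mm(0, 0) * o0 + Mm(0, 1) * o1 + Mm(0, 2) * o2;
            const double dy = Mm(1, 0) * o0 + Mm(1, 1) * o1 + Mm(1, 2) * o2;
            const double dz = Mm(2, 0) * o0 + Mm(2, 1) * o1 + Mm(2, 2) * o2;
            if (std::abs(dx) > bx || std::abs(dy) > by || std::abs(dz) > bz)
              continue;
            const double w = std::exp(-0.5 * (dx * dx / (sx * sx) +
                                              dy * dy / (sy * sy) +
                                              dz * dz / (sz * sz)));
            num += w * vol(q0, q1, q2);
            den += w;
          }
      if (den <= 0.0) continue;
      const double fv = obs(i, j), mv = num / den;
      sf += fv; sm += mv; sff += fv * fv; smm += mv * mv; sfm += fv * mv;
      n++;
    }
  double ncc = 0.0;
  if (n > 1) {
    const double vf = sff - sf * sf / n, vm = smm - sm * sm / n;
    if (vf > 1e-12 && vm > 1e-12)
      ncc = (sfm - sf * sm / n) / std::sqrt(vf * vm);
  }
  return List::create(_["ncc"] = ncc, _["n"] = (double)n);
}

// Trilinear resample of a volume at a matrix of continuous 0-based indices
// (rows are points).  NA outside the grid.
// [[Rcpp::export]]
NumericVector cpp_trilinear(const arma::cube& vol, const arma::mat& pts) {
  NumericVector out(pts.n_rows);
  for (arma::uword r = 0; r < pts.n_rows; r++) {
    double v;
    out[r] = trilinear(vol, pts(r, 0), pts(r, 1), pts(r, 2), v) ? v : NA_REAL;
  }
  return out;
}
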