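#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Siddon-style exact ray/voxel-grid traversal.
//
// Labelled voxel grid (0 = air), isotropic voxel size, grid centred on the
// isocenter.  For each detector pixel the ray from the source to the pixel
// centre is traced and the intersection length with every material label is
// accumulated.  Lengths are returned in mm, one column per material label.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_siddon_forward")]]
NumericMatrix cpp_siddon_forward(IntegerVector labels, IntegerVector dims,
                                 double voxel_mm, int n_mat,
                                 NumericVector source, NumericMatrix pixels) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int npix = pixels.nrow();
  NumericMatrix out(npix, n_mat);

  const double x0 = -0.5 * nx * voxel_mm;
  const double y0 = -0.5 * ny * voxel_mm;
  const double z0 = -0.5 * nz * voxel_mm;
  const double sx = source[0], sy = source[1], sz = source[2];
  const int *lab = INTEGER(labels);

  for (int p = 0; p < npix; ++p) {
    const double dx = pixels(p, 0) - sx;
    const double dy = pixels(p, 1) - sy;
    const double dz = pixels(p, 2) - sz;
    const double ray_len = std::sqrt(dx * dx + dy * dy + dz * dz);

    // parametric entry/exit of the grid bounding box, t in [0, 1]
    double tmin = 0.0, tmax = 1.0;
    const double d[3] = {dx, dy, dz};
    const double s[3] = {sx, sy, sz};
    const double lo[3] = {x0, y0, z0};
    const double hi[3] = {x0 + nx * voxel_mm, y0 + ny * voxel_mm,
                          z0 + nz * voxel_mm};
    bool miss = false;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        if (s[a] <= lo[a] || s[a] >= hi[a]) { miss = true; break; }
      } else {
        double t1 = (lo[a] - s[a]) / d[a];
        double t2 = (hi[a] - s[a]) / d[a];
        if (t1 > t2) std::swap(t1, t2);
        if (t1 > tmin) tmin = t1;
        if (t2 < tmax) tmax = t2;
      }
    }
    if (miss || tmin >= tmax) continue;

    // voxel index at entry point (nudged inside)
    double t = tmin;
    const double eps = 1e-10;
    double px = s[0] + (t + eps) * d[0];
    double py = s[1] + (t + eps) * d[1];
    double pz = s[2] + (t + eps) * d[2];
    int ix = (int)std::floor((px - x0) / voxel_mm);
    int iy = (int)std::floor((py - y0) / voxel_mm);
    int iz = (int)std::floor((pz - z0) / voxel_mm);
    ix = std::min(std::max(ix, 0), nx - 1);
    iy = std::min(std::max(iy, 0), ny - 1);
    iz = std::min(std::max(iz, 0), nz - 1);

    const int step[3] = {d[0] > 0 ? 1 : -1, d[1] > 0 ? 1 : -1,
                         d[2] > 0 ? 1 : -1};
    double tnext[3], dt[3];
    int idx[3] = {ix, iy, iz};
    const int nd[3] = {nx, ny, nz};
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) < 1e-12) {
        tnext[a] = 2.0;  // never crossed
        dt[a] = 2.0;
      } else {
        double bound =
            lo[a] + (idx[a] + (step[a] > 0 ? 1 : 0)) * voxel_mm;
        tnext[a] = (bound - s[a]) / d[a];
        dt[a] = voxel_mm / std::fabs(d[a]);
      }
    }

    while (t < tmax) {
      int a = 0;
      if (tnext[1] < tnext[a]) a = 1;
      if (tnext[2] < tnext[a]) a = 2;
      double tstop = std::min(tnext[a], tmax);
      double seg = (tstop - t) * ray_len;
      if (seg > 0) {
        int m = lab[idx[0] + nd[0] * (idx[1] + (R_xlen_t)nd[1] * idx[2])];
        if (m > 0 && m <= n_mat) out(p, m - 1) += seg;
      }
      t = tstop;
      idx[a] += step[a];
      if (idx[a] < 0 || idx[a] >= nd[a]) break;
      tnext[a] += dt[a];
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// FDK voxel-driven backprojection for a circular cone-beam orbit.
//
// q: filtered projections, dim [n_rows, n_channels, n_views], detector
// coordinates already rescaled to the virtual detector through the isocenter
// (pitch du_iso / dv_iso).  Source at SID*(cos a, sin a, 0); detector u-axis
// (-sin a, cos a, 0), v-axis +z.  The caller applies the angular step and
// full-scan 1/2 factor through `scale`.
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_fdk_backproject")]]
NumericVector cpp_fdk_backproject(NumericVector q, IntegerVector qdim,
                                  NumericVector angles_rad, double sid,
                                  double du_iso, double dv_iso,
                                  IntegerVector vdim, double voxel_mm,
                                  double scale) {
  const int nr = qdim[0], nc = qdim[1], nk = qdim[2];
  const int nx = vdim[0], ny = vdim[1], nz = vdim[2];
  NumericVector vol((R_xlen_t)nx * ny * nz);
  const double *qp = REAL(q);
  double *vp = REAL(vol);

  const double cu = 0.5 * (nc - 1);
  const double cv = 0.5 * (nr - 1);

  for (int k = 0; k < nk; ++k) {
    const double ca = std::cos(angles_rad[k]);
    const double sa = std::sin(angles_rad[k]);
    const double *qk = qp + (R_xlen_t)k * nr * nc;
    R_xlen_t v_at = 0;
    for (int izv = 0; izv < nz; ++izv) {
      const double z = (izv - 0.5 * (nz - 1)) * voxel_mm;
      for (int iyv = 0; iyv < ny; ++iyv) {
        const double y = (iyv - 0.5 * (ny - 1)) * voxel_mm;
        for (int ixv = 0; ixv < nx; ++ixv, ++v_at) {
          const double x = (ixv - 0.5 * (nx - 1)) * voxel_mm;
          const double L = sid - (x * ca + y * sa);
          if (L <= 1e-6) continue;
          const double mag = sid / L;
          const double up = (-x * sa + y * ca) * mag;  // u' on iso detector
          const double vv = z * mag;
          const double fc = up / du_iso + cu;
          const double fr = cv - vv / dv_iso;
          const int c0 = (int)std::floor(fc);
          const int r0 = (int)std::floor(fr);
          if (c0 < 0 || c0 >= nc - 1 || r0 < 0 || r0 >= nr - 1) continue;
          const double wc = fc - c0, wr = fr - r0;
          const double q00 = qk[r0 + (R_xlen_t)nr * c0];
          const double q01 = qk[r0 + (R_xlen_t)nr * (c0 + 1)];
          const double q10 = qk[r0 + 1 + (R_xlen_t)nr * c0];
          const double q11 = qk[r0 + 1 + (R_xlen_t)nr * (c0 + 1)];
          const double val = (1 - wr) * ((1 - wc) * q00 + wc * q01) +
                             wr * ((1 - wc) * q10 + wc * q11);
          vp[v_at] += mag * mag * val;
        }
      }
    }
  }
  for (R_xlen_t i = 0; i < vol.size(); ++i) vp[i] *= scale;
  vol.attr("dim") = vdim;
  return vol;
}

// ---------------------------------------------------------------------------
// 2-D median filter with a rectangular window (kr x kc), window truncated at
// the image border.  Used by the ring-artifact estimator, whose kernel is
// deliberately anisotropic (narrow across rows, wide along channels).
// ---------------------------------------------------------------------------

// [[Rcpp::export(name = ".cpp_median2d")]]
NumericMatrix cpp_median2d(NumericMatrix x, int kr, int kc) {
  const int nr = x.nrow(), nc = x.ncol();
  const int hr = kr / 2, hc = kc / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)kr * kc);
  for (int j = 0; j < nc; ++j) {
    const int j0 = std::max(0, j - hc), j1 = std::min(nc - 1, j + hc);
    for (int i = 0; i < nr; ++i) {
      const int i0 = std::max(0, i - hr), i1 = std::min(nr - 1, i + hr);
      buf.clear();
      for (int jj = j0; jj <= j1; ++jj)
        for (int ii = i0; ii <= i1; ++ii) buf.push_back(x(ii, jj));
      const size_t n = buf.size();
      std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
      double med = buf[n / 2];
      if (n % 2 == 0) {
        std::nth_element(buf.begin(), buf.begin() + n / 2 - 1,
                         buf.begin() + n / 2);
        med = 0.5 * (med + buf[n / 2 - 1]);
      }
      out(i, j) = med;
    }
  }
  return out;
}

// ---------------------------------------------------------------------------
// 3-D ROF total-variation denoising:  min_x 1/2 ||x - x0||^2 + lambda TV(x)
// solved with Chambolle's dual projection algorithm (tau = 1/12 for the 3-D
// gradient operator).  Deterministic, no stopping tolerance: fixed niter.
// ---------------------------------------------------------------------------

static inline R_xlen_t at3(int i, int j, int k, int nx, int ny) {
  return i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k);
}

// [[Rcpp::export(name = ".cpp_tv_rof3d")]]
NumericVector cpp_tv_rof3d(NumericVector x0, IntegerVector dims,
                           double lambda, int niter) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> p1(n, 0.0), p2(n, 0.0), p3(n, 0.0), dv(n, 0.0);
  const double *x0p = REAL(x0);
  const double tau = 1.0 / 12.0;

  for (int it = 0; it < niter; ++it) {
    // dv = div(p) - x0/lambda
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t a = at3(i, j, k, nx, ny);
          double d = p1[a] + p2[a] + p3[a];
          if (i > 0) d -= p1[at3(i - 1, j, k, nx, ny)];
          if (j > 0) d -= p2[at3(i, j - 1, k, nx, ny)];
          if (k > 0) d -= p3[at3(i, j, k - 1, nx, ny)];
          dv[a] = d - x0p[a] / lambda;
        }
    // p <- (p + tau grad(dv)) / (1 + tau |grad(dv)|)
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx; ++i) {
          const R_xlen_t a = at3(i, j, k, nx, ny);
          const double g1 =
              (i < nx - 1) ? dv[at3(i + 1, j, k, nx, ny)] - dv[a] : 0.0;
          const double g2 =
              (j < ny - 1) ? dv[at3(i, j + 1, k, nx, ny)] - dv[a] : 0.0;
          const double g3 =
              (k < nz - 1) ? dv[at3(i, j, k + 1, nx, ny)] - dv[a] : 0.0;
          const double gn = std::sqrt(g1 * g1 + g2 * g2 + g3 * g3);
          const double den = 1.0 + tau * gn;
          p1[a] = (p1[a] + tau * g1) / den;
          p2[a] = (p2[a] + tau * g2) / den;
          p3[a] = (p3[a] + tau * g3) / den;
        }
  }

  NumericVector out(n);
  double *op = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t a = at3(i, j, k, nx, ny);
        double d = p1[a] + p2[a] + p3[a];
        if (i > 0) d -= p1[at3(i - 1, j, k, nx, ny)];
        if (j > 0) d -= p2[at3(i, j - 1, k, nx, ny)];
        if (k > 0) d -= p3[at3(i, j, k - 1, nx, ny)];
        op[a] = x0p[a] - lambda * d;
      }
  out.attr("dim") = dims;
  return out;
}
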