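#include <Rcpp.h>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// Trilinear sample of a node-centred grid; positions outside the node
// bounding box contribute 0.
static inline double sample_trilinear(const double* v,
                                      int nx, int ny, int nz,
                                      double gx, double gy, double gz) {
  if (gx < 0.0 || gy < 0.0 || gz < 0.0 ||
      gx > nx - 1.0 || gy > ny - 1.0 || gz > nz - 1.0)
    return 0.0;
  int i0 = (int)std::floor(gx); if (i0 > nx - 2) i0 = nx - 2;
  int j0 = (int)std::floor(gy); if (j0 > ny - 2) j0 = ny - 2;
  int k0 = (int)std::floor(gz); if (k0 > nz - 2) k0 = nz - 2;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  const double* base = v + (size_t)k0 * nx * ny + (size_t)j0 * nx + i0;
  size_t sy = nx, sz = (size_t)nx * ny;
  double c000 = base[0],      c100 = base[1];
  double c010 = base[sy],     c110 = base[sy + 1];
  double c001 = base[sz],     c101 = base[sz + 1];
  double c011 = base[sz + sy], c111 = base[sz + sy + 1];
  double c00 = c000 + fx * (c100 - c000);
  double c10 = c010 + fx * (c110 - c010);
  double c01 = c001 + fx * (c101 - c001);
  double c11 = c011 + fx * (c111 - c011);
  double c0 = c00 + fy * (c10 - c00);
  double c1 = c01 + fy * (c11 - c01);
  return c0 + fz * (c1 - c0);
}

// Perspective DRR: for every detector pixel, the line integral of the
// (rigidly posed) volume along the source->pixel ray, midpoint rule at a
// fixed nominal step with trilinear interpolation.
//
// The volume is never resampled: the inverse pose maps world sample
// positions into the volume's unrotated grid.
// [[Rcpp::export]]
NumericMatrix cast_drr_cpp(NumericVector values, IntegerVector dims,
                           NumericVector spacing, NumericVector origin,
                           NumericMatrix Rinv, NumericVector center,
                           NumericVector source, NumericVector det_origin,
                           NumericVector u_axis, NumericVector v_axis,
                           double pixel_spacing, int nu, int nv,
                           double step) {
  if (step <= 0) stop("ray step must be > 0");
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* vp = values.begin();
  NumericMatrix img(nu, nv);

  // source position in volume-grid coordinates (continuous index space)
  double sc[3];
  for (int a = 0; a < 3; ++a) {
    double d = 0;
    for (int b = 0; b < 3; ++b)
      d += Rinv(a, b) * (source[b] - center[b]);
    sc[a] = center[a] + d;
  }
  double sg[3] = { (sc[0] - origin[0]) / spacing[0],
                   (sc[1] - origin[1]) / spacing[1],
                   (sc[2] - origin[2]) / spacing[2] };

  double u0 = -((nu + 1) / 2.0) * pixel_spacing;
  double v0 = -((nv + 1) / 2.0) * pixel_spacing;

  for (int j = 0; j < nv; ++j) {
    double vmm = v0 + (j + 1) * pixel_spacing;
    for (int i = 0; i < nu; ++i) {
      double umm = u0 + (i + 1) * pixel_spacing;
      // pixel world position, then into volume-grid coordinates
      double pw[3], pc[3];
      for (int a = 0; a < 3; ++a)
        pw[a] = det_origin[a] + umm * u_axis[a] + vmm * v_axis[a];
      for (int a = 0; a < 3; ++a) {
        double d = 0;
        for (int b = 0; b < 3; ++b)
          d += Rinv(a, b) * (pw[b] - center[b]);
        pc[a] = center[a] + d;
      }
      double pg[3] = { (pc[0] - origin[0]) / spacing[0],
                       (pc[1] - origin[1]) / spacing[1],
                       (pc[2] - origin[2]) / spacing[2] };
      // ray in grid coords: sg + t*(pg-sg), t in [0,1]; world length factor
      double dir[3] = { pg[0] - sg[0], pg[1] - sg[1], pg[2] - sg[2] };
      double world_len = 0;
      for (int a = 0; a < 3; ++a) {
        double w = dir[a] * spacing[a];
        world_len += w * w;
      }
      world_len = std::sqrt(world_len);
      if (world_len <= 0) continue;
      // clip t to the grid node box [0, n-1] per axis (slab method)
      double t0 = 0.0, t1 = 1.0;
      bool miss = false;
      for (int a = 0; a < 3; ++a) {
        double lo = 0.0, hi = (a == 0 ? nx : (a == 1 ? ny : nz)) - 1.0;
        if (std::fabs(dir[a]) < 1e-14) {
          if (sg[a] < lo || sg[a] > hi) { miss = true; break; }
        } else {
          double ta = (lo - sg[a]) / dir[a];
          double tb = (hi - sg[a]) / dir[a];
          if (ta > tb) std::swap(ta, tb);
          if (ta > t0) t0 = ta;
          if (tb < t1) t1 = tb;
          if (t0 > t1) { miss = true; break; }
        }
      }
      if (miss || t1 <= t0) continue;
      double seg_len = (t1 - t0) * world_len;
      int nsteps = (int)std::ceil(seg_len / step);
      if (nsteps < 1) nsteps = 1;
      double dt = (t1 - t0) / nsteps;
      double dl = seg_len / nsteps;
      double acc = 0.0;
      for (int s = 0; s < nsteps; ++s) {
        double t = t0 + (s + 0.5) * dt;
        acc += sample_trilinear(vp, nx, ny, nz,
                                sg[0] + t * dir[0],
                                sg[1] + t * dir[1],
                                sg[2] + t * dir[2]);
      }
      img(i, j) = acc * dl;
    }
  }
  return img;
}
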