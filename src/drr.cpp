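// Digitally reconstructed radiograph (DRR) rendering: per-pixel line
// integrals of a posed attenuation volume along calibrated camera rays.
// Fixed-step ray marching with trilinear sampling, matching the forward
// model assumed by the two-view NCC tracking cost.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double trilinear(const arma::cube& vol, double x, double y,
                               double z) {
  // x,y,z are continuous zero-based voxel coordinates
  const int nx = vol.n_rows, ny = vol.n_cols, nz = vol.n_slices;
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1)
    return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y), z0 = (int)std::floor(z);
  if (x0 == nx - 1) x0--;
  if (y0 == ny - 1) y0--;
  if (z0 == nz - 1) z0--;
  const double fx = x - x0, fy = y - y0, fz = z - z0;
  const double c000 = vol(x0, y0, z0),     c100 = vol(x0 + 1, y0, z0);
  const double c010 = vol(x0, y0 + 1, z0), c110 = vol(x0 + 1, y0 + 1, z0);
  const double c001 = vol(x0, y0, z0 + 1), c101 = vol(x0 + 1, y0, z0 + 1);
  const double c011 = vol(x0, y0 + 1, z0 + 1),
               c111 = vol(x0 + 1, y0 + 1, z0 + 1);
  const double c00 = c000 * (1 - fx) + c100 * fx;
  const double c10 = c010 * (1 - fx) + c110 * fx;
  const double c01 = c001 * (1 - fx) + c101 * fx;
  const double c11 = c011 * (1 - fx) + c111 * fx;
  const double c0 = c00 * (1 - fy) + c10 * fy;
  const double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Renders the pixel window [u0, u0+width) x [v0, v0+height) of the detector;
// the full frame is u0 = v0 = 0 with the detector size.
// [[Rcpp::export(name = ".drr_render_cpp")]]
arma::mat drr_render_cpp(const arma::cube& vol, const arma::vec& spacing,
                         const arma::mat& Rpose, const arma::vec& tpose,
                         const arma::vec& cam_center, const arma::mat& Minv,
                         int width, int height, double step,
                         int u0 = 0, int v0 = 0) {
  arma::mat img(height, width, arma::fill::zeros);
  const arma::mat Rt = Rpose.t();
  const arma::vec o_l = Rt * (cam_center - tpose);  // ray origin, bone frame
  const arma::vec ext = {spacing(0) * (vol.n_rows - 1),
                         spacing(1) * (vol.n_cols - 1),
                         spacing(2) * (vol.n_slices - 1)};
  for (int v = 0; v < height; ++v) {
    for (int u = 0; u < width; ++u) {
      arma::vec pix = {(double)(u + u0), (double)(v + v0), 1.0};
      arma::vec d_w = Minv * pix;
      d_w /= arma::norm(d_w);
      const arma::vec d_l = Rt * d_w;
      // slab intersection with the local axis-aligned volume box
      double tmin = 0.0, tmax = std::numeric_limits<double>::infinity();
      bool hit = true;
      for (int k = 0; k < 3; ++k) {
        if (std::abs(d_l(k)) < 1e-12) {
          if (o_l(k) < 0 || o_l(k) > ext(k)) { hit = false; break; }
        } else {
          double t1 = (0.0 - o_l(k)) / d_l(k);
          double t2 = (ext(k) - o_l(k)) / d_l(k);
          if (t1 > t2) std::swap(t1, t2);
          tmin = std::max(tmin, t1);
          tmax = std::min(tmax, t2);
          if (tmin > tmax) { hit = false; break; }
        }
      }
      if (!hit) continue;
      double acc = 0.0;
      for (double s = tmin + step * 0.5; s < tmax; s += step) {
        const double px = (o_l(0) + s * d_l(0)) / spacing(0);
        const double py = (o_l(1) + s * d_l(1)) / spacing(1);
        const double pz = (o_l(2) + s * d_l(2)) / spacing(2);
        acc += trilinear(vol, px, py, pz);
      }
      img(v, u) = acc * step;
    }
  }
  return img;
}
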