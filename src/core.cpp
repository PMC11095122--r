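#include <Rcpp.h>
using namespace Rcpp;

// All pixel coordinates are 0-based: x = column, y = row, origin top-left.
// rot2(v, th) rotates (x, y) by th about the origin:
//   x' = cos*x - sin*y ; y' = sin*x + cos*y
// A sample-frame point q appears, with the sample at rotation angle th, at
// lab position c + rot2(q - c, th).

static inline double bilin(const NumericMatrix &img, double x, double y) {
  const int H = img.nrow(), W = img.ncol();
  if (x < 0.0 || y < 0.0 || x > W - 1.0 || y > H - 1.0) return 0.0;
  int x0 = (int)std::floor(x), y0 = (int)std::floor(y);
  if (x0 == W - 1) x0--;
  if (y0 == H - 1) y0--;
  double fx = x - x0, fy = y - y0;
  return (1 - fx) * (1 - fy) * img(y0, x0) + fx * (1 - fy) * img(y0, x0 + 1) +
         (1 - fx) * fy * img(y0 + 1, x0) + fx * fy * img(y0 + 1, x0 + 1);
}

static inline double cross2(double ax, double ay, double bx, double by) {
  return ax * by - ay * bx;
}

// [[Rcpp::export]]
NumericVector cpp_bilinear(NumericMatrix img, NumericVector x, NumericVector y) {
  const R_xlen_t n = x.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = bilin(img, x[i], y[i]);
  return out;
}

// Bilinear rotation of image content by angle_rad about (cx, cy);
// samples falling outside the frame read as 0.
// [[Rcpp::export]]
NumericMatrix cpp_rotate_image(NumericMatrix img, double angle_rad,
                               double cx, double cy) {
  const int H = img.nrow(), W = img.ncol();
  NumericMatrix out(H, W);
  const double co = std::cos(-angle_rad), si = std::sin(-angle_rad);
  for (int y = 0; y < H; ++y) {
    const double dy = y - cy;
    for (int x = 0; x < W; ++x) {
      const double dx = x - cx;
      out(y, x) = bilin(img, cx + co * dx - si * dy, cy + si * dx + co * dy);
    }
  }
  return out;
}

// Trace all vertical scan rays for a set of projection angles.
// structure: image integrated along the refracted path (sample frame)
// inside:    integer mask (1 = inside the sample silhouette), sample frame
// pts:       K x 2 ordered contour points (x, y), sample frame
// normals:   K x 2 outward unit normals at the contour points
// thetas:    projection angles (radians); the lab ray is vertical (+y) at
//            column w; tracing is done in the sample frame by rotating the
//            ray by -theta
// Returns per (projection, column): integrated intensity, subpixel entry
// point, signed incident angle alpha (vs outward normal), signed refracted
// angle beta, TIR flag and hit flag.
// [[Rcpp::export]]
List cpp_trace_rays(NumericMatrix structure, IntegerMatrix inside,
                    NumericMatrix pts, NumericMatrix normals,
                    double cx, double cy, NumericVector thetas, int W,
                    double n1, double n2, double step, bool march) {
  const int P = thetas.size();
  const int K = pts.nrow();
  const int H = inside.nrow(), WM = inside.ncol();
  NumericMatrix inten(P, W), ex(P, W), ey(P, W), alpha(P, W), beta(P, W),
      dirx(P, W), diry(P, W);
  IntegerMatrix tir(P, W), hit(P, W);
  std::fill(ex.begin(), ex.end(), NA_REAL);
  std::fill(ey.begin(), ey.end(), NA_REAL);
  std::fill(alpha.begin(), alpha.end(), NA_REAL);
  std::fill(beta.begin(), beta.end(), NA_REAL);
  std::fill(dirx.begin(), dirx.end(), NA_REAL);
  std::fill(diry.begin(), diry.end(), NA_REAL);
  const int max_steps = 4 * std::max(H, WM);

  for (int p = 0; p < P; ++p) {
    const double th = thetas[p];
    const double co = std::cos(-th), si = std::sin(-th);
    // sample-frame direction of the downward lab ray
    const double dx = -si, dy = co;
    for (int w = 0; w < W; ++w) {
      // sample-frame point of lab position (w, 0)
      const double q0x = cx + co * (w - cx) - si * (0.0 - cy);
      const double q0y = cy + si * (w - cx) + co * (0.0 - cy);
      // first intersection with the contour polygon (smallest t, i.e.
      // topmost in the lab frame; t may be negative: the ray extends
      // upward beyond the frame's first row)
      double tmin = R_PosInf;
      int seg = -1;
      double umin = 0.0;
      for (int i = 0; i < K; ++i) {
        const int j = (i + 1 == K) ? 0 : i + 1;
        const double exx = pts(j, 0) - pts(i, 0), eyy = pts(j, 1) - pts(i, 1);
        const double det = exx * dy - dx * eyy;
        if (std::fabs(det) < 1e-14) continue;
        const double bx = pts(i, 0) - q0x, by = pts(i, 1) - q0y;
        const double u = (dx * by - bx * dy) / det;
        if (u < 0.0 || u >= 1.0) continue;
        const double t = (exx * by - bx * eyy) / det;
        if (t < tmin) { tmin = t; seg = i; umin = u; }
      }
      if (seg < 0) continue;  // ray misses the sample
      const double Ex = q0x + tmin * dx, Ey = q0y + tmin * dy;
      const int vi = (umin < 0.5) ? seg : (seg + 1) % K;
      const double nx = normals(vi, 0), ny = normals(vi, 1);
      const double mx = -dx, my = -dy;              // toward the source
      const double dot = mx * nx + my * ny;         // cos(alpha)
      if (dot <= 1e-9) continue;                    // grazing: treat as miss
      const double a = std::atan2(cross2(nx, ny, mx, my), dot);
      hit(p, w) = 1;
      ex(p, w) = Ex; ey(p, w) = Ey; alpha(p, w) = a;
      const double eta = n1 / n2;
      const double sin2t = eta * eta * (1.0 - dot * dot);
      if (sin2t > 1.0) { tir(p, w) = 1; continue; } // total internal reflection
      const double cost = std::sqrt(1.0 - sin2t);
      double tx = eta * dx + (eta * dot - cost) * nx;
      double ty = eta * dy + (eta * dot - cost) * ny;
      const double nrm = std::sqrt(tx * tx + ty * ty);
      tx /= nrm; ty /= nrm;
      beta(p, w) = std::atan2(cross2(-nx, -ny, tx, ty), -nx * tx - ny * ty);
      dirx(p, w) = tx; diry(p, w) = ty;
      if (!march) continue;
      double s = 0.0, px = Ex, py = Ey;
      for (int k = 0; k < max_steps; ++k) {
        px += step * tx; py += step * ty;
        const int ix = (int)std::lround(px), iy = (int)std::lround(py);
        if (ix < 0 || iy < 0 || ix >= WM || iy >= H) break;
        if (!inside(iy, ix)) break;                 // crossed the backside
        s += bilin(structure, px, py);
      }
      inten(p, w) = s;
    }
  }
  return List::create(_["intensity"] = inten, _["entry_x"] = ex,
                      _["entry_y"] = ey, _["alpha"] = alpha, _["beta"] = beta,
                      _["dir_x"] = dirx, _["dir_y"] = diry,
                      _["tir"] = tir, _["hit"] = hit);
}

// Back-projection of ramp-filtered projections onto an N x N grid.
// filt: P x W filtered sinogram, row p acquired at thetas[p].
// The lab column of sample-frame pixel (x, y) at angle th is
//   s = cx + cos(th) (x - cx) - sin(th) (y - cy)
// matching the forward model in cpp_trace_rays.
// [[Rcpp::export]]
NumericMatrix cpp_backproject(NumericMatrix filt, NumericVector thetas,
                              double cx, double cy, int N) {
  const int P = filt.nrow(), W = filt.ncol();
  NumericMatrix out(N, N);
  for (int p = 0; p < P; ++p) {
    const double co = std::cos(thetas[p]), si = std::sin(thetas[p]);
    for (int y = 0; y < N; ++y) {
      const double base = cx - si * (y - cy);
      for (int x = 0; x < N; ++x) {
        const double s = base + co * (x - cx);
        const int j = (int)std::floor(s);
        if (j < 0 || j >= W - 1) continue;
        const double f = s - j;
        out(y, x) += (1.0 - f) * filt(p, j) + f * filt(p, j + 1);
      }
    }
  }
  return out;
}

// Separable "valid"-region convolution with a symmetric 1-D kernel; pixels
// whose window exceeds the frame are NA (used by the SSIM map).
// [[Rcpp::export]]
NumericMatrix cpp_sepconv_valid(NumericMatrix img, NumericVector k) {
  const int H = img.nrow(), W = img.ncol(), L = k.size(), h = (L - 1) / 2;
  NumericMatrix tmp(H, W), out(H, W);
  std::fill(tmp.begin(), tmp.end(), NA_REAL);
  std::fill(out.begin(), out.end(), NA_REAL);
  for (int y = 0; y < H; ++y)
    for (int x = h; x < W - h; ++x) {
      double s = 0.0;
      for (int j = 0; j < L; ++j) s += k[j] * img(y, x + j - h);
      tmp(y, x) = s;
    }
  for (int y = h; y < H - h; ++y)
    for (int x = h; x < W - h; ++x) {
      double s = 0.0;
      for (int j = 0; j < L; ++j) s += k[j] * tmp(y + j - h, x);
      out(y, x) = s;
    }
  return out;
}
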