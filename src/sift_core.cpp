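#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Reflect-101 index (mirror about the edge pixel, edge not repeated).
static inline int reflect(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i;
    if (i >= n) i = 2 * n - 2 - i;
  }
  return i;
}

// Separable Gaussian blur, reflect-101 borders, kernel truncated at 4 sigma.
// [[Rcpp::export]]
NumericMatrix gauss_blur_cpp(const NumericMatrix& img, double sigma) {
  int nr = img.nrow(), nc = img.ncol();
  if (sigma <= 0) return clone(img);
  int radius = std::max(1, (int)std::ceil(4.0 * sigma));
  std::vector<double> w(2 * radius + 1);
  double s2 = 2.0 * sigma * sigma, sum = 0.0;
  for (int i = -radius; i <= radius; ++i) {
    w[i + radius] = std::exp(-(double)(i * i) / s2);
    sum += w[i + radius];
  }
  for (double& v : w) v /= sum;

  NumericMatrix tmp(nr, nc), out(nr, nc);
  // along columns (vertical)
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += w[i + radius] * img(reflect(r + i, nr), c);
      tmp(r, c) = acc;
    }
  // along rows (horizontal)
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      double acc = 0.0;
      for (int i = -radius; i <= radius; ++i)
        acc += w[i + radius] * tmp(r, reflect(c + i, nc));
      out(r, c) = acc;
    }
  return out;
}

static inline double dog_at(const NumericVector& d, int nr, int nc,
                            int r, int c, int l) {
  return d[r + nr * (c + nc * l)];
}

// Scan one octave's DoG stack (nr x nc x nl array) for strict local extrema.
// l1 = TRUE uses the 6-connected (axis) neighborhood, otherwise the full
// 26-neighbor 3x3x3 shell. Returns 0-based (level, row, col) triples.
// [[Rcpp::export]]
IntegerMatrix find_extrema_cpp(const NumericVector& dog, int nr, int nc,
                               int nl, int border, bool l1) {
  std::vector<int> lev, row, col;
  for (int l = 1; l < nl - 1; ++l)
    for (int c = border; c < nc - border; ++c)
      for (int r = border; r < nr - border; ++r) {
        double v = dog_at(dog, nr, nc, r, c, l);
        bool mx = true, mn = true;
        if (l1) {
          const int dr[6] = {-1, 1, 0, 0, 0, 0};
          const int dc[6] = {0, 0, -1, 1, 0, 0};
          const int dl[6] = {0, 0, 0, 0, -1, 1};
          for (int k = 0; k < 6 && (mx || mn); ++k) {
            double u = dog_at(dog, nr, nc, r + dr[k], c + dc[k], l + dl[k]);
            if (v <= u) mx = false;
            if (v >= u) mn = false;
          }
        } else {
          for (int dl = -1; dl <= 1 && (mx || mn); ++dl)
            for (int dc2 = -1; dc2 <= 1 && (mx || mn); ++dc2)
              for (int dr2 = -1; dr2 <= 1; ++dr2) {
                if (dl == 0 && dc2 == 0 && dr2 == 0) continue;
                double u = dog_at(dog, nr, nc, r + dr2, c + dc2, l + dl);
                if (v <= u) mx = false;
                if (v >= u) mn = false;
                if (!mx && !mn) break;
              }
        }
        if (mx || mn) { lev.push_back(l); row.push_back(r); col.push_back(c); }
      }
  int n = lev.size();
  IntegerMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    out(i, 0) = lev[i]; out(i, 1) = row[i]; out(i, 2) = col[i];
  }
  return out;
}

// Quadratic (second-order Taylor) sub-pixel refinement of DoG extrema plus
// the contrast and eigenvalue-ratio (edge response) tests.
// cand: 0-based (level, row, col). Returns one row per candidate:
//   code (0 accepted, 1 diverged, 2 low_contrast, 3 edge_like),
//   level, row, col (final integer position), dx, dy, ds (sub-pixel offsets,
//   x = column, y = row, s = level), contrast (signed interpolated D),
//   evr (lambda_max / lambda_min of the 2x2 spatial Hessian, NA if rejected
//   before the edge test).
// [[Rcpp::export]]
NumericMatrix refine_candidates_cpp(const NumericVector& dog, int nr, int nc,
                                    int nl, const IntegerMatrix& cand,
                                    double contrast_thresh, double evr_thresh,
                                    int border, int max_iter) {
  int n = cand.nrow();
  NumericMatrix out(n, 9);
  for (int i = 0; i < n; ++i) {
    int l = cand(i, 0), r = cand(i, 1), c = cand(i, 2);
    double dx = 0, dy = 0, ds = 0, gx = 0, gy = 0, gs = 0, v = 0;
    int code = 1;  // diverged unless proven otherwise
    for (int it = 0; it < max_iter; ++it) {
      v = dog_at(dog, nr, nc, r, c, l);
      gx = 0.5 * (dog_at(dog, nr, nc, r, c + 1, l) - dog_at(dog, nr, nc, r, c - 1, l));
      gy = 0.5 * (dog_at(dog, nr, nc, r + 1, c, l) - dog_at(dog, nr, nc, r - 1, c, l));
      gs = 0.5 * (dog_at(dog, nr, nc, r, c, l + 1) - dog_at(dog, nr, nc, r, c, l - 1));
      double dxx = dog_at(dog, nr, nc, r, c + 1, l) + dog_at(dog, nr, nc, r, c - 1, l) - 2 * v;
      double dyy = dog_at(dog, nr, nc, r + 1, c, l) + dog_at(dog, nr, nc, r - 1, c, l) - 2 * v;
      double dss = dog_at(dog, nr, nc, r, c, l + 1) + dog_at(dog, nr, nc, r, c, l - 1) - 2 * v;
      double dxy = 0.25 * (dog_at(dog, nr, nc, r + 1, c + 1, l) - dog_at(dog, nr, nc, r + 1, c - 1, l)
                         - dog_at(dog, nr, nc, r - 1, c + 1, l) + dog_at(dog, nr, nc, r - 1, c - 1, l));
      double dxs = 0.25 * (dog_at(dog, nr, nc, r, c + 1, l + 1) - dog_at(dog, nr, nc, r, c - 1, l + 1)
                         - dog_at(dog, nr, nc, r, c + 1, l - 1) + dog_at(dog, nr, nc, r, c - 1, l - 1));
      double dys = 0.25 * (dog_at(dog, nr, nc, r + 1, c, l + 1) - dog_at(dog, nr, nc, r - 1, c, l + 1)
                         - dog_at(dog, nr, nc, r + 1, c, l - 1) + dog_at(dog, nr, nc, r - 1, c, l - 1));
      // solve H * delta = -g by Cramer's rule (x, y, s order)
      double det = dxx * (dyy * dss - dys * dys)
                 - dxy * (dxy * dss - dys * dxs)
                 + dxs * (dxy * dys - dyy * dxs);
      if (std::fabs(det) < 1e-300) break;  // singular fit -> diverged
      double bx = -gx, by = -gy, bs = -gs;
      dx = (bx * (dyy * dss - dys * dys) - dxy * (by * dss - dys * bs)
            + dxs * (by * dys - dyy * bs)) / det;
      dy = (dxx * (by * dss - dys * bs) - bx * (dxy * dss - dys * dxs)
            + dxs * (dxy * bs - by * dxs)) / det;
      ds = (dxx * (dyy * bs - by * dys) - dxy * (dxy * bs - by * dxs)
            + bx * (dxy * dys - dyy * dxs)) / det;
      if (std::fabs(dx) < 0.5 && std::fabs(dy) < 0.5 && std::fabs(ds) < 0.5) {
        code = 0;
        break;
      }
      // step to the nearest sample and retry
      if (dx > 0.5) ++c; else if (dx < -0.5) --c;
      if (dy > 0.5) ++r; else if (dy < -0.5) --r;
      if (ds > 0.5) ++l; else if (ds < -0.5) --l;
      if (l < 1 || l > nl - 2 || r < border || r >= nr - border ||
          c < border || c >= nc - border) { code = 1; break; }
    }
    double contrast = NA_REAL, evr = NA_REAL;
    if (code == 0) {
      contrast = v + 0.5 * (gx * dx + gy * dy + gs * ds);
      if (std::fabs(contrast) < contrast_thresh) {
        code = 2;
      } else {
        // edge test on the 2x2 spatial Hessian at the final sample
        double dxx = dog_at(dog, nr, nc, r, c + 1, l) + dog_at(dog, nr, nc, r, c - 1, l)
                   - 2 * dog_at(dog, nr, nc, r, c, l);
        double dyy = dog_at(dog, nr, nc, r + 1, c, l) + dog_at(dog, nr, nc, r - 1, c, l)
                   - 2 * dog_at(dog, nr, nc, r, c, l);
        double dxy = 0.25 * (dog_at(dog, nr, nc, r + 1, c + 1, l) - dog_at(dog, nr, nc, r + 1, c - 1, l)
                           - dog_at(dog, nr, nc, r - 1, c + 1, l) + dog_at(dog, nr, nc, r - 1, c - 1, l));
        double tr = dxx + dyy, det2 = dxx * dyy - dxy * dxy;
        if (det2 <= 0 || tr * contrast >= 0) {
          code = 3;  // curvatures of opposite sign / inconsistent with extremum
        } else {
          double q = tr * tr / det2;       // (evr + 1)^2 / evr
          double t = q - 2.0;              // evr + 1/evr
          evr = 0.5 * (t + std::sqrt(std::max(t * t - 4.0, 0.0)));
          if (evr > evr_thresh) code = 3;
        }
      }
    }
    out(i, 0) = code; out(i, 1) = l; out(i, 2) = r; out(i, 3) = c;
    out(i, 4) = dx; out(i, 5) = dy; out(i, 6) = ds;
    out(i, 7) = contrast; out(i, 8) = evr;
  }
  colnames(out) = CharacterVector::create("code", "level", "row", "col",
                                          "dx", "dy", "ds", "contrast", "evr");
  return out;
}

// 36-bin gradient orientation histogram around (x, y) on an octave-level
// Gaussian image. x = column, y = row, 0-based. Gradients by central pixel
// differences; samples weighted by magnitude and a Gaussian of width
// 1.5 * sigma_oct. Angles from +x toward +y (row-down image convention).
// [[Rcpp::export]]
NumericVector orientation_hist_cpp(const NumericMatrix& img, double x,
                                   double y, double sigma_oct) {
  int nr = img.nrow(), nc = img.ncol();
  NumericVector hist(36);
  double wsig = 1.5 * sigma_oct;
  int radius = (int)std::round(3.0 * wsig);
  int rc = (int)std::round(y), cc = (int)std::round(x);
  for (int i = -radius; i <= radius; ++i)
    for (int j = -radius; j <= radius; ++j) {
      int r = rc + i, c = cc + j;
      if (r < 1 || r >= nr - 1 || c < 1 || c >= nc - 1) continue;
      double gx = 0.5 * (img(r, c + 1) - img(r, c - 1));
      double gy = 0.5 * (img(r + 1, c) - img(r - 1, c));
      double mag = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx) * 180.0 / M_PI;
      if (ang < 0) ang += 360.0;
      double w = std::exp(-(double)(i * i + j * j) / (2.0 * wsig * wsig));
      int bin = (int)std::floor(ang / 10.0) % 36;
      hist[bin] += w * mag;
    }
  return hist;
}

// 4x4x8 gradient descriptor (128 values, unnormalized) sampled on an
// octave-level Gaussian image around (x, y), rotated by ori_deg, with
// trilinear soft-binning. Histogram cell width is 3 * sigma_oct pixels.
// [[Rcpp::export]]
NumericVector descriptor_cpp(const NumericMatrix& img, double x, double y,
                             double sigma_oct, double ori_deg) {
  const int d = 4, nbins = 8;
  int nr = img.nrow(), nc = img.ncol();
  NumericVector desc(d * d * nbins);
  double hw = 3.0 * sigma_oct;                       // histogram cell width, px
  double th = ori_deg * M_PI / 180.0;
  double ct = std::cos(th), st = std::sin(th);
  double bins_per_deg = nbins / 360.0;
  int radius = (int)(hw * std::sqrt(2.0) * (d + 1) * 0.5 + 0.5);
  int rc = (int)std::round(y), cc = (int)std::round(x);
  for (int i = -radius; i <= radius; ++i)
    for (int j = -radius; j <= radius; ++j) {
      // rotate the offset into the keypoint frame, in cell units
      double u = (ct * j + st * i) / hw;
      double v = (-st * j + ct * i) / hw;
      double rbin = v + d / 2.0 - 0.5;
      double cbin = u + d / 2.0 - 0.5;
      if (rbin <= -1 || rbin >= d || cbin <= -1 || cbin >= d) continue;
      int r = rc + i, c = cc + j;
      if (r < 1 || r >= nr - 1 || c < 1 || c >= nc - 1) continue;
      double gx = 0.5 * (img(r, c + 1) - img(r, c - 1));
      double gy = 0.5 * (img(r + 1, c) - img(r - 1, c));
      double mag = std::sqrt(gx * gx + gy * gy);
      double ang = std::atan2(gy, gx) * 180.0 / M_PI - ori_deg;
      while (ang < 0) ang += 360.0;
      while (ang >= 360.0) ang -= 360.0;
      double obin = ang * bins_per_deg;
      double w = std::exp(-(u * u + v * v) / (0.5 * d * d)) * mag;
      int r0 = (int)std::floor(rbin), c0 = (int)std::floor(cbin),
          o0 = (int)std::floor(obin);
      double fr = rbin - r0, fc = cbin - c0, fo = obin - o0;
      for (int dr = 0; dr <= 1; ++dr) {
        int rb = r0 + dr;
        if (rb < 0 || rb >= d) continue;
        double wr = w * (dr ? fr : 1 - fr);
        for (int dc2 = 0; dc2 <= 1; ++dc2) {
          int cb = c0 + dc2;
          if (cb < 0 || cb >= d) continue;
          double wc = wr * (dc2 ? fc : 1 - fc);
          for (int dod = 0; dod <= 1; ++dod) {
            int ob = (o0 + dod) % nbins;
            desc[(rb * d + cb) * nbins + ob] += wc * (dod ? fo : 1 - fo);
          }
        }
      }
    }
  return desc;
}

// Inverse-mapped bilinear warp. minv is the 2x3 inverse transform taking
// output (x, y, 1) to source coordinates, 0-based pixel centers, x = column.
// Out-of-frame samples are 0 and flagged invalid in the mask.
// [[Rcpp::export]]
List warp_bilinear_cpp(const NumericMatrix& img, const NumericMatrix& minv) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  LogicalMatrix mask(nr, nc);
  double m00 = minv(0, 0), m01 = minv(0, 1), m02 = minv(0, 2);
  double m10 = minv(1, 0), m11 = minv(1, 1), m12 = minv(1, 2);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r) {
      double xs = m00 * c + m01 * r + m02;
      double ys = m10 * c + m11 * r + m12;
      if (xs < 0 || xs > nc - 1 || ys < 0 || ys > nr - 1) {
        out(r, c) = 0.0; mask(r, c) = false; continue;
      }
      int x0 = (int)std::floor(xs), y0 = (int)std::floor(ys);
      int x1 = std::min(x0 + 1, nc - 1), y1 = std::min(y0 + 1, nr - 1);
      double fx = xs - x0, fy = ys - y0;
      out(r, c) = (1 - fy) * ((1 - fx) * img(y0, x0) + fx * img(y0, x1))
                + fy * ((1 - fx) * img(y1, x0) + fx * img(y1, x1));
      mask(r, c) = true;
    }
  return List::create(_["image"] = out, _["mask"] = mask);
}
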