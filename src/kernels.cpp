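// Low-level image kernels for the detection chain and the synthetic renderer.
// Matrices are numeric h x w (row = y, col = x); pixel coordinates are 0-based
// with the origin at the top-left corner and pixel centers on integer lattice
// points (x = col - 1, y = row - 1 seen from R).

#include <Rcpp.h>
#include <random>
#include <cmath>
#include <vector>

using namespace Rcpp;

// ---- colour ----------------------------------------------------------------

// RGB (0..255) -> HSV with H in degrees [0, 360), S in [0, 1], V in [0, 1].
// Matches grDevices::rgb2hsv (which reports H as a fraction of 360).
// [[Rcpp::export]]
List cpp_rgb2hsv(NumericVector frame) {
  IntegerVector dims = frame.attr("dim");
  if (dims.size() != 3 || dims[2] != 3)
    stop("frame must be an h x w x 3 array");
  const int h = dims[0], w = dims[1];
  const R_xlen_t n = (R_xlen_t)h * w;
  NumericMatrix H(h, w), S(h, w), V(h, w);
  const double *p = REAL(frame);
  for (R_xlen_t i = 0; i < n; ++i) {
    double r = p[i], g = p[i + n], b = p[i + 2 * n];
    double mx = std::max(r, std::max(g, b));
    double mn = std::min(r, std::min(g, b));
    double d = mx - mn;
    double hh = 0.0;
    if (d > 0) {
      if (mx == r)      hh = 60.0 * (g - b) / d;
      else if (mx == g) hh = 120.0 + 60.0 * (b - r) / d;
      else              hh = 240.0 + 60.0 * (r - g) / d;
      if (hh < 0) hh += 360.0;
      if (hh >= 360.0) hh -= 360.0;
    }
    H[i] = hh;
    S[i] = mx > 0 ? d / mx : 0.0;
    V[i] = mx / 255.0;
  }
  return List::create(_["h"] = H, _["s"] = S, _["v"] = V);
}

// ---- separable smoothing ---------------------------------------------------

static NumericMatrix sep_filter(const NumericMatrix &img,
                                const std::vector<double> &ker) {
  const int h = img.nrow(), w = img.ncol();
  const int k = (int)ker.size(), r = k / 2;
  NumericMatrix tmp(h, w), out(h, w);
  const double *src = &img[0];
  double *t = &tmp[0], *o = &out[0];
  // horizontal pass (replicate border): column-at-a-time axpy keeps the
  // column-major layout cache-friendly
  for (int x = 0; x < w; ++x) {
    double *dst = t + (R_xlen_t)x * h;
    for (int y = 0; y < h; ++y) dst[y] = 0.0;
    for (int j = -r; j <= r; ++j) {
      int xx = x + j;
      if (xx < 0) xx = 0;
      if (xx >= w) xx = w - 1;
      const double kj = ker[j + r];
      const double *s = src + (R_xlen_t)xx * h;
      for (int y = 0; y < h; ++y) dst[y] += kj * s[y];
    }
  }
  // vertical pass: within-column windows are contiguous
  for (int x = 0; x < w; ++x) {
    const double *s = t + (R_xlen_t)x * h;
    double *dst = o + (R_xlen_t)x * h;
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      if (y >= r && y < h - r) {
        for (int j = -r; j <= r; ++j) acc += ker[j + r] * s[y + j];
      } else {
        for (int j = -r; j <= r; ++j) {
          int yy = y + j;
          if (yy < 0) yy = 0;
          if (yy >= h) yy = h - 1;
          acc += ker[j + r] * s[yy];
        }
      }
      dst[y] = acc;
    }
  }
  return out;
}

// Normalized box (mean) filter with odd kernel size k.
// [[Rcpp::export]]
NumericMatrix cpp_box_filter(NumericMatrix img, int k) {
  if (k < 1 || k % 2 == 0) stop("box kernel size must be odd and >= 1");
  if (k == 1) return clone(img);
  std::vector<double> ker(k, 1.0 / k);
  return sep_filter(img, ker);
}

// Gaussian filter with odd kernel size k and standard deviation sigma (px).
// [[Rcpp::export]]
NumericMatrix cpp_gauss_filter(NumericMatrix img, int k, double sigma) {
  if (k < 1 || k % 2 == 0) stop("gaussian kernel size must be odd and >= 1");
  if (sigma <= 0) stop("gaussian sigma must be positive");
  if (k == 1) return clone(img);
  int r = k / 2;
  std::vector<double> ker(k);
  double s = 0.0;
  for (int j = -r; j <= r; ++j) {
    ker[j + r] = std::exp(-0.5 * (double)j * j / (sigma * sigma));
    s += ker[j + r];
  }
  for (int j = 0; j < k; ++j) ker[j] /= s;
  return sep_filter(img, ker);
}

// ---- HSV range mask --------------------------------------------------------

// Foreground mask: 1 where (H, S, V) falls inside [lo, hi] componentwise.
// A hue range with lo > hi wraps through 0 degrees.
// [[Rcpp::export]]
IntegerMatrix cpp_hsv_mask(NumericMatrix H, NumericMatrix S, NumericMatrix V,
                           NumericVector lo, NumericVector hi) {
  if (lo.size() != 3 || hi.size() != 3) stop("lo and hi must be HSV triples");
  const int h = H.nrow(), w = H.ncol();
  IntegerMatrix mask(h, w);
  const bool wrap = lo[0] > hi[0];
  const R_xlen_t n = (R_xlen_t)h * w;
  const double *ph = &H[0], *ps = &S[0], *pv = &V[0];
  const double hlo = lo[0], hhi = hi[0], slo = lo[1], shi = hi[1],
               vlo = lo[2], vhi = hi[2];
  int *pm = &mask[0];
  for (R_xlen_t i = 0; i < n; ++i) {
    bool inh = wrap ? (ph[i] >= hlo || ph[i] <= hhi)
                    : (ph[i] >= hlo && ph[i] <= hhi);
    pm[i] = (inh && ps[i] >= slo && ps[i] <= shi &&
             pv[i] >= vlo && pv[i] <= vhi) ? 1 : 0;
  }
  return mask;
}

// ---- fused front end -------------------------------------------------------

static void sep_filter_buf(const double *src, double *dst, double *tmp,
                           int h, int w, const std::vector<double> &ker) {
  const int k = (int)ker.size(), r = k / 2;
  std::vector<const double *> cols(k);
  for (int x = 0; x < w; ++x) {
    double *d = tmp + (R_xlen_t)x * h;
    for (int j = -r; j <= r; ++j) {
      int xx = x + j;
      if (xx < 0) xx = 0;
      if (xx >= w) xx = w - 1;
      cols[j + r] = src + (R_xlen_t)xx * h;
    }
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      for (int j = 0; j < k; ++j) acc += ker[j] * cols[j][y];
      d[y] = acc;
    }
  }
  for (int x = 0; x < w; ++x) {
    const double *s = tmp + (R_xlen_t)x * h;
    double *d = dst + (R_xlen_t)x * h;
    for (int y = 0; y < h; ++y) {
      double acc = 0.0;
      if (y >= r && y < h - r) {
        for (int j = -r; j <= r; ++j) acc += ker[j + r] * s[y + j];
      } else {
        for (int j = -r; j <= r; ++j) {
          int yy = y + j;
          if (yy < 0) yy = 0;
          if (yy >= h) yy = h - 1;
          acc += ker[j + r] * s[yy];
        }
      }
      d[y] = acc;
    }
  }
}

// Full front end of the detection chain in one pass: RGB -> HSV, box then
// Gaussian smoothing of each HSV channel, HSV range mask, and the 256-bin
// histogram of the masked grayscale (smoothed V * 255 where mask is 1,
// 0 elsewhere). Identical to composing cpp_rgb2hsv, cpp_box_filter,
// cpp_gauss_filter and cpp_hsv_mask (asserted in the tests); exists because
// the per-frame loop is the hot path.
// [[Rcpp::export]]
List cpp_chain_mask(NumericVector frame, NumericVector lo, NumericVector hi,
                    int box_k, int gauss_k, double gauss_sigma) {
  IntegerVector dims = frame.attr("dim");
  if (dims.size() != 3 || dims[2] != 3) stop("frame must be h x w x 3");
  const int h = dims[0], w = dims[1];
  const R_xlen_t n = (R_xlen_t)h * w;
  NumericMatrix Hm(h, w), Sm(h, w), Vm(h, w);
  {
    const double *p = REAL(frame);
    double *ph = &Hm[0], *ps = &Sm[0], *pv = &Vm[0];
    for (R_xlen_t i = 0; i < n; ++i) {
      double r = p[i], g = p[i + n], b = p[i + 2 * n];
      double mx = std::max(r, std::max(g, b));
      double mn = std::min(r, std::min(g, b));
      double d = mx - mn, hh = 0.0;
      if (d > 0) {
        if (mx == r)      hh = 60.0 * (g - b) / d;
        else if (mx == g) hh = 120.0 + 60.0 * (b - r) / d;
        else              hh = 240.0 + 60.0 * (r - g) / d;
        if (hh < 0) hh += 360.0;
        if (hh >= 360.0) hh -= 360.0;
      }
      ph[i] = hh;
      ps[i] = mx > 0 ? d / mx : 0.0;
      pv[i] = mx / 255.0;
    }
  }
  std::vector<double> kbox(box_k, 1.0 / box_k), kg(gauss_k), tmp(n), buf(n);
  {
    int r = gauss_k / 2;
    double s = 0.0;
    for (int j = -r; j <= r; ++j) {
      kg[j + r] = std::exp(-0.5 * (double)j * j / (gauss_sigma * gauss_sigma));
      s += kg[j + r];
    }
    for (int j = 0; j < gauss_k; ++j) kg[j] /= s;
  }
  NumericMatrix *chans[3] = {&Hm, &Sm, &Vm};
  for (int c = 0; c < 3; ++c) {
    double *p = &(*chans[c])[0];
    if (box_k > 1) {
      sep_filter_buf(p, buf.data(), tmp.data(), h, w, kbox);
      std::copy(buf.begin(), buf.end(), p);
    }
    if (gauss_k > 1) {
      sep_filter_buf(p, buf.data(), tmp.data(), h, w, kg);
      std::copy(buf.begin(), buf.end(), p);
    }
  }
  IntegerMatrix mask(h, w);
  NumericVector hist(256);
  {
    const double *ph = &Hm[0], *ps = &Sm[0], *pv = &Vm[0];
    int *pm = &mask[0];
    const bool wrap = lo[0] > hi[0];
    for (R_xlen_t i = 0; i < n; ++i) {
      bool inh = wrap ? (ph[i] >= lo[0] || ph[i] <= hi[0])
                      : (ph[i] >= lo[0] && ph[i] <= hi[0]);
      bool m = inh && ps[i] >= lo[1] && ps[i] <= hi[1] &&
               pv[i] >= lo[2] && pv[i] <= hi[2];
      pm[i] = m ? 1 : 0;
      int bin = m ? (int)std::floor(pv[i] * 255.0) : 0;
      if (bin < 0) bin = 0;
      if (bin > 255) bin = 255;
      hist[bin] += 1.0;
    }
  }
  return List::create(_["mask"] = mask, _["v_smooth"] = Vm,
                      _["gray_hist"] = hist);
}

// Binary image: mask foreground whose masked grayscale (v * 255) exceeds
// the threshold.
// [[Rcpp::export]]
IntegerMatrix cpp_apply_threshold(IntegerMatrix mask, NumericMatrix v,
                                  double thr) {
  const R_xlen_t n = (R_xlen_t)mask.nrow() * mask.ncol();
  IntegerMatrix out(mask.nrow(), mask.ncol());
  const int *pm = &mask[0];
  const double *pv = &v[0];
  int *po = &out[0];
  for (R_xlen_t i = 0; i < n; ++i)
    po[i] = (pm[i] != 0 && pv[i] * 255.0 > thr) ? 1 : 0;
  return out;
}

// ---- connected components --------------------------------------------------

// 8-connected labelling of a binary mask. Returns the label image (0 =
// background) and a per-label stats matrix: size, sum_x, sum_y, xmin, xmax,
// ymin, ymax (pixel coordinates, 0-based).
// [[Rcpp::export]]
List cpp_label(IntegerMatrix mask) {
  const int h = mask.nrow(), w = mask.ncol();
  IntegerMatrix labels(h, w);
  std::vector<double> size, sx, sy;
  std::vector<int> xmin, xmax, ymin, ymax;
  std::vector<int> stack;
  stack.reserve(1024);
  int next = 0;
  for (int x0 = 0; x0 < w; ++x0)
    for (int y0 = 0; y0 < h; ++y0) {
      if (mask(y0, x0) == 0 || labels(y0, x0) != 0) continue;
      ++next;
      size.push_back(0); sx.push_back(0); sy.push_back(0);
      xmin.push_back(x0); xmax.push_back(x0);
      ymin.push_back(y0); ymax.push_back(y0);
      stack.push_back(y0 + x0 * h);
      labels(y0, x0) = next;
      while (!stack.empty()) {
        int idx = stack.back(); stack.pop_back();
        int y = idx % h, x = idx / h;
        size[next - 1] += 1; sx[next - 1] += x; sy[next - 1] += y;
        if (x < xmin[next - 1]) xmin[next - 1] = x;
        if (x > xmax[next - 1]) xmax[next - 1] = x;
        if (y < ymin[next - 1]) ymin[next - 1] = y;
        if (y > ymax[next - 1]) ymax[next - 1] = y;
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0) continue;
            int yy = y + dy, xx = x + dx;
            if (yy < 0 || yy >= h || xx < 0 || xx >= w) continue;
            if (mask(yy, xx) != 0 && labels(yy, xx) == 0) {
              labels(yy, xx) = next;
              stack.push_back(yy + xx * h);
            }
          }
      }
    }
  NumericMatrix stats(next, 7);
  for (int i = 0; i < next; ++i) {
    stats(i, 0) = size[i]; stats(i, 1) = sx[i]; stats(i, 2) = sy[i];
    stats(i, 3) = xmin[i]; stats(i, 4) = xmax[i];
    stats(i, 5) = ymin[i]; stats(i, 6) = ymax[i];
  }
  colnames(stats) = CharacterVector::create("size", "sum_x", "sum_y",
                                            "xmin", "xmax", "ymin", "ymax");
  return List::create(_["labels"] = labels, _["stats"] = stats);
}

// ---- boundary tracing ------------------------------------------------------

// Moore-neighbour boundary tracing (clockwise, Jacob's stopping criterion)
// of the component with the given label. Returns an n x 2 matrix of (x, y)
// pixel-center coordinates, ordered along the outer boundary.
// [[Rcpp::export]]
NumericMatrix cpp_trace_boundary(IntegerMatrix labels, int id) {
  const int h = labels.nrow(), w = labels.ncol();
  // clockwise neighbour order starting East (x right, y down)
  static const int DX[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  static const int DY[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int sx = -1, sy = -1;
  for (int y = 0; y < h && sx < 0; ++y)
    for (int x = 0; x < w; ++x)
      if (labels(y, x) == id) { sx = x; sy = y; break; }
  if (sx < 0) stop("label not present in image");
  std::vector<std::pair<int, int>> pts;
  pts.push_back({sx, sy});
  // entered the start pixel "from the west" (scan order guarantees the west
  // neighbour is background)
  int b = 4;  // direction from current pixel to its backtrack neighbour
  int cx = sx, cy = sy;
  const int b0 = b;
  // directed-state visit map: Jacob's criterion alone can cycle on thin
  // 8-connected structures, so any repeated (pixel, backtrack) state stops
  // the trace as well
  std::vector<unsigned char> seen((size_t)h * w, 0);
  seen[(size_t)sy + (size_t)sx * h] |= (unsigned char)(1 << b);
  long guard = 8L * (long)h * (long)w + 8;
  while (guard-- > 0) {
    int found = -1, fi = -1;
    for (int i = 1; i <= 8; ++i) {
      int d = (b + i) % 8;
      int nx = cx + DX[d], ny = cy + DY[d];
      if (nx < 0 || nx >= w || ny < 0 || ny >= h) continue;
      if (labels(ny, nx) == id) { found = d; fi = i; break; }
    }
    if (found < 0) break;  // isolated pixel
    // backtrack for the next pixel: the neighbour checked just before the
    // one that was found (always background or out of bounds)
    int e = (b + fi - 1) % 8;
    int rx = cx + DX[e], ry = cy + DY[e];
    cx += DX[found]; cy += DY[found];
    int ddx = rx - cx, ddy = ry - cy;
    int nb = -1;
    for (int d = 0; d < 8; ++d)
      if (DX[d] == ddx && DY[d] == ddy) { nb = d; break; }
    b = nb;
    // Jacob's criterion: back at the start pixel with the original backtrack
    if (cx == sx && cy == sy && b == b0) break;
    size_t si = (size_t)cy + (size_t)cx * h;
    if (seen[si] & (1 << b)) break;  // directed state repeated: closed tour
    seen[si] |= (unsigned char)(1 << b);
    pts.push_back({cx, cy});
  }
  NumericMatrix out(pts.size(), 2);
  for (size_t i = 0; i < pts.size(); ++i) {
    out(i, 0) = pts[i].first;
    out(i, 1) = pts[i].second;
  }
  colnames(out) = CharacterVector::create("x", "y");
  return out;
}

// ---- minimum enclosing circle ----------------------------------------------

struct Circ { double x, y, r; };

static inline bool in_circ(const Circ &c, double px, double py) {
  double dx = px - c.x, dy = py - c.y;
  return std::sqrt(dx * dx + dy * dy) <= c.r + 1e-9 * (1.0 + c.r);
}

static Circ circ2(double ax, double ay, double bx, double by) {
  double dx = bx - ax, dy = by - ay;
  return {(ax + bx) / 2, (ay + by) / 2, std::sqrt(dx * dx + dy * dy) / 2};
}

static Circ circ3(double ax, double ay, double bx, double by,
                  double cx, double cy) {
  double d = 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by));
  if (std::fabs(d) < 1e-12) {
    Circ c1 = circ2(ax, ay, bx, by), c2 = circ2(ax, ay, cx, cy),
         c3 = circ2(bx, by, cx, cy);
    Circ best = c1;
    if (c2.r > best.r) best = c2;
    if (c3.r > best.r) best = c3;
    return best;
  }
  double a2 = ax * ax + ay * ay, b2 = bx * bx + by * by,
         c2_ = cx * cx + cy * cy;
  double ux = (a2 * (by - cy) + b2 * (cy - ay) + c2_ * (ay - by)) / d;
  double uy = (a2 * (cx - bx) + b2 * (ax - cx) + c2_ * (bx - ax)) / d;
  double dx = ax - ux, dy = ay - uy;
  return {ux, uy, std::sqrt(dx * dx + dy * dy)};
}

// Welzl's move-to-front minimum enclosing circle; points are shuffled with
// a deterministic LCG so the result does not depend on input order.
// [[Rcpp::export]]
NumericVector cpp_min_enclosing_circle(NumericMatrix points) {
  int n = points.nrow();
  if (n < 1) stop("`points` must contain at least one point");
  std::vector<double> X(n), Y(n);
  for (int i = 0; i < n; ++i) { X[i] = points(i, 0); Y[i] = points(i, 1); }
  // deterministic Fisher-Yates
  uint64_t s = 0x9e3779b97f4a7c15ULL + (uint64_t)n;
  for (int i = n - 1; i > 0; --i) {
    s = s * 6364136223846793005ULL + 1442695040888963407ULL;
    int j = (int)((s >> 33) % (uint64_t)(i + 1));
    std::swap(X[i], X[j]); std::swap(Y[i], Y[j]);
  }
  if (n == 1) return NumericVector::create(X[0], Y[0], 0.0);
  Circ c = circ2(X[0], Y[0], X[1], Y[1]);
  for (int i = 2; i < n; ++i) {
    if (in_circ(c, X[i], Y[i])) continue;
    c = {X[i], Y[i], 0.0};
    for (int j = 0; j < i; ++j) {
      if (in_circ(c, X[j], Y[j])) continue;
      c = circ2(X[i], Y[i], X[j], Y[j]);
      for (int k = 0; k < j; ++k) {
        if (in_circ(c, X[k], Y[k])) continue;
        c = circ3(X[i], Y[i], X[j], Y[j], X[k], Y[k]);
      }
    }
  }
  return NumericVector::create(c.x, c.y, c.r);
}

// ---- circle-restricted pixel counting --------------------------------------

// Counts pixels whose centers lie inside the disk (center cx,cy radius r):
// total, nonzero (mask foreground), zero, and "filled" = foreground OR inside
// the convex hull polygon (n x 2, (x,y), in order). The hull fill models
// convex restoration of the egg silhouette; an empty hull (0 rows) disables it.
// [[Rcpp::export]]
NumericVector cpp_disk_counts(IntegerMatrix mask, double cx, double cy,
                              double r, NumericMatrix hull) {
  const int h = mask.nrow(), w = mask.ncol();
  const int x0 = std::max(0, (int)std::floor(cx - r) - 1);
  const int x1 = std::min(w - 1, (int)std::ceil(cx + r) + 1);
  const int y0 = std::max(0, (int)std::floor(cy - r) - 1);
  const int y1 = std::min(h - 1, (int)std::ceil(cy + r) + 1);
  const double r2 = r * r + 1e-9;
  const int nh = hull.nrow();
  double total = 0, nonzero = 0, filled = 0;
  for (int y = y0; y <= y1; ++y)
    for (int x = x0; x <= x1; ++x) {
      double dx = x - cx, dy = y - cy;
      if (dx * dx + dy * dy > r2) continue;
      total += 1;
      bool fg = mask(y, x) != 0;
      if (fg) nonzero += 1;
      if (fg) { filled += 1; continue; }
      if (nh >= 3) {
        // point-in-convex-polygon: consistent sign of cross products
        bool pos = false, neg = false, inside = true;
        for (int i = 0; i < nh; ++i) {
          int j = (i + 1) % nh;
          double cr = (hull(j, 0) - hull(i, 0)) * (y - hull(i, 1)) -
                      (hull(j, 1) - hull(i, 1)) * (x - hull(i, 0));
          if (cr > 1e-9) pos = true;
          if (cr < -1e-9) neg = true;
          if (pos && neg) { inside = false; break; }
        }
        if (inside) filled += 1;
      }
    }
  return NumericVector::create(_["total"] = total, _["nonzero"] = nonzero,
                               _["zero"] = total - nonzero,
                               _["filled"] = filled);
}

// ---- synthetic renderer ----------------------------------------------------

// Renders one conveyor frame. eggs: rows (cx, cy, a, b, R, G, B); dirt: rows
// (egg_row, cx, cy, radius, darkness). field: h x w illumination multiplier.
// Gaussian achromatic noise with sd noise_sd is added to all three channels
// (seeded deterministically); values are clipped to [0, 255].
// [[Rcpp::export]]
NumericVector cpp_render_frame(int h, int w, NumericVector bg,
                               NumericMatrix field, NumericMatrix eggs,
                               NumericMatrix dirt, double noise_sd,
                               double seed) {
  if (bg.size() != 3) stop("bg must be an RGB triple");
  const R_xlen_t n = (R_xlen_t)h * w;
  NumericVector out(n * 3);
  double *p = REAL(out);
  // background
  for (int x = 0; x < w; ++x)
    for (int y = 0; y < h; ++y) {
      R_xlen_t i = (R_xlen_t)y + (R_xlen_t)x * h;
      double f = field(y, x);
      p[i] = bg[0] * f; p[i + n] = bg[1] * f; p[i + 2 * n] = bg[2] * f;
    }
  // eggs and dirt
  for (int e = 0; e < eggs.nrow(); ++e) {
    double cx = eggs(e, 0), cy = eggs(e, 1), a = eggs(e, 2), b = eggs(e, 3);
    int x0 = std::max(0, (int)std::floor(cx - a));
    int x1 = std::min(w - 1, (int)std::ceil(cx + a));
    int y0 = std::max(0, (int)std::floor(cy - b));
    int y1 = std::min(h - 1, (int)std::ceil(cy + b));
    for (int y = y0; y <= y1; ++y)
      for (int x = x0; x <= x1; ++x) {
        double ex = (x - cx) / a, ey = (y - cy) / b;
        if (ex * ex + ey * ey > 1.0) continue;
        double mul = 1.0;
        for (int d = 0; d < dirt.nrow(); ++d) {
          if ((int)dirt(d, 0) != e + 1) continue;
          double dx = x - dirt(d, 1), dy = y - dirt(d, 2);
          if (dx * dx + dy * dy <= dirt(d, 3) * dirt(d, 3))
            mul = std::min(mul, dirt(d, 4));
        }
        double f = field(y, x);
        R_xlen_t i = (R_xlen_t)y + (R_xlen_t)x * h;
        p[i] = eggs(e, 4) * mul * f;
        p[i + n] = eggs(e, 5) * mul * f;
        p[i + 2 * n] = eggs(e, 6) * mul * f;
      }
  }
  // achromatic sensor noise; clip fused into the same pass (noise-free
  // synthetic colours already lie in [0, 255])
  if (noise_sd > 0) {
    std::mt19937_64 rng((uint64_t)seed);
    std::normal_distribution<double> norm(0.0, noise_sd);
    for (R_xlen_t i = 0; i < n; ++i) {
      double z = norm(rng);
      for (int c = 0; c < 3; ++c) {
        double v = p[i + c * n] + z;
        if (v < 0) v = 0;
        if (v > 255) v = 255;
        p[i + c * n] = v;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(h, w, 3);
  return out;
}
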