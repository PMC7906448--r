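// Image-processing kernels for top-view livestock morphometry.
//
// All kernels operate on R matrices in the usual orientation: H rows
// (y, down) by W columns (x, right), 0-based internally. They are the
// single implementation behind both the per-frame R API and the
// streaming synthetic-video path, so measurements agree bit-for-bit.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <limits>

using namespace Rcpp;

static const double EDT_INF = 1e20;

// ---------------------------------------------------------------------------
// Otsu threshold on an 8-bit histogram. Foreground is gray > t.
// ---------------------------------------------------------------------------
static int otsu_from_hist(const std::vector<double> &hist) {
  double total = 0.0, sum_all = 0.0;
  for (int i = 0; i < 256; ++i) {
    total += hist[i];
    sum_all += i * hist[i];
  }
  if (total <= 0) return 127;
  double w0 = 0.0, sum0 = 0.0, best = -1.0;
  int first_t = 0, last_t = 0;
  for (int t = 0; t < 256; ++t) {
    w0 += hist[t];
    if (w0 <= 0) continue;
    double w1 = total - w0;
    if (w1 <= 0) break;
    sum0 += t * hist[t];
    double mu0 = sum0 / w0;
    double mu1 = (sum_all - sum0) / w1;
    double between = w0 * w1 * (mu0 - mu1) * (mu0 - mu1);
    if (between > best + 1e-9) {
      best = between;
      first_t = last_t = t;
    } else if (between >= best - 1e-9) {
      last_t = t;  // plateau: every threshold separates equally well
    }
  }
  return (first_t + last_t) / 2;  // midpoint of the argmax plateau
}

// [[Rcpp::export]]
int otsu_threshold_cpp(IntegerMatrix gray) {
  std::vector<double> hist(256, 0.0);
  const int n = gray.size();
  for (int i = 0; i < n; ++i) {
    int v = gray[i];
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    hist[v] += 1.0;
  }
  return otsu_from_hist(hist);
}

// ---------------------------------------------------------------------------
// Largest 8-connected component of a binary image (stored as 0/1 ints in
// a flat vector, h x w). Ties on area are broken by the smallest bounding-
// box top-left coordinate (min row, then min col). Returns area (0 if no
// foreground); fills `out` with the component mask and bbox[4] = r0,r1,c0,c1.
// ---------------------------------------------------------------------------
static int largest_component_lab(const std::vector<unsigned char> &bin, int h,
                                 int w, std::vector<int> &label, int &best_lab_out,
                                 int bbox[4]) {
  label.assign(static_cast<size_t>(h) * w, 0);
  std::vector<int> stack;
  stack.reserve(1024);
  int best_area = 0, best_lab = 0;
  int best_r0 = h, best_c0 = w;
  int lab = 0;
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      size_t idx = static_cast<size_t>(c) * h + r;
      if (!bin[idx] || label[idx]) continue;
      ++lab;
      int area = 0, r0 = r, r1 = r, c0 = c, c1 = c;
      label[idx] = lab;
      stack.clear();
      stack.push_back(static_cast<int>(idx));
      while (!stack.empty()) {
        int cur = stack.back();
        stack.pop_back();
        int cr = cur % h, cc = cur / h;
        ++area;
        if (cr < r0) r0 = cr;
        if (cr > r1) r1 = cr;
        if (cc < c0) c0 = cc;
        if (cc > c1) c1 = cc;
        for (int dc = -1; dc <= 1; ++dc) {
          int nc = cc + dc;
          if (nc < 0 || nc >= w) continue;
          for (int dr = -1; dr <= 1; ++dr) {
            if (dr == 0 && dc == 0) continue;
            int nr = cr + dr;
            if (nr < 0 || nr >= h) continue;
            size_t nidx = static_cast<size_t>(nc) * h + nr;
            if (bin[nidx] && !label[nidx]) {
              label[nidx] = lab;
              stack.push_back(static_cast<int>(nidx));
            }
          }
        }
      }
      bool better = area > best_area ||
                    (area == best_area &&
                     (r0 < best_r0 || (r0 == best_r0 && c0 < best_c0)));
      if (better) {
        best_area = area;
        best_lab = lab;
        best_r0 = r0;
        best_c0 = c0;
        bbox[0] = r0; bbox[1] = r1; bbox[2] = c0; bbox[3] = c1;
      }
    }
  }
  best_lab_out = best_lab;
  return best_area;
}

static int largest_component(const std::vector<unsigned char> &bin, int h, int w,
                             std::vector<unsigned char> &out, int bbox[4]) {
  std::vector<int> label;
  int best_lab = 0;
  int best_area = largest_component_lab(bin, h, w, label, best_lab, bbox);
  out.assign(static_cast<size_t>(h) * w, 0);
  if (best_area == 0) return 0;
  for (size_t i = 0; i < label.size(); ++i)
    if (label[i] == best_lab) out[i] = 1;
  return best_area;
}

// ---------------------------------------------------------------------------
// 1-D squared distance transform (lower envelope of parabolas).
// ---------------------------------------------------------------------------
static void dt1d(const std::vector<double> &f, std::vector<double> &d, int n,
                 std::vector<int> &v, std::vector<double> &z) {
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_INF;
  z[1] = EDT_INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = EDT_INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance to the nearest "seed" pixel (f = 0 at seeds,
// INF elsewhere), in place, on an h x w column-major grid.
static void edt2d(std::vector<double> &f, int h, int w) {
  int nmax = std::max(h, w);
  std::vector<double> col(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);
  for (int c = 0; c < w; ++c) {
    double *p = &f[static_cast<size_t>(c) * h];
    for (int r = 0; r < h; ++r) col[r] = p[r];
    dt1d(col, d, h, v, z);
    for (int r = 0; r < h; ++r) p[r] = d[r];
  }
  std::vector<double> row(w);
  for (int r = 0; r < h; ++r) {
    for (int c = 0; c < w; ++c) row[c] = f[static_cast<size_t>(c) * h + r];
    dt1d(row, d, w, v, z);
    for (int c = 0; c < w; ++c) f[static_cast<size_t>(c) * h + r] = d[c];
  }
}

// ---------------------------------------------------------------------------
// Binary opening by a Euclidean disc of radius `radius` on a crop whose
// offset within the full frame is (roff, coff); the full frame is H x W.
// Pixels outside the image count as background for the erosion (objects
// clipped by the frame edge erode there, as with a zero-padded border).
// ---------------------------------------------------------------------------
static void open_disc(std::vector<unsigned char> &m, int h, int w,
                      double radius, int roff, int coff, int H, int W) {
  if (radius <= 0) return;
  const double r2 = radius * radius;
  size_t n = static_cast<size_t>(h) * w;
  std::vector<double> f(n);
  // erosion: distance to nearest background (incl. outside the image)
  for (size_t i = 0; i < n; ++i) f[i] = m[i] ? EDT_INF : 0.0;
  edt2d(f, h, w);
  std::vector<unsigned char> er(n, 0);
  for (int c = 0; c < w; ++c) {
    for (int r = 0; r < h; ++r) {
      size_t i = static_cast<size_t>(c) * h + r;
      if (!m[i]) continue;
      double gr = r + roff, gc = c + coff;
      double db = std::min(std::min(gr + 1.0, H - gr), std::min(gc + 1.0, W - gc));
      double sq = std::min(f[i], db * db);
      if (sq > r2) er[i] = 1;
    }
  }
  // dilation of the eroded set by the same disc
  for (size_t i = 0; i < n; ++i) f[i] = er[i] ? 0.0 : EDT_INF;
  edt2d(f, h, w);
  for (size_t i = 0; i < n; ++i) m[i] = (f[i] <= r2) ? 1 : 0;
}

// ---------------------------------------------------------------------------
// Moore-neighbour boundary tracing of a single 8-connected component.
// Returns ordered (x, y) boundary pixels, 0-based.
// ---------------------------------------------------------------------------
static void trace_contour(const std::vector<unsigned char> &m, int h, int w,
                          std::vector<double> &cx, std::vector<double> &cy) {
  cx.clear();
  cy.clear();
  int sr = -1, sc = -1;
  for (int r = 0; r < h && sr < 0; ++r)
    for (int c = 0; c < w; ++c)
      if (m[static_cast<size_t>(c) * h + r]) { sr = r; sc = c; break; }
  if (sr < 0) return;
  // clockwise neighbour ring (y down): W, NW, N, NE, E, SE, S, SW
  static const int dr[8] = {0, -1, -1, -1, 0, 1, 1, 1};
  static const int dc[8] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto fg = [&](int r, int c) {
    return r >= 0 && r < h && c >= 0 && c < w &&
           m[static_cast<size_t>(c) * h + r];
  };
  auto ring_index = [&](int drr, int dcc) {
    for (int k = 0; k < 8; ++k)
      if (dr[k] == drr && dc[k] == dcc) return k;
    return 0;
  };
  // start pixel is topmost-leftmost, so its west neighbour is background
  int br = sr, bc = sc;          // current boundary pixel
  int tr = sr, tc = sc - 1;      // backtrack (last background seen)
  const int tr0 = tr, tc0 = tc;  // Jacob's stopping state
  cx.push_back(bc);
  cy.push_back(br);
  const size_t maxit = 4 * static_cast<size_t>(h) * w + 16;
  for (size_t it = 0; it < maxit; ++it) {
    int base = ring_index(tr - br, tc - bc);
    int found = -1, lr = tr, lc = tc;
    for (int k = 1; k <= 8; ++k) {
      int d = (base + k) % 8;
      int nr = br + dr[d], nc = bc + dc[d];
      if (fg(nr, nc)) {
        found = d;
        break;
      }
      lr = nr;
      lc = nc;
    }
    if (found < 0) return;  // isolated single pixel
    int nr = br + dr[found], nc = bc + dc[found];
    if (nr == sr && nc == sc && lr == tr0 && lc == tc0) return;  // loop closed
    br = nr;
    bc = nc;
    tr = lr;
    tc = lc;
    cx.push_back(bc);
    cy.push_back(br);
  }
}

// ---------------------------------------------------------------------------
// Convex hull (monotone chain) and exact rotating-calipers minimum-area
// rectangle. Points are (x, y) doubles. The reported sides follow the pixel
// footprint convention: each extent is padded by `pad` (split half per end).
// ---------------------------------------------------------------------------
struct Pt { double x, y; };

static double cross3(const Pt &o, const Pt &a, const Pt &b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

static std::vector<Pt> convex_hull(std::vector<Pt> pts) {
  std::sort(pts.begin(), pts.end(), [](const Pt &a, const Pt &b) {
    return a.x < b.x || (a.x == b.x && a.y < b.y);
  });
  pts.erase(std::unique(pts.begin(), pts.end(), [](const Pt &a, const Pt &b) {
              return a.x == b.x && a.y == b.y;
            }),
            pts.end());
  int n = static_cast<int>(pts.size());
  if (n < 3) return pts;
  std::vector<Pt> hull(2 * n);
  int k = 0;
  for (int i = 0; i < n; ++i) {
    while (k >= 2 && cross3(hull[k - 2], hull[k - 1], pts[i]) <= 0) --k;
    hull[k++] = pts[i];
  }
  int lower = k + 1;
  for (int i = n - 2; i >= 0; --i) {
    while (k >= lower && cross3(hull[k - 2], hull[k - 1], pts[i]) <= 0) --k;
    hull[k++] = pts[i];
  }
  hull.resize(k - 1);
  return hull;
}

static List min_area_rect_core(const std::vector<Pt> &pts, double pad) {
  std::vector<Pt> hull = convex_hull(pts);
  int n = static_cast<int>(hull.size());
  if (n < 3) return List::create(Named("ok") = false);
  double best_area = std::numeric_limits<double>::infinity();
  double b_ca = 0, b_sa = 0, b_u0 = 0, b_u1 = 0, b_v0 = 0, b_v1 = 0;
  for (int i = 0; i < n; ++i) {
    const Pt &p = hull[i];
    const Pt &q = hull[(i + 1) % n];
    double ex = q.x - p.x, ey = q.y - p.y;
    double len = std::sqrt(ex * ex + ey * ey);
    if (len <= 0) continue;
    double ca = ex / len, sa = ey / len;
    double u0 = EDT_INF, u1 = -EDT_INF, v0 = EDT_INF, v1 = -EDT_INF;
    for (int j = 0; j < n; ++j) {
      double u = hull[j].x * ca + hull[j].y * sa;
      double v = -hull[j].x * sa + hull[j].y * ca;
      if (u < u0) u0 = u;
      if (u > u1) u1 = u;
      if (v < v0) v0 = v;
      if (v > v1) v1 = v;
    }
    double area = (u1 - u0) * (v1 - v0);
    if (area < best_area) {
      best_area = area;
      b_ca = ca; b_sa = sa; b_u0 = u0; b_u1 = u1; b_v0 = v0; b_v1 = v1;
    }
  }
  if (!std::isfinite(best_area)) return List::create(Named("ok") = false);
  double half = pad / 2.0;
  double side_a = (b_u1 - b_u0) + pad;
  double side_b = (b_v1 - b_v0) + pad;
  double mu = (b_u0 + b_u1) / 2.0, mv = (b_v0 + b_v1) / 2.0;
  double cx = mu * b_ca - mv * b_sa;
  double cy = mu * b_sa + mv * b_ca;
  NumericMatrix corners(4, 2);
  double us[4] = {b_u0 - half, b_u1 + half, b_u1 + half, b_u0 - half};
  double vs[4] = {b_v0 - half, b_v0 - half, b_v1 + half, b_v1 + half};
  for (int k = 0; k < 4; ++k) {
    corners(k, 0) = us[k] * b_ca - vs[k] * b_sa;
    corners(k, 1) = us[k] * b_sa + vs[k] * b_ca;
  }
  double ang = std::atan2(b_sa, b_ca) * 180.0 / M_PI;
  while (ang < 0) ang += 180.0;
  while (ang >= 180.0) ang -= 180.0;
  return List::create(Named("ok") = true, Named("center_x") = cx,
                      Named("center_y") = cy, Named("side_a") = side_a,
                      Named("side_b") = side_b, Named("angle") = ang,
                      Named("corners") = corners);
}

// [[Rcpp::export]]
List min_area_rect_cpp(NumericMatrix points, double pad) {
  std::vector<Pt> pts(points.nrow());
  for (int i = 0; i < points.nrow(); ++i) {
    pts[i].x = points(i, 0);
    pts[i].y = points(i, 1);
  }
  return min_area_rect_core(pts, pad);
}

// ---------------------------------------------------------------------------
// Shared segmentation core: threshold -> largest component -> disc opening
// -> largest component -> ordered contour + centroid.
// ---------------------------------------------------------------------------
struct SegResult {
  bool found;
  int area;
  int threshold;
  bool bright_foreground;
  std::vector<unsigned char> mask;  // full frame (only if requested)
  std::vector<double> cx, cy;       // contour, 0-based (x, y)
  double centroid_x, centroid_y;
};

// Reusable scratch buffers so the per-frame streaming loop does not
// reallocate full-frame arrays on every call.
struct SegWorkspace {
  std::vector<unsigned char> bin, crop, opened;
  std::vector<int> label;
};

static void segment_core(const int *gray, int h, int w, double open_radius,
                         int fixed_threshold, bool auto_polarity,
                         bool want_mask, SegWorkspace &ws, SegResult &res) {
  size_t n = static_cast<size_t>(h) * w;
  std::vector<double> hist(256, 0.0);
  for (size_t i = 0; i < n; ++i) {
    int v = gray[i];
    if (v < 0) v = 0;
    if (v > 255) v = 255;
    hist[v] += 1.0;
  }
  int t = fixed_threshold >= 0 ? fixed_threshold : otsu_from_hist(hist);
  res.threshold = t;
  ws.bin.resize(n);
  int bbox[4] = {0, 0, 0, 0};
  int best_lab = 0;
  bool bright = true;
  for (size_t i = 0; i < n; ++i) ws.bin[i] = gray[i] > t;
  int area = largest_component_lab(ws.bin, h, w, ws.label, best_lab, bbox);
  if (auto_polarity && area >= (int)(n / 2)) {
    for (size_t i = 0; i < n; ++i) ws.bin[i] = gray[i] <= t;
    int area2 = largest_component_lab(ws.bin, h, w, ws.label, best_lab, bbox);
    if (area2 < (int)(n / 2)) {
      area = area2;
      bright = false;
    } else {
      area = 0;  // neither side yields a sub-half-frame object
    }
  }
  res.bright_foreground = bright;
  if (area == 0) {
    res.found = false;
    res.area = 0;
    return;
  }
  // opening on a padded crop of the component's bounding box
  int margin = static_cast<int>(std::ceil(open_radius)) + 2;
  int r0 = std::max(0, bbox[0] - margin), r1 = std::min(h - 1, bbox[1] + margin);
  int c0 = std::max(0, bbox[2] - margin), c1 = std::min(w - 1, bbox[3] + margin);
  int ch = r1 - r0 + 1, cw = c1 - c0 + 1;
  ws.crop.assign(static_cast<size_t>(ch) * cw, 0);
  for (int c = c0; c <= c1; ++c)
    for (int r = r0; r <= r1; ++r)
      ws.crop[static_cast<size_t>(c - c0) * ch + (r - r0)] =
          ws.label[static_cast<size_t>(c) * h + r] == best_lab;
  open_disc(ws.crop, ch, cw, open_radius, r0, c0, h, w);
  int obbox[4];
  int oarea = largest_component(ws.crop, ch, cw, ws.opened, obbox);
  if (oarea == 0) {
    res.found = false;
    res.area = 0;
    return;
  }
  res.found = true;
  res.area = oarea;
  double sx = 0, sy = 0;
  if (want_mask) res.mask.assign(n, 0);
  for (int c = 0; c < cw; ++c) {
    for (int r = 0; r < ch; ++r) {
      if (ws.opened[static_cast<size_t>(c) * ch + r]) {
        if (want_mask)
          res.mask[static_cast<size_t>(c + c0) * h + (r + r0)] = 1;
        sx += c + c0;
        sy += r + r0;
      }
    }
  }
  res.centroid_x = sx / oarea;
  res.centroid_y = sy / oarea;
  trace_contour(ws.opened, ch, cw, res.cx, res.cy);
  for (size_t i = 0; i < res.cx.size(); ++i) {
    res.cx[i] += c0;
    res.cy[i] += r0;
  }
}

// [[Rcpp::export]]
List segment_largest_cpp(IntegerMatrix gray, double open_radius,
                         int fixed_threshold, bool auto_polarity) {
  int h = gray.nrow(), w = gray.ncol();
  SegWorkspace ws;
  SegResult res;
  segment_core(&gray[0], h, w, open_radius, fixed_threshold, auto_polarity,
               true, ws, res);
  if (!res.found) {
    return List::create(Named("found") = false,
                        Named("threshold") = res.threshold,
                        Named("bright_foreground") = res.bright_foreground);
  }
  LogicalMatrix mask(h, w);
  for (size_t i = 0; i < res.mask.size(); ++i) mask[i] = res.mask[i] != 0;
  int np = static_cast<int>(res.cx.size());
  NumericMatrix contour(np, 2);
  for (int i = 0; i < np; ++i) {
    contour(i, 0) = res.cx[i];
    contour(i, 1) = res.cy[i];
  }
  return List::create(
      Named("found") = true, Named("mask") = mask, Named("area") = res.area,
      Named("contour") = contour, Named("threshold") = res.threshold,
      Named("bright_foreground") = res.bright_foreground,
      Named("centroid_x") = res.centroid_x, Named("centroid_y") = res.centroid_y);
}

// ---------------------------------------------------------------------------
// Synthetic scene renderer. The animal is a filled rotated ellipse plus a
// thin tail rectangle at the +major pole; the depth surface tapers from the
// nominal height at the body centre to 70% at the outline. Depth noise is
// Gaussian truncated at +/- 4 sd, using R's RNG stream.
// ---------------------------------------------------------------------------
struct SceneBody {
  double cx, cy, ct, st, a, b, tail_len, tail_half;
};

static inline bool in_body(const SceneBody &s, double x, double y,
                           double &rell, bool &is_tail) {
  double dx = x - s.cx, dy = y - s.cy;
  double u = dx * s.ct + dy * s.st;
  double v = -dx * s.st + dy * s.ct;
  double q = (u / s.a) * (u / s.a) + (v / s.b) * (v / s.b);
  if (q <= 1.0) {
    rell = std::sqrt(q);
    is_tail = false;
    return true;
  }
  if (u >= s.a * 0.95 && u <= s.a + s.tail_len && std::fabs(v) <= s.tail_half) {
    rell = 1.0;
    is_tail = true;
    return true;
  }
  return false;
}

static SceneBody make_body(double cx, double cy, double theta_deg,
                           double len_px, double wid_px, double tail_len,
                           double tail_wid) {
  SceneBody s;
  s.cx = cx;
  s.cy = cy;
  double th = theta_deg * M_PI / 180.0;
  s.ct = std::cos(th);
  s.st = std::sin(th);
  s.a = len_px / 2.0;
  s.b = wid_px / 2.0;
  s.tail_len = tail_len;
  s.tail_half = tail_wid / 2.0;
  return s;
}

// Fill `g` (column-major h x w) with the floor intensity, draw the body,
// and optionally apply a directional box blur. `blur_src` is scratch.
static void render_gray_core(int *g, int width, int height, const SceneBody &s,
                             int pig_gray, int floor_gray, bool blurred,
                             double blur_len, double blur_theta_deg,
                             std::vector<int> &blur_src) {
  size_t n = static_cast<size_t>(width) * height;
  std::fill(g, g + n, floor_gray);
  double reach = s.a + s.tail_len + 2.0;
  int c0 = std::max(0, (int)std::floor(s.cx - reach));
  int c1 = std::min(width - 1, (int)std::ceil(s.cx + reach));
  int r0 = std::max(0, (int)std::floor(s.cy - reach));
  int r1 = std::min(height - 1, (int)std::ceil(s.cy + reach));
  for (int c = c0; c <= c1; ++c) {
    for (int r = r0; r <= r1; ++r) {
      double rell;
      bool tail;
      if (in_body(s, (double)c, (double)r, rell, tail))
        g[static_cast<size_t>(c) * height + r] = pig_gray;
    }
  }
  if (blurred && blur_len > 1.0) {
    double bt = blur_theta_deg * M_PI / 180.0;
    double bx = std::cos(bt), by = std::sin(bt);
    int k = (int)std::floor(blur_len / 2.0);
    int nk = 2 * k + 1;
    std::vector<int> off_r(nk), off_c(nk);
    for (int t = -k; t <= k; ++t) {
      off_c[t + k] = (int)std::lround(t * bx);
      off_r[t + k] = (int)std::lround(t * by);
    }
    int pad = (int)std::ceil(blur_len) + 1;
    int bc0 = std::max(0, c0 - pad), bc1 = std::min(width - 1, c1 + pad);
    int br0 = std::max(0, r0 - pad), br1 = std::min(height - 1, r1 + pad);
    blur_src.assign(g, g + n);
    for (int c = bc0; c <= bc1; ++c) {
      for (int r = br0; r <= br1; ++r) {
        double acc = 0.0;
        for (int t = 0; t < nk; ++t) {
          int sc = c + off_c[t];
          int sr = r + off_r[t];
          if (sc < 0) sc = 0;
          if (sc >= width) sc = width - 1;
          if (sr < 0) sr = 0;
          if (sr >= height) sr = height - 1;
          acc += blur_src[static_cast<size_t>(sc) * height + sr];
        }
        g[static_cast<size_t>(c) * height + r] = (int)std::lround(acc / nk);
      }
    }
  }
}

// [[Rcpp::export]]
List render_scene_cpp(int width, int height, double cx, double cy,
                      double theta_deg, double len_px, double wid_px,
                      double height_m, double posture_scale, bool blurred,
                      double blur_len, double blur_theta_deg,
                      int floor_depth_mm, double depth_noise_sd,
                      int pig_gray, int floor_gray, double tail_len,
                      double tail_wid, bool want_depth) {
  SceneBody s = make_body(cx, cy, theta_deg, len_px, wid_px, tail_len,
                          tail_wid);
  IntegerMatrix gray(height, width);
  std::vector<int> scratch;
  render_gray_core(&gray[0], width, height, s, pig_gray, floor_gray, blurred,
                   blur_len, blur_theta_deg, scratch);
  if (!want_depth) return List::create(Named("gray") = gray);

  IntegerMatrix depth(height, width);
  std::fill(depth.begin(), depth.end(), floor_depth_mm);
  double reach = s.a + tail_len + 2.0;
  int c0 = std::max(0, (int)std::floor(cx - reach));
  int c1 = std::min(width - 1, (int)std::ceil(cx + reach));
  int r0 = std::max(0, (int)std::floor(cy - reach));
  int r1 = std::min(height - 1, (int)std::ceil(cy + reach));
  double eff_h = height_m * posture_scale;
  for (int c = c0; c <= c1; ++c) {
    for (int r = r0; r <= r1; ++r) {
      double rell;
      bool tail;
      if (!in_body(s, (double)c, (double)r, rell, tail)) continue;
      // rounded-back profile: flat at the spine, 70% height at the outline
      double profile = tail ? 0.4 : (1.0 - 0.3 * rell * rell);
      int d = floor_depth_mm - (int)std::lround(1000.0 * eff_h * profile);
      depth(r, c) = d < 0 ? 0 : d;
    }
  }
  if (depth_noise_sd > 0) {
    int n = depth.size();
    double lim = 4.0 * depth_noise_sd;
    for (int i = 0; i < n; ++i) {
      double e = R::rnorm(0.0, depth_noise_sd);
      if (e > lim) e = lim;
      if (e < -lim) e = -lim;
      int d = depth[i] + (int)std::lround(e);
      if (d < 0) d = 0;
      if (d > 65535) d = 65535;
      depth[i] = d;
    }
  }
  return List::create(Named("gray") = gray, Named("depth") = depth);
}

// ---------------------------------------------------------------------------
// Streaming synthetic-video morphometry: render + segment + rotated box +
// QC per frame without materializing frames in R. QC codes:
// 0 = OK, 1 = NO_OBJECT, 2 = BORDER_ATTACHED, 3 = AREA_OUT_OF_RANGE.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
DataFrame measure_sim_video_cpp(int width, int height, NumericVector cx,
                                NumericVector cy, NumericVector theta_deg,
                                NumericVector len_px, NumericVector wid_px,
                                LogicalVector blurred, NumericVector blur_theta,
                                double blur_len, int pig_gray, int floor_gray,
                                double tail_len, double tail_wid,
                                double open_radius, int fixed_threshold,
                                bool auto_polarity, double border_margin,
                                double min_frac, double max_frac) {
  int nf = cx.size();
  IntegerVector qc(nf);
  NumericVector length_px(nf), width_px(nf), area_px(nf);
  std::vector<Pt> pts;
  double npix = (double)width * height;
  SegWorkspace ws;
  SegResult res;
  std::vector<int> gray(static_cast<size_t>(width) * height), scratch;
  for (int f = 0; f < nf; ++f) {
    SceneBody s = make_body(cx[f], cy[f], theta_deg[f], len_px[f], wid_px[f],
                            tail_len, tail_wid);
    render_gray_core(gray.data(), width, height, s, pig_gray, floor_gray,
                     blurred[f], blur_len, blur_theta[f], scratch);
    segment_core(gray.data(), height, width, open_radius, fixed_threshold,
                 auto_polarity, false, ws, res);
    length_px[f] = NA_REAL;
    width_px[f] = NA_REAL;
    area_px[f] = res.found ? res.area : NA_REAL;
    if (!res.found || res.cx.size() < 3) {
      qc[f] = 1;
      continue;
    }
    pts.resize(res.cx.size());
    for (size_t i = 0; i < res.cx.size(); ++i) {
      pts[i].x = res.cx[i];
      pts[i].y = res.cy[i];
    }
    List box = min_area_rect_core(pts, 1.0);
    if (!as<bool>(box["ok"])) {
      qc[f] = 1;
      continue;
    }
    NumericMatrix corners = box["corners"];
    bool attached = false;
    for (int k = 0; k < 4; ++k) {
      double x = corners(k, 0), y = corners(k, 1);
      if (x < border_margin || x > (width - 1) - border_margin ||
          y < border_margin || y > (height - 1) - border_margin) {
        attached = true;
        break;
      }
    }
    if (attached) {
      qc[f] = 2;
      continue;
    }
    if (res.area < min_frac * npix || res.area > max_frac * npix) {
      qc[f] = 3;
      continue;
    }
    double sa = box["side_a"], sb = box["side_b"];
    length_px[f] = std::max(sa, sb);
    width_px[f] = std::min(sa, sb);
    qc[f] = 0;
  }
  return DataFrame::create(Named("frame") = seq_len(nf), Named("qc") = qc,
                           Named("length_px") = length_px,
                           Named("width_px") = width_px,
                           Named("area_px") = area_px);
}
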