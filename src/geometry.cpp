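#include <Rcpp.h>
using namespace Rcpp;

// Planar Euclidean buffer geometry. All coordinates are metres in one
// projected system. The disc is closed (boundary points belong to it).

// [[Rcpp::export]]
int cpp_count_in_disc(NumericVector x, NumericVector y,
                      double cx, double cy, double r) {
  const double r2 = r * r;
  int n = 0;
  for (int i = 0; i < x.size(); ++i) {
    const double dx = x[i] - cx, dy = y[i] - cy;
    if (dx * dx + dy * dy <= r2) ++n;
  }
  return n;
}

// Length of one segment's intersection with the closed disc, found from the
// quadratic |p1 + t(p2-p1) - c|^2 = r^2 clipped to t in [0,1].
static double seg_disc_len(double x1, double y1, double x2, double y2,
                           double cx, double cy, double r) {
  const double dx = x2 - x1, dy = y2 - y1;
  const double a = dx * dx + dy * dy;
  if (a <= 0.0) return 0.0;  // degenerate zero-length segment
  const double fx = x1 - cx, fy = y1 - cy;
  const double b = 2.0 * (fx * dx + fy * dy);
  const double c = fx * fx + fy * fy - r * r;
  const double disc = b * b - 4.0 * a * c;
  if (disc < 0.0) return 0.0;
  const double sq = std::sqrt(disc);
  double t0 = (-b - sq) / (2.0 * a), t1 = (-b + sq) / (2.0 * a);
  t0 = std::max(t0, 0.0);
  t1 = std::min(t1, 1.0);
  if (t1 <= t0) return 0.0;
  return (t1 - t0) * std::sqrt(a);
}

// Total clipped length of each polyline (matrix of vertices) in the disc.
// [[Rcpp::export]]
NumericVector cpp_polyline_disc_length(List lines, double cx, double cy,
                                       double r) {
  const int n = lines.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    NumericMatrix m = as<NumericMatrix>(lines[k]);
    double tot = 0.0;
    for (int i = 0; i + 1 < m.nrow(); ++i)
      tot += seg_disc_len(m(i, 0), m(i, 1), m(i + 1, 0), m(i + 1, 1),
                          cx, cy, r);
    out[k] = tot;
  }
  return out;
}

// Sutherland-Hodgman clip of a simple polygon against one half-plane
// (inside = left of directed edge a->b).
static void clip_halfplane(std::vector<double>& px, std::vector<double>& py,
                           double ax, double ay, double bx, double by) {
  const size_t n = px.size();
  std::vector<double> qx, qy;
  qx.reserve(n + 4);
  qy.reserve(n + 4);
  const double ex = bx - ax, ey = by - ay;
  for (size_t i = 0; i < n; ++i) {
    const size_t j = (i + 1) % n;
    const double ci = ex * (py[i] - ay) - ey * (px[i] - ax);
    const double cj = ex * (py[j] - ay) - ey * (px[j] - ax);
    const bool ini = ci >= 0.0, inj = cj >= 0.0;
    if (ini) {
      qx.push_back(px[i]);
      qy.push_back(py[i]);
    }
    if (ini != inj) {
      const double t = ci / (ci - cj);
      qx.push_back(px[i] + t * (px[j] - px[i]));
      qy.push_back(py[i] + t * (py[j] - py[i]));
    }
  }
  px.swap(qx);
  py.swap(qy);
}

static double shoelace(const std::vector<double>& px,
                       const std::vector<double>& py) {
  const size_t n = px.size();
  if (n < 3) return 0.0;
  double s = 0.0;
  for (size_t i = 0; i < n; ++i) {
    const size_t j = (i + 1) % n;
    s += px[i] * py[j] - px[j] * py[i];
  }
  return std::fabs(s) / 2.0;
}

// Area of each polygon's intersection with the disc, the disc approximated
// by a regular ngon-gon circumscribing error < 0.1% at ngon = 128.
// [[Rcpp::export]]
NumericVector cpp_polygon_disc_area(List polys, double cx, double cy,
                                    double r, int ngon) {
  std::vector<double> gx(ngon), gy(ngon);
  for (int i = 0; i < ngon; ++i) {
    const double th = 2.0 * M_PI * i / ngon;
    gx[i] = cx + r * std::cos(th);
    gy[i] = cy + r * std::sin(th);
  }
  const int n = polys.size();
  NumericVector out(n);
  for (int k = 0; k < n; ++k) {
    NumericMatrix m = as<NumericMatrix>(polys[k]);
    int nv = m.nrow();
    // drop an explicitly repeated closing vertex
    if (nv > 1 && m(0, 0) == m(nv - 1, 0) && m(0, 1) == m(nv - 1, 1)) --nv;
    std::vector<double> px(nv), py(nv);
    // enforce counter-clockwise orientation for the half-plane tests
    double signed_area = 0.0;
    for (int i = 0; i < nv; ++i) {
      const int j = (i + 1) % nv;
      signed_area += m(i, 0) * m(j, 1) - m(j, 0) * m(i, 1);
    }
    if (signed_area >= 0.0) {
      for (int i = 0; i < nv; ++i) { px[i] = m(i, 0); py[i] = m(i, 1); }
    } else {
      for (int i = 0; i < nv; ++i) {
        px[i] = m(nv - 1 - i, 0);
        py[i] = m(nv - 1 - i, 1);
      }
    }
    for (int e = 0; e < ngon && !px.empty(); ++e)
      clip_halfplane(px, py, gx[e], gy[e], gx[(e + 1) % ngon],
                     gy[(e + 1) % ngon]);
    out[k] = shoelace(px, py);
  }
  return out;
}

// [[Rcpp::export]]
double cpp_polygon_area(NumericMatrix m) {
  int nv = m.nrow();
  if (nv > 1 && m(0, 0) == m(nv - 1, 0) && m(0, 1) == m(nv - 1, 1)) --nv;
  std::vector<double> px(nv), py(nv);
  for (int i = 0; i < nv; ++i) { px[i] = m(i, 0); py[i] = m(i, 1); }
  return shoelace(px, py);
}
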