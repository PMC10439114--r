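// Spatial kernels for point-pattern statistics: neighbour counts via
// cell lists, nearest-neighbour queries, Getis-Franklin map interpolation,
// and exact Voronoi cell areas clipped to a rectangle.
#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

namespace {

struct CellList {
  double w, h, cell;
  int nx, ny;
  std::vector<std::vector<int>> cells;
  CellList(const NumericVector& x, const NumericVector& y,
           double w_, double h_, double cell_) : w(w_), h(h_), cell(cell_) {
    nx = std::max(1, (int)std::floor(w / cell));
    ny = std::max(1, (int)std::floor(h / cell));
    cells.resize((size_t)nx * ny);
    for (int i = 0; i < x.size(); ++i) {
      int cx = std::min(nx - 1, std::max(0, (int)std::floor(x[i] / w * nx)));
      int cy = std::min(ny - 1, std::max(0, (int)std::floor(y[i] / h * ny)));
      cells[(size_t)cy * nx + cx].push_back(i);
    }
  }
  // visit all candidate indices in cells overlapping a disc of radius r
  template <class F>
  void visit(double px, double py, double r, bool toroidal, F f) const {
    double cw = w / nx, ch = h / ny;
    int cx0 = (int)std::floor((px - r) / cw), cx1 = (int)std::floor((px + r) / cw);
    int cy0 = (int)std::floor((py - r) / ch), cy1 = (int)std::floor((py + r) / ch);
    if (!toroidal) {
      cx0 = std::max(cx0, 0); cx1 = std::min(cx1, nx - 1);
      cy0 = std::max(cy0, 0); cy1 = std::min(cy1, ny - 1);
    } else {
      // never visit a wrapped cell twice
      if (cx1 - cx0 + 1 >= nx) { cx0 = 0; cx1 = nx - 1; }
      if (cy1 - cy0 + 1 >= ny) { cy0 = 0; cy1 = ny - 1; }
    }
    for (int cy = cy0; cy <= cy1; ++cy) {
      int wy = toroidal ? ((cy % ny) + ny) % ny : cy;
      for (int cx = cx0; cx <= cx1; ++cx) {
        int wx = toroidal ? ((cx % nx) + nx) % nx : cx;
        for (int j : cells[(size_t)wy * nx + wx]) f(j);
      }
    }
  }
};

inline double sqdist(double dx, double dy) { return dx * dx + dy * dy; }

inline double tor_d2(double xi, double yi, double xj, double yj,
                     double w, double h) {
  double dx = std::fabs(xi - xj), dy = std::fabs(yi - yj);
  if (dx > w / 2) dx = w - dx;
  if (dy > h / 2) dy = h - dy;
  return dx * dx + dy * dy;
}

} // namespace

//' @name cpp_pair_counts
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_pair_counts(NumericVector x, NumericVector y,
                              double w, double h,
                              NumericVector radii, bool toroidal) {
  int n = x.size(), nr = radii.size();
  double rmax = 0;
  for (double r : radii) rmax = std::max(rmax, r);
  NumericVector counts(nr);
  std::vector<double> sr(nr);
  for (int k = 0; k < nr; ++k) sr[k] = radii[k] * radii[k];
  CellList cl(x, y, w, h, std::max(rmax, 1.0));
  for (int i = 0; i < n; ++i) {
    cl.visit(x[i], y[i], rmax, toroidal, [&](int j) {
      if (j == i) return;
      double d2 = toroidal ? tor_d2(x[i], y[i], x[j], y[j], w, h)
                           : sqdist(x[i] - x[j], y[i] - y[j]);
      if (d2 > rmax * rmax) return;
      // cumulative: add to every radius >= d
      for (int k = 0; k < nr; ++k)
        if (d2 <= sr[k]) counts[k] += 1.0;
    });
  }
  return counts; // ordered-pair counts per radius
}

//' @name cpp_local_counts
//' @noRd
// [[Rcpp::export]]
IntegerVector cpp_local_counts(NumericVector x, NumericVector y,
                               double w, double h, double r, bool toroidal) {
  int n = x.size();
  IntegerVector out(n);
  CellList cl(x, y, w, h, std::max(r, 1.0));
  double r2 = r * r;
  for (int i = 0; i < n; ++i) {
    int c = 0;
    cl.visit(x[i], y[i], r, toroidal, [&](int j) {
      if (j == i) return;
      double d2 = toroidal ? tor_d2(x[i], y[i], x[j], y[j], w, h)
                           : sqdist(x[i] - x[j], y[i] - y[j]);
      if (d2 <= r2) ++c;
    });
    out[i] = c;
  }
  return out;
}

//' Cumulative neighbour counts of pattern B around each point of A over a
//' radius grid. exclude_coincident drops zero-distance partners (used for the
//' auto-channel profile and for cross profiles so identical channels match).
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_cross_counts(NumericVector xa, NumericVector ya,
                               NumericVector xb, NumericVector yb,
                               double w, double h, NumericVector radii,
                               bool exclude_coincident) {
  int na = xa.size(), nr = radii.size();
  double rmax = 0;
  for (double r : radii) rmax = std::max(rmax, r);
  std::vector<double> sr(nr);
  for (int k = 0; k < nr; ++k) sr[k] = radii[k] * radii[k];
  NumericMatrix out(na, nr);
  CellList cl(xb, yb, w, h, std::max(rmax, 1.0));
  for (int i = 0; i < na; ++i) {
    cl.visit(xa[i], ya[i], rmax, false, [&](int j) {
      double d2 = sqdist(xa[i] - xb[j], ya[i] - yb[j]);
      if (d2 > rmax * rmax) return;
      if (exclude_coincident && d2 == 0.0) return;
      for (int k = 0; k < nr; ++k)
        if (d2 <= sr[k]) out(i, k) += 1.0;
    });
  }
  return out;
}

//' Nearest neighbour in B for each point of A: distance and 1-based index.
//' @noRd
// [[Rcpp::export]]
List cpp_nn(NumericVector xa, NumericVector ya,
            NumericVector xb, NumericVector yb,
            double w, double h) {
  int na = xa.size();
  NumericVector dist(na);
  IntegerVector idx(na);
  CellList cl(xb, yb, w, h, std::max(std::min(w, h) / 16.0, 1.0));
  double diag = std::sqrt(w * w + h * h);
  for (int i = 0; i < na; ++i) {
    double best = R_PosInf; int bj = -1;
    // expanding search radius
    for (double r = std::max(std::min(w, h) / 16.0, 1.0); ; r *= 2) {
      cl.visit(xa[i], ya[i], r, false, [&](int j) {
        double d2 = sqdist(xa[i] - xb[j], ya[i] - yb[j]);
        if (d2 < best) { best = d2; bj = j; }
      });
      if ((bj >= 0 && std::sqrt(best) <= r) || r > diag) break;
    }
    dist[i] = std::sqrt(best);
    idx[i] = bj + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = idx);
}

//' Inverse-distance-weighted interpolation of per-point values onto a grid.
//' Grid cells farther than r from every point are 0. Cell centres at
//' (i+0.5)*step. Returns matrix [ny x nx] (row = y).
//' @noRd
// [[Rcpp::export]]
NumericMatrix cpp_idw_map(NumericVector x, NumericVector y, NumericVector v,
                          double w, double h, double step, double r) {
  int nx = std::max(1, (int)std::round(w / step));
  int ny = std::max(1, (int)std::round(h / step));
  NumericMatrix out(ny, nx);
  CellList cl(x, y, w, h, std::max(r, 1.0));
  double r2 = r * r, eps = step * 1e-6;
  for (int gy = 0; gy < ny; ++gy) {
    double py = (gy + 0.5) * step;
    for (int gx = 0; gx < nx; ++gx) {
      double px = (gx + 0.5) * step;
      double num = 0, den = 0; bool exact = false; double exactv = 0;
      cl.visit(px, py, r, false, [&](int j) {
        double d2 = sqdist(px - x[j], py - y[j]);
        if (d2 > r2) return;
        double d = std::sqrt(d2);
        if (d < eps) { exact = true; exactv = v[j]; return; }
        double wgt = 1.0 / d;
        num += wgt * v[j]; den += wgt;
      });
      out(gy, gx) = exact ? exactv : (den > 0 ? num / den : 0.0);
    }
  }
  return out;
}

//' Exact Voronoi cell areas clipped to [0,w] x [0,h], by incremental
//' half-plane clipping with distance pruning.
//' @noRd
// [[Rcpp::export]]
NumericVector cpp_voronoi_areas(NumericVector x, NumericVector y,
                                double w, double h) {
  int n = x.size();
  NumericVector areas(n);
  std::vector<int> ord(n);
  std::vector<double> px(2 * (size_t)n + 16), py(2 * (size_t)n + 16);
  std::vector<double> qx(2 * (size_t)n + 16), qy(2 * (size_t)n + 16);
  for (int i = 0; i < n; ++i) {
    // order other sites by distance to i
    std::vector<std::pair<double, int>> d;
    d.reserve(n - 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      d.emplace_back(sqdist(x[i] - x[j], y[i] - y[j]), j);
    }
    std::sort(d.begin(), d.end());
    // start polygon = bounding rectangle
    int m = 4;
    px[0] = 0; py[0] = 0; px[1] = w; py[1] = 0;
    px[2] = w; py[2] = h; px[3] = 0; py[3] = h;
    for (auto& pr : d) {
      if (m == 0) break;
      // max distance from site i to a polygon vertex
      double maxd2 = 0;
      for (int k = 0; k < m; ++k)
        maxd2 = std::max(maxd2, sqdist(px[k] - x[i], py[k] - y[i]));
      if (pr.first >= 4.0 * maxd2) break; // bisector cannot cut the polygon
      int j = pr.second;
      // half-plane: points closer to i than to j
      // line: dot(p - mid, dir) <= 0 with dir = site_j - site_i
      double mx = 0.5 * (x[i] + x[j]), my = 0.5 * (y[i] + y[j]);
      double dx = x[j] - x[i], dy = y[j] - y[i];
      int mm = 0;
      for (int k = 0; k < m; ++k) {
        int k2 = (k + 1) % m;
        double f1 = (px[k] - mx) * dx + (py[k] - my) * dy;
        double f2 = (px[k2] - mx) * dx + (py[k2] - my) * dy;
        bool in1 = f1 <= 0, in2 = f2 <= 0;
        if (in1) { qx[mm] = px[k]; qy[mm] = py[k]; ++mm; }
        if (in1 != in2) {
          double t = f1 / (f1 - f2);
          qx[mm] = px[k] + t * (px[k2] - px[k]);
          qy[mm] = py[k] + t * (py[k2] - py[k]);
          ++mm;
        }
      }
      m = mm;
      std::copy(qx.begin(), qx.begin() + m, px.begin());
      std::copy(qy.begin(), qy.begin() + m, py.begin());
    }
    // shoelace
    double a = 0;
    for (int k = 0; k < m; ++k) {
      int k2 = (k + 1) % m;
      a += px[k] * py[k2] - px[k2] * py[k];
    }
    areas[i] = std::fabs(a) / 2.0;
  }
  return areas;
}

//' 8-connected component labelling of a logical matrix. Returns integer
//' matrix of labels (0 = background), labelled in row-major scan order.
//' @noRd
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix m) {
  int nr = m.nrow(), nc = m.ncol();
  IntegerMatrix lab(nr, nc);
  int next = 0;
  std::vector<std::pair<int,int>> stack;
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      if (!m(i, j) || lab(i, j)) continue;
      ++next;
      stack.emplace_back(i, j);
      lab(i, j) = next;
      while (!stack.empty()) {
        auto [ci, cj] = stack.back(); stack.pop_back();
        for (int di = -1; di <= 1; ++di)
          for (int dj = -1; dj <= 1; ++dj) {
            int ni = ci + di, nj = cj + dj;
            if (ni < 0 || nj < 0 || ni >= nr || nj >= nc) continue;
            if (m(ni, nj) && !lab(ni, nj)) {
              lab(ni, nj) = next;
              stack.emplace_back(ni, nj);
            }
          }
      }
    }
  }
  return lab;
}
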