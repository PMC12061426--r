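// Pooled neighbourhood angle statistics (NBH-1/2/3) for 2D point sets,
// either in the plane or on a torus (minimum-image metric).
//
// For every particle: d_i = distance to its nearest neighbour, d_ave = mean
// distance to its 4 nearest neighbours.  A particle is a home (interior)
// particle when at least 6 others lie within d_med * sqrt(2) * alpha2, where
// d_med is the median of the d_i.  For each home particle the neighbour set
// is: NBH-1 its 4 nearest, NBH-2 its 6 nearest, NBH-3 all particles within
// d_ave * sqrt(2) * alpha1.  The reported angles are the gaps between
// azimuthally consecutive neighbour directions (they sum to 2*pi); ties in
// distance or azimuth are broken by point index so perfect lattices are
// handled deterministically.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Cand {
  double d;
  int idx;
};

struct PointGeom {
  const std::vector<double>& x;
  const std::vector<double>& y;
  bool periodic;
  double boxx, boxy;

  double dxij(int i, int j) const {
    double d = x[j] - x[i];
    if (periodic) d -= boxx * std::round(d / boxx);
    return d;
  }
  double dyij(int i, int j) const {
    double d = y[j] - y[i];
    if (periodic) d -= boxy * std::round(d / boxy);
    return d;
  }
  double dist(int i, int j) const {
    double a = dxij(i, j), b = dyij(i, j);
    return std::sqrt(a * a + b * b);
  }
};

// simple uniform cell list over the (possibly wrapped) coordinates
struct CellList {
  int ncx, ncy;
  double ox, oy, cw, ch;
  bool periodic;
  std::vector<std::vector<int>> cells;

  void build(const std::vector<double>& x, const std::vector<double>& y,
             bool per, double boxx, double boxy, double target_cell) {
    periodic = per;
    int n = x.size();
    double xmin, xmax, ymin, ymax;
    if (per) {
      xmin = 0; xmax = boxx; ymin = 0; ymax = boxy;
    } else {
      xmin = *std::min_element(x.begin(), x.end());
      xmax = *std::max_element(x.begin(), x.end());
      ymin = *std::min_element(y.begin(), y.end());
      ymax = *std::max_element(y.begin(), y.end());
    }
    double ex = std::max(xmax - xmin, 1e-9), ey = std::max(ymax - ymin, 1e-9);
    ncx = std::max(1, (int)std::floor(ex / target_cell));
    ncy = std::max(1, (int)std::floor(ey / target_cell));
    ox = xmin; oy = ymin;
    cw = ex / ncx * (1 + 1e-12);
    ch = ey / ncy * (1 + 1e-12);
    cells.assign(ncx * ncy, {});
    for (int i = 0; i < n; ++i) {
      int cx = std::min(ncx - 1, std::max(0, (int)((x[i] - ox) / cw)));
      int cy = std::min(ncy - 1, std::max(0, (int)((y[i] - oy) / ch)));
      cells[cy * ncx + cx].push_back(i);
    }
  }

  // all j != i with dist <= r, as (distance, index) pairs
  void gather(const PointGeom& g, int i, double r, std::vector<Cand>& out) const {
    out.clear();
    int cx = std::min(ncx - 1, std::max(0, (int)((g.x[i] - ox) / cw)));
    int cy = std::min(ncy - 1, std::max(0, (int)((g.y[i] - oy) / ch)));
    int rx = (int)std::ceil(r / cw), ry = (int)std::ceil(r / ch);
    int lox = cx - rx, hix = cx + rx, loy = cy - ry, hiy = cy + ry;
    if (!periodic) {
      lox = std::max(lox, 0); hix = std::min(hix, ncx - 1);
      loy = std::max(loy, 0); hiy = std::min(hiy, ncy - 1);
    } else {
      if (hix - lox + 1 > ncx) { lox = 0; hix = ncx - 1; }
      if (hiy - loy + 1 > ncy) { loy = 0; hiy = ncy - 1; }
    }
    for (int byi = loy; byi <= hiy; ++byi) {
      int wy = periodic ? ((byi % ncy) + ncy) % ncy : byi;
      for (int bxi = lox; bxi <= hix; ++bxi) {
        int wx = periodic ? ((bxi % ncx) + ncx) % ncx : bxi;
        for (int j : cells[wy * ncx + wx]) {
          if (j == i) continue;
          double d = g.dist(i, j);
          if (d <= r) out.push_back({d, j});
        }
      }
    }
  }
};

bool cand_less(const Cand& a, const Cand& b) {
  if (a.d != b.d) return a.d < b.d;
  return a.idx < b.idx;
}

// gaps between azimuthally consecutive directions from home particle i
void push_gap_angles(const PointGeom& g, int i, const std::vector<int>& nb,
                     std::vector<double>& pool) {
  const int m = nb.size();
  std::vector<std::pair<double, int>> az(m);
  for (int q = 0; q < m; ++q)
    az[q] = {std::atan2(g.dyij(i, nb[q]), g.dxij(i, nb[q])), nb[q]};
  std::sort(az.begin(), az.end());
  for (int q = 0; q < m - 1; ++q) pool.push_back(az[q + 1].first - az[q].first);
  pool.push_back(az[0].first + 2.0 * M_PI - az[m - 1].first);
}

}  // namespace

// [[Rcpp::export]]
List pooled_angles_cpp(NumericVector px, NumericVector py, int k,
                       bool periodic, double boxx, double boxy,
                       double alpha1, double alpha2) {
  const int n = px.size();
  if (n < 7) stop("at least 7 points are required");
  std::vector<double> x(n), y(n);
  for (int i = 0; i < n; ++i) {
    x[i] = px[i]; y[i] = py[i];
    if (periodic) {
      x[i] -= boxx * std::floor(x[i] / boxx);
      y[i] -= boxy * std::floor(y[i] / boxy);
    }
  }
  PointGeom g{x, y, periodic, boxx, boxy};
  double area = periodic ? boxx * boxy
                         : std::max((*std::max_element(x.begin(), x.end()) -
                                     *std::min_element(x.begin(), x.end())) *
                                    (*std::max_element(y.begin(), y.end()) -
                                     *std::min_element(y.begin(), y.end())), 1e-12);
  double a0 = std::sqrt(area / n);
  CellList cl;
  cl.build(x, y, periodic, boxx, boxy, std::max(a0, 1e-6));

  // six nearest neighbours of every particle (ties by index)
  std::vector<std::vector<Cand>> nn6(n);
  std::vector<double> d1(n), dave(n);
  std::vector<Cand> cand;
  for (int i = 0; i < n; ++i) {
    double r = 2.0 * a0;
    for (;;) {
      cl.gather(g, i, r, cand);
      if ((int)cand.size() >= std::min(6, n - 1) || r > 1e3 * a0 * (1 + std::sqrt((double)n)))
        break;
      r *= 2.0;
    }
    std::sort(cand.begin(), cand.end(), cand_less);
    int keep = std::min<int>(6, cand.size());
    nn6[i].assign(cand.begin(), cand.begin() + keep);
    d1[i] = nn6[i][0].d;
    double s = 0;
    int m4 = std::min(4, keep);
    for (int q = 0; q < m4; ++q) s += nn6[i][q].d;
    dave[i] = s / m4;
  }

  // median of nearest-neighbour distances (matches stats::median)
  std::vector<double> ds = d1;
  std::sort(ds.begin(), ds.end());
  double dmed = (n % 2 == 1) ? ds[n / 2] : 0.5 * (ds[n / 2 - 1] + ds[n / 2]);

  // home-particle rule
  double r2 = dmed * std::sqrt(2.0) * alpha2;
  LogicalVector interior(n);
  for (int i = 0; i < n; ++i) {
    cl.gather(g, i, r2, cand);
    interior[i] = (int)cand.size() >= 6;
  }

  std::vector<double> pool;
  int skipped = 0;
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    if (!interior[i]) continue;
    nb.clear();
    if (k == 1 || k == 2) {
      int need = (k == 1) ? 4 : 6;
      if ((int)nn6[i].size() < need) { ++skipped; continue; }
      for (int q = 0; q < need; ++q) nb.push_back(nn6[i][q].idx);
    } else if (k == 3) {
      double r3 = dave[i] * std::sqrt(2.0) * alpha1;
      cl.gather(g, i, r3, cand);
      if ((int)cand.size() < 2) { ++skipped; continue; }
      for (const Cand& c : cand) nb.push_back(c.idx);
    } else {
      stop("k must be 1, 2 or 3");
    }
    push_gap_angles(g, i, nb, pool);
  }

  return List::create(_["angles"] = wrap(pool), _["interior"] = interior,
                      _["d_med"] = dmed, _["d_nn"] = wrap(d1),
                      _["d_ave"] = wrap(dave), _["n_skipped"] = skipped);
}
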