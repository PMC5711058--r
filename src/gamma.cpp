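#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Bilinear interpolation on a uniformly spaced grid. Returns false when the
// query lies outside the grid hull.
static inline bool bilin(const double x0, const double hx, const int nx,
                         const double y0, const double hy, const int ny,
                         const NumericMatrix &Z, const double x,
                         const double y, double &out) {
  const double fx = (x - x0) / hx;
  const double fy = (y - y0) / hy;
  if (fx < -1e-9 || fx > nx - 1 + 1e-9 || fy < -1e-9 || fy > ny - 1 + 1e-9)
    return false;
  int i = (int)std::floor(fx);
  int j = (int)std::floor(fy);
  if (i < 0) i = 0;
  if (i > nx - 2) i = nx - 2;
  if (j < 0) j = 0;
  if (j > ny - 2) j = ny - 2;
  const double tx = fx - i, ty = fy - j;
  out = Z(i, j) * (1 - tx) * (1 - ty) + Z(i + 1, j) * tx * (1 - ty) +
        Z(i, j + 1) * (1 - tx) * ty + Z(i + 1, j + 1) * tx * ty;
  return true;
}

struct Offset {
  double dx, dy, r2;
};

// Gamma index with dose criterion dcrit (absolute dose units), DTA dta (cm),
// search radius (cm) and subsample step (cm). For every reference grid point
// the evaluated plane is bilinearly subsampled on a step-spaced lattice of
// offsets centred on the point, restricted to the search disc and to the
// evaluated plane's hull; gamma^2 is minimised with early termination once
// the spatial term alone exceeds the current minimum. Points whose zero
// offset falls outside the evaluated plane get NA.
// [[Rcpp::export(name = ".gamma_kernel")]]
NumericMatrix gamma_kernel(NumericVector ref_x, NumericVector ref_y,
                           NumericMatrix ref_dose, NumericVector ev_x,
                           NumericVector ev_y, NumericMatrix ev_dose,
                           double dcrit, double dta, double radius,
                           double step) {
  const int nx = ref_x.size(), ny = ref_y.size();
  const int mx = ev_x.size(), my = ev_y.size();
  const double ex0 = ev_x[0], ey0 = ev_y[0];
  const double ehx = (ev_x[mx - 1] - ev_x[0]) / (mx - 1);
  const double ehy = (ev_y[my - 1] - ev_y[0]) / (my - 1);
  const double dta2 = dta * dta;

  const int k = (int)std::ceil(radius / step + 1e-9);
  std::vector<Offset> offs;
  offs.reserve((2 * k + 1) * (2 * k + 1));
  for (int a = -k; a <= k; ++a)
    for (int b = -k; b <= k; ++b) {
      const double dx = a * step, dy = b * step, r2 = dx * dx + dy * dy;
      if (r2 <= radius * radius + 1e-12) offs.push_back({dx, dy, r2});
    }
  std::sort(offs.begin(), offs.end(),
            [](const Offset &p, const Offset &q) { return p.r2 < q.r2; });

  NumericMatrix gamma(nx, ny);
  for (int i = 0; i < nx; ++i) {
    for (int j = 0; j < ny; ++j) {
      const double xr = ref_x[i], yr = ref_y[j], dr = ref_dose(i, j);
      double de;
      if (!bilin(ex0, ehx, mx, ey0, ehy, my, ev_dose, xr, yr, de)) {
        gamma(i, j) = NA_REAL;
        continue;
      }
      double g2min = R_PosInf;
      for (const Offset &o : offs) {
        const double spatial = o.r2 / dta2;
        if (spatial >= g2min) break;  // offsets sorted by distance
        if (!bilin(ex0, ehx, mx, ey0, ehy, my, ev_dose, xr + o.dx, yr + o.dy,
                   de))
          continue;
        const double dd = (de - dr) / dcrit;
        const double g2 = dd * dd + spatial;
        if (g2 < g2min) g2min = g2;
      }
      gamma(i, j) = std::sqrt(g2min);
    }
  }
  return gamma;
}
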