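#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bilinear interpolation of a grid at physical position (x, y).
// Returns NA outside the grid (beyond a small tolerance); positions on
// the boundary are clamped. Mirrors interp_bilinear() in R/dose_plane.R.
static inline double bilinear(const NumericMatrix& v,
                              double ox, double oy,
                              double sx, double sy,
                              double x, double y,
                              bool& inside) {
  const int nr = v.nrow(), nc = v.ncol();
  double gx = (x - ox) / sx;
  double gy = (y - oy) / sy;
  const double tol = 1e-9;
  if (gx < -tol || gx > (nc - 1) + tol || gy < -tol || gy > (nr - 1) + tol) {
    inside = false;
    return NA_REAL;
  }
  inside = true;
  if (gx < 0) gx = 0;
  if (gx > nc - 1) gx = nc - 1;
  if (gy < 0) gy = 0;
  if (gy > nr - 1) gy = nr - 1;
  int i0 = (int)std::floor(gx);
  int j0 = (int)std::floor(gy);
  if (i0 > nc - 2) i0 = nc - 2;
  if (j0 > nr - 2) j0 = nr - 2;
  const double fx = gx - i0, fy = gy - j0;
  const double v00 = v(j0, i0), v10 = v(j0, i0 + 1);
  const double v01 = v(j0 + 1, i0), v11 = v(j0 + 1, i0 + 1);
  return v00 * (1 - fx) * (1 - fy) + v10 * fx * (1 - fy) +
         v01 * (1 - fx) * fy + v11 * fx * fy;
}

// Minimum squared gamma per reference point: exhaustive search over the
// candidate offsets (disc around each point), bilinear interpolation of
// the calculated plane. Candidates outside the calculated plane are
// skipped. `denom` has length n_points (local normalization) or 1
// (global).
// [[Rcpp::export]]
NumericVector gamma_min_sq(NumericMatrix calc,
                           double calc_origin_x, double calc_origin_y,
                           double calc_spacing_x, double calc_spacing_y,
                           NumericVector px, NumericVector py,
                           NumericVector mdose, NumericVector denom,
                           double dta, double dose_diff,
                           NumericVector off_x, NumericVector off_y,
                           NumericVector off_d2) {
  const int n = px.size();
  const int k = off_x.size();
  const bool local = denom.size() > 1;
  const double dta2 = dta * dta;
  const double dd2 = dose_diff * dose_diff;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    const double den = local ? denom[i] : denom[0];
    double best = R_PosInf;
    for (int j = 0; j < k; ++j) {
      const double dist_term = off_d2[j] / dta2;
      if (dist_term >= best) continue;
      bool inside;
      const double c = bilinear(calc, calc_origin_x, calc_origin_y,
                                calc_spacing_x, calc_spacing_y,
                                px[i] + off_x[j], py[i] + off_y[j], inside);
      if (!inside) continue;
      const double d = 100.0 * (c - mdose[i]) / den;
      const double g2 = dist_term + d * d / dd2;
      if (g2 < best) best = g2;
    }
    out[i] = best;
  }
  return out;
}
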