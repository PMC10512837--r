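#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Zero-normalized cross-correlation between the nr x nc block of `pre`
// anchored at (i0, j0) and the equally sized block of `post` anchored at
// (pi, pj). Anchors are 0-based top-left corners. A zero-variance block on
// either side makes the value undefined; we return 0 and set `degenerate`.
static double zncc_at(const NumericMatrix& pre, int i0, int j0,
                      const NumericMatrix& post, int pi, int pj,
                      int nr, int nc, bool& degenerate) {
  double sa = 0.0, sb = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      sa += pre(i0 + i, j0 + j);
      sb += post(pi + i, pj + j);
    }
  const double n = (double)nr * (double)nc;
  const double ma = sa / n, mb = sb / n;
  double saa = 0.0, sbb = 0.0, sab = 0.0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) {
      const double a = pre(i0 + i, j0 + j) - ma;
      const double b = post(pi + i, pj + j) - mb;
      saa += a * a; sbb += b * b; sab += a * b;
    }
  if (saa <= 0.0 || sbb <= 0.0) { degenerate = true; return 0.0; }
  degenerate = false;
  return sab / std::sqrt(saa * sbb);
}

// Deterministic tie-break on equal correlation maxima: smallest lag
// magnitude, then smallest |axial|, then smallest |lateral|, then the
// signed lags (negative preferred only as a final disambiguation).
static bool lag_preferred(int di, int dj, int bi, int bj) {
  const int m1 = di * di + dj * dj, m2 = bi * bi + bj * bj;
  if (m1 != m2) return m1 < m2;
  if (std::abs(di) != std::abs(bi)) return std::abs(di) < std::abs(bi);
  if (std::abs(dj) != std::abs(bj)) return std::abs(dj) < std::abs(bj);
  if (di != bi) return di < bi;
  return dj < bj;
}

// Parabolic vertex offset through (s_m, s0, s_p); 0 on ties / flat apex.
static double parabola_offset(double s_m, double s0, double s_p) {
  const double denom = s_m - 2.0 * s0 + s_p;
  if (denom == 0.0) return 0.0;
  const double off = (s_m - s_p) / (2.0 * denom);
  if (!std::isfinite(off) || std::fabs(off) >= 0.5) return 0.0;
  return off;
}

// [[Rcpp::export(name = ".ncc_surface_cpp")]]
List ncc_surface_cpp(NumericMatrix block, NumericMatrix region) {
  const int nr = block.nrow(), nc = block.ncol();
  const int nlr = region.nrow() - nr + 1, nlc = region.ncol() - nc + 1;
  NumericMatrix surf(nlr, nlc);
  LogicalMatrix degen(nlr, nlc);
  for (int lj = 0; lj < nlc; ++lj)
    for (int li = 0; li < nlr; ++li) {
      bool d = false;
      surf(li, lj) = zncc_at(block, 0, 0, region, li, lj, nr, nc, d);
      degen(li, lj) = d;
    }
  return List::create(_["surface"] = surf, _["degenerate"] = degen);
}

// Block matching over the overlap-defined node grid. All anchors 0-based;
// node (a, l) uses the pre-frame block at rows i0..i0+bA-1 and searches
// post lags di in [-mA, mA], dj in [-mL, mL].
// flag: 0 ok, 1 zero-variance (pre block or chosen candidate), 2 peak on
// search border left unrefined.
// [[Rcpp::export(name = ".block_match_cpp")]]
List block_match_cpp(NumericMatrix pre, NumericMatrix post,
                     int block_ax, int block_lat,
                     int shift_ax, int shift_lat,
                     int margin_ax, int margin_lat,
                     bool refine) {
  const int nr = pre.nrow(), nc = pre.ncol();
  std::vector<int> i0s, j0s;
  for (int i0 = margin_ax; i0 + block_ax + margin_ax <= nr; i0 += shift_ax)
    i0s.push_back(i0);
  for (int j0 = margin_lat; j0 + block_lat + margin_lat <= nc; j0 += shift_lat)
    j0s.push_back(j0);
  const int na = (int)i0s.size(), nl = (int)j0s.size();
  NumericMatrix d_ax(na, nl), d_lat(na, nl), ncc(na, nl);
  IntegerMatrix flag(na, nl);
  const int sr = 2 * margin_ax + 1, sc = 2 * margin_lat + 1;
  std::vector<double> surf((size_t)sr * sc);
  std::vector<char> dg((size_t)sr * sc);

  for (int l = 0; l < nl; ++l) {
    for (int a = 0; a < na; ++a) {
      const int i0 = i0s[a], j0 = j0s[l];
      int bdi = 0, bdj = 0;
      double bv = -2.0;
      bool have = false;
      for (int dj = -margin_lat; dj <= margin_lat; ++dj) {
        for (int di = -margin_ax; di <= margin_ax; ++di) {
          bool d = false;
          const double v = zncc_at(pre, i0, j0, post, i0 + di, j0 + dj,
                                   block_ax, block_lat, d);
          surf[(size_t)(di + margin_ax) + (size_t)sr * (dj + margin_lat)] = v;
          dg[(size_t)(di + margin_ax) + (size_t)sr * (dj + margin_lat)] = d ? 1 : 0;
          if (!have || v > bv ||
              (v == bv && lag_preferred(di, dj, bdi, bdj))) {
            have = true; bv = v; bdi = di; bdj = dj;
          }
        }
      }
      double dax = bdi, dlt = bdj;
      int fl = 0;
      const size_t bidx = (size_t)(bdi + margin_ax) + (size_t)sr * (bdj + margin_lat);
      if (dg[bidx]) fl = 1;
      // A perfect-match peak (NCC == 1) cannot be improved; parabolic
      // refinement would only add a spurious fraction from the asymmetric
      // side lobes.
      if (refine && fl == 0 && bv < 1.0 - 1e-12) {
        if (std::abs(bdi) == margin_ax || std::abs(bdj) == margin_lat) {
          fl = 2;
        } else {
          const int pi = bdi + margin_ax, pj = bdj + margin_lat;
          dax += parabola_offset(surf[(size_t)(pi - 1) + (size_t)sr * pj],
                                 surf[(size_t)pi + (size_t)sr * pj],
                                 surf[(size_t)(pi + 1) + (size_t)sr * pj]);
          dlt += parabola_offset(surf[(size_t)pi + (size_t)sr * (pj - 1)],
                                 surf[(size_t)pi + (size_t)sr * pj],
                                 surf[(size_t)pi + (size_t)sr * (pj + 1)]);
        }
      }
      d_ax(a, l) = dax; d_lat(a, l) = dlt; ncc(a, l) = bv; flag(a, l) = fl;
    }
  }
  return List::create(_["i0"] = wrap(i0s), _["j0"] = wrap(j0s),
                      _["d_axial"] = d_ax, _["d_lateral"] = d_lat,
                      _["peak_ncc"] = ncc, _["flag"] = flag);
}

// Render one RF frame from point scatterers: separable Gaussian-envelope
// cosine PSF, sampled on the (fs, pitch) grid. Units: z/x in mm, f0/fs in
// Hz, c in m/s, sigma_t in s, sigma_x in mm. Contributions beyond 5 sigma
// are truncated; scatterers outside the grid contribute only through the
// tails that fall on it.
// [[Rcpp::export(name = ".render_frame_cpp")]]
NumericMatrix render_frame_cpp(NumericVector zs, NumericVector xs,
                               NumericVector amp,
                               double z0, double dz, int n_ax,
                               double x0, double pitch, int n_lines,
                               double f0, double c_mps,
                               double sigma_t, double sigma_x) {
  NumericMatrix F(n_ax, n_lines);
  const double half_z_mm = 5.0 * sigma_t * c_mps * 1000.0 / 2.0;
  const double half_x_mm = 5.0 * sigma_x;
  const double two_pi_f0 = 2.0 * M_PI * f0;
  for (int s = 0; s < zs.size(); ++s) {
    const double zc = zs[s], xc = xs[s], A = amp[s];
    if (A == 0.0) continue;
    int i_lo = (int)std::ceil((zc - half_z_mm - z0) / dz);
    int i_hi = (int)std::floor((zc + half_z_mm - z0) / dz);
    int j_lo = (int)std::ceil((xc - half_x_mm - x0) / pitch);
    int j_hi = (int)std::floor((xc + half_x_mm - x0) / pitch);
    if (i_lo < 0) i_lo = 0;
    if (i_hi > n_ax - 1) i_hi = n_ax - 1;
    if (j_lo < 0) j_lo = 0;
    if (j_hi > n_lines - 1) j_hi = n_lines - 1;
    if (i_lo > i_hi || j_lo > j_hi) continue;
    for (int j = j_lo; j <= j_hi; ++j) {
      const double dx = x0 + j * pitch - xc;
      const double gx = std::exp(-dx * dx / (2.0 * sigma_x * sigma_x));
      for (int i = i_lo; i <= i_hi; ++i) {
        const double dzm = z0 + i * dz - zc;           // mm
        const double tau = 2.0 * (dzm / 1000.0) / c_mps; // s (two-way)
        const double gz = std::exp(-tau * tau / (2.0 * sigma_t * sigma_t));
        F(i, j) += A * gz * std::cos(two_pi_f0 * tau) * gx;
      }
    }
  }
  return F;
}

// Minimum Euclidean distance from each query point to an open polyline.
// [[Rcpp::export(name = ".polyline_mindist_cpp")]]
NumericVector polyline_mindist_cpp(NumericVector px, NumericVector py,
                                   NumericVector qx, NumericVector qy) {
  const int np = px.size(), nv = qx.size();
  NumericVector out(np);
  for (int p = 0; p < np; ++p) {
    const double x = px[p], y = py[p];
    double best = R_PosInf;
    for (int v = 0; v + 1 < nv; ++v) {
      const double ax = qx[v], ay = qy[v];
      const double bx = qx[v + 1], by = qy[v + 1];
      const double ux = bx - ax, uy = by - ay;
      const double L2 = ux * ux + uy * uy;
      double t = 0.0;
      if (L2 > 0.0) {
        t = ((x - ax) * ux + (y - ay) * uy) / L2;
        if (t < 0.0) t = 0.0;
        if (t > 1.0) t = 1.0;
      }
      const double ddx = x - (ax + t * ux), ddy = y - (ay + t * uy);
      const double d2 = ddx * ddx + ddy * ddy;
      if (d2 < best) best = d2;
    }
    out[p] = std::sqrt(best);
  }
  return out;
}
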