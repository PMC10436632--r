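#include <Rcpp.h>
using namespace Rcpp;

// Bilinear sample with clamp-to-edge. r, c are 1-based fractional
// positions, as used throughout the package.
static inline double bilin(const NumericMatrix &img, double r, double c) {
  const int nr = img.nrow(), nc = img.ncol();
  double rr = r - 1.0, cc = c - 1.0;  // 0-based
  if (rr < 0) rr = 0;
  if (cc < 0) cc = 0;
  if (rr > nr - 1) rr = nr - 1;
  if (cc > nc - 1) cc = nc - 1;
  int r0 = (int)rr, c0 = (int)cc;
  int r1 = r0 + 1 < nr ? r0 + 1 : r0;
  int c1 = c0 + 1 < nc ? c0 + 1 : c0;
  double fr = rr - r0, fc = cc - c0;
  return (1 - fr) * ((1 - fc) * img(r0, c0) + fc * img(r0, c1)) +
         fr * ((1 - fc) * img(r1, c0) + fc * img(r1, c1));
}

// Lucas-Kanade flow at one pyramid level for a set of points.
//
// I0, I1: filtered frames at this level; Ix, Iy: spatial gradients of
// I0. pts: k x 2 (row, col), 1-based, level coordinates. guess: k x 2
// (drow, dcol) initial displacement carried down from coarser levels.
// Returns k x 3: (drow, dcol, valid) where (drow, dcol) is the total
// displacement at this level (guess + refinement).
//
// Each iteration rebuilds the temporal difference at the current
// estimate (frame 1 sampled at the displaced window) and solves the
// 2x2 normal equations of the window; the structure matrix is fixed
// per point. valid = 0 when the smaller eigenvalue falls below
// min_eig_floor * m^2 or the condition number exceeds max_cond.
// [[Rcpp::export]]
NumericMatrix cpp_lk_level(const NumericMatrix &I0, const NumericMatrix &I1,
                           const NumericMatrix &Ix, const NumericMatrix &Iy,
                           const NumericMatrix &pts,
                           const NumericMatrix &guess,
                           int m, int iterations,
                           double min_eig_floor, double max_cond) {
  const int k = pts.nrow();
  const int h = m / 2;
  const int win = m * m;
  NumericMatrix out(k, 3);
  std::vector<double> gx(win), gy(win), i0(win), wr(win), wc(win);

  for (int p = 0; p < k; ++p) {
    const double pr = pts(p, 0), pc = pts(p, 1);
    double dr = guess(p, 0), dc = guess(p, 1);

    double gxx = 0, gxy = 0, gyy = 0;
    int idx = 0;
    for (int i = -h; i <= h; ++i) {
      for (int j = -h; j <= h; ++j, ++idx) {
        const double r = pr + i, c = pc + j;
        wr[idx] = r;
        wc[idx] = c;
        const double vx = bilin(Ix, r, c);
        const double vy = bilin(Iy, r, c);
        gx[idx] = vx;
        gy[idx] = vy;
        i0[idx] = bilin(I0, r, c);
        gxx += vx * vx;
        gxy += vx * vy;
        gyy += vy * vy;
      }
    }

    // eigenvalues of [[gxx, gxy], [gxy, gyy]]
    const double tr = gxx + gyy;
    const double det = gxx * gyy - gxy * gxy;
    const double disc = std::sqrt(std::max(tr * tr / 4.0 - det, 0.0));
    const double lmin = tr / 2.0 - disc, lmax = tr / 2.0 + disc;
    bool valid = lmin >= min_eig_floor * win &&
                 (lmin > 0 ? lmax / lmin : R_PosInf) <= max_cond;

    if (valid) {
      for (int it = 0; it < iterations; ++it) {
        double bx = 0, by = 0;
        for (int q = 0; q < win; ++q) {
          const double dt = bilin(I1, wr[q] + dr, wc[q] + dc) - i0[q];
          bx -= gx[q] * dt;
          by -= gy[q] * dt;
        }
        // u along columns (x), v along rows (y)
        const double u = (gyy * bx - gxy * by) / det;
        const double v = (-gxy * bx + gxx * by) / det;
        dc += u;
        dr += v;
        if (u * u + v * v < 1e-8) break;
      }
    }
    out(p, 0) = dr;
    out(p, 1) = dc;
    out(p, 2) = valid ? 1.0 : 0.0;
  }
  return out;
}
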