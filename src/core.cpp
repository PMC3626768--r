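// Computational core: trilinear/nearest resampling through an affine +
// cubic-B-spline free-form deformation, normalised mutual information (NMI),
// a coordinate pattern-search FFD optimiser with incremental joint-histogram
// updates, and seeded monotone region growing on cluster-label slices.
//
// Conventions: volumes are R arrays with dim = (nz, ny, nx) indexed
// (slice, row, col); all coordinates here are 0-based continuous voxel
// coordinates in (z, y, x) order. The affine is a 4x4 matrix acting on
// homogeneous (z, y, x, 1) fixed-image coordinates and returning moving-image
// coordinates; the FFD adds a displacement (in voxels) evaluated on the fixed
// grid, i.e. T(x) = A x + D(x).

#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double nlogn(double n) { return n > 0.0 ? n * std::log(n) : 0.0; }

// cubic uniform B-spline weights for fractional offset f in [0,1)
static inline void bspline_w(double f, double w[4]) {
  const double f2 = f * f, f3 = f2 * f;
  w[0] = (1.0 - 3.0 * f + 3.0 * f2 - f3) / 6.0;
  w[1] = (3.0 * f3 - 6.0 * f2 + 4.0) / 6.0;
  w[2] = (-3.0 * f3 + 3.0 * f2 + 3.0 * f + 1.0) / 6.0;
  w[3] = f3 / 6.0;
}

struct Grid {
  int nz, ny, nx;
  Grid(IntegerVector d) : nz(d[0]), ny(d[1]), nx(d[2]) {}
  inline int idx(int z, int y, int x) const { return z + nz * (y + ny * x); }
  inline R_xlen_t n() const { return (R_xlen_t)nz * ny * nx; }
};

// trilinear sample of vol (dims g) at continuous (z,y,x); background outside
static inline double sample_lin(const double* vol, const Grid& g,
                                double z, double y, double x, double bg) {
  // pixel-centered domain: voxel centers at 0..n-1, grid covers +/- half voxel
  if (z < -0.5 || y < -0.5 || x < -0.5 ||
      z > g.nz - 0.5 || y > g.ny - 0.5 || x > g.nx - 0.5)
    return bg;
  if (z < 0) z = 0; if (y < 0) y = 0; if (x < 0) x = 0;
  if (z > g.nz - 1) z = g.nz - 1;
  if (y > g.ny - 1) y = g.ny - 1;
  if (x > g.nx - 1) x = g.nx - 1;
  int z0 = (int)std::floor(z), y0 = (int)std::floor(y), x0 = (int)std::floor(x);
  if (z0 == g.nz - 1) z0--;
  if (y0 == g.ny - 1) y0--;
  if (x0 == g.nx - 1) x0--;
  if (g.nz == 1) z0 = 0;
  if (g.ny == 1) y0 = 0;
  if (g.nx == 1) x0 = 0;
  double fz = z - z0, fy = y - y0, fx = x - x0;
  int z1 = std::min(z0 + 1, g.nz - 1), y1 = std::min(y0 + 1, g.ny - 1),
      x1 = std::min(x0 + 1, g.nx - 1);
  double c00 = vol[g.idx(z0, y0, x0)] * (1 - fz) + vol[g.idx(z1, y0, x0)] * fz;
  double c10 = vol[g.idx(z0, y1, x0)] * (1 - fz) + vol[g.idx(z1, y1, x0)] * fz;
  double c01 = vol[g.idx(z0, y0, x1)] * (1 - fz) + vol[g.idx(z1, y0, x1)] * fz;
  double c11 = vol[g.idx(z0, y1, x1)] * (1 - fz) + vol[g.idx(z1, y1, x1)] * fz;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fx) + c1 * fx;
}

static inline double sample_nn(const double* vol, const Grid& g,
                               double z, double y, double x, double bg) {
  int zi = (int)std::lround(z), yi = (int)std::lround(y), xi = (int)std::lround(x);
  if (zi < 0 || yi < 0 || xi < 0 || zi > g.nz - 1 || yi > g.ny - 1 || xi > g.nx - 1)
    return bg;
  return vol[g.idx(zi, yi, xi)];
}

// Per-axis B-spline support tables for a fixed grid axis of length n:
// base[t] = first control index with non-zero weight at coordinate t,
// w[4*t + k] = weight of control index base[t] + k.
struct AxisTab {
  std::vector<int> base;
  std::vector<double> w;
  void build(int n, double origin, double spacing, int gdim) {
    base.resize(n);
    w.resize(4 * n);
    for (int t = 0; t < n; ++t) {
      double u = (t - origin) / spacing;
      int b = (int)std::floor(u);
      double f = u - b;
      double wk[4];
      bspline_w(f, wk);
      int first = b - 1;
      // clamp control indices (replicate border); grid is built with margin so
      // this only triggers at the extreme edge
      if (first < 0) { first = 0; }
      if (first + 3 > gdim - 1) { first = gdim - 4 < 0 ? 0 : gdim - 4; }
      // recompute weights against clamped positions is unnecessary for a grid
      // with >=1 control-point margin; store raw weights
      base[t] = first;
      for (int k = 0; k < 4; ++k) w[4 * t + k] = wk[k];
    }
  }
};

struct FFD {
  int gz, gy, gx;
  const double* disp; // (gz, gy, gx, 3)
  AxisTab tz, ty, tx;
  bool active;
  inline int didx(int pz, int py, int px, int a) const {
    return pz + gz * (py + gy * (px + (R_xlen_t)gx * a));
  }
  inline void eval(int z, int y, int x, double d[3]) const {
    d[0] = d[1] = d[2] = 0.0;
    const int bz = tz.base[z], by = ty.base[y], bx = tx.base[x];
    const double* wz = &tz.w[4 * z];
    const double* wy = &ty.w[4 * y];
    const double* wx = &tx.w[4 * x];
    for (int a = 0; a < 3; ++a) {
      double acc = 0.0;
      for (int kx = 0; kx < 4; ++kx) {
        double accy = 0.0;
        for (int ky = 0; ky < 4; ++ky) {
          double accz = 0.0;
          const double* col = disp + didx(bz, by + ky, bx + kx, a);
          for (int kz = 0; kz < 4; ++kz) accz += wz[kz] * col[kz];
          accy += wy[ky] * accz;
        }
        acc += wx[kx] * accy;
      }
      d[a] = acc;
    }
  }
};

static FFD make_ffd(IntegerVector fdim, NumericVector gspacing,
                    NumericVector gorigin, IntegerVector gdim,
                    const NumericVector& disp) {
  FFD f;
  f.gz = gdim[0]; f.gy = gdim[1]; f.gx = gdim[2];
  f.disp = REAL(disp);
  f.tz.build(fdim[0], gorigin[0], gspacing[0], f.gz);
  f.ty.build(fdim[1], gorigin[1], gspacing[1], f.gy);
  f.tx.build(fdim[2], gorigin[2], gspacing[2], f.gx);
  f.active = true;
  return f;
}

// [[Rcpp::export]]
NumericVector cpp_warp(NumericVector moving, IntegerVector mdim,
                       IntegerVector fdim, NumericMatrix affine,
                       bool has_ffd, NumericVector gspacing,
                       NumericVector gorigin, IntegerVector gdim,
                       NumericVector disp, int interp, double background) {
  Grid gm(mdim), gf(fdim);
  NumericVector out((R_xlen_t)gf.n());
  const double* mv = REAL(moving);
  double* o = REAL(out);
  FFD ffd;
  if (has_ffd) ffd = make_ffd(fdim, gspacing, gorigin, gdim, disp);
  const double a00 = affine(0, 0), a01 = affine(0, 1), a02 = affine(0, 2), a03 = affine(0, 3);
  const double a10 = affine(1, 0), a11 = affine(1, 1), a12 = affine(1, 2), a13 = affine(1, 3);
  const double a20 = affine(2, 0), a21 = affine(2, 1), a22 = affine(2, 2), a23 = affine(2, 3);
  for (int x = 0; x < gf.nx; ++x)
    for (int y = 0; y < gf.ny; ++y)
      for (int z = 0; z < gf.nz; ++z) {
        double pz = a00 * z + a01 * y + a02 * x + a03;
        double py = a10 * z + a11 * y + a12 * x + a13;
        double px = a20 * z + a21 * y + a22 * x + a23;
        if (has_ffd) {
          double d[3];
          ffd.eval(z, y, x, d);
          pz += d[0]; py += d[1]; px += d[2];
        }
        o[gf.idx(z, y, x)] = interp == 0
          ? sample_nn(mv, gm, pz, py, px, background)
          : sample_lin(mv, gm, pz, py, px, background);
      }
  return out;
}

// [[Rcpp::export]]
NumericMatrix cpp_map_coords(IntegerVector fdim, NumericMatrix affine,
                             bool has_ffd, NumericVector gspacing,
                             NumericVector gorigin, IntegerVector gdim,
                             NumericVector disp) {
  Grid gf(fdim);
  NumericMatrix out(gf.n(), 3);
  FFD ffd;
  if (has_ffd) ffd = make_ffd(fdim, gspacing, gorigin, gdim, disp);
  for (int x = 0; x < gf.nx; ++x)
    for (int y = 0; y < gf.ny; ++y)
      for (int z = 0; z < gf.nz; ++z) {
        double pz = affine(0, 0) * z + affine(0, 1) * y + affine(0, 2) * x + affine(0, 3);
        double py = affine(1, 0) * z + affine(1, 1) * y + affine(1, 2) * x + affine(1, 3);
        double px = affine(2, 0) * z + affine(2, 1) * y + affine(2, 2) * x + affine(2, 3);
        if (has_ffd) {
          double d[3];
          ffd.eval(z, y, x, d);
          pz += d[0]; py += d[1]; px += d[2];
        }
        R_xlen_t i = gf.idx(z, y, x);
        out(i, 0) = pz; out(i, 1) = py; out(i, 2) = px;
      }
  return out;
}

static inline int binof(double v, double lo, double inv, int bins) {
  int b = (int)((v - lo) * inv);
  if (b < 0) b = 0;
  if (b > bins - 1) b = bins - 1;
  return b;
}

// [[Rcpp::export]]
double cpp_nmi(NumericVector a, NumericVector b, int bins,
               NumericVector arange, NumericVector brange) {
  R_xlen_t n = a.size();
  if (b.size() != n) stop("length mismatch");
  const double ainv = bins / std::max(arange[1] - arange[0], 1e-12);
  const double binv = bins / std::max(brange[1] - brange[0], 1e-12);
  std::vector<double> J(bins * bins, 0.0);
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  for (R_xlen_t i = 0; i < n; ++i) {
    int ba = binof(pa[i], arange[0], ainv, bins);
    int bb = binof(pb[i], brange[0], binv, bins);
    J[ba * bins + bb] += 1.0;
  }
  std::vector<double> ma(bins, 0.0), mb(bins, 0.0);
  double Sj = 0.0;
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      double c = J[i * bins + j];
      ma[i] += c; mb[j] += c; Sj += nlogn(c);
    }
  double Sa = 0.0, Sb = 0.0;
  for (int i = 0; i < bins; ++i) { Sa += nlogn(ma[i]); Sb += nlogn(mb[i]); }
  const double N = (double)n, lN = std::log(N);
  double Ha = lN - Sa / N, Hb = lN - Sb / N, Hab = lN - Sj / N;
  if (Hab <= 1e-12) return 2.0; // both images constant: perfectly predictable
  return (Ha + Hb) / Hab;
}

// Pattern-search optimisation of FFD control-point displacements maximising
// NMI(fixed, moving o T). Maintains mapped coordinates, warped values and the
// joint histogram; a control-point trial only touches voxels in the 4x4x4
// control-cell support and updates entropies incrementally.
// [[Rcpp::export]]
List cpp_ffd_optimize(NumericVector fixed, IntegerVector fdim,
                      NumericVector moving, IntegerVector mdim,
                      NumericMatrix affine, NumericVector gspacing,
                      NumericVector gorigin, IntegerVector gdim,
                      NumericVector disp0, int bins,
                      NumericVector frange, NumericVector mrange,
                      NumericVector steps, int sweeps, IntegerVector axes,
                      double background, double min_gain, double lambda) {
  Grid gf(fdim), gm(mdim);
  const R_xlen_t N = gf.n();
  NumericVector disp = clone(disp0);
  FFD ffd = make_ffd(fdim, gspacing, gorigin, gdim, disp);
  ffd.disp = REAL(disp);
  const double* fv = REAL(fixed);
  const double* mv = REAL(moving);
  const double finv = bins / std::max(frange[1] - frange[0], 1e-12);
  const double minv = bins / std::max(mrange[1] - mrange[0], 1e-12);

  // initial mapped coordinates, warped values, bins, histogram
  std::vector<double> cz(N), cy(N), cx(N), wval(N);
  std::vector<int> fb(N), mb(N);
  std::vector<double> J((R_xlen_t)bins * bins, 0.0), Mm(bins, 0.0), Mf(bins, 0.0);
  for (int x = 0; x < gf.nx; ++x)
    for (int y = 0; y < gf.ny; ++y)
      for (int z = 0; z < gf.nz; ++z) {
        R_xlen_t i = gf.idx(z, y, x);
        double pz = affine(0, 0) * z + affine(0, 1) * y + affine(0, 2) * x + affine(0, 3);
        double py = affine(1, 0) * z + affine(1, 1) * y + affine(1, 2) * x + affine(1, 3);
        double px = affine(2, 0) * z + affine(2, 1) * y + affine(2, 2) * x + affine(2, 3);
        double d[3];
        ffd.eval(z, y, x, d);
        cz[i] = pz + d[0]; cy[i] = py + d[1]; cx[i] = px + d[2];
        wval[i] = sample_lin(mv, gm, cz[i], cy[i], cx[i], background);
        fb[i] = binof(fv[i], frange[0], finv, bins);
        mb[i] = binof(wval[i], mrange[0], minv, bins);
        J[(R_xlen_t)fb[i] * bins + mb[i]] += 1.0;
      }
  double Sj = 0.0, Sm = 0.0, Sf = 0.0;
  for (int i = 0; i < bins; ++i)
    for (int j = 0; j < bins; ++j) {
      double c = J[(R_xlen_t)i * bins + j];
      Mf[i] += c; Mm[j] += c; Sj += nlogn(c);
    }
  for (int j = 0; j < bins; ++j) { Sm += nlogn(Mm[j]); Sf += nlogn(Mf[j]); }
  const double lN = std::log((double)N);
  const double Hf = lN - Sf / N;
  auto nmi_of = [&](double Sj_, double Sm_) {
    double Hm = lN - Sm_ / N, Hj = lN - Sj_ / N;
    if (Hj <= 1e-12) return 2.0;
    return (Hf + Hm) / Hj;
  };
  double cur = nmi_of(Sj, Sm);
  const double nmi0 = cur;

  // trial buffers
  std::vector<R_xlen_t> t_idx; t_idx.reserve(1 << 16);
  std::vector<double> t_coord, t_val; t_coord.reserve(1 << 16); t_val.reserve(1 << 16);
  std::vector<int> t_bin; t_bin.reserve(1 << 16);

  const int gz = gdim[0], gy = gdim[1], gx = gdim[2];
  // smoothness penalty: deviation of a control displacement from the mean of
  // its 6-neighbours, so information-free regions (pattern-replaced lesions,
  // uniform parenchyma) interpolate the surrounding deformation instead of
  // drifting on histogram noise
  double* dp = REAL(disp);
  auto nbr_mean = [&](int pz, int py, int px, int a) {
    double s = 0.0; int n = 0;
    const int dz[6] = { -1, 1, 0, 0, 0, 0 };
    const int dy[6] = { 0, 0, -1, 1, 0, 0 };
    const int dx[6] = { 0, 0, 0, 0, -1, 1 };
    for (int k = 0; k < 6; ++k) {
      int z = pz + dz[k], y = py + dy[k], x = px + dx[k];
      if (z < 0 || y < 0 || x < 0 || z >= gz || y >= gy || x >= gx) continue;
      s += dp[ffd.didx(z, y, x, a)]; n++;
    }
    return n ? s / n : 0.0;
  };
  auto local_penalty = [&](int pz, int py, int px, int a) {
    // terms centred at p and at each neighbour of p along axis a
    double e = 0.0;
    double d0 = dp[ffd.didx(pz, py, px, a)] - nbr_mean(pz, py, px, a);
    e += d0 * d0;
    const int dz[6] = { -1, 1, 0, 0, 0, 0 };
    const int dy[6] = { 0, 0, -1, 1, 0, 0 };
    const int dx[6] = { 0, 0, 0, 0, -1, 1 };
    for (int k = 0; k < 6; ++k) {
      int z = pz + dz[k], y = py + dy[k], x = px + dx[k];
      if (z < 0 || y < 0 || x < 0 || z >= gz || y >= gy || x >= gx) continue;
      double d = dp[ffd.didx(z, y, x, a)] - nbr_mean(z, y, x, a);
      e += d * d;
    }
    return lambda * e;
  };
  for (R_xlen_t si = 0; si < steps.size(); ++si) {
    double del = steps[si];
    for (int sweep = 0; sweep < sweeps; ++sweep) {
      bool any_accept = false;
      for (int px = 0; px < gx; ++px)
        for (int py = 0; py < gy; ++py)
          for (int pz = 0; pz < gz; ++pz) {
            // support box in fixed voxel coordinates
            int z0 = (int)std::ceil(gorigin[0] + (pz - 2) * gspacing[0]);
            int z1 = (int)std::floor(gorigin[0] + (pz + 2) * gspacing[0]);
            int y0 = (int)std::ceil(gorigin[1] + (py - 2) * gspacing[1]);
            int y1 = (int)std::floor(gorigin[1] + (py + 2) * gspacing[1]);
            int x0 = (int)std::ceil(gorigin[2] + (px - 2) * gspacing[2]);
            int x1 = (int)std::floor(gorigin[2] + (px + 2) * gspacing[2]);
            if (z0 < 0) z0 = 0; if (y0 < 0) y0 = 0; if (x0 < 0) x0 = 0;
            if (z1 > gf.nz - 1) z1 = gf.nz - 1;
            if (y1 > gf.ny - 1) y1 = gf.ny - 1;
            if (x1 > gf.nx - 1) x1 = gf.nx - 1;
            if (z0 > z1 || y0 > y1 || x0 > x1) continue;
            for (R_xlen_t ai = 0; ai < axes.size(); ++ai) {
              int a = axes[ai];
              double best_gain = min_gain;
              double best_delta = 0.0;
              for (int dir = 0; dir < 2; ++dir) {
                double d = dir == 0 ? del : -del;
                // evaluate trial
                t_idx.clear(); t_coord.clear(); t_val.clear(); t_bin.clear();
                double Sj_t = Sj, Sm_t = Sm;
                for (int x = x0; x <= x1; ++x) {
                  int kbx = ffd.tx.base[x];
                  if (px < kbx || px > kbx + 3) continue;
                  double wx = ffd.tx.w[4 * x + (px - kbx)];
                  for (int y = y0; y <= y1; ++y) {
                    int kby = ffd.ty.base[y];
                    if (py < kby || py > kby + 3) continue;
                    double wxy = wx * ffd.ty.w[4 * y + (py - kby)];
                    if (wxy == 0.0) continue;
                    for (int z = z0; z <= z1; ++z) {
                      int kbz = ffd.tz.base[z];
                      if (pz < kbz || pz > kbz + 3) continue;
                      double w = wxy * ffd.tz.w[4 * z + (pz - kbz)];
                      if (w < 1e-10) continue;
                      R_xlen_t i = gf.idx(z, y, x);
                      double nz = cz[i], ny2 = cy[i], nx2 = cx[i];
                      double delta = d * w;
                      if (a == 0) nz += delta; else if (a == 1) ny2 += delta; else nx2 += delta;
                      double nv = sample_lin(mv, gm, nz, ny2, nx2, background);
                      int nb = binof(nv, mrange[0], minv, bins);
                      t_idx.push_back(i);
                      t_coord.push_back(delta);
                      t_val.push_back(nv);
                      t_bin.push_back(nb);
                      if (nb != mb[i]) {
                        R_xlen_t jo = (R_xlen_t)fb[i] * bins + mb[i];
                        R_xlen_t jn = (R_xlen_t)fb[i] * bins + nb;
                        Sj_t += -nlogn(J[jo]) + nlogn(J[jo] - 1.0)
                                - nlogn(J[jn]) + nlogn(J[jn] + 1.0);
                        Sm_t += -nlogn(Mm[mb[i]]) + nlogn(Mm[mb[i]] - 1.0)
                                - nlogn(Mm[nb]) + nlogn(Mm[nb] + 1.0);
                        J[jo] -= 1.0; J[jn] += 1.0;
                        Mm[mb[i]] -= 1.0; Mm[nb] += 1.0;
                      }
                    }
                  }
                }
                double nmi_t = nmi_of(Sj_t, Sm_t);
                double dgain = 0.0;
                if (lambda > 0.0) {
                  R_xlen_t di = ffd.didx(pz, py, px, a);
                  double e0 = local_penalty(pz, py, px, a);
                  dp[di] += d;
                  double e1 = local_penalty(pz, py, px, a);
                  dp[di] -= d;
                  dgain = e1 - e0;
                }
                double gain = nmi_t - cur - dgain;
                // revert histogram (re-applied on accept)
                for (size_t k = 0; k < t_idx.size(); ++k) {
                  R_xlen_t i = t_idx[k];
                  if (t_bin[k] != mb[i]) {
                    J[(R_xlen_t)fb[i] * bins + t_bin[k]] -= 1.0;
                    J[(R_xlen_t)fb[i] * bins + mb[i]] += 1.0;
                    Mm[t_bin[k]] -= 1.0; Mm[mb[i]] += 1.0;
                  }
                }
                if (gain > best_gain) { best_gain = gain; best_delta = d; }
              }
              if (best_delta != 0.0) {
                // re-run the winning trial and commit
                double d = best_delta;
                double Sj_t = Sj, Sm_t = Sm;
                for (int x = x0; x <= x1; ++x) {
                  int kbx = ffd.tx.base[x];
                  if (px < kbx || px > kbx + 3) continue;
                  double wx = ffd.tx.w[4 * x + (px - kbx)];
                  for (int y = y0; y <= y1; ++y) {
                    int kby = ffd.ty.base[y];
                    if (py < kby || py > kby + 3) continue;
                    double wxy = wx * ffd.ty.w[4 * y + (py - kby)];
                    if (wxy == 0.0) continue;
                    for (int z = z0; z <= z1; ++z) {
                      int kbz = ffd.tz.base[z];
                      if (pz < kbz || pz > kbz + 3) continue;
                      double w = wxy * ffd.tz.w[4 * z + (pz - kbz)];
                      if (w < 1e-10) continue;
                      R_xlen_t i = gf.idx(z, y, x);
                      double delta = d * w;
                      if (a == 0) cz[i] += delta; else if (a == 1) cy[i] += delta; else cx[i] += delta;
                      double nv = sample_lin(mv, gm, cz[i], cy[i], cx[i], background);
                      int nb = binof(nv, mrange[0], minv, bins);
                      if (nb != mb[i]) {
                        R_xlen_t jo = (R_xlen_t)fb[i] * bins + mb[i];
                        R_xlen_t jn = (R_xlen_t)fb[i] * bins + nb;
                        Sj_t += -nlogn(J[jo]) + nlogn(J[jo] - 1.0)
                                - nlogn(J[jn]) + nlogn(J[jn] + 1.0);
                        Sm_t += -nlogn(Mm[mb[i]]) + nlogn(Mm[mb[i]] - 1.0)
                                - nlogn(Mm[nb]) + nlogn(Mm[nb] + 1.0);
                        J[jo] -= 1.0; J[jn] += 1.0;
                        Mm[mb[i]] -= 1.0; Mm[nb] += 1.0;
                        mb[i] = nb;
                      }
                      wval[i] = nv;
                    }
                  }
                }
                Sj = Sj_t; Sm = Sm_t;
                disp[ffd.didx(pz, py, px, a)] += d;
                cur = nmi_of(Sj, Sm);
                any_accept = true;
              }
            }
          }
      if (!any_accept) break;
    }
  }
  return List::create(_["disp"] = disp, _["nmi"] = cur, _["nmi0"] = nmi0);
}

// Seeded monotone region growing on one slice of cluster labels.
// direction +1: a neighbour is accepted when its label >= the current voxel's
// label (metastasis, labels ascend outward); -1: <= (HCC). Labels must also
// lie inside [lo, hi]. 8-connectivity. `lab` values <= 0 mark non-liver.
// [[Rcpp::export]]
LogicalMatrix cpp_grow_monotone(IntegerMatrix lab, IntegerMatrix seeds,
                                int direction, int lo, int hi) {
  int nr = lab.nrow(), nc = lab.ncol();
  LogicalMatrix out(nr, nc);
  std::vector<std::pair<int, int> > stack;
  for (int s = 0; s < seeds.nrow(); ++s) {
    int r = seeds(s, 0) - 1, c = seeds(s, 1) - 1;
    if (r < 0 || c < 0 || r >= nr || c >= nc) continue;
    int l = lab(r, c);
    if (l < lo || l > hi) continue;
    if (!out(r, c)) { out(r, c) = true; stack.push_back(std::make_pair(r, c)); }
  }
  const int dr[8] = { -1, -1, -1, 0, 0, 1, 1, 1 };
  const int dc[8] = { -1, 0, 1, -1, 1, -1, 0, 1 };
  while (!stack.empty()) {
    std::pair<int, int> p = stack.back();
    stack.pop_back();
    int lcur = lab(p.first, p.second);
    for (int k = 0; k < 8; ++k) {
      int r = p.first + dr[k], c = p.second + dc[k];
      if (r < 0 || c < 0 || r >= nr || c >= nc || out(r, c)) continue;
      int l = lab(r, c);
      if (l < lo || l > hi) continue;
      if (direction * (l - lcur) < 0) continue;
      out(r, c) = true;
      stack.push_back(std::make_pair(r, c));
    }
  }
  return out;
}
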