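#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a column-major volume at continuous 0-based voxel
// coordinates; points outside the grid contribute 0.
static inline double trilinear(const double* vol, int nx, int ny, int nz,
                               double x, double y, double z) {
  if (x < 0.0 || y < 0.0 || z < 0.0 ||
      x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) {
    return 0.0;
  }
  int i0 = (int)std::floor(x); if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  int j0 = (int)std::floor(y); if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  int k0 = (int)std::floor(z); if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  const int sx = 1, sy = nx, sz = nx * ny;
  const double* p = vol + i0 * sx + j0 * sy + (size_t)k0 * sz;
  double c00 = p[0] * (1 - fx) + p[sx] * fx;
  double c10 = p[sy] * (1 - fx) + p[sy + sx] * fx;
  double c01 = p[sz] * (1 - fx) + p[sz + sx] * fx;
  double c11 = p[sz + sy] * (1 - fx) + p[sz + sy + sx] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// Pull-back warp: out(v) = vol(v + disp(v)), displacement in mm on the same
// grid.  Used for dose warping to the reference phase and for resampling
// masks/densities through ground-truth deformation fields.
// [[Rcpp::export]]
NumericVector cpp_pullback(NumericVector vol, IntegerVector dim,
                           NumericVector spacing,
                           NumericVector dx, NumericVector dy,
                           NumericVector dz) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const double* v = REAL(vol);
  const double* px = REAL(dx); const double* py = REAL(dy);
  const double* pz = REAL(dz);
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  size_t idx = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i, ++idx) {
        out[idx] = trilinear(v, nx, ny, nz,
                             i + px[idx] / sx,
                             j + py[idx] / sy,
                             k + pz[idx] / sz);
      }
  return out;
}

// Water-equivalent path length per voxel for a parallel beam travelling
// along unit vector dir, integrated from the grid entry face by an
// incremental shear sweep along the dominant axis.  Requires the dominant
// component of dir to be >= 0.5 in magnitude (gantry within 60 degrees of a
// principal axis, which covers the anterior/oblique/posterior arrangements
// used here).
// [[Rcpp::export]]
NumericVector cpp_wepl(NumericVector density, IntegerVector dim,
                       NumericVector spacing, NumericVector dir) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  size_t n = (size_t)nx * ny * nz;
  NumericVector out(n);
  const double* rho = REAL(density);
  double* w = REAL(out);
  int nd[3] = {nx, ny, nz};
  double sp[3] = {spacing[0], spacing[1], spacing[2]};
  double d[3] = {dir[0], dir[1], dir[2]};
  int a = 0;
  for (int m = 1; m < 3; ++m) if (std::fabs(d[m]) > std::fabs(d[a])) a = m;
  if (std::fabs(d[a]) < 0.5) stop("beam direction too oblique for sweep");
  double L = sp[a] / std::fabs(d[a]);          // step length, mm
  // index offset of the upstream sample point in each axis
  double del[3];
  for (int m = 0; m < 3; ++m) del[m] = L * d[m] / sp[m];
  int strides[3] = {1, nx, nx * ny};
  int b = (a == 0) ? 1 : 0;                    // the two lateral axes
  int c = (a == 2) ? 1 : 2;
  bool forward = d[a] > 0;
  for (int s = 0; s < nd[a]; ++s) {
    int slab = forward ? s : nd[a] - 1 - s;
    for (int jc = 0; jc < nd[c]; ++jc) {
      for (int jb = 0; jb < nd[b]; ++jb) {
        size_t idx = (size_t)slab * strides[a] + (size_t)jb * strides[b] +
                     (size_t)jc * strides[c];
        double here = rho[idx];
        if (s == 0) { w[idx] = 0.5 * L * here; continue; }
        // upstream point: previous slab, laterally offset by del[b], del[c]
        double ub = jb - del[b];
        double uc = jc - del[c];
        int pslab = forward ? slab - 1 : slab + 1;
        double wprev = 0.0, rprev = 0.0;
        if (ub >= 0 && uc >= 0 && ub <= nd[b] - 1 && uc <= nd[c] - 1) {
          int b0 = (int)std::floor(ub); if (b0 > nd[b] - 2) b0 = nd[b] - 2;
          int c0 = (int)std::floor(uc); if (c0 > nd[c] - 2) c0 = nd[c] - 2;
          if (b0 < 0) b0 = 0; if (c0 < 0) c0 = 0;
          double fb = ub - b0, fc = uc - c0;
          size_t base = (size_t)pslab * strides[a] + (size_t)b0 * strides[b] +
                        (size_t)c0 * strides[c];
          size_t i00 = base;
          size_t i10 = base + strides[b];
          size_t i01 = base + strides[c];
          size_t i11 = base + strides[b] + strides[c];
          wprev = w[i00] * (1 - fb) * (1 - fc) + w[i10] * fb * (1 - fc) +
                  w[i01] * (1 - fb) * fc + w[i11] * fb * fc;
          rprev = rho[i00] * (1 - fb) * (1 - fc) + rho[i10] * fb * (1 - fc) +
                  rho[i01] * (1 - fb) * fc + rho[i11] * fb * fc;
        }
        w[idx] = wprev + 0.5 * L * (here + rprev);
      }
    }
  }
  return out;
}

// x^p for small integer p without libm pow (the build-up exponent is an
// integer in practice and this sits in the innermost dose loop).
static inline double fast_pow(double x, double p) {
  int ip = (int)p;
  if (ip == p && ip >= 0 && ip <= 16) {
    double r = 1.0;
    double b = x;
    int e = ip;
    while (e) {
      if (e & 1) r *= b;
      b *= b;
      e >>= 1;
    }
    return r;
  }
  return std::pow(x, p);
}

// Analytic Bragg-curve surrogate: normalized entrance dose 1, unique peak of
// height `peak` at depth == range, Gaussian distal falloff truncated (and
// shifted to zero continuously) at range + cut_sd * sigma_f.
static inline double bragg(double depth, double range, double peak,
                           double buildup_pow, double sigma_f,
                           double cut_sd) {
  if (depth < 0.0) return 0.0;
  if (depth <= range) {
    return 1.0 + (peak - 1.0) * fast_pow(depth / range, buildup_pow);
  }
  double edge = cut_sd * sigma_f;
  double over = depth - range;
  if (over >= edge) return 0.0;
  double c0 = std::exp(-0.5 * cut_sd * cut_sd);
  double g = std::exp(-0.5 * (over / sigma_f) * (over / sigma_f));
  return peak * (g - c0) / (1.0 - c0);
}

// [[Rcpp::export]]
NumericVector cpp_depth_dose(NumericVector depth, double range,
                             NumericVector pars) {
  int n = depth.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    if (depth[i] < 0) stop("negative depth");
    out[i] = bragg(depth[i], range, pars[0], pars[1], pars[2], pars[3]);
  }
  return out;
}

// Accumulate dose from a set of spots of one beam into `dose` (modified in
// place).  Geometry: beam direction (sin th, cos th, 0); lateral frame
// e_u = (cos th, -sin th, 0), e_v = (0, 0, 1).  Spot matrix columns:
// u, v (mm, relative to isocenter), range (mm WE), weight, sigma (mm).
// `iso` is the effective (scenario-shifted) isocenter in world mm.
// density_scale multiplies the water-equivalent depth.
// [[Rcpp::export]]
void cpp_add_spot_dose(NumericVector dose, NumericVector wepl,
                       IntegerVector dim, NumericVector spacing,
                       NumericVector origin, double theta,
                       NumericVector iso, NumericMatrix spots,
                       double density_scale, NumericVector bragg_pars,
                       double lateral_cut_sd) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double* D = REAL(dose);
  const double* W = REAL(wepl);
  double ct = std::cos(theta), st = std::sin(theta);
  double iso_u = ct * iso[0] - st * iso[1];
  double iso_v = iso[2];
  double pk = bragg_pars[0], bp = bragg_pars[1];
  double sf = bragg_pars[2], csd = bragg_pars[3];
  double edge = csd * sf;
  // per-column lateral coordinate u(i, j) and per-slice v(k)
  std::vector<double> uij((size_t)nx * ny);
  for (int j = 0; j < ny; ++j) {
    double yw = origin[1] + j * spacing[1];
    for (int i = 0; i < nx; ++i) {
      double xw = origin[0] + i * spacing[0];
      uij[(size_t)j * nx + i] = ct * xw - st * yw;
    }
  }
  std::vector<double> zk(nz);
  for (int k = 0; k < nz; ++k) zk[k] = origin[2] + k * spacing[2];
  int ns = spots.nrow();
  std::vector<double> gv(nz);
  // scratch: per-j i-band bounds and per-column lateral Gaussian x weight
  std::vector<int> ib0(ny), ib1(ny), goff(ny);
  std::vector<double> gu_buf((size_t)nx * ny);
  for (int s = 0; s < ns; ++s) {
    double su = iso_u + spots(s, 0);
    double sv = iso_v + spots(s, 1);
    double R = spots(s, 2);
    double wgt = spots(s, 3);
    if (wgt == 0.0) continue;
    double sig = spots(s, 4);
    double cut = lateral_cut_sd * sig;
    double inv2s2 = 1.0 / (2.0 * sig * sig);
    int k0 = (int)std::ceil((sv - cut - origin[2]) / spacing[2]);
    int k1 = (int)std::floor((sv + cut - origin[2]) / spacing[2]);
    if (k0 < 0) k0 = 0;
    if (k1 > nz - 1) k1 = nz - 1;
    if (k0 > k1) continue;
    for (int k = k0; k <= k1; ++k) {
      double dv = zk[k] - sv;
      gv[k] = std::exp(-dv * dv * inv2s2);
    }
    // per j: analytic i-range with |u(i, j) - su| <= cut (u linear in i
    // with positive slope ct * spacing[0]; ct >= 0.5 for |gantry| <= 60)
    double slope = ct * spacing[0];
    int off = 0;
    for (int j = 0; j < ny; ++j) {
      double u_at0 = uij[(size_t)j * nx];
      int i0 = (int)std::ceil((su - cut - u_at0) / slope);
      int i1 = (int)std::floor((su + cut - u_at0) / slope);
      if (i0 < 0) i0 = 0;
      if (i1 > nx - 1) i1 = nx - 1;
      ib0[j] = i0; ib1[j] = i1; goff[j] = off;
      const double* urow = &uij[(size_t)j * nx];
      for (int i = i0; i <= i1; ++i) {
        double du = urow[i] - su;
        gu_buf[off++] = std::exp(-du * du * inv2s2) * wgt;
      }
    }
    // k-outer sweep keeps the wepl/dose access contiguous in i
    for (int k = k0; k <= k1; ++k) {
      double g = gv[k];
      size_t kbase = (size_t)k * nx * ny;
      for (int j = 0; j < ny; ++j) {
        if (ib0[j] > ib1[j]) continue;
        const double* gb = &gu_buf[goff[j]];
        size_t base = kbase + (size_t)j * nx;
        for (int i = ib0[j]; i <= ib1[j]; ++i) {
          size_t idx = base + i;
          double dep = W[idx] * density_scale;
          if (dep > R + edge) continue;
          double b = bragg(dep, R, pk, bp, sf, csd);
          D[idx] += gb[i - ib0[j]] * g * b;
        }
      }
    }
  }
}

// Accumulate the dose of one energy layer delivered as a set of spots on a
// regular lateral lattice (centers uc x vc relative to isocenter, weight
// matrix Wm, shared range R and sigma).  Equivalent to cpp_add_spot_dose
// over the same spots but visits each voxel once per layer instead of once
// per spot: the lateral Gaussian sum is evaluated per voxel column through
// the lattice window.
// [[Rcpp::export]]
void cpp_add_layer_dose(NumericVector dose, NumericVector wepl,
                        IntegerVector dim, NumericVector spacing,
                        NumericVector origin, double theta,
                        NumericVector iso, NumericVector uc,
                        NumericVector vc, NumericMatrix Wm, double R,
                        double sigma, double density_scale,
                        NumericVector bragg_pars, double lateral_cut_sd) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double* D = REAL(dose);
  const double* W = REAL(wepl);
  double ct = std::cos(theta), st = std::sin(theta);
  double iso_u = ct * iso[0] - st * iso[1];
  double iso_v = iso[2];
  double pk = bragg_pars[0], bp = bragg_pars[1];
  double sf = bragg_pars[2], csd = bragg_pars[3];
  double edge = csd * sf;
  double cut = lateral_cut_sd * sigma;
  double inv2s2 = 1.0 / (2.0 * sigma * sigma);
  int nu = uc.size(), nv = vc.size();
  double vlo = iso_v + vc[0] - cut, vhi = iso_v + vc[nv - 1] + cut;
  int k0 = (int)std::ceil((vlo - origin[2]) / spacing[2]);
  int k1 = (int)std::floor((vhi - origin[2]) / spacing[2]);
  if (k0 < 0) k0 = 0;
  if (k1 > nz - 1) k1 = nz - 1;
  if (k0 > k1) return;
  int nk = k1 - k0 + 1;
  // M[c][k] = sum_r Wm[c][r] * exp(-(z_k - v_r)^2 / 2 sigma^2)
  std::vector<double> M((size_t)nu * nk, 0.0);
  for (int k = 0; k < nk; ++k) {
    double z = origin[2] + (k0 + k) * spacing[2];
    for (int r = 0; r < nv; ++r) {
      double dv = z - (iso_v + vc[r]);
      if (dv > cut || dv < -cut) continue;
      double g = std::exp(-dv * dv * inv2s2);
      for (int c = 0; c < nu; ++c) {
        double wv = Wm(c, r);
        if (wv != 0.0) M[(size_t)c * nk + k] += wv * g;
      }
    }
  }
  double u_first = iso_u + uc[0], u_last = iso_u + uc[nu - 1];
  double du_lat = nu > 1 ? (uc[1] - uc[0]) : 1.0;
  double slope = ct * spacing[0];
  std::vector<double> colfac(nk);
  for (int j = 0; j < ny; ++j) {
    double yw = origin[1] + j * spacing[1];
    double u_at0 = ct * origin[0] - st * yw;
    int i0 = (int)std::ceil((u_first - cut - u_at0) / slope);
    int i1 = (int)std::floor((u_last + cut - u_at0) / slope);
    if (i0 < 0) i0 = 0;
    if (i1 > nx - 1) i1 = nx - 1;
    for (int i = i0; i <= i1; ++i) {
      double u = u_at0 + i * slope;
      int c0 = nu > 1 ? (int)std::ceil((u - cut - u_first) / du_lat) : 0;
      int c1 = nu > 1 ? (int)std::floor((u + cut - u_first) / du_lat) : 0;
      if (c0 < 0) c0 = 0;
      if (c1 > nu - 1) c1 = nu - 1;
      if (c0 > c1) continue;
      for (int k = 0; k < nk; ++k) colfac[k] = 0.0;
      bool any = false;
      for (int c = c0; c <= c1; ++c) {
        double duu = u - (u_first + c * du_lat);
        if (duu > cut || duu < -cut) continue;
        double g = std::exp(-duu * duu * inv2s2);
        const double* Mc = &M[(size_t)c * nk];
        for (int k = 0; k < nk; ++k) colfac[k] += g * Mc[k];
        any = true;
      }
      if (!any) continue;
      size_t base = (size_t)i + (size_t)j * nx;
      for (int k = 0; k < nk; ++k) {
        double cf = colfac[k];
        if (cf == 0.0) continue;
        size_t idx = base + (size_t)(k0 + k) * nx * ny;
        double dep = W[idx] * density_scale;
        if (dep > R + edge) continue;
        D[idx] += cf * bragg(dep, R, pk, bp, sf, csd);
      }
    }
  }
}

// Dense dose-influence block for one beam restricted to a voxel subset:
// out[r, s] = dose at voxel voxel_idx[r] (1-based) per unit weight of spot s.
// [[Rcpp::export]]
NumericMatrix cpp_influence(NumericVector wepl, IntegerVector dim,
                            NumericVector spacing, NumericVector origin,
                            double theta, NumericVector iso,
                            NumericMatrix spots, double density_scale,
                            NumericVector bragg_pars, double lateral_cut_sd,
                            IntegerVector voxel_idx) {
  int nx = dim[0], ny = dim[1];
  const double* W = REAL(wepl);
  double ct = std::cos(theta), st = std::sin(theta);
  double iso_u = ct * iso[0] - st * iso[1];
  double iso_v = iso[2];
  double pk = bragg_pars[0], bp = bragg_pars[1];
  double sf = bragg_pars[2], csd = bragg_pars[3];
  double edge = csd * sf;
  int nv = voxel_idx.size();
  int ns = spots.nrow();
  NumericMatrix out(nv, ns);
  std::vector<double> uu(nv), vv(nv), dep0(nv);
  for (int r = 0; r < nv; ++r) {
    size_t idx = (size_t)voxel_idx[r] - 1;
    int k = (int)(idx / ((size_t)nx * ny));
    size_t rem = idx - (size_t)k * nx * ny;
    int j = (int)(rem / nx);
    int i = (int)(rem - (size_t)j * nx);
    double xw = origin[0] + i * spacing[0];
    double yw = origin[1] + j * spacing[1];
    uu[r] = ct * xw - st * yw;
    vv[r] = origin[2] + k * spacing[2];
    dep0[r] = W[idx] * density_scale;
  }
  for (int s = 0; s < ns; ++s) {
    double su = iso_u + spots(s, 0);
    double sv = iso_v + spots(s, 1);
    double R = spots(s, 2);
    double sig = spots(s, 4);
    double cut = lateral_cut_sd * sig;
    double inv2s2 = 1.0 / (2.0 * sig * sig);
    for (int r = 0; r < nv; ++r) {
      double du = uu[r] - su;
      if (du > cut || du < -cut) continue;
      double dv = vv[r] - sv;
      if (dv > cut || dv < -cut) continue;
      double dep = dep0[r];
      if (dep > R + edge) continue;
      double b = bragg(dep, R, pk, bp, sf, csd);
      out(r, s) = std::exp(-(du * du + dv * dv) * inv2s2) * b;
    }
  }
  return out;
}
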