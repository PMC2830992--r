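// Core numerical kernels: trilinear sampling, mean-square registration
// metrics for linear and B-spline transforms, cubic B-spline displacement
// fields, isosurface extraction and 6-connectivity labelling.
//
// Volume layout convention (shared with the R side): a volume is a numeric
// array with dim = (nz, ny, nx), indexed [z, y, x]; R is column-major so the
// flat offset of voxel (k, j, i) = (z, y, x) is k + nz*j + nz*ny*i.
// Physical vectors are always ordered (x, y, z).

#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

static inline double sample_trilinear(const double* v, int nz, int ny, int nx,
                                      double x, double y, double z,
                                      bool& inside, double* grad /* or NULL */) {
  // x, y, z are continuous 0-based voxel coordinates
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    inside = false;
    if (grad) grad[0] = grad[1] = grad[2] = 0.0;
    return 0.0;
  }
  inside = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
  if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
  if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
  // degenerate single-voxel axes
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double tx = (nx == 1) ? 0.0 : x - i0;
  double ty = (ny == 1) ? 0.0 : y - j0;
  double tz = (nz == 1) ? 0.0 : z - k0;
  int i1 = (nx == 1) ? i0 : i0 + 1;
  int j1 = (ny == 1) ? j0 : j0 + 1;
  int k1 = (nz == 1) ? k0 : k0 + 1;
  size_t sy = (size_t)nz, sx = (size_t)nz * ny;
  const double c000 = v[k0 + sy*j0 + sx*i0], c001 = v[k1 + sy*j0 + sx*i0];
  const double c010 = v[k0 + sy*j1 + sx*i0], c011 = v[k1 + sy*j1 + sx*i0];
  const double c100 = v[k0 + sy*j0 + sx*i1], c101 = v[k1 + sy*j0 + sx*i1];
  const double c110 = v[k0 + sy*j1 + sx*i1], c111 = v[k1 + sy*j1 + sx*i1];
  // interpolate along z, then y, then x
  double a00 = c000 + tz * (c001 - c000);
  double a01 = c010 + tz * (c011 - c010);
  double a10 = c100 + tz * (c101 - c100);
  double a11 = c110 + tz * (c111 - c110);
  double b0 = a00 + ty * (a01 - a00);
  double b1 = a10 + ty * (a11 - a10);
  double val = b0 + tx * (b1 - b0);
  if (grad) {
    // d/dx
    grad[0] = b1 - b0;
    // d/dy
    double g0 = a01 - a00, g1 = a11 - a10;
    grad[1] = g0 + tx * (g1 - g0);
    // d/dz
    double dz00 = c001 - c000, dz01 = c011 - c010;
    double dz10 = c101 - c100, dz11 = c111 - c110;
    double e0 = dz00 + ty * (dz01 - dz00);
    double e1 = dz10 + ty * (dz11 - dz10);
    grad[2] = e0 + tx * (e1 - e0);
  }
  return val;
}


// central-difference gradient of the trilinear interpolant (half-voxel
// stencil). At points aligned with the voxel grid the analytic derivative
// of trilinear interpolation is one-sided (the slope of one cell), which
// on binary images can point uphill; the symmetric stencil matches the
// gradient finite differences of the metric much better.
static inline double sample_central(const double* v, int nz, int ny, int nx,
                                    double x, double y, double z,
                                    bool& inside, double* grad) {
  double val = sample_trilinear(v, nz, ny, nx, x, y, z, inside, NULL);
  if (!inside) {
    if (grad) grad[0] = grad[1] = grad[2] = 0.0;
    return val;
  }
  if (grad) {
    bool ins;
    const double h = 0.5;
    double xp = sample_trilinear(v, nz, ny, nx, x + h, y, z, ins, NULL);
    double xm = sample_trilinear(v, nz, ny, nx, x - h, y, z, ins, NULL);
    double yp = sample_trilinear(v, nz, ny, nx, x, y + h, z, ins, NULL);
    double ym = sample_trilinear(v, nz, ny, nx, x, y - h, z, ins, NULL);
    double zp = sample_trilinear(v, nz, ny, nx, x, y, z + h, ins, NULL);
    double zm = sample_trilinear(v, nz, ny, nx, x, y, z - h, ins, NULL);
    grad[0] = (xp - xm) / (2 * h);
    grad[1] = (yp - ym) / (2 * h);
    grad[2] = (zp - zm) / (2 * h);
  }
  return val;
}

// [[Rcpp::export]]
NumericVector cpp_sample_trilinear(NumericVector vol, IntegerVector dim,
                                   NumericMatrix vox) {
  // vox: N x 3 continuous 0-based voxel coords, columns (x, y, z)
  int nz = dim[0], ny = dim[1], nx = dim[2];
  int n = vox.nrow();
  NumericVector out(n);
  const double* v = vol.begin();
  bool inside;
  for (int r = 0; r < n; ++r) {
    out[r] = sample_trilinear(v, nz, ny, nx, vox(r,0), vox(r,1), vox(r,2),
                              inside, NULL);
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mse_linear(NumericVector fixedv, IntegerVector fdim,
                    NumericVector forigin, NumericVector fspacing,
                    NumericVector movingv, IntegerVector mdim,
                    NumericVector morigin, NumericVector mspacing,
                    NumericMatrix L, NumericVector b) {
  // Mean squared intensity difference between fixed and moving under the
  // linear map x' = L x + b (physical coords, (x,y,z) order), averaged over
  // fixed voxels whose mapped position lies inside the moving domain.
  int fnz = fdim[0], fny = fdim[1], fnx = fdim[2];
  int mnz = mdim[0], mny = mdim[1], mnx = mdim[2];
  const double* fv = fixedv.begin();
  const double* mv = movingv.begin();
  double L00=L(0,0), L01=L(0,1), L02=L(0,2);
  double L10=L(1,0), L11=L(1,1), L12=L(1,2);
  double L20=L(2,0), L21=L(2,1), L22=L(2,2);
  double bx=b[0], by=b[1], bz=b[2];
  double sum = 0.0; long long n = 0;
  bool inside;
  size_t idx = 0;
  for (int i = 0; i < fnx; ++i) {
    double px = forigin[0] + i * fspacing[0];
    for (int j = 0; j < fny; ++j) {
      double py = forigin[1] + j * fspacing[1];
      for (int k = 0; k < fnz; ++k) {
        double pz = forigin[2] + k * fspacing[2];
        double qx = L00*px + L01*py + L02*pz + bx;
        double qy = L10*px + L11*py + L12*pz + by;
        double qz = L20*px + L21*py + L22*pz + bz;
        double vx = (qx - morigin[0]) / mspacing[0];
        double vy = (qy - morigin[1]) / mspacing[1];
        double vz = (qz - morigin[2]) / mspacing[2];
        double m = sample_trilinear(mv, mnz, mny, mnx, vx, vy, vz, inside, NULL);
        if (inside) {
          double d = fv[idx] - m;
          sum += d * d;
          ++n;
        }
        ++idx;
      }
    }
  }
  // flat index order above is z fastest, then y, then x: matches R layout
  // only if we walk idx accordingly; we walked x outer so recompute check:
  // offset(k,j,i) = k + nz*j + nz*ny*i, and loops run i (outer), j, k (inner)
  // giving idx = k + fnz*j + fnz*fny*i. Consistent.
  return List::create(_["sum"] = sum, _["n"] = (double)n,
                      _["metric"] = n > 0 ? sum / n : NA_REAL);
}

// Cubic B-spline basis for fractional offset t in [0,1)
static inline void bspline_weights(double t, double* w) {
  double t2 = t * t, t3 = t2 * t;
  w[0] = (1 - 3*t + 3*t2 - t3) / 6.0;
  w[1] = (4 - 6*t2 + 3*t3) / 6.0;
  w[2] = (1 + 3*t + 3*t2 - 3*t3) / 6.0;
  w[3] = t3 / 6.0;
}

struct BGrid {
  int nz, ny, nx;          // control point counts
  double ox, oy, oz;       // control grid origin (physical)
  double sx, sy, sz;       // control grid spacing (physical)
  const double* coef;      // array dim (nz, ny, nx, 3)
  size_t comp_stride;      // nz*ny*nx
};

static inline void bspline_support(double p, double o, double s, int nc,
                                   int& i0, double* w) {
  // support start index and 4 weights along one axis
  double u = (p - o) / s;
  int fl = (int)std::floor(u);
  i0 = fl - 1;
  if (i0 < 0) i0 = 0;
  if (i0 > nc - 4) i0 = nc - 4;
  double t = u - (i0 + 1);
  if (t < 0) t = 0; if (t > 1) t = 1;
  bspline_weights(t, w);
}

static inline void bspline_disp_at(const BGrid& g, double px, double py, double pz,
                                   double* D,
                                   int* si /*3*/, double* wx, double* wy, double* wz) {
  bspline_support(px, g.ox, g.sx, g.nx, si[0], wx);
  bspline_support(py, g.oy, g.sy, g.ny, si[1], wy);
  bspline_support(pz, g.oz, g.sz, g.nz, si[2], wz);
  D[0] = D[1] = D[2] = 0.0;
  size_t sy = (size_t)g.nz, sx = (size_t)g.nz * g.ny;
  for (int a = 0; a < 4; ++a) {
    size_t offx = sx * (size_t)(si[0] + a);
    for (int bq = 0; bq < 4; ++bq) {
      double wxy = wx[a] * wy[bq];
      size_t offxy = offx + sy * (size_t)(si[1] + bq);
      for (int c = 0; c < 4; ++c) {
        double w = wxy * wz[c];
        size_t off = offxy + (size_t)(si[2] + c);
        D[0] += w * g.coef[off];
        D[1] += w * g.coef[off + g.comp_stride];
        D[2] += w * g.coef[off + 2 * g.comp_stride];
      }
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_bspline_disp(NumericVector coef, IntegerVector cdim,
                               NumericVector corigin, NumericVector cspacing,
                               NumericMatrix pts) {
  // pts: N x 3 physical points (x,y,z); coef dim (ncz, ncy, ncx, 3)
  BGrid g;
  g.nz = cdim[0]; g.ny = cdim[1]; g.nx = cdim[2];
  g.oz = corigin[2]; g.oy = corigin[1]; g.ox = corigin[0];
  g.sz = cspacing[2]; g.sy = cspacing[1]; g.sx = cspacing[0];
  g.coef = coef.begin();
  g.comp_stride = (size_t)g.nz * g.ny * g.nx;
  int n = pts.nrow();
  NumericMatrix out(n, 3);
  int si[3]; double wx[4], wy[4], wz[4], D[3];
  for (int r = 0; r < n; ++r) {
    bspline_disp_at(g, pts(r,0), pts(r,1), pts(r,2), D, si, wx, wy, wz);
    out(r,0) = D[0]; out(r,1) = D[1]; out(r,2) = D[2];
  }
  return out;
}

// [[Rcpp::export]]
List cpp_mse_bspline(NumericVector fixedv, IntegerVector fdim,
                     NumericVector forigin, NumericVector fspacing,
                     NumericVector movingv, IntegerVector mdim,
                     NumericVector morigin, NumericVector mspacing,
                     NumericVector coef, IntegerVector cdim,
                     NumericVector corigin, NumericVector cspacing,
                     NumericMatrix L, NumericVector b, bool want_grad) {
  // Metric for T(x) = M(x + D(x)) with M the linear map (L, b); analytic
  // gradient with respect to the control-point coefficients.
  int fnz = fdim[0], fny = fdim[1], fnx = fdim[2];
  int mnz = mdim[0], mny = mdim[1], mnx = mdim[2];
  const double* fv = fixedv.begin();
  const double* mv = movingv.begin();
  BGrid g;
  g.nz = cdim[0]; g.ny = cdim[1]; g.nx = cdim[2];
  g.oz = corigin[2]; g.oy = corigin[1]; g.ox = corigin[0];
  g.sz = cspacing[2]; g.sy = cspacing[1]; g.sx = cspacing[0];
  g.coef = coef.begin();
  g.comp_stride = (size_t)g.nz * g.ny * g.nx;
  double L00=L(0,0), L01=L(0,1), L02=L(0,2);
  double L10=L(1,0), L11=L(1,1), L12=L(1,2);
  double L20=L(2,0), L21=L(2,1), L22=L(2,2);
  NumericVector gradv;
  double* gr = NULL;
  if (want_grad) { gradv = NumericVector(coef.size()); gr = gradv.begin(); }
  double sum = 0.0; long long n = 0;
  double D[3], mg[3];
  bool inside;
  size_t idx = 0;
  size_t csy = (size_t)g.nz, csx = (size_t)g.nz * g.ny;
  // per-axis support tables: the control lattice is axis-aligned, so the
  // support index and the four basis weights depend on one coordinate only
  std::vector<int> six(fnx), sjy(fny), skz(fnz);
  std::vector<double> twx(4*fnx), twy(4*fny), twz(4*fnz);
  for (int i = 0; i < fnx; ++i)
    bspline_support(forigin[0] + i*fspacing[0], g.ox, g.sx, g.nx, six[i], &twx[4*i]);
  for (int j = 0; j < fny; ++j)
    bspline_support(forigin[1] + j*fspacing[1], g.oy, g.sy, g.ny, sjy[j], &twy[4*j]);
  for (int k = 0; k < fnz; ++k)
    bspline_support(forigin[2] + k*fspacing[2], g.oz, g.sz, g.nz, skz[k], &twz[4*k]);
  int si[3]; double wx[4], wy[4], wz[4];
  for (int i = 0; i < fnx; ++i) {
    double px = forigin[0] + i * fspacing[0];
    si[0] = six[i];
    for (int a = 0; a < 4; ++a) wx[a] = twx[4*i + a];
    for (int j = 0; j < fny; ++j) {
      double py = forigin[1] + j * fspacing[1];
      si[1] = sjy[j];
      for (int a = 0; a < 4; ++a) wy[a] = twy[4*j + a];
      for (int k = 0; k < fnz; ++k, ++idx) {
        double pz = forigin[2] + k * fspacing[2];
        si[2] = skz[k];
        for (int a = 0; a < 4; ++a) wz[a] = twz[4*k + a];
        // displacement from the precomputed supports
        D[0] = D[1] = D[2] = 0.0;
        for (int a = 0; a < 4; ++a) {
          size_t offx = csx * (size_t)(si[0] + a);
          for (int bq = 0; bq < 4; ++bq) {
            double wxy = wx[a] * wy[bq];
            size_t offxy = offx + csy * (size_t)(si[1] + bq);
            for (int c = 0; c < 4; ++c) {
              double w = wxy * wz[c];
              size_t off = offxy + (size_t)(si[2] + c);
              D[0] += w * g.coef[off];
              D[1] += w * g.coef[off + g.comp_stride];
              D[2] += w * g.coef[off + 2 * g.comp_stride];
            }
          }
        }
        double ux = px + D[0], uy = py + D[1], uz = pz + D[2];
        double qx = L00*ux + L01*uy + L02*uz + b[0];
        double qy = L10*ux + L11*uy + L12*uz + b[1];
        double qz = L20*ux + L21*uy + L22*uz + b[2];
        double vx = (qx - morigin[0]) / mspacing[0];
        double vy = (qy - morigin[1]) / mspacing[1];
        double vz = (qz - morigin[2]) / mspacing[2];
        double m = sample_central(mv, mnz, mny, mnx, vx, vy, vz, inside,
                                  want_grad ? mg : NULL);
        if (!inside) continue;
        double d = fv[idx] - m;
        sum += d * d;
        ++n;
        if (want_grad) {
          // moving gradient in physical moving space
          double gpx = mg[0] / mspacing[0];
          double gpy = mg[1] / mspacing[1];
          double gpz = mg[2] / mspacing[2];
          // chain through M: dq/du = L, so dm/du = L^T grad_m
          double cx = L00*gpx + L10*gpy + L20*gpz;
          double cy = L01*gpx + L11*gpy + L21*gpz;
          double cz = L02*gpx + L12*gpy + L22*gpz;
          double f0 = -2.0 * d; // d/dD of (f - m)^2 = -2 (f-m) dm/dD
          for (int a = 0; a < 4; ++a) {
            size_t offx = csx * (size_t)(si[0] + a);
            for (int bq = 0; bq < 4; ++bq) {
              double wxy = wx[a] * wy[bq];
              size_t offxy = offx + csy * (size_t)(si[1] + bq);
              for (int c = 0; c < 4; ++c) {
                double w = wxy * wz[c];
                size_t off = offxy + (size_t)(si[2] + c);
                gr[off] += f0 * w * cx;
                gr[off + g.comp_stride] += f0 * w * cy;
                gr[off + 2 * g.comp_stride] += f0 * w * cz;
              }
            }
          }
        }
      }
    }
  }
  double metric = n > 0 ? sum / n : NA_REAL;
  if (want_grad && n > 0) {
    for (R_xlen_t t = 0; t < gradv.size(); ++t) gradv[t] /= (double)n;
  }
  if (want_grad)
    return List::create(_["metric"] = metric, _["n"] = (double)n,
                        _["grad"] = gradv);
  return List::create(_["metric"] = metric, _["n"] = (double)n);
}

// ---------------------------------------------------------------------------
// Isosurface extraction: per-cell face-contour tracing.
//
// In each cell the isocontour crossings on the 12 cube edges are linked into
// closed loops by pairing the crossings on each face; faces with four
// crossings are disambiguated with the asymptotic decider (sign of the
// bilinear saddle value), which is consistent between the two cells sharing
// a face, so the resulting mesh is watertight. Loops are fan-triangulated
// and oriented against the local trilinear gradient (outward normals).
// Vertices coincide with classic marching-cubes edge intersections.
// ---------------------------------------------------------------------------

// corner bit layout: bit0 = +x, bit1 = +y, bit2 = +z
static const int CORNER_OFF[8][3] = { // (dx, dy, dz)
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
};
// faces as 4 corners (a,b,c,d) with edges a-b, c-d, a-c, b-d; a/d diagonal
static const int FACES6[6][4] = {
  {0,1,2,3},{4,5,6,7},{0,1,4,5},{2,3,6,7},{0,2,4,6},{1,3,5,7}
};

// [[Rcpp::export]]
List cpp_marching_cubes(NumericVector vol, IntegerVector dim, double level) {
  int nz = dim[0], ny = dim[1], nx = dim[2];
  const double* v = vol.begin();
  size_t sy = (size_t)nz, sx = (size_t)nz * ny;
  std::vector<double> verts;        // x,y,z triples in voxel coords
  std::vector<int> tris;            // 0-based vertex ids
  // global edge key: (linear voxel id of lower corner) * 3 + axis
  std::map<long long, int> vmap;
  auto corner_val = [&](int i, int j, int k) -> double {
    return v[(size_t)k + sy*j + sx*i];
  };
  auto get_vertex = [&](int i1, int j1, int k1, int i2, int j2, int k2) -> int {
    // order endpoints canonically
    long long id1 = (long long)k1 + (long long)nz*j1 + (long long)nz*ny*i1;
    long long id2 = (long long)k2 + (long long)nz*j2 + (long long)nz*ny*i2;
    int axis = (i1 != i2) ? 0 : (j1 != j2) ? 1 : 2;
    long long lo = id1 < id2 ? id1 : id2;
    long long key = lo * 3 + axis;
    std::map<long long,int>::iterator it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    // endpoints in canonical order
    bool swap = id2 < id1;
    int ia = swap ? i2 : i1, ja = swap ? j2 : j1, ka = swap ? k2 : k1;
    int ib = swap ? i1 : i2, jb = swap ? j1 : j2, kb = swap ? k1 : k2;
    double va = corner_val(ia, ja, ka), vb = corner_val(ib, jb, kb);
    double t = (level - va) / (vb - va);
    verts.push_back(ia + t * (ib - ia));
    verts.push_back(ja + t * (jb - ja));
    verts.push_back(ka + t * (kb - ka));
    int idx = (int)(verts.size() / 3) - 1;
    vmap[key] = idx;
    return idx;
  };
  double cv[8];
  int cpx[8], cpy[8], cpz[8];
  for (int i = 0; i < nx - 1; ++i) {
    for (int j = 0; j < ny - 1; ++j) {
      for (int k = 0; k < nz - 1; ++k) {
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          cpx[c] = i + CORNER_OFF[c][0];
          cpy[c] = j + CORNER_OFF[c][1];
          cpz[c] = k + CORNER_OFF[c][2];
          cv[c] = corner_val(cpx[c], cpy[c], cpz[c]) - level;
          if (cv[c] >= 0) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        // collect arcs (pairs of crossing edges, edges as corner pairs)
        int arcs[12][4]; int narc = 0; // each arc: c1a,c1b,c2a,c2b
        for (int f = 0; f < 6; ++f) {
          int a = FACES6[f][0], bq = FACES6[f][1], c = FACES6[f][2], d = FACES6[f][3];
          int fe[4][2] = { {a,bq},{c,d},{a,c},{bq,d} };
          int cross[4]; int ncr = 0;
          for (int e = 0; e < 4; ++e)
            if ((cv[fe[e][0]] >= 0) != (cv[fe[e][1]] >= 0)) cross[ncr++] = e;
          if (ncr == 2) {
            arcs[narc][0] = fe[cross[0]][0]; arcs[narc][1] = fe[cross[0]][1];
            arcs[narc][2] = fe[cross[1]][0]; arcs[narc][3] = fe[cross[1]][1];
            ++narc;
          } else if (ncr == 4) {
            double denom = cv[a] + cv[d] - cv[bq] - cv[c];
            double s = denom != 0 ? (cv[a]*cv[d] - cv[bq]*cv[c]) / denom : 0.0;
            bool pos_ad = cv[a] >= 0;
            bool conn = ((s >= 0) == pos_ad); // diag corners joined thru center
            if (conn) { // arcs cut off corners b and c
              arcs[narc][0]=a; arcs[narc][1]=bq; arcs[narc][2]=bq; arcs[narc][3]=d; ++narc;
              arcs[narc][0]=a; arcs[narc][1]=c;  arcs[narc][2]=c;  arcs[narc][3]=d; ++narc;
            } else {    // arcs cut off corners a and d
              arcs[narc][0]=a; arcs[narc][1]=bq; arcs[narc][2]=a; arcs[narc][3]=c; ++narc;
              arcs[narc][0]=bq; arcs[narc][1]=d; arcs[narc][2]=c; arcs[narc][3]=d; ++narc;
            }
          }
        }
        // build loops over crossing edges; edge id within cell: min*8+max
        int adj[64][2]; int adjn[64];
        for (int t = 0; t < 64; ++t) adjn[t] = 0;
        int present[64]; int npres = 0; int plist[12];
        for (int t = 0; t < 64; ++t) present[t] = 0;
        auto eid = [](int c1, int c2) {
          int lo = c1 < c2 ? c1 : c2, hi = c1 < c2 ? c2 : c1;
          return lo * 8 + hi;
        };
        for (int t = 0; t < narc; ++t) {
          int e1 = eid(arcs[t][0], arcs[t][1]);
          int e2 = eid(arcs[t][2], arcs[t][3]);
          adj[e1][adjn[e1]++] = e2;
          adj[e2][adjn[e2]++] = e1;
          if (!present[e1]) { present[e1] = 1; plist[npres++] = e1; }
          if (!present[e2]) { present[e2] = 1; plist[npres++] = e2; }
        }
        int visited[64];
        for (int t = 0; t < 64; ++t) visited[t] = 0;
        for (int s0 = 0; s0 < npres; ++s0) {
          int start = plist[s0];
          if (visited[start]) continue;
          int loop[12]; int nl = 0;
          int prev = -1, cur = start;
          while (true) {
            loop[nl++] = cur;
            visited[cur] = 1;
            int nxt = (adj[cur][0] != prev) ? adj[cur][0] : adj[cur][1];
            if (nxt == start) break;
            prev = cur; cur = nxt;
            if (nl >= 12) break; // safety
          }
          if (nl < 3) continue;
          // vertex ids for the loop
          int vids[12];
          for (int t = 0; t < nl; ++t) {
            int c1 = loop[t] / 8, c2 = loop[t] % 8;
            vids[t] = get_vertex(cpx[c1], cpy[c1], cpz[c1],
                                 cpx[c2], cpy[c2], cpz[c2]);
          }
          // fan triangulation with gradient-based orientation
          for (int t = 1; t < nl - 1; ++t) {
            int ia = vids[0], ib = vids[t], ic = vids[t+1];
            double ax = verts[3*ia], ay = verts[3*ia+1], az = verts[3*ia+2];
            double bx2 = verts[3*ib], by2 = verts[3*ib+1], bz2 = verts[3*ib+2];
            double cx2 = verts[3*ic], cy2 = verts[3*ic+1], cz2 = verts[3*ic+2];
            double mx = (ax+bx2+cx2)/3.0 - i;
            double my = (ay+by2+cy2)/3.0 - j;
            double mz = (az+bz2+cz2)/3.0 - k;
            // trilinear gradient at centroid (local coords in [0,1]^3)
            double gx=0, gy=0, gz=0;
            for (int c = 0; c < 8; ++c) {
              double wxc = CORNER_OFF[c][0] ? mx : 1 - mx;
              double wyc = CORNER_OFF[c][1] ? my : 1 - my;
              double wzc = CORNER_OFF[c][2] ? mz : 1 - mz;
              double sxc = CORNER_OFF[c][0] ? 1 : -1;
              double syc = CORNER_OFF[c][1] ? 1 : -1;
              double szc = CORNER_OFF[c][2] ? 1 : -1;
              gx += sxc * wyc * wzc * cv[c];
              gy += syc * wxc * wzc * cv[c];
              gz += szc * wxc * wyc * cv[c];
            }
            double nxv = (by2-ay)*(cz2-az) - (bz2-az)*(cy2-ay);
            double nyv = (bz2-az)*(cx2-ax) - (bx2-ax)*(cz2-az);
            double nzv = (bx2-ax)*(cy2-ay) - (by2-ay)*(cx2-ax);
            bool flip = (nxv*gx + nyv*gy + nzv*gz) > 0;
            tris.push_back(ia);
            tris.push_back(flip ? ic : ib);
            tris.push_back(flip ? ib : ic);
          }
        }
      }
    }
  }
  int nv = (int)(verts.size() / 3), nf = (int)(tris.size() / 3);
  NumericMatrix V(nv, 3);
  for (int t = 0; t < nv; ++t) {
    V(t,0) = verts[3*t]; V(t,1) = verts[3*t+1]; V(t,2) = verts[3*t+2];
  }
  IntegerMatrix F(nf, 3);
  for (int t = 0; t < nf; ++t) {
    F(t,0) = tris[3*t] + 1; F(t,1) = tris[3*t+1] + 1; F(t,2) = tris[3*t+2] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// [[Rcpp::export]]
IntegerVector cpp_label6(LogicalVector mask, IntegerVector dim) {
  // 6-connected component labelling (BFS), labels 1..ncomp, background 0
  int nz = dim[0], ny = dim[1], nx = dim[2];
  size_t n = (size_t)nz * ny * nx;
  IntegerVector lab(mask.size(), 0);
  std::vector<size_t> queue;
  int cur = 0;
  size_t sy = (size_t)nz, sx = (size_t)nz * ny;
  for (size_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    queue.clear();
    queue.push_back(s);
    lab[s] = cur;
    while (!queue.empty()) {
      size_t p = queue.back(); queue.pop_back();
      int k = (int)(p % nz);
      int j = (int)((p / sy) % ny);
      int i = (int)(p / sx);
      const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int q = 0; q < 6; ++q) {
        int ii = i + d[q][0], jj = j + d[q][1], kk = k + d[q][2];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        size_t pp = (size_t)kk + sy*jj + sx*ii;
        if (mask[pp] && lab[pp] == 0) {
          lab[pp] = cur;
          queue.push_back(pp);
        }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// [[Rcpp::export]]
List cpp_mse_linear_grad(NumericVector fixedv, IntegerVector fdim,
                         NumericVector forigin, NumericVector fspacing,
                         NumericVector movingv, IntegerVector mdim,
                         NumericVector morigin, NumericVector mspacing,
                         NumericMatrix L, NumericVector b) {
  // As cpp_mse_linear, but also accumulates the quantities needed for the
  // analytic metric gradient of any linear parameterization:
  //   gb = sum_i d_i * grad_m(q_i)          (3-vector)
  //   G  = sum_i d_i * grad_m(q_i) p_i^T    (3x3, p in fixed physical space)
  // where d_i = fixed(p_i) - moving(q_i). Parameter gradients follow by
  // chain rule on the R side (times -2/N).
  int fnz = fdim[0], fny = fdim[1], fnx = fdim[2];
  int mnz = mdim[0], mny = mdim[1], mnx = mdim[2];
  const double* fv = fixedv.begin();
  const double* mv = movingv.begin();
  double L00=L(0,0), L01=L(0,1), L02=L(0,2);
  double L10=L(1,0), L11=L(1,1), L12=L(1,2);
  double L20=L(2,0), L21=L(2,1), L22=L(2,2);
  double sum = 0.0; long long n = 0;
  double gb[3] = {0,0,0};
  double G[9] = {0,0,0,0,0,0,0,0,0}; // row-major G[a*3+b]
  bool inside;
  double mg[3];
  size_t idx = 0;
  for (int i = 0; i < fnx; ++i) {
    double px = forigin[0] + i * fspacing[0];
    for (int j = 0; j < fny; ++j) {
      double py = forigin[1] + j * fspacing[1];
      for (int k = 0; k < fnz; ++k, ++idx) {
        double pz = forigin[2] + k * fspacing[2];
        double qx = L00*px + L01*py + L02*pz + b[0];
        double qy = L10*px + L11*py + L12*pz + b[1];
        double qz = L20*px + L21*py + L22*pz + b[2];
        double vx = (qx - morigin[0]) / mspacing[0];
        double vy = (qy - morigin[1]) / mspacing[1];
        double vz = (qz - morigin[2]) / mspacing[2];
        double m = sample_central(mv, mnz, mny, mnx, vx, vy, vz, inside, mg);
        if (!inside) continue;
        double d = fv[idx] - m;
        sum += d * d;
        ++n;
        double gx = d * mg[0] / mspacing[0];
        double gy = d * mg[1] / mspacing[1];
        double gz = d * mg[2] / mspacing[2];
        gb[0] += gx; gb[1] += gy; gb[2] += gz;
        G[0] += gx*px; G[1] += gx*py; G[2] += gx*pz;
        G[3] += gy*px; G[4] += gy*py; G[5] += gy*pz;
        G[6] += gz*px; G[7] += gz*py; G[8] += gz*pz;
      }
    }
  }
  NumericVector gbv(3); for (int a=0;a<3;++a) gbv[a]=gb[a];
  NumericMatrix Gm(3,3);
  for (int a=0;a<3;++a) for (int c=0;c<3;++c) Gm(a,c)=G[a*3+c];
  return List::create(_["sum"] = sum, _["n"] = (double)n,
                      _["metric"] = n > 0 ? sum / n : NA_REAL,
                      _["gb"] = gbv, _["G"] = Gm);
}
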