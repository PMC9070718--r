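#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Volumes are column-major with dim = (nx, ny, nz), x fastest.

static const double BIG = 1e18;

// 1D squared distance transform on a sampled function (Felzenszwalb & Huttenlocher 2012)
static void dt1d(const double* f, double* d, int n, int* v, double* z) {
  int k = 0;
  v[0] = 0;
  z[0] = -BIG;
  z[1] = BIG;
  for (int q = 1; q < n; q++) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      k--;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = BIG;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    d[q] = (double)(q - v[k]) * (q - v[k]) + f[v[k]];
  }
}

// Exact squared Euclidean distance from every voxel to the nearest FALSE voxel.
// Voxels outside the grid are NOT considered background here (callers add the
// border term when the morphology requires it).
// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  NumericVector out(n);
  double* D = REAL(out);
  for (R_xlen_t i = 0; i < n; i++) D[i] = mask[i] ? BIG : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      double* line = D + (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx;
      for (int x = 0; x < nx; x++) f[x] = line[x];
      dt1d(f.data(), d.data(), nx, v.data(), z.data());
      for (int x = 0; x < nx; x++) line[x] = d[x];
    }
  // pass along y
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      double* base = D + (R_xlen_t)zz * nx * ny + xx;
      for (int y = 0; y < ny; y++) f[y] = base[(R_xlen_t)y * nx];
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int y = 0; y < ny; y++) base[(R_xlen_t)y * nx] = d[y];
    }
  // pass along z
  const R_xlen_t plane = (R_xlen_t)nx * ny;
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      double* base = D + (R_xlen_t)yy * nx + xx;
      for (int zc = 0; zc < nz; zc++) f[zc] = base[(R_xlen_t)zc * plane];
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int zc = 0; zc < nz; zc++) base[(R_xlen_t)zc * plane] = d[zc];
    }
  return out;
}

// Connected-component labeling (6/18/26 connectivity), labels assigned in
// scan order (x fastest) so the result is deterministic.
// [[Rcpp::export]]
IntegerVector cpp_label(LogicalVector mask, IntegerVector dim, int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dim");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");

  std::vector<int> offx, offy, offz;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if ((connectivity == 6 && m > 1) || (connectivity == 18 && m > 2)) continue;
        offx.push_back(dx); offy.push_back(dy); offz.push_back(dz);
      }
  const int noff = (int)offx.size();

  IntegerVector lab(n, 0);
  int* L = INTEGER(lab);
  int next = 0;
  std::queue<R_xlen_t> q;
  const R_xlen_t plane = (R_xlen_t)nx * ny;

  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || L[i] != 0) continue;
    next++;
    L[i] = next;
    q.push(i);
    while (!q.empty()) {
      R_xlen_t cur = q.front(); q.pop();
      int cz = (int)(cur / plane);
      int rem = (int)(cur % plane);
      int cy = rem / nx;
      int cx = rem % nx;
      for (int k = 0; k < noff; k++) {
        int xx = cx + offx[k], yy = cy + offy[k], zz = cz + offz[k];
        if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
        R_xlen_t j = (R_xlen_t)zz * plane + (R_xlen_t)yy * nx + xx;
        if (mask[j] && L[j] == 0) { L[j] = next; q.push(j); }
      }
    }
  }
  return lab;
}

// Separable convolution with a symmetric odd-length kernel, reflected boundary.
// [[Rcpp::export]]
NumericVector cpp_conv_sep(NumericVector vol, IntegerVector dim, NumericVector kernel) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dim");
  const int klen = kernel.size();
  if (klen % 2 == 0) stop("kernel length must be odd");
  const int kr = klen / 2;
  const double* K = REAL(kernel);

  NumericVector a = clone(vol);
  NumericVector b(n);
  double* A = REAL(a);
  double* B = REAL(b);
  const R_xlen_t plane = (R_xlen_t)nx * ny;

  // reflect index into [0, n)
  auto refl = [](int i, int nn) {
    while (i < 0 || i >= nn) {
      if (i < 0) i = -i - 1;
      if (i >= nn) i = 2 * nn - 1 - i;
    }
    return i;
  };

  // along x: A -> B
  for (int zz = 0; zz < nz; zz++)
    for (int yy = 0; yy < ny; yy++) {
      const double* src = A + (R_xlen_t)zz * plane + (R_xlen_t)yy * nx;
      double* dst = B + (R_xlen_t)zz * plane + (R_xlen_t)yy * nx;
      for (int x = 0; x < nx; x++) {
        double s = 0.0;
        for (int k = -kr; k <= kr; k++) s += K[k + kr] * src[refl(x + k, nx)];
        dst[x] = s;
      }
    }
  // along y: B -> A
  for (int zz = 0; zz < nz; zz++)
    for (int xx = 0; xx < nx; xx++) {
      const double* src = B + (R_xlen_t)zz * plane + xx;
      double* dst = A + (R_xlen_t)zz * plane + xx;
      for (int y = 0; y < ny; y++) {
        double s = 0.0;
        for (int k = -kr; k <= kr; k++)
          s += K[k + kr] * src[(R_xlen_t)refl(y + k, ny) * nx];
        dst[(R_xlen_t)y * nx] = s;
      }
    }
  // along z: A -> B
  for (int yy = 0; yy < ny; yy++)
    for (int xx = 0; xx < nx; xx++) {
      const double* src = A + (R_xlen_t)yy * nx + xx;
      double* dst = B + (R_xlen_t)yy * nx + xx;
      for (int zc = 0; zc < nz; zc++) {
        double s = 0.0;
        for (int k = -kr; k <= kr; k++)
          s += K[k + kr] * src[(R_xlen_t)refl(zc + k, nz) * plane];
        dst[(R_xlen_t)zc * plane] = s;
      }
    }
  return b;
}

// Triangulated isosurface area by marching tetrahedra (6-tet cube split).
// Vertices interpolated on tetrahedron edges at `level`; returns total
// triangle area in voxel^2. Cells are interior only, so surface lying outside
// the grid (objects cut by the volume boundary) contributes nothing.
// [[Rcpp::export]]
double cpp_mt_area(NumericVector vol, IntegerVector dim, double level) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (vol.size() != n) stop("volume length does not match dim");
  const double* V = REAL(vol);
  const R_xlen_t plane = (R_xlen_t)nx * ny;

  // cube corner offsets, bit0 = x, bit1 = y, bit2 = z
  static const int CX[8] = {0, 1, 0, 1, 0, 1, 0, 1};
  static const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
  static const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
  static const int TETS[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}};

  double area = 0.0;
  double px[8], py[8], pz[8], val[8];

  auto triArea = [](double ax, double ay, double az,
                    double bx, double by, double bz,
                    double cx, double cy, double cz) {
    double ux = bx - ax, uy = by - ay, uz = bz - az;
    double vx = cx - ax, vy = cy - ay, vz = cz - az;
    double wx = uy * vz - uz * vy;
    double wy = uz * vx - ux * vz;
    double wz = ux * vy - uy * vx;
    return 0.5 * std::sqrt(wx * wx + wy * wy + wz * wz);
  };

  for (int zz = 0; zz + 1 < nz; zz++)
    for (int yy = 0; yy + 1 < ny; yy++)
      for (int xx = 0; xx + 1 < nx; xx++) {
        double mn = BIG, mx = -BIG;
        for (int c = 0; c < 8; c++) {
          val[c] = V[(R_xlen_t)(zz + CZ[c]) * plane + (R_xlen_t)(yy + CY[c]) * nx +
                     (xx + CX[c])];
          if (val[c] < mn) mn = val[c];
          if (val[c] > mx) mx = val[c];
          px[c] = xx + CX[c]; py[c] = yy + CY[c]; pz[c] = zz + CZ[c];
        }
        if (mn >= level || mx < level) continue;
        for (int t = 0; t < 6; t++) {
          const int* tet = TETS[t];
          int in[4], nin = 0;
          for (int i = 0; i < 4; i++)
            if (val[tet[i]] >= level) in[nin++] = i;
          if (nin == 0 || nin == 4) continue;
          bool flip = false;
          int sel[4], nsel = nin;
          if (nin == 3) {  // use the single outside vertex instead
            nsel = 1; flip = true;
            int j = 0;
            for (int i = 0; i < 4; i++)
              if (val[tet[i]] < level) sel[j++] = i;
          } else {
            for (int i = 0; i < nin; i++) sel[i] = in[i];
          }
          (void)flip;
          // interpolate crossing point on edge (i -> j) of the tetrahedron
          auto ip = [&](int i, int j, double& ox, double& oy, double& oz) {
            int gi = tet[i], gj = tet[j];
            double tt = (level - val[gi]) / (val[gj] - val[gi]);
            ox = px[gi] + tt * (px[gj] - px[gi]);
            oy = py[gi] + tt * (py[gj] - py[gi]);
            oz = pz[gi] + tt * (pz[gj] - pz[gi]);
          };
          if (nsel == 1) {
            int i0 = sel[0];
            double qx[3], qy[3], qz[3];
            int j = 0;
            for (int i = 0; i < 4; i++) {
              if (i == i0) continue;
              ip(i0, i, qx[j], qy[j], qz[j]);
              j++;
            }
            area += triArea(qx[0], qy[0], qz[0], qx[1], qy[1], qz[1],
                            qx[2], qy[2], qz[2]);
          } else {  // nsel == 2: quad split into two triangles
            int i0 = sel[0], i1 = sel[1];
            int oth[2], j = 0;
            for (int i = 0; i < 4; i++)
              if (i != i0 && i != i1) oth[j++] = i;
            double qx[4], qy[4], qz[4];
            ip(i0, oth[0], qx[0], qy[0], qz[0]);
            ip(i0, oth[1], qx[1], qy[1], qz[1]);
            ip(i1, oth[0], qx[2], qy[2], qz[2]);
            ip(i1, oth[1], qx[3], qy[3], qz[3]);
            area += triArea(qx[0], qy[0], qz[0], qx[1], qy[1], qz[1],
                            qx[3], qy[3], qz[3]);
            area += triArea(qx[0], qy[0], qz[0], qx[3], qy[3], qz[3],
                            qx[2], qy[2], qz[2]);
          }
        }
      }
  return area;
}
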