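#include <Rcpp.h>
#include <queue>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// ---- 1D squared Euclidean distance transform (Felzenszwalb & Huttenlocher).
// f: squared distances along one scan line (INF where no site yet).
static void edt1d(std::vector<double> &f, std::vector<double> &d,
                  std::vector<int> &v, std::vector<double> &z) {
  const int n = (int)f.size();
  const double INF = 1e30;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact squared EDT of a 3D logical array (distance of TRUE voxels to the
// nearest FALSE voxel centre, in voxel units). Pass dim = c(nx, ny, nz);
// nz = 1 gives the 2D transform.
// [[Rcpp::export(name = ".edt_sq")]]
NumericVector edt_sq(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double INF = 1e30;
  NumericVector out(mask.size());
  // init: 0 at background, INF at foreground (distance to background)
  for (R_xlen_t i = 0; i < mask.size(); ++i)
    out[i] = mask[i] ? INF : 0.0;
  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      const R_xlen_t off = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      f.assign(out.begin() + off, out.begin() + off + nx);
      edt1d(f, d, v, z);
      std::copy(d.begin(), d.begin() + nx, out.begin() + off);
    }
  // pass along y
  f.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      const R_xlen_t off = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[off + (R_xlen_t)j * nx];
      edt1d(f, d, v, z);
      for (int j = 0; j < ny; ++j) out[off + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  if (nz > 1) {
    f.resize(nz);
    const R_xlen_t nxy = (R_xlen_t)nx * ny;
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t off = (R_xlen_t)j * nx + i;
        for (int k = 0; k < nz; ++k) f[k] = out[off + (R_xlen_t)k * nxy];
        edt1d(f, d, v, z);
        for (int k = 0; k < nz; ++k) out[off + (R_xlen_t)k * nxy] = d[k];
      }
  }
  return out;
}

// Local thickness by the maximal-inscribed-sphere construction
// (Hildebrand & Ruegsegger): every foreground voxel is assigned the
// diameter of the largest sphere that contains it and fits inside the
// structure. Accelerated by painting only from distance-ridge voxels
// (spheres not contained in a neighbour's sphere), largest first.
// dt_sq: squared EDT of the mask (voxel units). Returns thickness in
// voxel units (diameter).
// [[Rcpp::export(name = ".local_thickness")]]
NumericVector local_thickness(LogicalVector mask, NumericVector dt_sq,
                              IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  NumericVector thick(mask.size());

  // collect ridge voxels: sphere at p not contained in a neighbour's sphere
  std::vector<R_xlen_t> ridge;
  std::vector<double> rad(mask.size(), 0.0);
  for (R_xlen_t idx = 0; idx < mask.size(); ++idx)
    if (mask[idx]) rad[idx] = std::sqrt(dt_sq[idx]);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        const R_xlen_t idx = (R_xlen_t)k * nxy + (R_xlen_t)j * nx + i;
        if (!mask[idx]) continue;
        const double rp = rad[idx];
        bool contained = false;
        for (int dk = -1; dk <= 1 && !contained; ++dk)
          for (int dj = -1; dj <= 1 && !contained; ++dj)
            for (int di = -1; di <= 1 && !contained; ++di) {
              if (!di && !dj && !dk) continue;
              const int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              const R_xlen_t nb = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii;
              if (!mask[nb]) continue;
              const double dd = std::sqrt((double)(di * di + dj * dj + dk * dk));
              if (rad[nb] >= rp + dd - 1e-9) contained = true;
            }
        if (!contained) ridge.push_back(idx);
      }
  std::sort(ridge.begin(), ridge.end(),
            [&](R_xlen_t a, R_xlen_t b) { return rad[a] > rad[b]; });

  for (R_xlen_t ri = 0; ri < (R_xlen_t)ridge.size(); ++ri) {
    const R_xlen_t idx = ridge[ri];
    const double r = rad[idx];
    const double diam = 2.0 * r;
    const int i0 = (int)(idx % nx);
    const int j0 = (int)((idx / nx) % ny);
    const int k0 = (int)(idx / nxy);
    const int ir = (int)std::floor(r);
    const double r2 = r * r + 1e-9;
    for (int dk = -ir; dk <= ir; ++dk) {
      const int kk = k0 + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -ir; dj <= ir; ++dj) {
        const int jj = j0 + dj;
        if (jj < 0 || jj >= ny) continue;
        const double d2 = (double)dk * dk + (double)dj * dj;
        if (d2 > r2) continue;
        const int imax = (int)std::floor(std::sqrt(r2 - d2));
        for (int di = -imax; di <= imax; ++di) {
          const int ii = i0 + di;
          if (ii < 0 || ii >= nx) continue;
          const R_xlen_t nb = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii;
          if (mask[nb] && thick[nb] < diam) thick[nb] = diam;
        }
      }
    }
  }
  return thick;
}

// 6-connected (3D) / 4-connected (2D, nz == 1) labelling by BFS.
// Returns integer labels, 0 for background, 1..n for components
// (labelled in raster order of their first voxel).
// [[Rcpp::export(name = ".label_components")]]
IntegerVector label_components(LogicalVector mask, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  IntegerVector lab(mask.size(), 0);
  int cur = 0;
  std::queue<R_xlen_t> q;
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s]) continue;
    lab[s] = ++cur;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t idx = q.front();
      q.pop();
      const int i = (int)(idx % nx);
      const int j = (int)((idx / nx) % ny);
      const int k = (int)(idx / nxy);
      for (int m = 0; m < 6; ++m) {
        const int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;
        const R_xlen_t nb = (R_xlen_t)kk * nxy + (R_xlen_t)jj * nx + ii;
        if (mask[nb] && !lab[nb]) {
          lab[nb] = cur;
          q.push(nb);
        }
      }
    }
  }
  return lab;
}
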