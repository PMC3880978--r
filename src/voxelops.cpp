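#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Trilinear interpolation of a 3D volume at continuous 0-based voxel
// indices. `vol` is the column-major flattened array with dimensions
// `dim`; `idx` holds one point per row. Points whose continuous index
// falls outside [0, dim - 1] on any axis receive `fill`.
// [[Rcpp::export]]
NumericVector c_trilinear(NumericVector vol, IntegerVector dim,
                          NumericMatrix idx, double fill) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double *v = vol.begin();
  const double *px = &idx(0, 0), *py = &idx(0, 1), *pz = &idx(0, 2);
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;

  for (R_xlen_t p = 0; p < n; ++p) {
    const double x = px[p], y = py[p], z = pz[p];
    if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
          x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0)) {
      out[p] = fill;  // also catches NaN
      continue;
    }
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
        k0 = (int)std::floor(z);
    const double fx = x - i0, fy = y - j0, fz = z - k0;
    const int i1 = (i0 + 1 < nx) ? i0 + 1 : nx - 1;
    const int j1 = (j0 + 1 < ny) ? j0 + 1 : ny - 1;
    const int k1 = (k0 + 1 < nz) ? k0 + 1 : nz - 1;

    const size_t b00 = sy * j0 + sz * k0, b10 = sy * j1 + sz * k0;
    const size_t b01 = sy * j0 + sz * k1, b11 = sy * j1 + sz * k1;
    const double c000 = v[i0 + b00], c100 = v[i1 + b00];
    const double c010 = v[i0 + b10], c110 = v[i1 + b10];
    const double c001 = v[i0 + b01], c101 = v[i1 + b01];
    const double c011 = v[i0 + b11], c111 = v[i1 + b11];

    const double e00 = c000 + fx * (c100 - c000);
    const double e10 = c010 + fx * (c110 - c010);
    const double e01 = c001 + fx * (c101 - c001);
    const double e11 = c011 + fx * (c111 - c011);
    const double f0 = e00 + fy * (e10 - e00);
    const double f1 = e01 + fy * (e11 - e01);
    out[p] = f0 + fz * (f1 - f0);
  }
  return out;
}

// Mutual information (bits) between pre-binned fixed-image samples and
// the moving image sampled at mapped points, in one pass. `map` is the
// 3x4 affine taking a world sample point to a continuous 0-based moving
// voxel index; `abin` holds 1-based fixed-image bin labels per sample.
// Samples mapping outside the moving volume read the out-of-field value
// `fill` instead of being dropped: a constant sample population avoids
// the overlap-shrinkage artifact of mutual information.
// [[Rcpp::export]]
double c_mi_objective(NumericVector mvals, IntegerVector mdim,
                      NumericMatrix pts, NumericMatrix map,
                      IntegerVector abin, int n_bins,
                      double bmin, double bmax, double fill) {
  const int nx = mdim[0], ny = mdim[1], nz = mdim[2];
  const double *v = mvals.begin();
  const size_t sy = (size_t)nx, sz = (size_t)nx * ny;
  const R_xlen_t n = pts.nrow();
  const double *px = &pts(0, 0), *py = &pts(0, 1), *pz = &pts(0, 2);
  const double m00 = map(0, 0), m01 = map(0, 1), m02 = map(0, 2),
               m03 = map(0, 3);
  const double m10 = map(1, 0), m11 = map(1, 1), m12 = map(1, 2),
               m13 = map(1, 3);
  const double m20 = map(2, 0), m21 = map(2, 1), m22 = map(2, 2),
               m23 = map(2, 3);
  const double bw = (bmax > bmin) ? n_bins / (bmax - bmin) : 0.0;

  std::vector<double> joint((size_t)n_bins * n_bins, 0.0);
  double total = 0.0;
  for (R_xlen_t p = 0; p < n; ++p) {
    const double wx = px[p], wy = py[p], wz = pz[p];
    const double x = m00 * wx + m01 * wy + m02 * wz + m03;
    const double y = m10 * wx + m11 * wy + m12 * wz + m13;
    const double z = m20 * wx + m21 * wy + m22 * wz + m23;
    double bv;
    if (!(x >= 0.0 && y >= 0.0 && z >= 0.0 &&
          x <= nx - 1.0 && y <= ny - 1.0 && z <= nz - 1.0)) {
      bv = fill;
    } else {
      int i0 = (int)std::floor(x), j0 = (int)std::floor(y),
          k0 = (int)std::floor(z);
      const double fx = x - i0, fy = y - j0, fz = z - k0;
      const int i1 = (i0 + 1 < nx) ? i0 + 1 : nx - 1;
      const int j1 = (j0 + 1 < ny) ? j0 + 1 : ny - 1;
      const int k1 = (k0 + 1 < nz) ? k0 + 1 : nz - 1;
      const size_t b00 = sy * j0 + sz * k0, b10 = sy * j1 + sz * k0;
      const size_t b01 = sy * j0 + sz * k1, b11 = sy * j1 + sz * k1;
      const double e00 = v[i0 + b00] + fx * (v[i1 + b00] - v[i0 + b00]);
      const double e10 = v[i0 + b10] + fx * (v[i1 + b10] - v[i0 + b10]);
      const double e01 = v[i0 + b01] + fx * (v[i1 + b01] - v[i0 + b01]);
      const double e11 = v[i0 + b11] + fx * (v[i1 + b11] - v[i0 + b11]);
      const double f0 = e00 + fy * (e10 - e00);
      const double f1 = e01 + fy * (e11 - e01);
      bv = f0 + fz * (f1 - f0);
    }
    int bb = (bw > 0.0) ? (int)std::floor((bv - bmin) * bw) : 0;
    if (bb < 0) bb = 0;
    if (bb >= n_bins) bb = n_bins - 1;
    joint[(size_t)bb * n_bins + (abin[p] - 1)] += 1.0;
    total += 1.0;
  }
  if (total <= 0.0) return R_NegInf;

  std::vector<double> pa(n_bins, 0.0), pb(n_bins, 0.0);
  for (int b = 0; b < n_bins; ++b)
    for (int a = 0; a < n_bins; ++a) {
      const double c = joint[(size_t)b * n_bins + a];
      pa[a] += c;
      pb[b] += c;
    }
  double mi = 0.0;
  const double log2e = 1.4426950408889634;
  for (int b = 0; b < n_bins; ++b)
    for (int a = 0; a < n_bins; ++a) {
      const double c = joint[(size_t)b * n_bins + a];
      if (c > 0.0)
        mi += (c / total) *
              std::log(c * total / (pa[a] * pb[b])) * log2e;
    }
  return mi > 0.0 ? mi : 0.0;
}

// 26-connected component of `mask` containing the (1-based) seed voxel,
// via breadth-first search. Returns a logical array of the same shape.
// [[Rcpp::export]]
LogicalVector c_component26(LogicalVector mask, IntegerVector dim,
                            IntegerVector seed) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t ntot = (size_t)nx * ny * nz;
  LogicalVector out(ntot);
  const int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  const size_t s0 = si + (size_t)nx * (sj + (size_t)ny * sk);
  if (!mask[s0]) return out;

  std::vector<size_t> stack;
  stack.push_back(s0);
  out[s0] = TRUE;
  while (!stack.empty()) {
    const size_t cur = stack.back();
    stack.pop_back();
    const int k = cur / ((size_t)nx * ny);
    const size_t rem = cur - (size_t)k * nx * ny;
    const int j = rem / nx;
    const int i = rem - (size_t)j * nx;
    for (int dk = -1; dk <= 1; ++dk) {
      const int kk = k + dk;
      if (kk < 0 || kk >= nz) continue;
      for (int dj = -1; dj <= 1; ++dj) {
        const int jj = j + dj;
        if (jj < 0 || jj >= ny) continue;
        for (int di = -1; di <= 1; ++di) {
          const int ii = i + di;
          if (ii < 0 || ii >= nx || (di == 0 && dj == 0 && dk == 0))
            continue;
          const size_t q = ii + (size_t)nx * (jj + (size_t)ny * kk);
          if (mask[q] && !out[q]) {
            out[q] = TRUE;
            stack.push_back(q);
          }
        }
      }
    }
  }
  out.attr("dim") = dim;
  return out;
}

// Morphological dilation of a binary mask by `steps` iterations of the
// 26-neighbourhood structuring element (i.e. Chebyshev ball of radius
// `steps`), clipped at the array boundary.
// [[Rcpp::export]]
LogicalVector c_dilate26(LogicalVector mask, IntegerVector dim, int steps) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t ntot = (size_t)nx * ny * nz;
  std::vector<char> cur(ntot), nxt(ntot);
  for (size_t q = 0; q < ntot; ++q) cur[q] = mask[q] ? 1 : 0;

  for (int s = 0; s < steps; ++s) {
    for (int k = 0; k < nz; ++k) {
      const int klo = k > 0 ? k - 1 : 0, khi = k < nz - 1 ? k + 1 : nz - 1;
      for (int j = 0; j < ny; ++j) {
        const int jlo = j > 0 ? j - 1 : 0, jhi = j < ny - 1 ? j + 1 : ny - 1;
        for (int i = 0; i < nx; ++i) {
          const int ilo = i > 0 ? i - 1 : 0,
                    ihi = i < nx - 1 ? i + 1 : nx - 1;
          char hit = 0;
          for (int kk = klo; kk <= khi && !hit; ++kk)
            for (int jj = jlo; jj <= jhi && !hit; ++jj)
              for (int ii = ilo; ii <= ihi; ++ii)
                if (cur[ii + (size_t)nx * (jj + (size_t)ny * kk)]) {
                  hit = 1;
                  break;
                }
          nxt[i + (size_t)nx * (j + (size_t)ny * k)] = hit;
        }
      }
    }
    cur.swap(nxt);
  }
  LogicalVector out(ntot);
  for (size_t q = 0; q < ntot; ++q) out[q] = cur[q] != 0;
  out.attr("dim") = dim;
  return out;
}
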