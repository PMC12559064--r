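#include <Rcpp.h>
#include <vector>
#include <algorithm>

// Separable squared Euclidean distance transform (Felzenszwalb & Huttenlocher,
// Theory of Computing 2012), generalized to anisotropic sample spacing: the
// 1-D transform of f sampled at physical positions x_i = i*w is
//   d(x_q) = min_i ( (x_q - x_i)^2 + f(x_i) ).
// Applying it along each axis in turn gives the exact squared Euclidean
// distance in mm^2 to the nearest seed voxel center in 3D. Non-seed cells
// start at a large finite sentinel; physical squared distances in a chest
// volume are < 1e7 mm^2, so sentinel-dominated cells remain identifiable.

static const double EDT_BIG = 1e30;

// One 1-D lower-envelope pass over n samples with spacing w; data is read and
// written with stride `stride`. v, z, fbuf are scratch (z needs n+1 slots).
static void edt_pass_1d(double* data, int n, int stride, double w,
                        std::vector<int>& v, std::vector<double>& z,
                        std::vector<double>& fbuf) {
  for (int q = 0; q < n; ++q) fbuf[q] = data[(size_t)q * stride];
  int k = 0;
  v[0] = 0;
  z[0] = -EDT_BIG;
  z[1] = EDT_BIG;
  for (int q = 1; q < n; ++q) {
    double xq = q * w;
    double s;
    for (;;) {
      double xv = v[k] * w;
      s = ((fbuf[q] + xq * xq) - (fbuf[v[k]] + xv * xv)) / (2.0 * (xq - xv));
      if (s <= z[k] && k > 0) { --k; continue; }
      break;
    }
    if (s <= z[k]) {  // k == 0 and q's parabola dominates everywhere
      v[0] = q;
    } else {
      ++k;
      v[k] = q;
      z[k] = s;
    }
    z[k + 1] = EDT_BIG;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * w;
    while (z[k + 1] < xq) ++k;
    double dx = xq - v[k] * w;
    data[(size_t)q * stride] = dx * dx + fbuf[v[k]];
  }
}

// [[Rcpp::export]]
Rcpp::NumericVector edt_squared_cpp(Rcpp::LogicalVector mask,
                                    Rcpp::IntegerVector dim,
                                    Rcpp::NumericVector spacing) {
  if (dim.size() != 3 || spacing.size() != 3)
    Rcpp::stop("edt_squared_cpp expects a 3-D mask with 3 spacing values");
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const size_t n = (size_t)nx * ny * nz;
  if ((size_t)mask.size() != n) Rcpp::stop("mask length does not match dim");

  Rcpp::NumericVector out((R_xlen_t)n);
  double* d = REAL(out);
  for (size_t i = 0; i < n; ++i)
    d[i] = (mask[i] == TRUE) ? 0.0 : EDT_BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<int> v(nmax);
  std::vector<double> z(nmax + 1), fbuf(nmax);

  for (int k = 0; k < nz; ++k)                       // along x (fastest axis)
    for (int j = 0; j < ny; ++j)
      edt_pass_1d(d + (size_t)k * nx * ny + (size_t)j * nx, nx, 1, spacing[0],
                  v, z, fbuf);
  for (int k = 0; k < nz; ++k)                       // along y
    for (int i = 0; i < nx; ++i)
      edt_pass_1d(d + (size_t)k * nx * ny + i, ny, nx, spacing[1], v, z, fbuf);
  for (int j = 0; j < ny; ++j)                       // along z
    for (int i = 0; i < nx; ++i)
      edt_pass_1d(d + (size_t)j * nx + i, nz, nx * ny, spacing[2], v, z, fbuf);

  for (size_t i = 0; i < n; ++i)
    if (d[i] >= EDT_BIG / 2.0) d[i] = R_PosInf;
  return out;
}
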