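#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// multilinear interpolation at 0-based fractional coordinates, clamped to
// the array bounds (border replication); arrays are column-major R arrays
static double interp3(const double *a, int n1, int n2, int n3,
                      double c1, double c2, double c3) {
  c1 = clampd(c1, 0.0, n1 - 1.0);
  c2 = clampd(c2, 0.0, n2 - 1.0);
  c3 = clampd(c3, 0.0, n3 - 1.0);
  int i0 = (int)std::floor(c1), j0 = (int)std::floor(c2), k0 = (int)std::floor(c3);
  int i1 = i0 + 1 < n1 ? i0 + 1 : i0;
  int j1 = j0 + 1 < n2 ? j0 + 1 : j0;
  int k1 = k0 + 1 < n3 ? k0 + 1 : k0;
  double f1 = c1 - i0, f2 = c2 - j0, f3 = c3 - k0;
  double g1 = 1.0 - f1, g2 = 1.0 - f2, g3 = 1.0 - f3;
  const long s2 = n1, s3 = (long)n1 * n2;
  double v000 = a[i0 + s2 * j0 + s3 * k0], v100 = a[i1 + s2 * j0 + s3 * k0];
  double v010 = a[i0 + s2 * j1 + s3 * k0], v110 = a[i1 + s2 * j1 + s3 * k0];
  double v001 = a[i0 + s2 * j0 + s3 * k1], v101 = a[i1 + s2 * j0 + s3 * k1];
  double v011 = a[i0 + s2 * j1 + s3 * k1], v111 = a[i1 + s2 * j1 + s3 * k1];
  return g3 * (g2 * (g1 * v000 + f1 * v100) + f2 * (g1 * v010 + f1 * v110)) +
         f3 * (g2 * (g1 * v001 + f1 * v101) + f2 * (g1 * v011 + f1 * v111));
}

// Resample a (possibly degenerate) 3D array to new dimensions. Output sample
// i maps to input coordinate (i + 0.5) * n_in / n_out - 0.5 (pixel-center
// alignment), so equal sizes reproduce the input exactly. nearest = TRUE
// rounds to the closest input sample (for label masks).
// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector src, IntegerVector odim, bool nearest) {
  IntegerVector sdim = src.attr("dim");
  if (sdim.size() != 3 || odim.size() != 3)
    stop("cpp_resample expects 3D dims (pad 2D inputs with a singleton axis)");
  int s1 = sdim[0], s2 = sdim[1], s3 = sdim[2];
  int o1 = odim[0], o2 = odim[1], o3 = odim[2];
  const double *a = REAL(src);
  NumericVector out((R_xlen_t)o1 * o2 * o3);
  double *o = REAL(out);
  double r1 = (double)s1 / o1, r2 = (double)s2 / o2, r3 = (double)s3 / o3;
  R_xlen_t idx = 0;
  for (int k = 0; k < o3; ++k) {
    double c3 = (k + 0.5) * r3 - 0.5;
    for (int j = 0; j < o2; ++j) {
      double c2 = (j + 0.5) * r2 - 0.5;
      for (int i = 0; i < o1; ++i, ++idx) {
        double c1 = (i + 0.5) * r1 - 0.5;
        if (nearest) {
          int ii = (int)clampd(std::floor(c1 + 0.5), 0.0, s1 - 1.0);
          int jj = (int)clampd(std::floor(c2 + 0.5), 0.0, s2 - 1.0);
          int kk = (int)clampd(std::floor(c3 + 0.5), 0.0, s3 - 1.0);
          o[idx] = a[ii + (long)s1 * jj + (long)s1 * s2 * kk];
        } else {
          o[idx] = interp3(a, s1, s2, s3, c1, c2, c3);
        }
      }
    }
  }
  out.attr("dim") = odim;
  return out;
}

// mask-aware multilinear interpolation: corners outside the mask are
// excluded and the weights renormalized, so boundary samples never dilute
// towards the (zeroed) background and constant objects stay exactly constant
static double interp3_masked(const double *a, const int *mk,
                             int n1, int n2, int n3,
                             double c1, double c2, double c3) {
  c1 = clampd(c1, 0.0, n1 - 1.0);
  c2 = clampd(c2, 0.0, n2 - 1.0);
  c3 = clampd(c3, 0.0, n3 - 1.0);
  int i0 = (int)std::floor(c1), j0 = (int)std::floor(c2), k0 = (int)std::floor(c3);
  int i1 = i0 + 1 < n1 ? i0 + 1 : i0;
  int j1 = j0 + 1 < n2 ? j0 + 1 : j0;
  int k1 = k0 + 1 < n3 ? k0 + 1 : k0;
  double f1 = c1 - i0, f2 = c2 - j0, f3 = c3 - k0;
  const long s2 = n1, s3 = (long)n1 * n2;
  double num = 0.0, den = 0.0;
  int ii[2] = {i0, i1}, jj[2] = {j0, j1}, kk[2] = {k0, k1};
  double wi[2] = {1.0 - f1, f1}, wj[2] = {1.0 - f2, f2}, wk[2] = {1.0 - f3, f3};
  for (int ck = 0; ck < 2; ++ck)
    for (int cj = 0; cj < 2; ++cj)
      for (int ci = 0; ci < 2; ++ci) {
        long idx = ii[ci] + s2 * jj[cj] + s3 * kk[ck];
        if (mk[idx] != 0) {
          double w = wi[ci] * wj[cj] * wk[ck];
          num += w * a[idx];
          den += w;
        }
      }
  return den > 0.0 ? num / den : 0.0;
}

// Mean intensity along rays cast from `center` in directions `dirs` (one row
// per ray, 3 columns). Samples are taken every `step` voxels starting at the
// center (t = 0); a ray ends at the first sample whose nearest voxel is
// outside the array or outside the mask. Intensity is interpolated with the
// mask-aware multilinear rule above; the ray-termination mask test is a
// nearest-neighbor lookup. The center sample always contributes, so no ray
// is empty when the center lies in the mask.
// [[Rcpp::export]]
NumericVector cpp_raycast(NumericVector vals, IntegerVector mask,
                          NumericMatrix dirs, NumericVector center,
                          double step) {
  IntegerVector dim = vals.attr("dim");
  if (dim.size() != 3) stop("cpp_raycast expects a 3D array");
  int n1 = dim[0], n2 = dim[1], n3 = dim[2];
  const double *a = REAL(vals);
  const int *mk = INTEGER(mask);
  int nray = dirs.nrow();
  // generous bound on samples per ray: the cube diagonal
  int maxn = (int)(std::sqrt((double)n1 * n1 + (double)n2 * n2 + (double)n3 * n3) / step) + 2;
  NumericVector out(nray);
  for (int r = 0; r < nray; ++r) {
    double d1 = dirs(r, 0), d2 = dirs(r, 1), d3 = dirs(r, 2);
    double acc = 0.0;
    int cnt = 0;
    for (int s = 0; s < maxn; ++s) {
      double t = step * s;
      double c1 = center[0] + t * d1;
      double c2 = center[1] + t * d2;
      double c3 = center[2] + t * d3;
      int i = (int)std::floor(c1 + 0.5);
      int j = (int)std::floor(c2 + 0.5);
      int k = (int)std::floor(c3 + 0.5);
      if (i < 0 || i >= n1 || j < 0 || j >= n2 || k < 0 || k >= n3) break;
      if (mk[i + (long)n1 * j + (long)n1 * n2 * k] == 0) break;
      acc += interp3_masked(a, mk, n1, n2, n3, c1, c2, c3);
      ++cnt;
    }
    out[r] = cnt > 0 ? acc / cnt : NA_REAL;
  }
  return out;
}
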