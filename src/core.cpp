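#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Volumes are R arrays dim (nx, ny, nz), x fastest; public coordinates are
// 0-based voxel indices with voxel centers at integers.

static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + (R_xlen_t)ny * k);
}

// Trilinear sample at continuous 0-based (x,y,z); valid only when the whole
// 8-corner cell lies inside the grid. Sets ok = false otherwise.
static double trilinear(const double* d, int nx, int ny, int nz,
                        double x, double y, double z, bool& ok) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) {
    ok = false;
    return 0.0;
  }
  ok = true;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) i0--;
  if (j0 == ny - 1) j0--;
  if (k0 == nz - 1) k0--;
  if (i0 < 0) i0 = 0;
  if (j0 < 0) j0 = 0;
  if (k0 < 0) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  double c000 = d[idx3(i0, j0, k0, nx, ny)],     c100 = d[idx3(i0 + 1, j0, k0, nx, ny)];
  double c010 = d[idx3(i0, j0 + 1, k0, nx, ny)], c110 = d[idx3(i0 + 1, j0 + 1, k0, nx, ny)];
  double c001 = d[idx3(i0, j0, k0 + 1, nx, ny)], c101 = d[idx3(i0 + 1, j0, k0 + 1, nx, ny)];
  double c011 = d[idx3(i0, j0 + 1, k0 + 1, nx, ny)], c111 = d[idx3(i0 + 1, j0 + 1, k0 + 1, nx, ny)];
  double c00 = c000 * (1 - fx) + c100 * fx;
  double c10 = c010 * (1 - fx) + c110 * fx;
  double c01 = c001 * (1 - fx) + c101 * fx;
  double c11 = c011 * (1 - fx) + c111 * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// [[Rcpp::export]]
NumericVector cpp_trilinear(NumericVector vol, NumericMatrix pts) {
  IntegerVector dm = vol.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  const double* d = vol.begin();
  int n = pts.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; r++) {
    bool ok;
    double v = trilinear(d, nx, ny, nz, pts(r, 0), pts(r, 1), pts(r, 2), ok);
    out[r] = ok ? v : NA_REAL;
  }
  return out;
}

// Mean over the local bundle direction: out(p) = mean of trilinear samples at
// p + k * dir(p_y), k = -h..h, dropping samples outside the grid.
// dirs: ny x 3 unit vectors (one per integer y).
// [[Rcpp::export]]
NumericVector cpp_longitudinal_average(NumericVector vol, NumericMatrix dirs,
                                       int half_window) {
  IntegerVector dm = vol.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  const double* d = vol.begin();
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  double* o = out.begin();
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      double vx = dirs(j, 0), vy = dirs(j, 1), vz = dirs(j, 2);
      for (int i = 0; i < nx; i++) {
        double acc = 0.0;
        int cnt = 0;
        for (int s = -half_window; s <= half_window; s++) {
          bool ok;
          double v = trilinear(d, nx, ny, nz,
                               i + s * vx, j + s * vy, k + s * vz, ok);
          if (ok) { acc += v; cnt++; }
        }
        o[idx3(i, j, k, nx, ny)] = cnt > 0 ? acc / cnt : d[idx3(i, j, k, nx, ny)];
      }
    }
  }
  return out;
}

// Separable convolution along one axis (0=x,1=y,2=z) with border
// renormalization (weights of in-bounds taps rescaled to sum 1).
// [[Rcpp::export]]
NumericVector cpp_convolve_axis(NumericVector vol, NumericVector kernel, int axis) {
  IntegerVector dm = vol.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  int klen = kernel.size();
  int half = (klen - 1) / 2;
  const double* d = vol.begin();
  NumericVector out(vol.size());
  out.attr("dim") = dm;
  double* o = out.begin();
  int nax = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  for (int k = 0; k < nz; k++) {
    for (int j = 0; j < ny; j++) {
      for (int i = 0; i < nx; i++) {
        int pos = (axis == 0) ? i : (axis == 1) ? j : k;
        double acc = 0.0, wsum = 0.0;
        for (int s = -half; s <= half; s++) {
          int q = pos + s;
          if (q < 0 || q >= nax) continue;
          double w = kernel[s + half];
          int ii = i, jj = j, kk = k;
          if (axis == 0) ii = q; else if (axis == 1) jj = q; else kk = q;
          acc += w * d[idx3(ii, jj, kk, nx, ny)];
          wsum += w;
        }
        o[idx3(i, j, k, nx, ny)] = wsum > 0 ? acc / wsum : 0.0;
      }
    }
  }
  return out;
}

static inline double bilin(const double* m, int nr, int nc, double x, double z,
                           bool& ok) {
  if (x < 0 || z < 0 || x > nr - 1 || z > nc - 1) { ok = false; return 0.0; }
  ok = true;
  int i0 = (int)std::floor(x), k0 = (int)std::floor(z);
  if (i0 == nr - 1) i0--;
  if (k0 == nc - 1) k0--;
  double fx = x - i0, fz = z - k0;
  double a = m[i0 + nr * k0], b = m[i0 + 1 + nr * k0];
  double c = m[i0 + nr * (k0 + 1)], e = m[i0 + 1 + nr * (k0 + 1)];
  return (a * (1 - fx) + b * fx) * (1 - fz) + (c * (1 - fx) + e * fx) * fz;
}

// Matched-filter score of one kernel at one continuous position:
// sum over the kernel grid of kernel * bilinear(section, center + offset).
// Returns NA when any sample would fall outside the section.
// [[Rcpp::export]]
double cpp_score_single(NumericMatrix section, NumericMatrix kernel,
                        double cx, double cz) {
  int nr = section.nrow(), nc = section.ncol();
  int K = kernel.nrow();
  int R = (K - 1) / 2;
  if (cx - R < 0 || cz - R < 0 || cx + R > nr - 1 || cz + R > nc - 1)
    return NA_REAL;
  const double* m = section.begin();
  double acc = 0.0;
  for (int v = -R; v <= R; v++) {
    for (int u = -R; u <= R; u++) {
      bool ok;
      double s = bilin(m, nr, nc, cx + u, cz + v, ok);
      acc += kernel(u + R, v + R) * s;
    }
  }
  return acc;
}

// Scores of one kernel at many integer positions (direct indexing, no
// interpolation). pos: n x 2 integer (x,z). NA where support exits.
// [[Rcpp::export]]
NumericVector cpp_score_integer(NumericMatrix section, NumericMatrix kernel,
                                IntegerMatrix pos) {
  int nr = section.nrow(), nc = section.ncol();
  int K = kernel.nrow();
  int R = (K - 1) / 2;
  const double* m = section.begin();
  const double* kk = kernel.begin();
  int n = pos.nrow();
  NumericVector out(n);
  for (int r = 0; r < n; r++) {
    int cx = pos(r, 0), cz = pos(r, 1);
    if (cx - R < 0 || cz - R < 0 || cx + R > nr - 1 || cz + R > nc - 1) {
      out[r] = NA_REAL;
      continue;
    }
    double acc = 0.0;
    for (int v = 0; v < K; v++) {
      const double* scol = m + (cx - R) + (R_xlen_t)nr * (cz - R + v);
      const double* kcol = kk + (R_xlen_t)K * v;
      for (int u = 0; u < K; u++) acc += kcol[u] * scol[u];
    }
    out[r] = acc;
  }
  return out;
}

// Scores of a stack of equally-sized kernels (K x K x nk array) at many
// continuous positions. The section patch is resampled once per position and
// reused across kernels. Returns npos x nk matrix; NA rows where the patch
// exits the section.
// [[Rcpp::export]]
NumericMatrix cpp_score_stack(NumericMatrix section, NumericVector kstack,
                              NumericMatrix pos) {
  IntegerVector kd = kstack.attr("dim");
  int K = kd[0], nk = kd[2];
  int R = (K - 1) / 2;
  int nr = section.nrow(), nc = section.ncol();
  const double* m = section.begin();
  const double* ks = kstack.begin();
  int npos = pos.nrow();
  NumericMatrix out(npos, nk);
  std::vector<double> patch((size_t)K * K);
  for (int r = 0; r < npos; r++) {
    double cx = pos(r, 0), cz = pos(r, 1);
    if (cx - R < 0 || cz - R < 0 || cx + R > nr - 1 || cz + R > nc - 1) {
      for (int q = 0; q < nk; q++) out(r, q) = NA_REAL;
      continue;
    }
    // resample the patch once
    for (int v = 0; v < K; v++) {
      double z = cz + v - R;
      int k0 = (int)std::floor(z);
      if (k0 >= nc - 1) k0 = nc - 2;
      double fz = z - k0;
      for (int u = 0; u < K; u++) {
        double x = cx + u - R;
        int i0 = (int)std::floor(x);
        if (i0 >= nr - 1) i0 = nr - 2;
        double fx = x - i0;
        const double* c0 = m + i0 + (R_xlen_t)nr * k0;
        const double* c1 = m + i0 + (R_xlen_t)nr * (k0 + 1);
        patch[(size_t)K * v + u] =
          (c0[0] * (1 - fx) + c0[1] * fx) * (1 - fz) +
          (c1[0] * (1 - fx) + c1[1] * fx) * fz;
      }
    }
    for (int q = 0; q < nk; q++) {
      const double* kq = ks + (R_xlen_t)K * K * q;
      double acc = 0.0;
      for (size_t t = 0; t < (size_t)K * K; t++) acc += kq[t] * patch[t];
      out(r, q) = acc;
    }
  }
  return out;
}

// For each row of P (n x 3), the minimum Euclidean distance to rows of Q.
// [[Rcpp::export]]
NumericVector cpp_min_dist(NumericMatrix P, NumericMatrix Q) {
  int n = P.nrow(), m = Q.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m; j++) {
      double dx = px - Q(j, 0), dy = py - Q(j, 1), dz = pz - Q(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Apply per-y linear filters (the c-coefficient row of the weighted
// quadratic fit) to interior voxels; border voxels (filter support not fully
// inside) are copied from the input. filters: list of 3D arrays with odd
// dims; fidx: length-ny 1-based index into filters.
// [[Rcpp::export]]
List cpp_polyreg_apply(NumericVector vol, List filters, IntegerVector fidx) {
  IntegerVector dm = vol.attr("dim");
  int nx = dm[0], ny = dm[1], nz = dm[2];
  const double* d = vol.begin();
  NumericVector out = clone(vol);
  double* o = out.begin();
  R_xlen_t copied = 0;
  int nf = filters.size();
  std::vector<NumericVector> fv(nf);
  std::vector<IntegerVector> fd(nf);
  for (int q = 0; q < nf; q++) {
    fv[q] = as<NumericVector>(filters[q]);
    fd[q] = as<IntegerVector>(fv[q].attr("dim"));
  }
  for (int j = 0; j < ny; j++) {
    int q = fidx[j] - 1;
    const double* w = fv[q].begin();
    int hx = (fd[q][0] - 1) / 2, hy = (fd[q][1] - 1) / 2, hz = (fd[q][2] - 1) / 2;
    int fnx = fd[q][0], fny = fd[q][1];
    bool yok = (j - hy >= 0) && (j + hy <= ny - 1);
    for (int k = 0; k < nz; k++) {
      bool zok = (k - hz >= 0) && (k + hz <= nz - 1);
      for (int i = 0; i < nx; i++) {
        if (!yok || !zok || i - hx < 0 || i + hx > nx - 1) {
          copied++;
          continue; // out already holds the input value
        }
        double acc = 0.0;
        for (int c = -hz; c <= hz; c++) {
          for (int b = -hy; b <= hy; b++) {
            const double* wcol = w + (hx - hx) + (R_xlen_t)fnx * ((b + hy) + (R_xlen_t)fny * (c + hz));
            const double* dcol = d + (i - hx) + (R_xlen_t)nx * ((j + b) + (R_xlen_t)ny * (k + c));
            for (int a = 0; a < 2 * hx + 1; a++) acc += wcol[a] * dcol[a];
          }
        }
        o[idx3(i, j, k, nx, ny)] = acc;
      }
    }
  }
  return List::create(_["volume"] = out, _["n_copied"] = (double)copied);
}

// For each row of P, the exact minimum distance to the piecewise-linear
// curve through the rows of M (point-to-segment projection) - the limit of
// arbitrarily fine interpolation of the polyline.
// [[Rcpp::export]]
NumericVector cpp_polyline_dist(NumericMatrix P, NumericMatrix M) {
  int n = P.nrow(), m = M.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; i++) {
    double px = P(i, 0), py = P(i, 1), pz = P(i, 2);
    double best = R_PosInf;
    for (int j = 0; j < m - 1; j++) {
      double ax = M(j, 0), ay = M(j, 1), az = M(j, 2);
      double bx = M(j + 1, 0) - ax, by = M(j + 1, 1) - ay, bz = M(j + 1, 2) - az;
      double len2 = bx * bx + by * by + bz * bz;
      double t = 0.0;
      if (len2 > 0) {
        t = ((px - ax) * bx + (py - ay) * by + (pz - az) * bz) / len2;
        if (t < 0) t = 0;
        if (t > 1) t = 1;
      }
      double dx = px - (ax + t * bx), dy = py - (ay + t * by),
             dz = pz - (az + t * bz);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}
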