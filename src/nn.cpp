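#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>

using namespace Rcpp;

// Nearest-neighbour queries between 3D point sets.  A uniform spatial grid
// over the reference set gives near-linear scaling for the mesh sizes used
// during registration; small sets fall back to direct scan.  Correctness is
// defined by the O(n*m) scan: a cell ring at Chebyshev index distance d can
// only contain points at Euclidean distance >= (d-1)*h, so the ring search
// stops once the current best is below that bound.

static inline double sqdist(const double *a, const double *b) {
  double dx = a[0] - b[0], dy = a[1] - b[1], dz = a[2] - b[2];
  return dx * dx + dy * dy + dz * dz;
}

static IntegerVector nn_brute(const NumericMatrix &query, const NumericMatrix &ref) {
  const int n = query.nrow(), m = ref.nrow();
  std::vector<double> q(3), r(3);
  IntegerVector out(n);
  std::vector<double> rx(m), ry(m), rz(m);
  for (int j = 0; j < m; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    double best = std::numeric_limits<double>::infinity();
    int bj = 0;
    for (int j = 0; j < m; ++j) {
      double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      double d = dx * dx + dy * dy + dz * dz;
      if (d < best) { best = d; bj = j; }
    }
    out[i] = bj + 1;
  }
  return out;
}

// [[Rcpp::export(name = ".nn_index_cpp")]]
IntegerVector nn_index_cpp(NumericMatrix query, NumericMatrix ref) {
  const int n = query.nrow(), m = ref.nrow();
  if (m == 0) stop("reference point set is empty");
  if (m <= 64 || n <= 8) return nn_brute(query, ref);

  // bounding box of the reference set
  double lo[3], hi[3];
  for (int c = 0; c < 3; ++c) { lo[c] = ref(0, c); hi[c] = ref(0, c); }
  for (int j = 0; j < m; ++j)
    for (int c = 0; c < 3; ++c) {
      double v = ref(j, c);
      if (v < lo[c]) lo[c] = v;
      if (v > hi[c]) hi[c] = v;
    }
  double ext[3], maxext = 0.0;
  for (int c = 0; c < 3; ++c) {
    ext[c] = hi[c] - lo[c];
    if (ext[c] > maxext) maxext = ext[c];
  }
  if (maxext <= 0.0) return nn_brute(query, ref);

  // cube cells sized for ~2 points per occupied cell, capped total cells
  double vol = 1.0;
  for (int c = 0; c < 3; ++c) vol *= std::max(ext[c], 1e-9 * maxext);
  double h = std::cbrt(2.0 * vol / m);
  int dim[3];
  for (;;) {
    long total = 1;
    for (int c = 0; c < 3; ++c) {
      dim[c] = std::max(1, (int)std::floor(ext[c] / h) + 1);
      total *= dim[c];
    }
    if (total <= (1L << 22)) break;
    h *= 1.5;
  }
  const long ncell = (long)dim[0] * dim[1] * dim[2];

  auto cell_of = [&](double x, double y, double z, int *ijk) {
    ijk[0] = std::min(dim[0] - 1, std::max(0, (int)std::floor((x - lo[0]) / h)));
    ijk[1] = std::min(dim[1] - 1, std::max(0, (int)std::floor((y - lo[1]) / h)));
    ijk[2] = std::min(dim[2] - 1, std::max(0, (int)std::floor((z - lo[2]) / h)));
  };
  auto flat = [&](int i, int j, int k) -> long {
    return ((long)i * dim[1] + j) * dim[2] + k;
  };

  // counting sort of reference points into cells
  std::vector<int> count(ncell + 1, 0), start(ncell + 1, 0);
  std::vector<int> cell(m);
  {
    int ijk[3];
    for (int j = 0; j < m; ++j) {
      cell_of(ref(j, 0), ref(j, 1), ref(j, 2), ijk);
      cell[j] = (int)flat(ijk[0], ijk[1], ijk[2]);
      ++count[cell[j] + 1];
    }
  }
  for (long c = 0; c < ncell; ++c) count[c + 1] += count[c];
  start = count;
  std::vector<int> bucket(m);
  {
    std::vector<int> cur(start.begin(), start.end() - 1);
    for (int j = 0; j < m; ++j) bucket[cur[cell[j]]++] = j;
  }

  std::vector<double> rx(m), ry(m), rz(m);
  for (int j = 0; j < m; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }

  IntegerVector out(n);
  const int dmax = std::max(dim[0], std::max(dim[1], dim[2]));
  for (int i = 0; i < n; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int c0[3];
    cell_of(qx, qy, qz, c0);
    double best = std::numeric_limits<double>::infinity();
    int bj = -1;
    for (int d = 0; d <= dmax; ++d) {
      if (bj >= 0 && d >= 1) {
        double bound = (double)(d - 1) * h;
        if (best <= bound * bound) break;
      }
      int i0 = std::max(0, c0[0] - d), i1 = std::min(dim[0] - 1, c0[0] + d);
      int j0 = std::max(0, c0[1] - d), j1 = std::min(dim[1] - 1, c0[1] + d);
      int k0 = std::max(0, c0[2] - d), k1 = std::min(dim[2] - 1, c0[2] + d);
      for (int ci = i0; ci <= i1; ++ci)
        for (int cj = j0; cj <= j1; ++cj)
          for (int ck = k0; ck <= k1; ++ck) {
            // only the shell at Chebyshev distance d
            int cd = std::max(std::abs(ci - c0[0]),
                     std::max(std::abs(cj - c0[1]), std::abs(ck - c0[2])));
            if (cd != d) continue;
            long f = flat(ci, cj, ck);
            for (int p = start[f]; p < start[f + 1]; ++p) {
              int j = bucket[p];
              double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
              double dd = dx * dx + dy * dy + dz * dz;
              if (dd < best) { best = dd; bj = j; }
            }
          }
    }
    out[i] = bj + 1;
  }
  return out;
}
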