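#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// Squared Euclidean distance between row i of a and row j of b (n x 3 layout,
// column-major as stored by R).
static inline double sqdist3(const double* a, int na, int i,
                             const double* b, int nb, int j) {
  double dx = a[i] - b[j];
  double dy = a[i + na] - b[j + nb];
  double dz = a[i + 2 * na] - b[j + 2 * nb];
  return dx * dx + dy * dy + dz * dz;
}

// Symmetric Chamfer distance: mean over a of squared nearest-neighbour
// distance into b, plus the same with roles swapped.
static double chamfer_pair(const double* a, int na, const double* b, int nb) {
  double acc = 0.0;
  for (int i = 0; i < na; ++i) {
    double best = INF;
    for (int j = 0; j < nb; ++j) {
      double d = sqdist3(a, na, i, b, nb, j);
      if (d < best) best = d;
    }
    acc += best;
  }
  double out = acc / na;
  acc = 0.0;
  for (int j = 0; j < nb; ++j) {
    double best = INF;
    for (int i = 0; i < na; ++i) {
      double d = sqdist3(a, na, i, b, nb, j);
      if (d < best) best = d;
    }
    acc += best;
  }
  return out + acc / nb;
}

// Hungarian algorithm with potentials (Jonker–Volgenant style shortest
// augmenting paths), O(n^3). cost is n x n column-major; fills col_to_row.
static double hungarian(const std::vector<double>& cost, int n,
                        std::vector<int>& col_to_row) {
  std::vector<double> u(n + 1, 0.0), v(n + 1, 0.0), minv(n + 1);
  std::vector<int> p(n + 1, 0), way(n + 1, 0);
  for (int i = 1; i <= n; ++i) {
    p[0] = i;
    int j0 = 0;
    std::fill(minv.begin(), minv.end(), INF);
    std::vector<char> used(n + 1, 0);
    do {
      used[j0] = 1;
      int i0 = p[j0], j1 = 0;
      double delta = INF;
      for (int j = 1; j <= n; ++j) {
        if (used[j]) continue;
        double cur = cost[(i0 - 1) + (j - 1) * n] - u[i0] - v[j];
        if (cur < minv[j]) { minv[j] = cur; way[j] = j0; }
        if (minv[j] < delta) { delta = minv[j]; j1 = j; }
      }
      for (int j = 0; j <= n; ++j) {
        if (used[j]) { u[p[j]] += delta; v[j] -= delta; }
        else minv[j] -= delta;
      }
      j0 = j1;
    } while (p[j0] != 0);
    do { int j1 = way[j0]; p[j0] = p[j1]; j0 = j1; } while (j0);
  }
  double total = 0.0;
  col_to_row.assign(n, 0);
  for (int j = 1; j <= n; ++j) {
    col_to_row[j - 1] = p[j] - 1;
    total += cost[(p[j] - 1) + (j - 1) * n];
  }
  return total;
}

// EMD between equally sized sets: minimal mean Euclidean (unsquared) distance
// under an optimal bijection.
static double emd_pair(const double* a, const double* b, int n) {
  std::vector<double> cost(static_cast<size_t>(n) * n);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      cost[i + static_cast<size_t>(j) * n] = std::sqrt(sqdist3(a, n, i, b, n, j));
  std::vector<int> asg;
  return hungarian(cost, n, asg) / n;
}

// Ordered L2: per-point RMS of the index-wise differences.
static double l2_pair(const double* a, const double* b, int n) {
  double acc = 0.0;
  for (int i = 0; i < n; ++i) acc += sqdist3(a, n, i, b, n, i);
  return std::sqrt(acc / n);
}

// [[Rcpp::export(name = ".cpp_chamfer")]]
double cpp_chamfer(NumericMatrix a, NumericMatrix b) {
  return chamfer_pair(REAL(a), a.nrow(), REAL(b), b.nrow());
}

// [[Rcpp::export(name = ".cpp_emd")]]
List cpp_emd(NumericMatrix a, NumericMatrix b) {
  int n = a.nrow();
  std::vector<double> cost(static_cast<size_t>(n) * n);
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  for (int j = 0; j < n; ++j)
    for (int i = 0; i < n; ++i)
      cost[i + static_cast<size_t>(j) * n] = std::sqrt(sqdist3(pa, n, i, pb, n, j));
  std::vector<int> asg;
  double total = hungarian(cost, n, asg);
  IntegerVector perm(n);  // perm[j] = 1-based row of a matched to row j of b
  for (int j = 0; j < n; ++j) perm[j] = asg[j] + 1;
  return List::create(_["value"] = total / n, _["assignment"] = perm);
}

// Pairwise distance matrix between two stacks of same-N shapes, each stored
// as an (S*N) x 3 matrix of vertically concatenated shapes.
// kind: 1 = Chamfer, 2 = EMD, 3 = ordered L2.
// [[Rcpp::export(name = ".cpp_pairwise")]]
NumericMatrix cpp_pairwise(NumericMatrix a, NumericMatrix b, int n, int kind) {
  int sa = a.nrow() / n, sb = b.nrow() / n;
  NumericMatrix out(sa, sb);
  int na = a.nrow(), nb = b.nrow();
  const double* pa = REAL(a);
  const double* pb = REAL(b);
  // copy each shape into a compact n x 3 buffer so sqdist3's stride is n
  std::vector<double> sha(3 * n), shb(3 * n);
  for (int ia = 0; ia < sa; ++ia) {
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < n; ++r) sha[r + c * n] = pa[ia * n + r + c * na];
    for (int ib = 0; ib < sb; ++ib) {
      for (int c = 0; c < 3; ++c)
        for (int r = 0; r < n; ++r) shb[r + c * n] = pb[ib * n + r + c * nb];
      double v;
      switch (kind) {
      case 1: v = chamfer_pair(sha.data(), n, shb.data(), n); break;
      case 2: v = emd_pair(sha.data(), shb.data(), n); break;
      default: v = l2_pair(sha.data(), shb.data(), n);
      }
      out(ia, ib) = v;
    }
    Rcpp::checkUserInterrupt();
  }
  return out;
}
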