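#include <Rcpp.h>
using namespace Rcpp;

// Ward agglomeration on a precomputed distance matrix, treating the
// distances as if Euclidean. Merge cost between clusters A, B is
//   c(A,B) = (nA*nB/(nA+nB)) * ||centroid_A - centroid_B||^2,
// initialized for singletons as d^2/2 and updated by the Lance-Williams
// recursion. Ties are broken by the lowest (i, j) active-slot pair (slots
// carry the smallest original observation index of their cluster).
//
// A per-row nearest-neighbor cache avoids rescanning the full cost matrix
// at every step; rows are rescanned only when their cached neighbor was
// touched by the latest merge, so tie-breaking is identical to the naive
// full scan.
//
// Returns an hclust-style merge matrix (negative entries are singleton
// observations, positive entries earlier merge steps) and the merge costs.
// [[Rcpp::export(name = ".ward_merge_cpp")]]
List ward_merge_cpp(NumericMatrix d) {
  int n = d.nrow();
  if (n != d.ncol()) stop("distance matrix must be square");
  std::vector<double> cost((size_t)n * n, 0.0);
  std::vector<int> size(n, 1), id(n, 0), nn(n, -1);
  std::vector<double> nnd(n, R_PosInf);
  std::vector<bool> active(n, true);
  for (int i = 0; i < n; ++i) {
    id[i] = -(i + 1);
    for (int j = 0; j < n; ++j) {
      double dij = d(i, j);
      cost[(size_t)i * n + j] = dij * dij / 2.0;
    }
  }
  // nearest active neighbor with index > i (strict < keeps the lowest j)
  auto scan_row = [&](int i) {
    nn[i] = -1;
    nnd[i] = R_PosInf;
    for (int j = i + 1; j < n; ++j) {
      if (!active[j]) continue;
      double c = cost[(size_t)i * n + j];
      if (c < nnd[i]) { nnd[i] = c; nn[i] = j; }
    }
  };
  for (int i = 0; i < n; ++i) scan_row(i);

  IntegerMatrix merge(n - 1, 2);
  NumericVector height(n - 1);

  for (int step = 0; step < n - 1; ++step) {
    double best = R_PosInf;
    int bi = -1;
    for (int i = 0; i < n; ++i) {
      if (!active[i] || nn[i] < 0) continue;
      if (nnd[i] < best) { best = nnd[i]; bi = i; }
    }
    int bj = nn[bi];
    merge(step, 0) = id[bi];
    merge(step, 1) = id[bj];
    height[step] = best;

    int ni = size[bi], nj = size[bj];
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi || k == bj) continue;
      int nk = size[k];
      double cik = cost[(size_t)bi * n + k];
      double cjk = cost[(size_t)bj * n + k];
      double c = ((ni + nk) * cik + (nj + nk) * cjk - nk * best) /
                 (double)(ni + nj + nk);
      cost[(size_t)bi * n + k] = c;
      cost[(size_t)k * n + bi] = c;
    }
    size[bi] = ni + nj;
    active[bj] = false;
    id[bi] = step + 1;

    scan_row(bi);
    for (int k = 0; k < n; ++k) {
      if (!active[k] || k == bi) continue;
      if (nn[k] == bi || nn[k] == bj) {
        scan_row(k);
      } else if (k < bi) {
        double c = cost[(size_t)k * n + bi];
        // match the full-scan tie-break: prefer the lower column index
        if (c < nnd[k] || (c == nnd[k] && bi < nn[k])) {
          nnd[k] = c;
          nn[k] = bi;
        }
      }
    }
  }
  return List::create(_["merge"] = merge, _["height"] = height);
}
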