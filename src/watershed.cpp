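#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Marker-based watershed by priority flooding, 4-connectivity.
// Pixels are flooded in order of increasing elevation; ties are resolved by
// insertion order (seeds first, then discovery order), which makes the
// result deterministic for a fixed input.
struct Px {
  double elev;
  long order;
  int idx;
};
struct PxCmp {
  bool operator()(const Px& a, const Px& b) const {
    if (a.elev != b.elev) return a.elev > b.elev;  // min-heap on elevation
    return a.order > b.order;                      // then FIFO
  }
};

// [[Rcpp::export]]
IntegerMatrix watershed_flood(NumericMatrix elev, IntegerMatrix seeds,
                              LogicalMatrix mask) {
  int nr = elev.nrow(), nc = elev.ncol();
  if (seeds.nrow() != nr || seeds.ncol() != nc ||
      mask.nrow() != nr || mask.ncol() != nc)
    stop("elevation, seeds and mask must share dimensions");
  IntegerMatrix lab(nr, nc);
  std::priority_queue<Px, std::vector<Px>, PxCmp> q;
  long order = 0;
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i)
      if (seeds(i, j) > 0 && mask(i, j)) {
        lab(i, j) = seeds(i, j);
        q.push({elev(i, j), order++, j * nr + i});
      }
  const int di[4] = {-1, 1, 0, 0};
  const int dj[4] = {0, 0, -1, 1};
  while (!q.empty()) {
    Px p = q.top();
    q.pop();
    int i = p.idx % nr, j = p.idx / nr;
    int l = lab(i, j);
    for (int k = 0; k < 4; ++k) {
      int ii = i + di[k], jj = j + dj[k];
      if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
      if (!mask(ii, jj) || lab(ii, jj) != 0) continue;
      lab(ii, jj) = l;
      q.push({elev(ii, jj), order++, jj * nr + ii});
    }
  }
  return lab;
}
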