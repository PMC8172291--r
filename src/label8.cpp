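// Two-pass 8-connected component labelling with union-find.

#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static int findRoot(std::vector<int>& par, int i) {
  while (par[i] != i) { par[i] = par[par[i]]; i = par[i]; }
  return i;
}

// [[Rcpp::export(name = ".label8")]]
IntegerMatrix label8(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> par(1, 0);
  for (int j = 0; j < W; ++j) {
    for (int i = 0; i < H; ++i) {
      if (!mask(i, j)) continue;
      int neigh[4], nn = 0;
      if (i > 0 && lab(i - 1, j)) neigh[nn++] = lab(i - 1, j);
      if (j > 0) {
        if (lab(i, j - 1)) neigh[nn++] = lab(i, j - 1);
        if (i > 0 && lab(i - 1, j - 1)) neigh[nn++] = lab(i - 1, j - 1);
        if (i < H - 1 && mask(i + 1, j - 1) && lab(i + 1, j - 1))
          neigh[nn++] = lab(i + 1, j - 1);
      }
      if (nn == 0) {
        par.push_back((int)par.size());
        lab(i, j) = (int)par.size() - 1;
      } else {
        int m = findRoot(par, neigh[0]);
        for (int k = 1; k < nn; ++k) {
          int r = findRoot(par, neigh[k]);
          if (r != m) { if (r < m) std::swap(r, m); par[r] = m; }
        }
        lab(i, j) = m;
      }
    }
  }
  // compress and renumber consecutively
  std::vector<int> newId(par.size(), 0);
  int nxt = 0;
  for (size_t k = 1; k < par.size(); ++k)
    if (findRoot(par, (int)k) == (int)k) newId[k] = ++nxt;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i)
      if (lab(i, j)) lab(i, j) = newId[findRoot(par, lab(i, j))];
  return lab;
}
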