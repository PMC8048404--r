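#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path compression
static int uf_find(std::vector<int>& parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int>& parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labelling of a logical matrix.
// connectivity: 4 or 8. Returns an integer matrix; background (FALSE)
// pixels are 0, components are labelled 1..k in raster order of their
// first pixel.
// [[Rcpp::export]]
IntegerMatrix ccl_label(LogicalMatrix img, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int n = img.nrow(), m = img.ncol();
  IntegerMatrix lab(n, m);
  std::vector<int> parent;
  parent.reserve(1024);
  int next = 0;
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < n; ++i) {
      if (!img(i, j)) continue;
      int up = (i > 0 && img(i - 1, j)) ? lab(i - 1, j) : 0;
      int left = (j > 0 && img(i, j - 1)) ? lab(i, j - 1) : 0;
      int ul = 0, dl = 0;
      if (connectivity == 8) {
        ul = (i > 0 && j > 0 && img(i - 1, j - 1)) ? lab(i - 1, j - 1) : 0;
        dl = (i < n - 1 && j > 0 && img(i + 1, j - 1)) ? lab(i + 1, j - 1) : 0;
      }
      int nb[4] = {up, left, ul, dl};
      int lmin = 0;
      for (int k = 0; k < 4; ++k)
        if (nb[k] > 0 && (lmin == 0 || nb[k] < lmin)) lmin = nb[k];
      if (lmin == 0) {
        ++next;
        parent.push_back(next - 1); // parent index is label-1, self
        lab(i, j) = next;
      } else {
        lab(i, j) = lmin;
        for (int k = 0; k < 4; ++k)
          if (nb[k] > 0) uf_union(parent, nb[k] - 1, lmin - 1);
      }
    }
  }
  // resolve equivalences, relabel compactly in order of first appearance
  std::vector<int> remap(next + 1, 0);
  int out = 0;
  for (int j = 0; j < m; ++j)
    for (int i = 0; i < n; ++i) {
      int l = lab(i, j);
      if (l == 0) continue;
      int r = uf_find(parent, l - 1) + 1;
      if (remap[r] == 0) remap[r] = ++out;
      lab(i, j) = remap[r];
    }
  return lab;
}
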