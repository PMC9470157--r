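#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// union-find with path compression
static int uf_find(std::vector<int> &parent, int x) {
  while (parent[x] != x) {
    parent[x] = parent[parent[x]];
    x = parent[x];
  }
  return x;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[std::max(ra, rb)] = std::min(ra, rb);
}

// Two-pass connected-component labelling of a logical matrix.
// connectivity: 4 (edge-adjacent) or 8 (edge- or corner-adjacent).
// Labels are 1..K in order of first appearance (column-major scan);
// background (FALSE) is 0.
// [[Rcpp::export(name = ".cc_label")]]
IntegerMatrix cc_label(LogicalMatrix mask, int connectivity) {
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> parent;
  parent.push_back(0); // provisional label 0 unused

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c)) continue;
      int best = 0;
      // neighbours already visited in a column-major scan
      int neigh8[4][2] = {
        {r - 1, c},     // above, same column
        {r - 1, c - 1}, // diagonal up-left
        {r, c - 1},     // left
        {r + 1, c - 1}  // diagonal down-left
      };
      int neigh4[2][2] = {{r - 1, c}, {r, c - 1}};
      int nn = (connectivity == 8) ? 4 : 2;
      for (int k = 0; k < nn; ++k) {
        int rr = (connectivity == 8) ? neigh8[k][0] : neigh4[k][0];
        int cc = (connectivity == 8) ? neigh8[k][1] : neigh4[k][1];
        if (rr < 0 || rr >= nr || cc < 0) continue;
        int l = lab(rr, cc);
        if (l > 0) {
          if (best == 0) best = l;
          else uf_union(parent, best, l);
        }
      }
      if (best == 0) {
        int fresh = (int)parent.size();
        parent.push_back(fresh);
        lab(r, c) = fresh;
      } else {
        lab(r, c) = best;
      }
    }
  }

  // second pass: resolve to roots, then compact to 1..K by first appearance
  std::vector<int> compact(parent.size(), 0);
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      int l = lab(r, c);
      if (l == 0) continue;
      int root = uf_find(parent, l);
      if (compact[root] == 0) compact[root] = ++next;
      lab(r, c) = compact[root];
    }
  }
  return lab;
}
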