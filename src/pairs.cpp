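#include <Rcpp.h>
#include <cstdint>
#include <vector>
using namespace Rcpp;

// Leaf labels encode gene/trait state as 2*gene + trait:
//   0 = g-t- ("ab"), 1 = g-t+ ("aB"), 2 = g+t- ("Ab"), 3 = g+t+ ("AB").
// A contrasting pair joins labels l and 3-l; it is "supporting" when the
// states co-vary (labels {0,3}), "opposing" when they anti-vary ({1,2}).
// DP state per node: for each leftover label s in 0..3 (a leaf of label s
// whose path to the node is still unused) plus 4 = no leftover, track the
// maximum pair count in the subtree and, conditional on that maximum, the
// max/min number of supporting pairs. Paths of distinct pairs must be
// edge-disjoint, which in a rooted binary tree equals node-disjoint, so at
// most one leftover path crosses any node: one state per node suffices.

struct Cell {
  int mp;  // max pairs, -1 = infeasible
  int mx;  // max supporting given mp
  int mn;  // min supporting given mp
};

static inline void upd(Cell &c, int pairs, int smax, int smin) {
  if (pairs > c.mp) { c.mp = pairs; c.mx = smax; c.mn = smin; }
  else if (pairs == c.mp) {
    if (smax > c.mx) c.mx = smax;
    if (smin < c.mn) c.mn = smin;
  }
}

// Core DP. children: (nNodes x 2) 0-based, -1 for leaves.
// postorder: node indices, children before parents. labels: per node,
// meaningful at leaves only.
static void dp_run(const int *ch0, const int *ch1, const int *post, int nNodes,
                   const int *labels, std::vector<Cell> &S, int root,
                   int &max_pairs, int &best, int &worst) {
  for (int k = 0; k < nNodes; ++k) {
    int v = post[k];
    Cell *sv = &S[5 * v];
    for (int s = 0; s < 5; ++s) { sv[s].mp = -1; sv[s].mx = 0; sv[s].mn = 0; }
    int a = ch0[v];
    if (a < 0) {                      // leaf
      sv[labels[v]].mp = 0;
      sv[4].mp = 0;
      continue;
    }
    int b = ch1[v];
    const Cell *L = &S[5 * a], *R = &S[5 * b];
    // no leftover: both children resolved, or close a pair across v
    if (L[4].mp >= 0 && R[4].mp >= 0)
      upd(sv[4], L[4].mp + R[4].mp, L[4].mx + R[4].mx, L[4].mn + R[4].mn);
    for (int l = 0; l < 4; ++l) {
      int r = 3 - l;
      if (L[l].mp >= 0 && R[r].mp >= 0) {
        int add = (l == 0 || l == 3) ? 1 : 0;
        upd(sv[4], L[l].mp + R[r].mp + 1, L[l].mx + R[r].mx + add,
            L[l].mn + R[r].mn + add);
      }
    }
    // leftover s passed up from one child, other child resolved
    for (int s = 0; s < 4; ++s) {
      if (L[s].mp >= 0 && R[4].mp >= 0)
        upd(sv[s], L[s].mp + R[4].mp, L[s].mx + R[4].mx, L[s].mn + R[4].mn);
      if (L[4].mp >= 0 && R[s].mp >= 0)
        upd(sv[s], L[4].mp + R[s].mp, L[4].mx + R[s].mx, L[4].mn + R[s].mn);
    }
  }
  const Cell *rt = &S[5 * root];
  max_pairs = 0; best = 0; worst = 0;
  for (int s = 0; s < 5; ++s) if (rt[s].mp > max_pairs) max_pairs = rt[s].mp;
  bool first = true;
  for (int s = 0; s < 5; ++s) {
    if (rt[s].mp == max_pairs) {
      if (first) { best = rt[s].mx; worst = rt[s].mn; first = false; }
      else {
        if (rt[s].mx > best) best = rt[s].mx;
        if (rt[s].mn < worst) worst = rt[s].mn;
      }
    }
  }
}

// [[Rcpp::export]]
IntegerVector pair_summary_cpp(IntegerMatrix children, IntegerVector postorder,
                               IntegerVector labels) {
  int nNodes = children.nrow();
  std::vector<int> c0(nNodes), c1(nNodes), post(nNodes), lab(nNodes, 0);
  for (int i = 0; i < nNodes; ++i) {
    c0[i] = children(i, 0); c1[i] = children(i, 1);
    post[i] = postorder[i]; lab[i] = labels[i];
  }
  std::vector<Cell> S(5 * (size_t)nNodes);
  int root = post[nNodes - 1];
  int mp, bs, ws;
  dp_run(c0.data(), c1.data(), post.data(), nNodes, lab.data(), S, root, mp, bs, ws);
  return IntegerVector::create(mp, bs, ws);
}

// Batch DP over gene columns (and optional repetitions, for timing studies).
// genes: nLeaves x nGenes 0/1; trait: nLeaves 0/1; leafNodes: node index of
// leaf i (0-based), aligned with rows of genes.
// [[Rcpp::export]]
IntegerMatrix pair_summary_multi_cpp(IntegerMatrix children,
                                     IntegerVector postorder,
                                     IntegerVector leafNodes,
                                     IntegerMatrix genes, IntegerVector trait,
                                     int reps = 1) {
  int nNodes = children.nrow(), nLeaves = leafNodes.size(),
      nGenes = genes.ncol();
  std::vector<int> c0(nNodes), c1(nNodes), post(nNodes), lab(nNodes, 0);
  for (int i = 0; i < nNodes; ++i) {
    c0[i] = children(i, 0); c1[i] = children(i, 1); post[i] = postorder[i];
  }
  std::vector<Cell> S(5 * (size_t)nNodes);
  int root = post[nNodes - 1];
  IntegerMatrix out(nGenes, 3);
  for (int rep = 0; rep < reps; ++rep) {
    for (int g = 0; g < nGenes; ++g) {
      for (int i = 0; i < nLeaves; ++i)
        lab[leafNodes[i]] = 2 * genes(i, g) + trait[i];
      int mp, bs, ws;
      dp_run(c0.data(), c1.data(), post.data(), nNodes, lab.data(), S, root,
             mp, bs, ws);
      out(g, 0) = mp; out(g, 1) = bs; out(g, 2) = ws;
    }
  }
  return out;
}

// splitmix64: tiny deterministic PRNG so permutation results depend only on
// the supplied seed, never on R's global RNG state or evaluation order.
static inline uint64_t splitmix64(uint64_t &x) {
  uint64_t z = (x += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline int rand_below(uint64_t &state, int n) {
  // rejection sampling for an unbiased draw in [0, n)
  uint64_t lim = UINT64_MAX - (UINT64_MAX % (uint64_t)n);
  uint64_t r;
  do { r = splitmix64(state); } while (r >= lim);
  return (int)(r % (uint64_t)n);
}

// Null distribution of best_supporting under uniform permutation of a trait
// vector with nPos positives over the leaves (gene and tree fixed).
// [[Rcpp::export]]
IntegerVector perm_null_cpp(IntegerMatrix children, IntegerVector postorder,
                            IntegerVector leafNodes, IntegerVector gene,
                            int nPos, int nPermut, double seed) {
  int nNodes = children.nrow(), nLeaves = leafNodes.size();
  std::vector<int> c0(nNodes), c1(nNodes), post(nNodes), lab(nNodes, 0);
  for (int i = 0; i < nNodes; ++i) {
    c0[i] = children(i, 0); c1[i] = children(i, 1); post[i] = postorder[i];
  }
  std::vector<Cell> S(5 * (size_t)nNodes);
  int root = post[nNodes - 1];
  std::vector<int> tr(nLeaves, 0);
  for (int i = 0; i < nPos; ++i) tr[i] = 1;
  uint64_t state = (uint64_t)seed;
  splitmix64(state);  // decorrelate consecutive integer seeds
  IntegerVector out(nPermut);
  for (int p = 0; p < nPermut; ++p) {
    for (int i = nLeaves - 1; i > 0; --i) {  // Fisher–Yates
      int j = rand_below(state, i + 1);
      int t = tr[i]; tr[i] = tr[j]; tr[j] = t;
    }
    for (int i = 0; i < nLeaves; ++i)
      lab[leafNodes[i]] = 2 * gene[i] + tr[i];
    int mp, bs, ws;
    dp_run(c0.data(), c1.data(), post.data(), nNodes, lab.data(), S, root,
           mp, bs, ws);
    out[p] = bs;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Independent exhaustive oracle: branch-and-bound enumeration of all sets of
// edge-disjoint contrasting leaf pairs, tracking path edge sets explicitly as
// bitmasks. Shares no logic with the DP above. Feasible for <= ~12 leaves.

struct Oracle {
  int nLeaves;
  std::vector<int> lab;                 // per leaf
  std::vector<std::vector<uint64_t>> pathMask;  // leaf x leaf edge bitmask
  int bestPairs, bestSupp, worstSupp;

  void search(int leaf, uint64_t used, int pairs, int supp) {
    if (leaf == nLeaves) {
      if (pairs > bestPairs) {
        bestPairs = pairs; bestSupp = supp; worstSupp = supp;
      } else if (pairs == bestPairs) {
        if (supp > bestSupp) bestSupp = supp;
        if (supp < worstSupp) worstSupp = supp;
      }
      return;
    }
    search(leaf + 1, used, pairs, supp);  // leaf left unpaired
    for (int j = leaf + 1; j < nLeaves; ++j) {
      if (lab[leaf] + lab[j] != 3) continue;          // must contrast
      uint64_t m = pathMask[leaf][j];
      if (m & used) continue;                          // edges must be free
      int add = (lab[leaf] == 0 || lab[leaf] == 3) ? 1 : 0;
      search(leaf + 1, used | m, pairs + 1, supp + add);
    }
  }
};

// [[Rcpp::export]]
IntegerVector brute_force_pairs_cpp(IntegerMatrix children,
                                    IntegerVector postorder,
                                    IntegerVector leafNodes,
                                    IntegerVector leafLabels) {
  int nNodes = children.nrow(), nLeaves = leafNodes.size();
  if (nLeaves > 12) stop("oracle limited to 12 leaves");
  std::vector<int> parent(nNodes, -1), depth(nNodes, 0);
  for (int v = 0; v < nNodes; ++v) {
    if (children(v, 0) >= 0) {
      parent[children(v, 0)] = v;
      parent[children(v, 1)] = v;
    }
  }
  // depths via repeated parent hops (trees here are tiny)
  for (int v = 0; v < nNodes; ++v) {
    int d = 0, u = v;
    while (parent[u] >= 0) { u = parent[u]; ++d; }
    depth[v] = d;
  }
  Oracle o;
  o.nLeaves = nLeaves;
  o.lab.resize(nLeaves);
  for (int i = 0; i < nLeaves; ++i) o.lab[i] = leafLabels[i];
  o.pathMask.assign(nLeaves, std::vector<uint64_t>(nLeaves, 0));
  for (int i = 0; i < nLeaves; ++i) {
    for (int j = i + 1; j < nLeaves; ++j) {
      uint64_t m = 0;
      int u = leafNodes[i], v = leafNodes[j];
      while (u != v) {
        if (depth[u] >= depth[v]) { m |= (1ULL << u); u = parent[u]; }
        else { m |= (1ULL << v); v = parent[v]; }
      }
      // bit k set = edge from node k to its parent lies on the path
      o.pathMask[i][j] = m;
    }
  }
  o.bestPairs = 0; o.bestSupp = 0; o.worstSupp = 0;
  o.search(0, 0, 0, 0);
  return IntegerVector::create(o.bestPairs, o.bestSupp, o.worstSupp);
}
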