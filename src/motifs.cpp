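// Directed 3-node subgraph census and degree-preserving edge switching.
// Hot loops live here because motif enrichment runs the census on ~10^3
// randomized replicates of the input network.
#include <Rcpp.h>
#include <unordered_set>
#include <set>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// All 6 permutations of three labels.
static const int PERM[6][3] = {
  {0, 1, 2}, {0, 2, 1}, {1, 0, 2}, {1, 2, 0}, {2, 0, 1}, {2, 1, 0}
};

// Bit position of the ordered pair (i, j) in the 6-bit adjacency code.
// Pair order: (0,1) (0,2) (1,0) (1,2) (2,0) (2,1).
static inline int bitpos(int i, int j) {
  static const int tbl[3][3] = {{-1, 0, 1}, {2, -1, 3}, {4, 5, -1}};
  return tbl[i][j];
}

static inline int permute_code(int code, const int* p) {
  int out = 0;
  for (int i = 0; i < 3; ++i) {
    for (int j = 0; j < 3; ++j) {
      if (i == j) continue;
      if (code & (1 << bitpos(i, j))) out |= (1 << bitpos(p[i], p[j]));
    }
  }
  return out;
}

// Canonical form: minimum 6-bit adjacency code over all node relabelings.
static inline int canon_code(int code) {
  int best = permute_code(code, PERM[0]);
  for (int k = 1; k < 6; ++k) {
    int c = permute_code(code, PERM[k]);
    if (c < best) best = c;
  }
  return best;
}

// Weak connectivity of 3 nodes: at least two of the three unordered pairs
// must carry an edge in some direction (any two distinct pairs share a node).
static inline bool connected3(int code) {
  int ab = (code & ((1 << 0) | (1 << 2))) ? 1 : 0;
  int ac = (code & ((1 << 1) | (1 << 4))) ? 1 : 0;
  int bc = (code & ((1 << 3) | (1 << 5))) ? 1 : 0;
  return ab + ac + bc >= 2;
}

// Sorted canonical codes of the 13 connected classes; class index is the
// 1-based position in this vector.
static const std::vector<int>& class_codes() {
  static std::vector<int> codes;
  if (codes.empty()) {
    std::set<int> s;
    for (int c = 1; c < 64; ++c)
      if (connected3(c)) s.insert(canon_code(c));
    codes.assign(s.begin(), s.end());
  }
  return codes;
}

static inline int class_index(int code) {
  if (!connected3(code)) return 0;
  const std::vector<int>& codes = class_codes();
  int canon = canon_code(code);
  int lo = (int)(std::lower_bound(codes.begin(), codes.end(), canon) -
                 codes.begin());
  return lo + 1;  // guaranteed present
}

// [[Rcpp::export(name = ".triad_class_codes_cpp")]]
IntegerVector triad_class_codes_cpp() {
  const std::vector<int>& codes = class_codes();
  return IntegerVector(codes.begin(), codes.end());
}

// [[Rcpp::export(name = ".classify_triad_code_cpp")]]
int classify_triad_code_cpp(int code) {
  if (code < 0 || code > 63) stop("adjacency code out of range");
  return class_index(code);
}

static inline long long ekey(int u, int v, int n) {
  return (long long)u * n + v;
}

struct EdgeIndex {
  std::unordered_set<long long> set;
  int n;
  EdgeIndex(const std::vector<int>& src, const std::vector<int>& dst, int n_)
      : n(n_) {
    set.reserve(src.size() * 2);
    for (size_t e = 0; e < src.size(); ++e)
      set.insert(ekey(src[e], dst[e], n));
  }
  bool has(int u, int v) const { return set.count(ekey(u, v, n)) > 0; }
};

// Census core. Enumerates each weakly connected unordered triple exactly
// once: a triple is generated at node u adjacent (in the undirected
// skeleton) to both v < w; if v and w are themselves adjacent (triangle,
// three centers) it is kept only when u is the smallest node.
static void census_core(const std::vector<int>& src,
                        const std::vector<int>& dst, int n,
                        std::vector<int>& counts,
                        std::vector<int>* inst_nodes,
                        std::vector<int>* inst_class) {
  counts.assign(13, 0);
  EdgeIndex idx(src, dst, n);
  std::vector<std::vector<int> > nb(n);
  for (size_t e = 0; e < src.size(); ++e) {
    nb[src[e]].push_back(dst[e]);
    nb[dst[e]].push_back(src[e]);
  }
  for (int u = 0; u < n; ++u) {
    std::vector<int>& v = nb[u];
    std::sort(v.begin(), v.end());
    v.erase(std::unique(v.begin(), v.end()), v.end());
  }
  for (int u = 0; u < n; ++u) {
    const std::vector<int>& nu = nb[u];
    int k = (int)nu.size();
    for (int i = 0; i < k; ++i) {
      int v = nu[i];
      for (int j = i + 1; j < k; ++j) {
        int w = nu[j];  // v < w by sortedness
        bool vw = idx.has(v, w) || idx.has(w, v);
        if (vw && u > v) continue;  // triangle counted at its smallest node
        int code = 0;
        if (idx.has(u, v)) code |= 1 << bitpos(0, 1);
        if (idx.has(u, w)) code |= 1 << bitpos(0, 2);
        if (idx.has(v, u)) code |= 1 << bitpos(1, 0);
        if (idx.has(v, w)) code |= 1 << bitpos(1, 2);
        if (idx.has(w, u)) code |= 1 << bitpos(2, 0);
        if (idx.has(w, v)) code |= 1 << bitpos(2, 1);
        int cls = class_index(code);
        if (cls == 0) continue;  // cannot happen: u links v and w
        counts[cls - 1]++;
        if (inst_nodes) {
          inst_nodes->push_back(u);
          inst_nodes->push_back(v);
          inst_nodes->push_back(w);
          inst_class->push_back(cls);
        }
      }
    }
  }
}

// [[Rcpp::export(name = ".census_cpp")]]
List census_cpp(IntegerVector src, IntegerVector dst, int n_nodes,
                bool keep_instances) {
  std::vector<int> s(src.begin(), src.end());
  std::vector<int> d(dst.begin(), dst.end());
  std::vector<int> counts;
  std::vector<int> inst_nodes, inst_class;
  census_core(s, d, n_nodes, counts,
              keep_instances ? &inst_nodes : (std::vector<int>*)0,
              keep_instances ? &inst_class : (std::vector<int>*)0);
  IntegerMatrix inst((int)inst_class.size(), 4);
  for (size_t r = 0; r < inst_class.size(); ++r) {
    inst(r, 0) = inst_nodes[3 * r];
    inst(r, 1) = inst_nodes[3 * r + 1];
    inst(r, 2) = inst_nodes[3 * r + 2];
    inst(r, 3) = inst_class[r];
  }
  return List::create(_["counts"] = IntegerVector(counts.begin(), counts.end()),
                      _["instances"] = inst);
}

// One attempted directed two-edge switch (a->b, c->d) => (a->d, c->b).
// Rejected if it would create a self-loop, a duplicate edge, or is a no-op.
static void do_swaps(std::vector<int>& src, std::vector<int>& dst, int n,
                     int n_swaps, std::unordered_set<long long>& eset) {
  int m = (int)src.size();
  if (m < 2) return;
  for (int s = 0; s < n_swaps; ++s) {
    int i = (int)(unif_rand() * m);
    int j = (int)(unif_rand() * m);
    if (i >= m) i = m - 1;
    if (j >= m) j = m - 1;
    if (i == j) continue;
    int a = src[i], b = dst[i], c = src[j], d = dst[j];
    if (a == c || b == d) continue;       // no-op or duplicate-producing
    if (a == d || c == b) continue;       // would create self-loop
    if (eset.count(ekey(a, d, n)) || eset.count(ekey(c, b, n))) continue;
    eset.erase(ekey(a, b, n));
    eset.erase(ekey(c, d, n));
    eset.insert(ekey(a, d, n));
    eset.insert(ekey(c, b, n));
    dst[i] = d;
    dst[j] = b;
  }
}

// [[Rcpp::export(name = ".randomize_cpp")]]
List randomize_cpp(IntegerVector src, IntegerVector dst, int n_nodes,
                   int n_swaps) {
  std::vector<int> s(src.begin(), src.end());
  std::vector<int> d(dst.begin(), dst.end());
  std::unordered_set<long long> eset;
  eset.reserve(s.size() * 2);
  for (size_t e = 0; e < s.size(); ++e) eset.insert(ekey(s[e], d[e], n_nodes));
  do_swaps(s, d, n_nodes, n_swaps, eset);
  return List::create(_["src"] = IntegerVector(s.begin(), s.end()),
                      _["dst"] = IntegerVector(d.begin(), d.end()));
}

// Erdos-Renyi style null: same node and edge counts, uniformly random
// distinct ordered pairs without self-loops.
static void er_sample(std::vector<int>& src, std::vector<int>& dst, int n,
                      int m) {
  std::unordered_set<long long> eset;
  eset.reserve(m * 2);
  src.clear();
  dst.clear();
  while ((int)src.size() < m) {
    int u = (int)(unif_rand() * n);
    int v = (int)(unif_rand() * n);
    if (u >= n) u = n - 1;
    if (v >= n) v = n - 1;
    if (u == v) continue;
    long long k = ekey(u, v, n);
    if (eset.count(k)) continue;
    eset.insert(k);
    src.push_back(u);
    dst.push_back(v);
  }
}

// Census counts over n_random null networks; one row per replicate.
// [[Rcpp::export(name = ".motif_null_counts_cpp")]]
IntegerMatrix motif_null_counts_cpp(IntegerVector src, IntegerVector dst,
                                    int n_nodes, int n_random, int n_swaps,
                                    bool er_null) {
  std::vector<int> s0(src.begin(), src.end());
  std::vector<int> d0(dst.begin(), dst.end());
  int m = (int)s0.size();
  IntegerMatrix out(n_random, 13);
  std::vector<int> counts;
  for (int r = 0; r < n_random; ++r) {
    std::vector<int> s, d;
    if (er_null) {
      er_sample(s, d, n_nodes, m);
    } else {
      s = s0;
      d = d0;
      std::unordered_set<long long> eset;
      eset.reserve(m * 2);
      for (int e = 0; e < m; ++e) eset.insert(ekey(s[e], d[e], n_nodes));
      do_swaps(s, d, n_nodes, n_swaps, eset);
    }
    census_core(s, d, n_nodes, counts, 0, 0);
    for (int c = 0; c < 13; ++c) out(r, c) = counts[c];
  }
  return out;
}
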