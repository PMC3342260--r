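// ESU census of connected induced k-subgraphs of a signed digraph, with
// canonical labeling by brute-force permutation (k <= 4), and a
// sign-stratified degree-preserving edge-swap randomizer.
//
// Edge codes between an ordered node pair: 0 none, 1 positive, 2 negative,
// 3 both signs present. A subgraph label is "k:" followed by the
// lexicographically minimal row-major code string over all k! relabelings.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <string>
#include <algorithm>
using namespace Rcpp;

typedef long long ll;

static inline ll pk(int u, int v, int n) { return (ll)u * n + v; }

static const int PERM3[6][3] = {
  {0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};

static std::vector<std::array<int,4> > perms4() {
  std::vector<std::array<int,4> > out;
  std::array<int,4> p = {0,1,2,3};
  do { out.push_back(p); } while (std::next_permutation(p.begin(), p.end()));
  return out;
}

// canonical label of the induced subgraph on nodes[0..k-1]
static std::string canon_label(const std::vector<int>& nodes, int k, int n,
                               const std::unordered_map<ll,int>& code) {
  int m[4][4];
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) {
      if (i == j) { m[i][j] = 0; continue; }
      std::unordered_map<ll,int>::const_iterator it =
        code.find(pk(nodes[i], nodes[j], n));
      m[i][j] = (it == code.end()) ? 0 : it->second;
    }
  std::string best;
  std::string cur(k * k, '0');
  if (k == 3) {
    for (int p = 0; p < 6; ++p) {
      const int* perm = PERM3[p];
      for (int i = 0; i < 3; ++i)
        for (int j = 0; j < 3; ++j)
          cur[i * 3 + j] = (char)('0' + m[perm[i]][perm[j]]);
      if (best.empty() || cur < best) best = cur;
    }
  } else if (k == 4) {
    static std::vector<std::array<int,4> > P4 = perms4();
    for (size_t p = 0; p < P4.size(); ++p) {
      const std::array<int,4>& perm = P4[p];
      for (int i = 0; i < 4; ++i)
        for (int j = 0; j < 4; ++j)
          cur[i * 4 + j] = (char)('0' + m[perm[i]][perm[j]]);
      if (best.empty() || cur < best) best = cur;
    }
  } else if (k == 2) {
    for (int a = 0; a < 2; ++a) {
      int perm[2] = {a, 1 - a};
      for (int i = 0; i < 2; ++i)
        for (int j = 0; j < 2; ++j)
          cur[i * 2 + j] = (char)('0' + m[perm[i]][perm[j]]);
      if (best.empty() || cur < best) best = cur;
    }
  } else {
    best.assign(1, (char)('0' + m[0][0]));
  }
  return std::to_string(k) + ":" + best;
}

struct EsuState {
  int n, k;
  bool collect;
  const std::vector<std::vector<int> >* adj;  // undirected, sorted
  const std::unordered_map<ll,int>* code;
  std::vector<char> in_sub, in_ext_or_nbr;
  std::vector<int> sub;
  std::unordered_map<std::string, int> counts;
  std::vector<std::string> labels;
  std::vector<std::vector<int> > instances;
};

static void extend(EsuState& st, std::vector<int>& ext, int v_root) {
  if ((int)st.sub.size() == st.k) {
    std::string lab = canon_label(st.sub, st.k, st.n, *st.code);
    if (st.collect) {
      st.labels.push_back(lab);
      st.instances.push_back(st.sub);
    } else {
      st.counts[lab] += 1;
    }
    return;
  }
  // neighbors of current subgraph (exclusive-neighborhood bookkeeping)
  std::unordered_set<int> sub_nbr;
  for (size_t i = 0; i < st.sub.size(); ++i) {
    const std::vector<int>& nb = (*st.adj)[st.sub[i]];
    for (size_t j = 0; j < nb.size(); ++j) sub_nbr.insert(nb[j]);
  }
  std::vector<int> ext_local = ext;
  while (!ext_local.empty()) {
    int w = ext_local.back();
    ext_local.pop_back();
    std::vector<int> ext_next = ext_local;
    const std::vector<int>& nbw = (*st.adj)[w];
    for (size_t j = 0; j < nbw.size(); ++j) {
      int u = nbw[j];
      if (u <= v_root) continue;
      if (st.in_sub[u]) continue;
      if (sub_nbr.count(u)) continue;  // not exclusive
      if (u == w) continue;
      ext_next.push_back(u);
    }
    st.sub.push_back(w);
    st.in_sub[w] = 1;
    extend(st, ext_next, v_root);
    st.in_sub[w] = 0;
    st.sub.pop_back();
  }
}

// [[Rcpp::export]]
List esu_census_cpp(int n, IntegerVector from, IntegerVector to,
                    IntegerVector sign, int k, bool collect) {
  if (k < 2 || k > 4) stop("subgraph size must be in {2, 3, 4}");
  std::unordered_map<ll,int> code;
  std::vector<std::unordered_set<int> > nbr(n);
  int m = from.size();
  for (int e = 0; e < m; ++e) {
    int u = from[e] - 1, v = to[e] - 1;
    if (u == v) continue;  // self-loops excluded from the census
    int bit = sign[e] > 0 ? 1 : 2;
    code[pk(u, v, n)] |= bit;
    nbr[u].insert(v);
    nbr[v].insert(u);
  }
  std::vector<std::vector<int> > adj(n);
  for (int u = 0; u < n; ++u) {
    adj[u].assign(nbr[u].begin(), nbr[u].end());
    std::sort(adj[u].begin(), adj[u].end());
  }
  EsuState st;
  st.n = n; st.k = k; st.collect = collect;
  st.adj = &adj; st.code = &code;
  st.in_sub.assign(n, 0);
  for (int v = 0; v < n; ++v) {
    std::vector<int> ext;
    for (size_t j = 0; j < adj[v].size(); ++j)
      if (adj[v][j] > v) ext.push_back(adj[v][j]);
    st.sub.clear();
    st.sub.push_back(v);
    std::fill(st.in_sub.begin(), st.in_sub.end(), 0);
    st.in_sub[v] = 1;
    extend(st, ext, v);
  }
  if (collect) {
    int ni = st.labels.size();
    IntegerMatrix inst(ni, k);
    CharacterVector labs(ni);
    for (int i = 0; i < ni; ++i) {
      labs[i] = st.labels[i];
      for (int j = 0; j < k; ++j) inst(i, j) = st.instances[i][j] + 1;
    }
    return List::create(_["labels"] = labs, _["nodes"] = inst);
  }
  int nc = st.counts.size();
  IntegerVector cnt(nc);
  CharacterVector nm(nc);
  int i = 0;
  for (std::unordered_map<std::string,int>::iterator it = st.counts.begin();
       it != st.counts.end(); ++it, ++i) {
    nm[i] = it->first;
    cnt[i] = it->second;
  }
  cnt.attr("names") = nm;
  return List::create(_["counts"] = cnt);
}

// [[Rcpp::export]]
std::string canonical_label_cpp(IntegerMatrix adj) {
  int k = adj.nrow();
  if (k < 1 || k > 4 || adj.ncol() != k) stop("adjacency must be k x k, k <= 4");
  std::unordered_map<ll,int> code;
  std::vector<int> nodes(k);
  for (int i = 0; i < k; ++i) nodes[i] = i;
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j)
      if (i != j && adj(i, j) != 0) code[pk(i, j, k)] = adj(i, j);
  return canon_label(nodes, k, k, code);
}

// Degree-preserving randomization within each sign class: repeated
// two-edge swaps (a->b, c->d) => (a->d, c->b), rejecting self-loops and
// duplicate edges within the class. per_edge * m swap trials per class,
// each retried up to `attempts` times. Uses R's RNG.
// [[Rcpp::export]]
List rewire_signed_cpp(int n, IntegerVector from, IntegerVector to,
                       IntegerVector sign, double per_edge, int attempts) {
  int m = from.size();
  std::vector<int> f(m), t(m);
  for (int e = 0; e < m; ++e) { f[e] = from[e] - 1; t[e] = to[e] - 1; }
  // group edge indices by sign class
  std::unordered_map<int, std::vector<int> > classes;
  for (int e = 0; e < m; ++e) classes[sign[e]].push_back(e);
  for (std::unordered_map<int, std::vector<int> >::iterator ci =
         classes.begin(); ci != classes.end(); ++ci) {
    std::vector<int>& idx = ci->second;
    int mc = idx.size();
    if (mc < 2) continue;
    std::unordered_set<ll> present;
    for (int i = 0; i < mc; ++i) present.insert(pk(f[idx[i]], t[idx[i]], n));
    ll trials = (ll)std::ceil(per_edge * mc);
    for (ll s = 0; s < trials; ++s) {
      for (int att = 0; att < attempts; ++att) {
        int i = idx[(int)(unif_rand() * mc)];
        int j = idx[(int)(unif_rand() * mc)];
        if (i == j) continue;
        int a = f[i], b = t[i], c = f[j], d = t[j];
        if (a == d || c == b) continue;            // would create self-loop
        if (b == d || a == c) continue;            // no-op swap
        if (present.count(pk(a, d, n)) || present.count(pk(c, b, n)))
          continue;                                // duplicate in class
        present.erase(pk(a, b, n));
        present.erase(pk(c, d, n));
        present.insert(pk(a, d, n));
        present.insert(pk(c, b, n));
        t[i] = d; t[j] = b;
        break;
      }
    }
  }
  IntegerVector nf(m), nt(m);
  for (int e = 0; e < m; ++e) { nf[e] = f[e] + 1; nt[e] = t[e] + 1; }
  return List::create(_["from"] = nf, _["to"] = nt, _["sign"] = sign);
}
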