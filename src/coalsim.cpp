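#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Two-population divergence coalescent, time in generations counted backwards.
// g1, g2, gA are gene-copy counts; a pair coalesces with probability 1/g per
// generation, so waiting times are Exp(k(k-1)/(2g)). At Td the two populations
// merge into the ancestral one. Tips 0..n-1 (population 1 first), internal
// nodes appended in coalescence order; root has parent -1.
struct Genealogy {
  std::vector<int> parent;
  std::vector<double> time;
  int root;
  int n;
};

static void coalesce_pair(std::vector<int> &pool, std::vector<int> &parent,
                          std::vector<double> &tm, int node, double t) {
  int k = (int)pool.size();
  int i = (int)(unif_rand() * k);
  if (i >= k) i = k - 1;
  int j = (int)(unif_rand() * (k - 1));
  if (j >= k - 1) j = k - 2;
  if (j >= i) ++j;
  int c1 = pool[i], c2 = pool[j];
  parent[c1] = node;
  parent[c2] = node;
  tm[node] = t;
  if (i > j) std::swap(i, j);
  pool.erase(pool.begin() + j);
  pool.erase(pool.begin() + i);
  pool.push_back(node);
}

static Genealogy sim_genealogy(int n1, int n2, double g1, double g2,
                               double gA, double Td) {
  int n = n1 + n2;
  if (n < 2) stop("need at least 2 lineages");
  Genealogy g;
  g.n = n;
  g.parent.assign(2 * n - 1, -1);
  g.time.assign(2 * n - 1, 0.0);
  std::vector<int> a1, a2;
  a1.reserve(n);
  for (int i = 0; i < n1; ++i) a1.push_back(i);
  for (int i = 0; i < n2; ++i) a2.push_back(n1 + i);
  double t = 0.0;
  int nxt = n;
  bool merged = (Td <= 0.0);
  if (merged && !a2.empty()) {
    a1.insert(a1.end(), a2.begin(), a2.end());
    a2.clear();
  }
  while ((int)(a1.size() + a2.size()) > 1) {
    if (!merged) {
      double r1 = a1.size() >= 2
                      ? a1.size() * (a1.size() - 1.0) / (2.0 * g1) : 0.0;
      double r2 = a2.size() >= 2
                      ? a2.size() * (a2.size() - 1.0) / (2.0 * g2) : 0.0;
      double rt = r1 + r2;
      double dt = rt > 0 ? R::rexp(1.0 / rt) : R_PosInf;
      if (t + dt >= Td) {
        t = Td;
        merged = true;
        a1.insert(a1.end(), a2.begin(), a2.end());
        a2.clear();
        continue;
      }
      t += dt;
      std::vector<int> &pool = (unif_rand() * rt < r1) ? a1 : a2;
      coalesce_pair(pool, g.parent, g.time, nxt++, t);
    } else {
      double rt = a1.size() * (a1.size() - 1.0) / (2.0 * gA);
      t += R::rexp(1.0 / rt);
      coalesce_pair(a1, g.parent, g.time, nxt++, t);
    }
  }
  g.root = nxt - 1;
  return g;
}

// Leaves below each node (tips map to themselves).
static std::vector<std::vector<int> > leaf_sets(const Genealogy &g,
                                                int n_nodes) {
  std::vector<std::vector<int> > below(n_nodes);
  for (int i = 0; i < g.n; ++i) below[i].push_back(i);
  // internal nodes were appended in increasing time order, so a single
  // pass in node order sees children before parents
  for (int v = 0; v < n_nodes; ++v) {
    int p = g.parent[v];
    if (p >= 0)
      below[p].insert(below[p].end(), below[v].begin(), below[v].end());
  }
  return below;
}

// Infinite-sites mutations: each mutation is a unique column, derived state
// carried by the tips below the branch it fell on. Returns an S x n 0/1
// matrix with rows in no particular order (S may be 0).
// [[Rcpp::export(name = ".cpp_sim_seq_infsites")]]
IntegerMatrix cpp_sim_seq_infsites(int n1, int n2, double g1, double g2,
                                   double gA, double Td, double muLocus) {
  Genealogy g = sim_genealogy(n1, n2, g1, g2, gA, Td);
  int n = g.n, nn = 2 * n - 1;
  std::vector<double> cum(nn, 0.0);
  double tot = 0.0;
  for (int v = 0; v < nn; ++v) {
    if (g.parent[v] >= 0) tot += g.time[g.parent[v]] - g.time[v];
    cum[v] = tot;
  }
  int M = (int)R::rpois(muLocus * tot);
  IntegerMatrix out(M, n);
  if (M == 0) return out;
  std::vector<std::vector<int> > below = leaf_sets(g, nn);
  for (int m = 0; m < M; ++m) {
    double u = unif_rand() * tot;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= nn) v = nn - 1;
    for (size_t k = 0; k < below[v].size(); ++k) out(m, below[v][k]) = 1;
  }
  return out;
}

struct Mut {
  int node;       // branch above this node
  double t;       // age of the mutation
  int aux;        // JC: unused; SSR: signed step size
};

// Jukes-Cantor finite-sites simulation with an optional outgroup lineage
// splitting at tOut generations (0 = no outgroup). Only mutated columns are
// returned: positions (1-based), tip base codes 0..3 (outgroup last column
// when present) and the ancestral base of each returned column.
// [[Rcpp::export(name = ".cpp_sim_seq_jc")]]
List cpp_sim_seq_jc(int n1, int n2, double g1, double g2, double gA,
                    double Td, double muSite, int L, double tOut) {
  Genealogy g = sim_genealogy(n1, n2, g1, g2, gA, Td);
  int n = g.n;
  bool og = tOut > 0.0;
  int n_nodes = 2 * n - 1 + (og ? 2 : 0);
  std::vector<int> parent(g.parent);
  std::vector<double> tm(g.time);
  parent.resize(n_nodes, -1);
  tm.resize(n_nodes, 0.0);
  int tip_out = -1, top = g.root;
  if (og) {
    double tEff = std::max(tOut, g.time[g.root] * (1.0 + 1e-9) + 1e-9);
    tip_out = 2 * n - 1;
    top = 2 * n;  // common ancestor of ingroup root and outgroup tip
    parent[g.root] = top;
    parent[tip_out] = top;
    tm[tip_out] = 0.0;
    tm[top] = tEff;
  }
  std::vector<double> cum(n_nodes, 0.0);
  double tot = 0.0;
  for (int v = 0; v < n_nodes; ++v) {
    if (parent[v] >= 0) tot += tm[parent[v]] - tm[v];
    cum[v] = tot;
  }
  int M = (int)R::rpois(muSite * (double)L * tot);
  std::map<int, std::vector<Mut> > by_site;
  for (int m = 0; m < M; ++m) {
    int pos = 1 + (int)(unif_rand() * L);
    if (pos > L) pos = L;
    double u = unif_rand() * tot;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= n_nodes) v = n_nodes - 1;
    double lo = tm[v], hi = tm[parent[v]];
    Mut mu;
    mu.node = v;
    mu.t = lo + unif_rand() * (hi - lo);
    mu.aux = 0;
    by_site[pos].push_back(mu);
  }
  int S = (int)by_site.size();
  int ncol_out = n + (og ? 1 : 0);
  IntegerMatrix states(S, ncol_out);
  IntegerVector pos_out(S), anc_out(S);
  // children lists for the DFS
  std::vector<std::vector<int> > child(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    if (parent[v] >= 0) child[parent[v]].push_back(v);
  std::vector<int> state(n_nodes);
  int row = 0;
  for (std::map<int, std::vector<Mut> >::iterator it = by_site.begin();
       it != by_site.end(); ++it, ++row) {
    pos_out[row] = it->first;
    int anc = (int)(unif_rand() * 4.0);
    if (anc > 3) anc = 3;
    anc_out[row] = anc;
    // mutations on each branch, oldest first
    std::map<int, std::vector<Mut> > on_branch;
    for (size_t k = 0; k < it->second.size(); ++k)
      on_branch[it->second[k].node].push_back(it->second[k]);
    std::vector<int> stack;
    state[top] = anc;
    stack.push_back(top);
    while (!stack.empty()) {
      int v = stack.back();
      stack.pop_back();
      if (v != top) {
        int b = state[parent[v]];
        std::map<int, std::vector<Mut> >::iterator mb = on_branch.find(v);
        if (mb != on_branch.end()) {
          std::sort(mb->second.begin(), mb->second.end(),
                    [](const Mut &a, const Mut &b2) { return a.t > b2.t; });
          for (size_t k = 0; k < mb->second.size(); ++k) {
            int step = 1 + (int)(unif_rand() * 3.0);
            if (step > 3) step = 3;
            b = (b + step) % 4;
          }
        }
        state[v] = b;
      }
      for (size_t c = 0; c < child[v].size(); ++c) stack.push_back(child[v][c]);
    }
    for (int i = 0; i < n; ++i) states(row, i) = state[i];
    if (og) states(row, n) = state[tip_out];
  }
  return List::create(_["pos"] = pos_out, _["states"] = states,
                      _["anc"] = anc_out);
}

static int reflect_allele(int a, int lo, int hi) {
  if (hi <= lo) return lo;
  long span = hi - lo, period = 2L * span;
  long x = (long)a - lo;
  long m = ((x % period) + period) % period;
  if (m > span) m = period - m;
  return lo + (int)m;
}

// Generalized stepwise mutation model on the diploid two-population
// coalescent: step sizes 1 + Geometric(1 - P), direction equiprobable,
// alleles reflected into [aMin, aMax]. Tips 2i and 2i+1 belong to
// individual i; population 1 holds individuals 0..nInd1-1.
// [[Rcpp::export(name = ".cpp_sim_ssr")]]
IntegerMatrix cpp_sim_ssr(int nInd1, int nInd2, double g1, double g2,
                          double gA, double Td, double muLocus, double P,
                          int aMin, int aMax, int founder) {
  int n = 2 * (nInd1 + nInd2);
  Genealogy g = sim_genealogy(2 * nInd1, 2 * nInd2, g1, g2, gA, Td);
  int n_nodes = 2 * n - 1;
  double tot = 0.0;
  std::vector<double> cum(n_nodes, 0.0);
  for (int v = 0; v < n_nodes; ++v) {
    if (g.parent[v] >= 0) tot += g.time[g.parent[v]] - g.time[v];
    cum[v] = tot;
  }
  int M = (int)R::rpois(muLocus * tot);
  std::map<int, std::vector<Mut> > on_branch;
  for (int m = 0; m < M; ++m) {
    double u = unif_rand() * tot;
    int v = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (v >= n_nodes) v = n_nodes - 1;
    double lo = g.time[v], hi = g.time[g.parent[v]];
    Mut mu;
    mu.node = v;
    mu.t = lo + unif_rand() * (hi - lo);
    int step = 1 + (P > 0 ? (int)R::rgeom(1.0 - P) : 0);
    mu.aux = unif_rand() < 0.5 ? step : -step;
    on_branch[v].push_back(mu);
  }
  std::vector<std::vector<int> > child(n_nodes);
  for (int v = 0; v < n_nodes; ++v)
    if (g.parent[v] >= 0) child[g.parent[v]].push_back(v);
  std::vector<int> allele(n_nodes, founder);
  std::vector<int> stack;
  stack.push_back(g.root);
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    if (v != g.root) {
      int a = allele[g.parent[v]];
      std::map<int, std::vector<Mut> >::iterator mb = on_branch.find(v);
      if (mb != on_branch.end()) {
        std::sort(mb->second.begin(), mb->second.end(),
                  [](const Mut &x, const Mut &y) { return x.t > y.t; });
        for (size_t k = 0; k < mb->second.size(); ++k)
          a = reflect_allele(a + mb->second[k].aux, aMin, aMax);
      }
      allele[v] = a;
    }
    for (size_t c = 0; c < child[v].size(); ++c) stack.push_back(child[v][c]);
  }
  int nInd = nInd1 + nInd2;
  IntegerMatrix out(nInd, 2);
  for (int i = 0; i < nInd; ++i) {
    out(i, 0) = allele[2 * i];
    out(i, 1) = allele[2 * i + 1];
  }
  return out;
}

// Genealogy exporter for the R-level synthetic-data builders (regimes are
// composed in R on top of these parent/time vectors).
// [[Rcpp::export(name = ".cpp_sim_genealogy")]]
List cpp_sim_genealogy(int n1, int n2, double g1, double g2, double gA,
                       double Td) {
  Genealogy g = sim_genealogy(n1, n2, g1, g2, gA, Td);
  return List::create(_["parent"] = IntegerVector(g.parent.begin(),
                                                  g.parent.end()),
                      _["time"] = NumericVector(g.time.begin(), g.time.end()),
                      _["root"] = g.root, _["n"] = g.n);
}
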