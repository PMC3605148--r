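// Coalescent simulation with recombination under a piecewise-constant
// population recombination rate through time.
//
// Time is measured in units of 2*Ne generations (pair-coalescence rate 1).
// Among k extant lineages, coalescence occurs at rate k(k-1)/2; each lineage
// recombines at rate (rho_epoch/2) * span, where span is the distance between
// the leftmost and rightmost ancestral material it carries (ms convention:
// breakpoints may fall in trapped non-ancestral material). Mutations are laid
// down afterwards as a Poisson process of rate theta/2 per unit time per unit
// sequence length on the recorded ancestral branches (infinite sites).

#include <Rcpp.h>
#include <map>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Seg {
  double l, r;
  int node; // marginal-tree node carried for [l, r)
};

struct Edge {
  double l, r;
  int parent, child;
};

typedef std::vector<Seg> Lineage;

inline double lin_lo(const Lineage &x) { return x.front().l; }
inline double lin_hi(const Lineage &x) { return x.back().r; }
inline double lin_span(const Lineage &x) { return lin_hi(x) - lin_lo(x); }

// ensure a key at x so count intervals can be split there
inline void split_at(std::map<double, int> &cnt, double x) {
  std::map<double, int>::iterator it = cnt.upper_bound(x);
  if (it == cnt.begin()) stop("internal error: split before origin");
  --it;
  if (it->first != x) cnt[x] = it->second;
}

} // namespace

// [[Rcpp::export]]
List sim_dataset_cpp(int n, double theta, NumericVector epoch_ends,
                     NumericVector rhos, double max_events) {
  if (n < 2) stop("sample size must be at least 2");
  if (epoch_ends.size() != rhos.size() || epoch_ends.size() < 1)
    stop("epoch tables must be non-empty and of equal length");
  if (!(epoch_ends[epoch_ends.size() - 1] == R_PosInf))
    stop("last epoch must be unbounded");

  std::vector<Lineage> lin(n);
  std::vector<double> node_time(n, 0.0);
  std::vector<Edge> edges;
  edges.reserve(4 * n);
  for (int i = 0; i < n; ++i) {
    Seg s; s.l = 0.0; s.r = 1.0; s.node = i;
    lin[i].push_back(s);
  }
  std::map<double, int> cnt; // extant-lineage coverage count per interval
  cnt[0.0] = n;
  cnt[1.0] = 0; // sentinel

  double t = 0.0;
  int epoch = 0;
  double n_events = 0.0;
  long n_rec = 0;

  while (lin.size() >= 2) {
    int k = (int)lin.size();
    double totspan = 0.0;
    for (int i = 0; i < k; ++i) totspan += lin_span(lin[i]);
    double rate_c = 0.5 * k * (double)(k - 1);
    double rate_r = 0.5 * rhos[epoch] * totspan;
    double tot = rate_c + rate_r;
    double dt = R::exp_rand() / tot;
    if (t + dt > epoch_ends[epoch]) {
      t = epoch_ends[epoch];
      ++epoch;
      continue;
    }
    t += dt;
    if (++n_events > max_events)
      stop("event cap exceeded: runaway parameterization?");

    if (unif_rand() * tot < rate_c) {
      // ---- coalescence of a uniform pair ----
      int i = (int)(unif_rand() * k); if (i == k) i = k - 1;
      int j = (int)(unif_rand() * (k - 1)); if (j >= k - 1) j = k - 2;
      if (j >= i) ++j;
      Lineage A = lin[i], B = lin[j];
      // remove (erase higher index first)
      if (i < j) std::swap(i, j);
      lin.erase(lin.begin() + i);
      lin.erase(lin.begin() + j);

      Lineage merged;
      merged.reserve(A.size() + B.size());
      int w = -1;
      size_t ia = 0, ib = 0;
      while (ia < A.size() && ib < B.size()) {
        Seg &a = A[ia];
        Seg &b = B[ib];
        if (a.r <= b.l) { merged.push_back(a); ++ia; continue; }
        if (b.r <= a.l) { merged.push_back(b); ++ib; continue; }
        double ol = std::max(a.l, b.l);
        double orr = std::min(a.r, b.r);
        if (a.l < ol) { Seg s = a; s.r = ol; merged.push_back(s); }
        if (b.l < ol) { Seg s = b; s.r = ol; merged.push_back(s); }
        if (w < 0) { w = (int)node_time.size(); node_time.push_back(t); }
        Edge e1; e1.l = ol; e1.r = orr; e1.parent = w; e1.child = a.node;
        Edge e2; e2.l = ol; e2.r = orr; e2.parent = w; e2.child = b.node;
        edges.push_back(e1);
        edges.push_back(e2);
        // decrement coverage on [ol, orr); keep pieces not yet at their MRCA
        split_at(cnt, ol);
        split_at(cnt, orr);
        for (std::map<double, int>::iterator it = cnt.find(ol);
             it != cnt.end() && it->first < orr; ++it) {
          it->second -= 1;
          if (it->second > 1) {
            std::map<double, int>::iterator nx = it; ++nx;
            Seg s; s.l = it->first; s.r = nx->first; s.node = w;
            merged.push_back(s);
          }
        }
        if (a.r == orr && b.r == orr) { ++ia; ++ib; }
        else if (a.r == orr) { ++ia; B[ib].l = orr; }
        else { ++ib; A[ia].l = orr; }
      }
      while (ia < A.size()) merged.push_back(A[ia++]);
      while (ib < B.size()) merged.push_back(B[ib++]);
      if (!merged.empty()) {
        std::sort(merged.begin(), merged.end(),
                  [](const Seg &x, const Seg &y) { return x.l < y.l; });
        lin.push_back(merged);
      }
    } else {
      // ---- recombination on a span-weighted lineage ----
      double u = unif_rand() * totspan;
      int i = 0;
      double acc = 0.0;
      for (; i < k; ++i) {
        acc += lin_span(lin[i]);
        if (u <= acc) break;
      }
      if (i == k) i = k - 1;
      double lo = lin_lo(lin[i]), hi = lin_hi(lin[i]);
      double x = lo + unif_rand() * (hi - lo);
      if (x <= lo || x >= hi) continue; // measure-zero boundary draw
      Lineage L, Rt;
      for (size_t s = 0; s < lin[i].size(); ++s) {
        const Seg &sg = lin[i][s];
        if (sg.r <= x) L.push_back(sg);
        else if (sg.l >= x) Rt.push_back(sg);
        else {
          Seg s1 = sg; s1.r = x;
          Seg s2 = sg; s2.l = x;
          L.push_back(s1);
          Rt.push_back(s2);
        }
      }
      ++n_rec;
      lin[i] = L;
      lin.push_back(Rt);
    }
  }
  if (!lin.empty() && !lin[0].empty())
    stop("internal error: ancestral material left with a single lineage");

  // ---- mutations on the recorded edges ----
  size_t ne = edges.size();
  std::vector<double> cum(ne);
  double mass = 0.0;
  for (size_t e = 0; e < ne; ++e) {
    mass += (node_time[edges[e].parent] - node_time[edges[e].child]) *
            (edges[e].r - edges[e].l);
    cum[e] = mass;
  }
  int nmut = (mass > 0.0) ? (int)R::rpois(0.5 * theta * mass) : 0;

  // per-node parent lookup
  std::vector<std::vector<Edge> > child_edges(node_time.size());
  for (size_t e = 0; e < ne; ++e) child_edges[edges[e].child].push_back(edges[e]);

  std::vector<std::pair<double, std::vector<int> > > muts;
  muts.reserve(nmut);
  for (int m = 0; m < nmut; ++m) {
    double u = unif_rand() * mass;
    size_t e = std::lower_bound(cum.begin(), cum.end(), u) - cum.begin();
    if (e >= ne) e = ne - 1;
    const Edge &ed = edges[e];
    double pos = ed.l + unif_rand() * (ed.r - ed.l);
    int c = ed.child;
    std::vector<int> carriers;
    for (int s = 0; s < n; ++s) {
      int cur = s;
      bool hit = false;
      while (true) {
        if (cur == c) { hit = true; break; }
        const std::vector<Edge> &pe = child_edges[cur];
        int nxt = -1;
        for (size_t q = 0; q < pe.size(); ++q)
          if (pe[q].l <= pos && pos < pe[q].r) { nxt = pe[q].parent; break; }
        if (nxt < 0) break;
        cur = nxt;
      }
      if (hit) carriers.push_back(s);
    }
    if (!carriers.empty() && (int)carriers.size() < n)
      muts.push_back(std::make_pair(pos, carriers));
  }
  std::sort(muts.begin(), muts.end(),
            [](const std::pair<double, std::vector<int> > &x,
               const std::pair<double, std::vector<int> > &y) {
              return x.first < y.first;
            });

  int S = (int)muts.size();
  IntegerMatrix haps(n, S);
  NumericVector positions(S);
  for (int s = 0; s < S; ++s) {
    positions[s] = muts[s].first;
    for (size_t q = 0; q < muts[s].second.size(); ++q)
      haps(muts[s].second[q], s) = 1;
  }
  return List::create(_["haplotypes"] = haps, _["positions"] = positions,
                      _["nRecombination"] = (double)n_rec,
                      _["tmrca"] = node_time.empty() ? NA_REAL : node_time.back());
}
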