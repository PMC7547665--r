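// Core routines for classifying deterministic memory-m strategies of the
// iterated prisoner's dilemma:
//   * defensibility  = no negative cycle in the adversarial state graph
//   * efficiency     = zero-error limit of self-play concentrates on full
//                      cooperation (Freidlin-Wentzell / stochastic stability)
//   * distinguishability = strictly positive limit payoff gap against AllC
// plus the bulk scanners used by the exhaustive m<=2 enumeration and the
// numerical small-e oracles the R level cross-checks against.
//
// Conventions (fixed throughout the package):
//   state index s in [0, 2^(2m)):  s = (hA << m) | hB, where hA/hB are the
//   m-bit histories of Alice/Bob, oldest action in the most significant bit,
//   c = 0, d = 1.  Strategy id bit i (LSB = state 0) is the action at state i.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static inline int shift_st(int s, int a, int b, int m) {
  int mask = (1 << m) - 1;
  int hA = s >> m, hB = s & mask;
  hA = ((hA << 1) | a) & mask;
  hB = ((hB << 1) | b) & mask;
  return (hA << m) | hB;
}

static inline int swap_st(int s, int m) {
  int mask = (1 << m) - 1;
  return ((s & mask) << m) | ((s >> m) & mask);
}

// sign of (payoff_A - payoff_B) for realized pair (a, b); payoff-free since
// it only uses T > S
static inline int pair_weight(int a, int b) {
  if (a == 1 && b == 0) return 1;
  if (a == 0 && b == 1) return -1;
  return 0;
}

// ---------------------------------------------------------------------------
// defensibility: Floyd-Warshall over the 2^(2m)-node graph where Alice's
// action is fixed by her table and Bob picks either action
// ---------------------------------------------------------------------------
static bool defensible_core(const std::vector<int>& act, int m) {
  const int n = 1 << (2 * m);
  const int INF = 1000000000;
  std::vector<int> D((size_t)n * n, INF);
  for (int s = 0; s < n; s++) {
    int a = act[s];
    for (int b = 0; b < 2; b++) {
      int t = shift_st(s, a, b, m);
      int w = pair_weight(a, b);
      if (w < D[(size_t)s * n + t]) D[(size_t)s * n + t] = w;
    }
  }
  for (int k = 0; k < n; k++) {
    for (int i = 0; i < n; i++) {
      int dik = D[(size_t)i * n + k];
      if (dik >= INF) continue;
      int* Di = &D[(size_t)i * n];
      const int* Dk = &D[(size_t)k * n];
      for (int j = 0; j < n; j++) {
        if (Dk[j] < INF && dik + Dk[j] < Di[j]) Di[j] = dik + Dk[j];
      }
    }
    for (int i = 0; i < n; i++)
      if (D[(size_t)i * n + i] < 0) return false;
  }
  return true;
}

// [[Rcpp::export]]
bool cpp_defensible(IntegerVector actions, int m) {
  std::vector<int> act(actions.begin(), actions.end());
  return defensible_core(act, m);
}

// ---------------------------------------------------------------------------
// minimum spanning arborescence (Chu-Liu/Edmonds), used for the
// Freidlin-Wentzell W-weights; operates on an edge list
// ---------------------------------------------------------------------------
struct Edge { int u, v; double w; };

static double min_out_arborescence(int root, int n, std::vector<Edge> edges) {
  const double INF = 1e18;
  double res = 0.0;
  while (true) {
    std::vector<double> inw(n, INF);
    std::vector<int> pre(n, -1);
    for (const Edge& e : edges)
      if (e.u != e.v && e.w < inw[e.v]) { inw[e.v] = e.w; pre[e.v] = e.u; }
    for (int v = 0; v < n; v++)
      if (v != root && inw[v] >= INF / 2) return INF;
    inw[root] = 0.0;
    for (int v = 0; v < n; v++)
      if (v != root) res += inw[v];
    int cnt = 0;
    std::vector<int> id(n, -1), vis(n, -1);
    for (int v = 0; v < n; v++) {
      int u = v;
      while (u != root && vis[u] == -1 && id[u] == -1) { vis[u] = v; u = pre[u]; }
      if (u != root && id[u] == -1 && vis[u] == v) {
        int x = u;
        do { id[x] = cnt; x = pre[x]; } while (x != u);
        cnt++;
      }
    }
    if (cnt == 0) return res;
    for (int v = 0; v < n; v++)
      if (id[v] == -1) id[v] = cnt++;
    std::vector<Edge> ne;
    ne.reserve(edges.size());
    for (const Edge& e : edges) {
      int u = id[e.u], v = id[e.v];
      if (u != v) ne.push_back({u, v, e.w - inw[e.v]});
    }
    n = cnt;
    root = id[root];
    edges.swap(ne);
  }
}

// Minimum weight of an in-arborescence to `root` (every other node has one
// outgoing edge; all paths lead to root).  cost(u,v) = weight of edge u -> v;
// entries >= 1e17 (or non-finite) are treated as absent.  Returns Inf when the
// root is not reachable from some node.
// [[Rcpp::export]]
double cpp_min_arborescence(NumericMatrix cost, int root) {
  int K = cost.nrow();
  if (root < 0 || root >= K) stop("root out of range");
  if (K == 1) return 0.0;
  std::vector<Edge> edges;  // reversed: in-tree to root == out-tree from root
  for (int u = 0; u < K; u++)
    for (int v = 0; v < K; v++) {
      double w = cost(u, v);
      if (u != v && R_finite(w) && w < 1e17) edges.push_back({v, u, w});
    }
  double res = min_out_arborescence(root, K, edges);
  return (res >= 1e17) ? R_PosInf : res;
}

// ---------------------------------------------------------------------------
// zero-error limit analysis of a deterministic strategy pair:
// recurrent classes of the e=0 map, minimal flip-cost class graph, W-weights
// ---------------------------------------------------------------------------
struct LimitRes {
  std::vector<int> class_of;               // -1 = transient
  std::vector<std::vector<int>> cycles;    // states of each recurrent class
  std::vector<std::vector<double>> V;      // class-to-class minimal costs
  std::vector<double> W;                   // arborescence weights
  std::vector<int> support;                // argmin W
};

static LimitRes limit_core(const std::vector<int>& aA, const std::vector<int>& aB, int m) {
  const int n = 1 << (2 * m);
  const double INF = 1e18;
  std::vector<int> nxt(n);
  for (int s = 0; s < n; s++) nxt[s] = shift_st(s, aA[s], aB[s], m);

  LimitRes R;
  R.class_of.assign(n, -1);
  std::vector<int> colr(n, 0);  // 0 unvisited, 1 on current path, 2 done
  std::vector<int> path;
  for (int s0 = 0; s0 < n; s0++) {
    if (colr[s0]) continue;
    path.clear();
    int u = s0;
    while (colr[u] == 0) { colr[u] = 1; path.push_back(u); u = nxt[u]; }
    if (colr[u] == 1) {  // new cycle closed within this walk
      int pos = 0;
      for (int i = 0; i < (int)path.size(); i++)
        if (path[i] == u) { pos = i; break; }
      int cid = (int)R.cycles.size();
      std::vector<int> cyc;
      for (int i = pos; i < (int)path.size(); i++) {
        cyc.push_back(path[i]);
        R.class_of[path[i]] = cid;
      }
      R.cycles.push_back(cyc);
    }
    for (int x : path) colr[x] = 2;
  }

  const int K = (int)R.cycles.size();
  R.V.assign(K, std::vector<double>(K, INF));
  // Dijkstra with flip-count weights from each class; paths may pass through
  // transient states but terminate on first contact with another class
  std::vector<double> dist(n);
  std::vector<char> done(n);
  for (int c = 0; c < K; c++) {
    std::fill(dist.begin(), dist.end(), INF);
    std::fill(done.begin(), done.end(), 0);
    for (int s : R.cycles[c]) dist[s] = 0.0;
    for (int iter = 0; iter < n; iter++) {
      int u = -1;
      double best = INF;
      for (int i = 0; i < n; i++)
        if (!done[i] && dist[i] < best) { best = dist[i]; u = i; }
      if (u < 0) break;
      done[u] = 1;
      int cu = R.class_of[u];
      if (cu != -1 && cu != c) {
        if (dist[u] < R.V[c][cu]) R.V[c][cu] = dist[u];
        continue;  // do not pass through other recurrent classes
      }
      for (int a = 0; a < 2; a++)
        for (int b = 0; b < 2; b++) {
          double w = (a != aA[u]) + (b != aB[u]);
          int t = shift_st(u, a, b, m);
          if (dist[u] + w < dist[t]) dist[t] = dist[u] + w;
        }
    }
  }

  R.W.assign(K, INF);
  if (K == 1) {
    R.W[0] = 0.0;
    R.support.push_back(0);
    return R;
  }
  std::vector<Edge> redges;  // reversed class graph
  for (int i = 0; i < K; i++)
    for (int j = 0; j < K; j++)
      if (i != j && R.V[i][j] < INF / 2) redges.push_back({j, i, R.V[i][j]});
  double best = INF;
  for (int r = 0; r < K; r++) {
    R.W[r] = min_out_arborescence(r, K, redges);
    if (R.W[r] < best) best = R.W[r];
  }
  for (int r = 0; r < K; r++)
    if (R.W[r] <= best + 1e-9) R.support.push_back(r);
  return R;
}

static void pair_actions(const std::vector<int>& actA, const std::vector<int>& actB,
                         int m, std::vector<int>& aA, std::vector<int>& aB) {
  const int n = 1 << (2 * m);
  aA.resize(n);
  aB.resize(n);
  for (int s = 0; s < n; s++) {
    aA[s] = actA[s];
    aB[s] = actB[swap_st(s, m)];
  }
}

// [[Rcpp::export]]
List cpp_limit_pair(IntegerVector actionsA, IntegerVector actionsB, int m) {
  std::vector<int> actA(actionsA.begin(), actionsA.end());
  std::vector<int> actB(actionsB.begin(), actionsB.end());
  std::vector<int> aA, aB;
  pair_actions(actA, actB, m, aA, aB);
  LimitRes R = limit_core(aA, aB, m);
  int K = (int)R.cycles.size();
  List cycles(K);
  NumericMatrix V(K, K);
  NumericVector W(K);
  for (int i = 0; i < K; i++) {
    cycles[i] = wrap(R.cycles[i]);
    W[i] = (R.W[i] >= 1e17) ? R_PosInf : R.W[i];
    for (int j = 0; j < K; j++)
      V(i, j) = (R.V[i][j] >= 1e17) ? R_PosInf : R.V[i][j];
  }
  return List::create(_["class_of"] = wrap(R.class_of), _["cycles"] = cycles,
                      _["cost"] = V, _["W"] = W, _["support"] = wrap(R.support));
}

// ---------------------------------------------------------------------------
// numerical stationary distribution of a memory-m pair chain (dense Gaussian
// elimination with partial pivoting); pAc/pBc are the realized cooperation
// probabilities at each joint state (error already folded in)
// ---------------------------------------------------------------------------
static bool stationary_mem(const std::vector<double>& pAc, const std::vector<double>& pBc,
                           int m, std::vector<double>& pi) {
  const int n = 1 << (2 * m);
  std::vector<double> M((size_t)n * n, 0.0);
  for (int s = 0; s < n; s++) {
    for (int a = 0; a < 2; a++)
      for (int b = 0; b < 2; b++) {
        double pr = (a == 0 ? pAc[s] : 1.0 - pAc[s]) * (b == 0 ? pBc[s] : 1.0 - pBc[s]);
        if (pr == 0.0) continue;
        M[(size_t)s * n + shift_st(s, a, b, m)] += pr;
      }
  }
  // solve pi' (M - I) = 0 with sum(pi) = 1  ->  A x = rhs
  std::vector<double> A((size_t)n * n), rhs(n, 0.0);
  for (int j = 0; j < n; j++) A[j] = 1.0;
  rhs[0] = 1.0;
  for (int i = 1; i < n; i++)
    for (int j = 0; j < n; j++)
      A[(size_t)i * n + j] = M[(size_t)j * n + i] - (i == j ? 1.0 : 0.0);
  // gaussian elimination
  std::vector<int> perm(n);
  for (int i = 0; i < n; i++) perm[i] = i;
  for (int col = 0; col < n; col++) {
    int piv = col;
    double best = std::abs(A[(size_t)col * n + col]);
    for (int r = col + 1; r < n; r++) {
      double v = std::abs(A[(size_t)r * n + col]);
      if (v > best) { best = v; piv = r; }
    }
    if (best < 1e-14) return false;
    if (piv != col) {
      for (int j = 0; j < n; j++) std::swap(A[(size_t)piv * n + j], A[(size_t)col * n + j]);
      std::swap(rhs[piv], rhs[col]);
    }
    double d = A[(size_t)col * n + col];
    for (int r = col + 1; r < n; r++) {
      double f = A[(size_t)r * n + col] / d;
      if (f == 0.0) continue;
      for (int j = col; j < n; j++) A[(size_t)r * n + j] -= f * A[(size_t)col * n + j];
      rhs[r] -= f * rhs[col];
    }
  }
  pi.assign(n, 0.0);
  for (int i = n - 1; i >= 0; i--) {
    double v = rhs[i];
    for (int j = i + 1; j < n; j++) v -= A[(size_t)i * n + j] * pi[j];
    pi[i] = v / A[(size_t)i * n + i];
  }
  return true;
}

static void det_coop_probs(const std::vector<int>& act, int m, double e,
                           std::vector<double>& pAc, std::vector<double>& pBc) {
  const int n = 1 << (2 * m);
  pAc.resize(n);
  pBc.resize(n);
  for (int s = 0; s < n; s++) {
    pAc[s] = (act[s] == 0) ? 1.0 - e : e;
    pBc[s] = (act[swap_st(s, m)] == 0) ? 1.0 - e : e;
  }
}

// stationary mass on the full-cooperation state in noisy self-play
// [[Rcpp::export]]
double cpp_coop_mass(IntegerVector actions, int m, double e) {
  std::vector<int> act(actions.begin(), actions.end());
  std::vector<double> pAc, pBc, pi;
  det_coop_probs(act, m, e, pAc, pBc);
  if (!stationary_mem(pAc, pBc, m, pi)) return NA_REAL;
  return pi[0];
}

// same, for every id of the memory-m space (bulk oracle)
// [[Rcpp::export]]
NumericVector cpp_coop_mass_all(int m, double e) {
  if (m > 2) stop("bulk oracle only for m <= 2");
  const int n = 1 << (2 * m);
  const long N = 1L << n;
  NumericVector out(N);
  std::vector<int> act(n);
  std::vector<double> pAc, pBc, pi;
  for (long id = 0; id < N; id++) {
    for (int i = 0; i < n; i++) act[i] = (int)((id >> i) & 1L);
    det_coop_probs(act, m, e, pAc, pBc);
    out[id] = stationary_mem(pAc, pBc, m, pi) ? pi[0] : NA_REAL;
    if ((id & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}

// payoff-free numerical (pi_A - pi_B) in units of (T - S) for the pair
// (strategy, AllC) at error rate e
// [[Rcpp::export]]
double cpp_unit_diff_vs_allc(IntegerVector actions, int m, double e) {
  std::vector<int> act(actions.begin(), actions.end());
  const int n = 1 << (2 * m);
  std::vector<double> pAc(n), pBc(n), pi;
  for (int s = 0; s < n; s++) {
    pAc[s] = (act[s] == 0) ? 1.0 - e : e;
    pBc[s] = 1.0 - e;  // AllC
  }
  if (!stationary_mem(pAc, pBc, m, pi)) return NA_REAL;
  double diff = 0.0;
  for (int s = 0; s < n; s++) {
    int a = (s >> m) & 1, b = s & 1;  // most recent realized pair
    diff += pi[s] * pair_weight(a, b);
  }
  return diff;
}

// ---------------------------------------------------------------------------
// the three criteria for one deterministic strategy
// ---------------------------------------------------------------------------
static bool efficient_from_limit(const LimitRes& R, const std::vector<int>& aA,
                                 const std::vector<int>& aB) {
  for (int c : R.support)
    for (int s : R.cycles[c])
      if (aA[s] != 0 || aB[s] != 0) return false;
  return true;
}

static bool efficient_core(const std::vector<int>& act, int m) {
  std::vector<int> aA, aB;
  pair_actions(act, act, m, aA, aB);
  LimitRes R = limit_core(aA, aB, m);
  return efficient_from_limit(R, aA, aB);
}

// 1 / 0 / NA (NA never returned: numerical fallback decides ties)
static int distinguishable_core(const std::vector<int>& act, int m) {
  const int n = 1 << (2 * m);
  std::vector<int> aA(act), aB(n, 0);  // Bob is AllC
  LimitRes R = limit_core(aA, aB, m);
  bool all_gain = true, none_gain = true;
  for (int c : R.support) {
    bool defect = false;
    for (int s : R.cycles[c])
      if (aA[s] == 1) { defect = true; break; }
    if (defect) none_gain = false; else all_gain = false;
  }
  if (all_gain) return 1;
  if (none_gain) return 0;
  // several minimal classes with opposite verdicts: defer to the numerical
  // stationary payoffs at small e
  std::vector<double> pAc(n), pBc(n), pi;
  double d5 = NA_REAL, d6 = NA_REAL;
  for (int k = 0; k < 2; k++) {
    double e = (k == 0) ? 1e-5 : 1e-6;
    for (int s = 0; s < n; s++) {
      pAc[s] = (act[s] == 0) ? 1.0 - e : e;
      pBc[s] = 1.0 - e;
    }
    if (!stationary_mem(pAc, pBc, m, pi)) return 0;
    double diff = 0.0;
    for (int s = 0; s < n; s++)
      diff += pi[s] * pair_weight((s >> m) & 1, s & 1);
    if (k == 0) d5 = diff; else d6 = diff;
  }
  return (d5 > 10 * 1e-5 && d6 > 10 * 1e-6) ? 1 : 0;
}

// [[Rcpp::export]]
List cpp_classify(IntegerVector actions, int m, bool need_distinguishable = true) {
  std::vector<int> act(actions.begin(), actions.end());
  bool def = defensible_core(act, m);
  bool eff = efficient_core(act, m);
  int dist = NA_INTEGER;
  if (need_distinguishable) dist = distinguishable_core(act, m);
  return List::create(_["efficient"] = eff, _["defensible"] = def,
                      _["distinguishable"] = (dist == NA_INTEGER)
                          ? LogicalVector::create(NA_LOGICAL)
                          : LogicalVector::create(dist == 1));
}

// exhaustive classification of the whole memory-m space (m <= 2);
// distinguishability is only evaluated for the friendly rivals
// [[Rcpp::export]]
List cpp_scan(int m) {
  if (m > 2) stop("exhaustive scan only for m <= 2");
  const int n = 1 << (2 * m);
  const long N = 1L << n;
  LogicalVector eff(N), def(N);
  LogicalVector dist(N, NA_LOGICAL);
  std::vector<int> act(n);
  for (long id = 0; id < N; id++) {
    for (int i = 0; i < n; i++) act[i] = (int)((id >> i) & 1L);
    bool d = defensible_core(act, m);
    bool f = efficient_core(act, m);
    def[id] = d;
    eff[id] = f;
    if (d && f) dist[id] = (distinguishable_core(act, m) == 1);
    if ((id & 0x3FF) == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["efficient"] = eff, _["defensible"] = def,
                      _["distinguishable"] = dist);
}

// ---------------------------------------------------------------------------
// adversarial co-simulation: worst-case long-run opponent advantage
// (pi_B - pi_A, in units of T - S) over all initial joint states, when Bob
// plays a fixed deterministic memory-m strategy
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
double cpp_max_opponent_gain(IntegerVector actionsA, IntegerVector actionsB, int m) {
  std::vector<int> actA(actionsA.begin(), actionsA.end());
  std::vector<int> actB(actionsB.begin(), actionsB.end());
  const int n = 1 << (2 * m);
  std::vector<int> aA, aB;
  pair_actions(actA, actB, m, aA, aB);
  std::vector<int> nxt(n), w(n);
  for (int s = 0; s < n; s++) {
    nxt[s] = shift_st(s, aA[s], aB[s], m);
    w[s] = pair_weight(aA[s], aB[s]);
  }
  std::vector<int> stamp(n, -1), pos(n, 0), path;
  double best = R_NegInf;
  for (int s0 = 0; s0 < n; s0++) {
    path.clear();
    int u = s0, t = 0;
    while (stamp[u] != s0) {
      stamp[u] = s0;
      pos[u] = t++;
      path.push_back(u);
      u = nxt[u];
    }
    int start = pos[u], len = t - start, sum = 0;
    for (int i = start; i < t; i++) sum += w[path[i]];
    double gain = -(double)sum / len;
    if (gain > best) best = gain;
  }
  return best;
}
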