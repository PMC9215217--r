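#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Exact solver for the balanced transportation problem
//
//   min sum_ij f_ij c_ij   s.t.  f >= 0, row sums = supply, col sums = demand
//
// via the transportation (network) simplex on the bipartite spanning-tree
// basis, with a Vogel-style initial solution. Forbidden arcs arrive as +Inf
// costs and are handled with a big-M surrogate; if any such arc carries mass
// at the optimum the problem is declared infeasible.
//
// Degeneracy: no numerical perturbation is applied (it would pollute exact
// zeros such as the self-distance); instead, leaving-arc ties are broken
// lexicographically and the entering rule falls back to Bland's rule after a
// run of zero-length pivots, which precludes cycling.

namespace {

struct DSU {
  std::vector<int> p;
  explicit DSU(int n) : p(n) { for (int i = 0; i < n; ++i) p[i] = i; }
  int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
  bool join(int a, int b) {
    a = find(a); b = find(b);
    if (a == b) return false;
    p[b] = a; return true;
  }
};

} // namespace

// [[Rcpp::export]]
List transport_simplex_cpp(NumericVector supply, NumericVector demand,
                           NumericMatrix cost) {
  const int m = supply.size(), n = demand.size();
  if (cost.nrow() != m || cost.ncol() != n)
    stop("cost matrix dimensions do not match supply/demand");

  // cost copy (row-major); replace +Inf by big-M
  std::vector<double> C((size_t)m * n);
  double max_finite = 0.0;
  bool any_inf = false;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      double c = cost(i, j);
      if (!std::isfinite(c)) { any_inf = true; }
      else if (c > max_finite) max_finite = c;
    }
  const double bigM = (max_finite + 1.0) * 1e7;
  for (int i = 0; i < m; ++i)
    for (int j = 0; j < n; ++j) {
      double c = cost(i, j);
      C[(size_t)i * n + j] = std::isfinite(c) ? c : bigM;
    }

  // ---------------- Vogel initialization ----------------
  std::vector<double> a(supply.begin(), supply.end());
  std::vector<double> b(demand.begin(), demand.end());
  std::vector<char> rowAct(m, 1), colAct(n, 1);
  int nRow = m, nCol = n;
  // cached best / second-best column per row (and row per column)
  std::vector<int> r1(m, -1), r2(m, -1), c1(n, -1), c2(n, -1);
  std::vector<char> rDirty(m, 1), cDirty(n, 1);

  std::vector<int> ar, ac;          // basis arc endpoints
  std::vector<double> af;           // basis arc flows
  ar.reserve(m + n); ac.reserve(m + n); af.reserve(m + n);

  auto recompRow = [&](int i) {
    int b1 = -1, b2 = -1;
    double v1 = std::numeric_limits<double>::infinity(), v2 = v1;
    const double* row = &C[(size_t)i * n];
    for (int j = 0; j < n; ++j) {
      if (!colAct[j]) continue;
      double c = row[j];
      if (c < v1) { v2 = v1; b2 = b1; v1 = c; b1 = j; }
      else if (c < v2) { v2 = c; b2 = j; }
    }
    r1[i] = b1; r2[i] = b2; rDirty[i] = 0;
  };
  auto recompCol = [&](int j) {
    int b1 = -1, b2 = -1;
    double v1 = std::numeric_limits<double>::infinity(), v2 = v1;
    for (int i = 0; i < m; ++i) {
      if (!rowAct[i]) continue;
      double c = C[(size_t)i * n + j];
      if (c < v1) { v2 = v1; b2 = b1; v1 = c; b1 = i; }
      else if (c < v2) { v2 = c; b2 = i; }
    }
    c1[j] = b1; c2[j] = b2; cDirty[j] = 0;
  };
  auto killRow = [&](int i) {
    rowAct[i] = 0; --nRow;
    for (int j = 0; j < n; ++j)
      if (colAct[j] && (c1[j] == i || c2[j] == i)) cDirty[j] = 1;
  };
  auto killCol = [&](int j) {
    colAct[j] = 0; --nCol;
    for (int i = 0; i < m; ++i)
      if (rowAct[i] && (r1[i] == j || r2[i] == j)) rDirty[i] = 1;
  };

  while (nRow > 0 && nCol > 0) {
    if (nRow == 1) {
      int i = 0; while (!rowAct[i]) ++i;
      for (int j = 0; j < n; ++j)
        if (colAct[j]) { ar.push_back(i); ac.push_back(j); af.push_back(b[j]); }
      break;
    }
    if (nCol == 1) {
      int j = 0; while (!colAct[j]) ++j;
      for (int i = 0; i < m; ++i)
        if (rowAct[i]) { ar.push_back(i); ac.push_back(j); af.push_back(a[i]); }
      break;
    }
    // pick the active line with the largest Vogel penalty
    double best = -1.0; bool bestIsRow = true; int bestIdx = -1;
    for (int i = 0; i < m; ++i) {
      if (!rowAct[i]) continue;
      if (rDirty[i]) recompRow(i);
      double pen = (r2[i] >= 0)
        ? C[(size_t)i * n + r2[i]] - C[(size_t)i * n + r1[i]]
        : std::numeric_limits<double>::infinity();
      if (pen > best) { best = pen; bestIsRow = true; bestIdx = i; }
    }
    for (int j = 0; j < n; ++j) {
      if (!colAct[j]) continue;
      if (cDirty[j]) recompCol(j);
      double pen = (c2[j] >= 0)
        ? C[(size_t)c2[j] * n + j] - C[(size_t)c1[j] * n + j]
        : std::numeric_limits<double>::infinity();
      if (pen > best) { best = pen; bestIsRow = false; bestIdx = j; }
    }
    int i, j;
    if (bestIsRow) { i = bestIdx; j = r1[i]; } else { j = bestIdx; i = c1[j]; }
    double q = std::min(a[i], b[j]);
    ar.push_back(i); ac.push_back(j); af.push_back(q);
    a[i] -= q; b[j] -= q;
    if (a[i] <= 0.0 && b[j] <= 0.0) {
      killRow(i); b[j] = 0.0;          // degenerate: keep the column alive
    } else if (a[i] <= 0.0) {
      killRow(i);
    } else {
      killCol(j);
    }
  }

  // ---------------- complete the spanning tree ----------------
  const int V = m + n;
  DSU dsu(V);
  for (size_t k = 0; k < ar.size(); ++k) dsu.join(ar[k], m + ac[k]);
  {
    int comps = 0;
    std::vector<char> seen(V, 0);
    for (int v = 0; v < V; ++v) { int r = dsu.find(v); if (!seen[r]) { seen[r] = 1; ++comps; } }
    while (comps > 1) {
      double bestc = std::numeric_limits<double>::infinity();
      int bi = -1, bj = -1;
      for (int i = 0; i < m; ++i)
        for (int j = 0; j < n; ++j)
          if (dsu.find(i) != dsu.find(m + j) && C[(size_t)i * n + j] < bestc) {
            bestc = C[(size_t)i * n + j]; bi = i; bj = j;
          }
      ar.push_back(bi); ac.push_back(bj); af.push_back(0.0);
      dsu.join(bi, m + bj);
      --comps;
    }
  }
  int B = (int)ar.size();            // == m + n - 1

  // ---------------- network simplex ----------------
  const double costScale = std::max(1.0, max_finite);
  const double rc_tol = 1e-11 * std::max(costScale, any_inf ? bigM : costScale);
  const long max_iter = 1000L + 200L * (long)(m + n);

  std::vector<int> head(V), nxt(2 * B), to(2 * B), eid(2 * B);
  std::vector<double> u(m), v(n);
  std::vector<int> par(V), pare(V), order(V);
  std::vector<char> vis(V);

  long iters = 0;
  int status = 0;
  long degen_run = 0;
  bool bland = false;

  for (;;) {
    if (++iters > max_iter) { status = 3; break; }
    // adjacency of the current basis tree
    std::fill(head.begin(), head.end(), -1);
    for (int e = 0; e < B; ++e) {
      int x = ar[e], y = m + ac[e];
      to[2 * e] = y; eid[2 * e] = e; nxt[2 * e] = head[x]; head[x] = 2 * e;
      to[2 * e + 1] = x; eid[2 * e + 1] = e; nxt[2 * e + 1] = head[y]; head[y] = 2 * e + 1;
    }
    // potentials by BFS from node 0, and parent pointers for cycle tracing
    std::fill(vis.begin(), vis.end(), 0);
    int qh = 0, qt = 0;
    order[qt++] = 0; vis[0] = 1; par[0] = -1; pare[0] = -1;
    u[0] = 0.0;
    while (qh < qt) {
      int x = order[qh++];
      for (int h = head[x]; h != -1; h = nxt[h]) {
        int y = to[h];
        if (vis[y]) continue;
        vis[y] = 1; par[y] = x; pare[y] = eid[h];
        int e = eid[h];
        double c = C[(size_t)ar[e] * n + ac[e]];
        if (y >= m) v[y - m] = c - u[x];   // x is the row side
        else        u[y] = c - v[x - m];
        order[qt++] = y;
      }
    }
    // entering arc
    int ei = -1, ej = -1;
    if (!bland) {
      double minrc = -rc_tol;
      for (int i = 0; i < m; ++i) {
        const double* row = &C[(size_t)i * n];
        double ui = u[i];
        for (int j = 0; j < n; ++j) {
          double rc = row[j] - ui - v[j];
          if (rc < minrc) { minrc = rc; ei = i; ej = j; }
        }
      }
    } else {
      for (int i = 0; i < m && ei < 0; ++i) {
        const double* row = &C[(size_t)i * n];
        double ui = u[i];
        for (int j = 0; j < n; ++j) {
          double rc = row[j] - ui - v[j];
          if (rc < -rc_tol) { ei = i; ej = j; break; }
        }
      }
    }
    if (ei < 0) break;                 // optimal

    // cycle: tree path from col node (m+ej) back to row node ei.
    // BFS above is rooted at node 0, so walk both endpoints to their LCA.
    // Simpler: re-trace with a dedicated BFS from ei.
    std::fill(vis.begin(), vis.end(), 0);
    qh = qt = 0;
    order[qt++] = ei; vis[ei] = 1; par[ei] = -1; pare[ei] = -1;
    int target = m + ej;
    while (qh < qt && !vis[target]) {
      int x = order[qh++];
      for (int h = head[x]; h != -1; h = nxt[h]) {
        int y = to[h];
        if (vis[y]) continue;
        vis[y] = 1; par[y] = x; pare[y] = eid[h];
        order[qt++] = y;
      }
    }
    // path arcs from target up to ei; entering arc has sign +1, then
    // alternate along the (even, bipartite) cycle
    double theta = std::numeric_limits<double>::infinity();
    int leave = -1; long leave_key = -1;
    {
      int node = target, sgn = -1;
      while (node != ei) {
        int e = pare[node];
        if (sgn < 0) {
          long key = (long)ar[e] * n + ac[e];
          if (af[e] < theta - 1e-18 ||
              (af[e] <= theta + 1e-18 && (leave < 0 || key < leave_key))) {
            if (af[e] < theta) theta = af[e];
            leave = e; leave_key = key;
          }
        }
        node = par[node]; sgn = -sgn;
      }
    }
    if (leave < 0) { status = 4; break; }   // should not happen
    if (theta < 0) theta = 0;
    // apply the flow change
    {
      int node = target, sgn = -1;
      while (node != ei) {
        int e = pare[node];
        af[e] += sgn * theta;
        if (af[e] < 0) af[e] = 0;
        node = par[node]; sgn = -sgn;
      }
    }
    // replace leaving arc by entering arc
    ar[leave] = ei; ac[leave] = ej; af[leave] = theta;

    if (theta <= 1e-15) {
      if (++degen_run > (long)(m + n)) bland = true;
    } else {
      degen_run = 0; bland = false;
    }
  }

  // ---------------- collect result ----------------
  double obj = 0.0;
  bool infeasible = false;
  std::vector<int> oi, oj; std::vector<double> om;
  for (int e = 0; e < B; ++e) {
    double f = af[e];
    if (f <= 0.0) continue;
    double c0 = cost(ar[e], ac[e]);
    if (!std::isfinite(c0)) {
      if (f > 1e-9) { infeasible = true; break; }
      continue;                       // numerical dust on a forbidden arc
    }
    obj += f * c0;
    oi.push_back(ar[e] + 1); oj.push_back(ac[e] + 1); om.push_back(f);
  }
  if (infeasible) status = 2;

  return List::create(_["i"] = wrap(oi), _["j"] = wrap(oj),
                      _["mass"] = wrap(om), _["objective"] = obj,
                      _["status"] = status, _["iterations"] = (double)iters);
}
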