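// Core combinatorics for dual-graph topologies: canonical labelling of
// small multigraphs (loops allowed, edge multiplicity up to 3) and
// exhaustive generation of all valid dual-graph adjacency matrices.
//
// Validity rules enforced by the generator:
//   * symmetric, diagonal in {0,2}, off-diagonal in {0..3}
//   * per-vertex degree (row sum, loop counted as 2) at most 4
//   * total degree exactly 4n - 2 (the chain termini carry no edge)
//   * connected
#include <Rcpp.h>
#include <unordered_set>
#include <string>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------
// Equitable-style colour refinement.  Produces an ordered partition of
// the vertices that is invariant under isomorphism; the permutation
// search below only permutes vertices within cells.
// ---------------------------------------------------------------------
static std::vector<std::vector<int>> refineCells(const std::vector<int>& A,
                                                 int n) {
  std::vector<std::vector<int>> sig(n);
  std::vector<int> cellOf(n, 0);
  for (int it = 0; it < n + 2; ++it) {
    for (int v = 0; v < n; ++v) {
      std::vector<int> s;
      s.push_back(cellOf[v]);
      s.push_back(A[v * n + v]);
      std::vector<std::pair<int, int>> nb;
      for (int u = 0; u < n; ++u) {
        if (u == v) continue;
        nb.push_back(std::make_pair(cellOf[u], A[v * n + u]));
      }
      std::sort(nb.begin(), nb.end());
      for (size_t k = 0; k < nb.size(); ++k) {
        s.push_back(nb[k].first);
        s.push_back(nb[k].second);
      }
      sig[v] = s;
    }
    // order distinct signatures lexicographically -> new cell indices
    std::vector<std::vector<int>> uniq(sig.begin(), sig.end());
    std::sort(uniq.begin(), uniq.end());
    uniq.erase(std::unique(uniq.begin(), uniq.end()), uniq.end());
    int ncell = (int)uniq.size();
    std::vector<int> newCell(n);
    for (int v = 0; v < n; ++v) {
      newCell[v] = (int)(std::lower_bound(uniq.begin(), uniq.end(), sig[v]) -
                         uniq.begin());
    }
    bool stable = (newCell == cellOf);
    cellOf = newCell;
    if (stable || ncell == n) break;
  }
  int ncell = 1 + *std::max_element(cellOf.begin(), cellOf.end());
  std::vector<std::vector<int>> cells(ncell);
  for (int v = 0; v < n; ++v) cells[cellOf[v]].push_back(v);
  return cells;
}

// ---------------------------------------------------------------------
// Canonical encoding: lexicographically smallest column-wise upper
// triangle (diag first per vertex) over all cell-respecting orderings.
// ---------------------------------------------------------------------
struct CanonSearch {
  int n;
  const std::vector<int>* A;
  std::vector<int> posCell;   // which cell feeds position p
  std::vector<std::vector<int>> cells;
  std::vector<int> best, cur, perm;
  std::vector<char> used;
  bool haveBest;

  void run(const std::vector<int>& adj, int nn) {
    n = nn;
    A = &adj;
    cells = refineCells(adj, n);
    posCell.clear();
    for (size_t c = 0; c < cells.size(); ++c)
      for (size_t k = 0; k < cells[c].size(); ++k)
        posCell.push_back((int)c);
    perm.assign(n, -1);
    used.assign(n, 0);
    cur.clear();
    best.clear();
    haveBest = false;
    dfs(0, true);
  }

  void dfs(int p, bool tight) {
    if (p == n) {
      if (!haveBest || cur < best) {
        best = cur;
        haveBest = true;
      }
      return;
    }
    const std::vector<int>& cand = cells[posCell[p]];
    size_t segStart = cur.size();
    for (size_t k = 0; k < cand.size(); ++k) {
      int v = cand[k];
      if (used[v]) continue;
      cur.push_back((*A)[v * n + v]);
      for (int q = 0; q < p; ++q) cur.push_back((*A)[v * n + perm[q]]);
      bool proceed = true, childTight = tight;
      if (haveBest && tight) {
        // compare the freshly written segment against best
        int cmpres = 0;
        for (size_t t = segStart; t < cur.size(); ++t) {
          if (cur[t] != best[t]) {
            cmpres = (cur[t] < best[t]) ? -1 : 1;
            break;
          }
        }
        if (cmpres > 0) proceed = false;
        else if (cmpres < 0) childTight = false;
      }
      if (proceed) {
        used[v] = 1;
        perm[p] = v;
        dfs(p + 1, childTight);
        used[v] = 0;
        perm[p] = -1;
      }
      cur.resize(segStart);
    }
  }
};

static std::string canonKey(const std::vector<int>& A, int n) {
  CanonSearch cs;
  cs.run(A, n);
  std::string key;
  key.reserve(cs.best.size() + 1);
  key.push_back((char)('0' + n));
  for (size_t i = 0; i < cs.best.size(); ++i)
    key.push_back((char)('0' + cs.best[i]));
  return key;
}

static bool isConnected(const std::vector<int>& A, int n) {
  std::vector<int> stack, seen(n, 0);
  stack.push_back(0);
  seen[0] = 1;
  int cnt = 1;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    for (int u = 0; u < n; ++u) {
      if (u != v && !seen[u] && A[v * n + u] > 0) {
        seen[u] = 1;
        ++cnt;
        stack.push_back(u);
      }
    }
  }
  return cnt == n;
}

// ---------------------------------------------------------------------
// Generator: backtracking over the upper triangle row by row.
// ---------------------------------------------------------------------
struct EnumState {
  int n;
  std::vector<int> A, deg;
  int deficit;  // sum of (4 - degree) over finalized vertices
  std::unordered_set<std::string> seen;
  std::vector<std::vector<int>> reps;

  void run(int nn) {
    n = nn;
    A.assign(n * n, 0);
    deg.assign(n, 0);
    deficit = 0;
    fill(0, 0);
  }

  // entry (i,j) with j >= i; j == i is the loop slot
  void fill(int i, int j) {
    if (i == n) {
      if (deficit == 2 && isConnected(A, n)) {
        std::string key = canonKey(A, n);
        if (seen.insert(key).second) reps.push_back(A);
      }
      return;
    }
    int nj = (j == n - 1) ? i + 1 : j + 1;
    int ni = (j == n - 1) ? i + 1 : i;
    if (i == j) {
      for (int c = 0; c <= 2; c += 2) {
        if (deg[i] + c > 4) break;
        A[i * n + i] = c;
        deg[i] += c;
        stepRowEnd(i, j, ni, nj);
        deg[i] -= c;
        A[i * n + i] = 0;
      }
    } else {
      for (int c = 0; c <= 3; ++c) {
        if (deg[i] + c > 4 || deg[j] + c > 4) break;
        A[i * n + j] = c;
        A[j * n + i] = c;
        deg[i] += c;
        deg[j] += c;
        stepRowEnd(i, j, ni, nj);
        deg[i] -= c;
        deg[j] -= c;
        A[i * n + j] = 0;
        A[j * n + i] = 0;
      }
    }
  }

  void stepRowEnd(int i, int j, int ni, int nj) {
    if (j == n - 1) {
      // row i complete -> degree of vertex i is final
      int d = 4 - deg[i];
      if (d < 0 || deficit + d > 2) return;
      deficit += d;
      fill(ni, nj);
      deficit -= d;
    } else {
      fill(ni, nj);
    }
  }
};

static std::vector<int> matToVec(const IntegerMatrix& M) {
  int n = M.nrow();
  std::vector<int> A(n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) A[i * n + j] = M(i, j);
  return A;
}

}  // namespace

// [[Rcpp::export(name = ".cppCanonicalKey")]]
std::string cppCanonicalKey(IntegerMatrix A) {
  int n = A.nrow();
  if (A.ncol() != n) stop("adjacency matrix must be square");
  return canonKey(matToVec(A), n);
}

// [[Rcpp::export(name = ".cppEnumerate")]]
List cppEnumerate(int n) {
  if (n < 2) stop("vertex count must be at least 2");
  EnumState es;
  es.run(n);
  List out(es.reps.size());
  for (size_t k = 0; k < es.reps.size(); ++k) {
    IntegerMatrix M(n, n);
    for (int i = 0; i < n; ++i)
      for (int j = 0; j < n; ++j) M(i, j) = es.reps[k][i * n + j];
    out[k] = M;
  }
  return out;
}

// [[Rcpp::export(name = ".cppIsConnected")]]
bool cppIsConnected(IntegerMatrix A) {
  int n = A.nrow();
  return isConnected(matToVec(A), n);
}
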