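// Exact enumeration of nonnegative integer haplotype-count vectors n with
//   B n = c - s,  per-site slack s_j in a finite slack set,  sum(n) = total.
// Depth-first search with constraint propagation; see enumerate_counts() on
// the R side for the contract.  Counts fit comfortably in int (<= 2N).
#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

namespace {

struct Search {
  int L, T, maxSlack;
  std::vector<std::vector<int>> carriersOf; // per site: haplotype indices
  std::vector<std::vector<int>> sitesOf;    // per haplotype: site indices
  std::vector<int> slack;                   // sorted allowed residuals
  long maxSolutions;
  long maxNodes, nodes = 0;
  bool overflow = false, budget = false;
  std::vector<int> solN;                    // flattened solutions
  std::vector<int> solR;                    // flattened terminal residuals
  long m = 0;

  bool inSlack(int v) const {
    return std::binary_search(slack.begin(), slack.end(), v);
  }

  void emit(const std::vector<int>& n, const std::vector<int>& r) {
    if (m >= maxSolutions) { overflow = true; return; }
    solN.insert(solN.end(), n.begin(), n.end());
    solR.insert(solR.end(), r.begin(), r.end());
    ++m;
  }

  void recurse(std::vector<int> n, std::vector<int> r, int R) {
    for (;;) {
      if (overflow || budget) return;
      if (++nodes > maxNodes) { budget = true; return; }
      for (int j = 0; j < L; ++j) if (r[j] < 0) return;
      // unfixed haplotypes and per-site unfixed-carrier counts
      std::vector<int> unfixed;
      for (int i = 0; i < T; ++i) if (n[i] < 0) unfixed.push_back(i);
      if (unfixed.empty()) {
        if (R != 0) return;
        for (int j = 0; j < L; ++j) if (!inSlack(r[j])) return;
        emit(n, r);
        return;
      }
      std::vector<int> ncar(L, 0);
      for (int j = 0; j < L; ++j)
        for (int i : carriersOf[j]) if (n[i] < 0) ++ncar[j];
      for (int j = 0; j < L; ++j)
        if (ncar[j] == 0 && !inSlack(r[j])) return;
      // upper bounds
      std::vector<int> ub(unfixed.size());
      long ubSum = 0;
      for (size_t q = 0; q < unfixed.size(); ++q) {
        int i = unfixed[q], b = R;
        for (int j : sitesOf[i]) b = std::min(b, r[j]);
        if (b < 0) return;
        ub[q] = b; ubSum += b;
      }
      if (ubSum < R) return;
      // per-site coverage lower bound: carriers must be able to bring the
      // residual down into the slack range
      for (int j = 0; j < L; ++j) {
        if (r[j] <= maxSlack) continue;
        long cov = 0;
        for (int i : carriersOf[j]) if (n[i] < 0) {
          // ub of carrier i
          int b = R;
          for (int jj : sitesOf[i]) b = std::min(b, r[jj]);
          cov += std::max(b, 0);
        }
        if (cov < (long)r[j] - maxSlack) return;
      }
      // single-carrier forcing / restricted branching
      int branchI = -1;
      std::vector<int> branchVals;
      bool forced = false;
      for (int j = 0; j < L && !forced; ++j) {
        if (ncar[j] != 1) continue;
        int i = -1;
        for (int k : carriersOf[j]) if (n[k] < 0) { i = k; break; }
        int ubi = R;
        for (int jj : sitesOf[i]) ubi = std::min(ubi, r[jj]);
        std::vector<int> vals;
        for (int s : slack) {
          int v = r[j] - s;
          if (v >= 0 && v <= ubi) vals.push_back(v);
        }
        if (vals.empty()) return;
        std::sort(vals.begin(), vals.end());
        vals.erase(std::unique(vals.begin(), vals.end()), vals.end());
        if (vals.size() == 1) {
          int v = vals[0];
          n[i] = v;
          for (int jj : sitesOf[i]) r[jj] -= v;
          R -= v;
          if (R < 0) return;
          forced = true;
        } else if (branchI < 0 || vals.size() < branchVals.size()) {
          branchI = i; branchVals = vals;
        }
      }
      if (forced) continue;
      if (branchI < 0) {
        // fall back: smallest-range unfixed haplotype, values 0..ub
        size_t best = 0;
        for (size_t q = 1; q < unfixed.size(); ++q)
          if (ub[q] < ub[best]) best = q;
        branchI = unfixed[best];
        branchVals.resize(ub[best] + 1);
        for (int v = 0; v <= ub[best]; ++v) branchVals[v] = v;
      }
      for (int v : branchVals) {
        if (overflow || budget) return;
        std::vector<int> n2(n), r2(r);
        n2[branchI] = v;
        for (int jj : sitesOf[branchI]) r2[jj] -= v;
        recurse(std::move(n2), std::move(r2), R - v);
      }
      return;
    }
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_enumerate_counts")]]
List cpp_enumerate_counts(IntegerMatrix B, IntegerVector cvec, int total,
                          IntegerVector slack_set, double max_solutions,
                          double max_nodes) {
  Search s;
  s.maxNodes = (long)max_nodes;
  s.L = B.nrow(); s.T = B.ncol();
  s.carriersOf.assign(s.L, {});
  s.sitesOf.assign(s.T, {});
  for (int j = 0; j < s.L; ++j)
    for (int i = 0; i < s.T; ++i)
      if (B(j, i) == 1) { s.carriersOf[j].push_back(i); s.sitesOf[i].push_back(j); }
  s.slack.assign(slack_set.begin(), slack_set.end());
  std::sort(s.slack.begin(), s.slack.end());
  s.slack.erase(std::unique(s.slack.begin(), s.slack.end()), s.slack.end());
  s.maxSlack = s.slack.empty() ? 0 : s.slack.back();
  s.maxSolutions = (long)max_solutions;
  std::vector<int> n(s.T, -1), r(cvec.begin(), cvec.end());
  s.recurse(std::move(n), std::move(r), total);
  IntegerMatrix N((int)s.m, s.T), Rm((int)s.m, s.L);
  for (long k = 0; k < s.m; ++k) {
    for (int i = 0; i < s.T; ++i) N(k, i) = s.solN[k * s.T + i];
    for (int j = 0; j < s.L; ++j) Rm(k, j) = s.solR[k * s.L + j];
  }
  return List::create(_["n"] = N, _["resid"] = Rm,
                      _["overflow"] = s.overflow,
                      _["budget_exceeded"] = s.budget);
}
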