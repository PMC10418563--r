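#include <Rcpp.h>
#include <algorithm>
using namespace Rcpp;

// One candidate fragment pairing between a query and a reference peak.
struct Pair {
  int q, r;
  bool shifted;
  double w;
};

// Enumerate candidate peak pairs: direct (|mzq - mzr| <= tol) and, when
// allow_shift, shifted (|mzq - mzr - shift| <= tol). A pair meeting both
// conditions is recorded once, flagged direct.
static std::vector<Pair> candidates(const NumericVector& qmz,
                                    const NumericVector& qw,
                                    const NumericVector& rmz,
                                    const NumericVector& rw,
                                    double tol, double shift,
                                    bool allow_shift) {
  std::vector<Pair> out;
  const int nq = qmz.size(), nr = rmz.size();
  for (int i = 0; i < nq; ++i) {
    for (int j = 0; j < nr; ++j) {
      const double d = qmz[i] - rmz[j];
      const bool direct = std::fabs(d) <= tol;
      const bool shifted = allow_shift && !direct &&
        std::fabs(d - shift) <= tol;
      if (direct || shifted) {
        Pair p;
        p.q = i; p.r = j; p.shifted = shifted; p.w = qw[i] * rw[j];
        out.push_back(p);
      }
    }
  }
  return out;
}

// [[Rcpp::export]]
List cpp_candidate_pairs(NumericVector qmz, NumericVector qw,
                         NumericVector rmz, NumericVector rw,
                         double tol, double shift, bool allow_shift) {
  std::vector<Pair> ps = candidates(qmz, qw, rmz, rw, tol, shift, allow_shift);
  const int n = (int) ps.size();
  IntegerVector q(n), r(n);
  LogicalVector sh(n);
  NumericVector w(n);
  for (int k = 0; k < n; ++k) {
    q[k] = ps[k].q + 1; r[k] = ps[k].r + 1;
    sh[k] = ps[k].shifted; w[k] = ps[k].w;
  }
  return List::create(_["q"] = q, _["r"] = r, _["shifted"] = sh, _["w"] = w);
}

// Greedy one-to-one selection: pairs taken in descending weight, ties
// broken by smaller query index then smaller reference index; each peak
// used at most once.
// [[Rcpp::export]]
List cpp_greedy_match(NumericVector qmz, NumericVector qw,
                      NumericVector rmz, NumericVector rw,
                      double tol, double shift, bool allow_shift) {
  std::vector<Pair> ps = candidates(qmz, qw, rmz, rw, tol, shift, allow_shift);
  std::vector<int> idx(ps.size());
  for (size_t k = 0; k < ps.size(); ++k) idx[k] = (int) k;
  std::stable_sort(idx.begin(), idx.end(), [&](int a, int b) {
    if (ps[a].w != ps[b].w) return ps[a].w > ps[b].w;
    if (ps[a].q != ps[b].q) return ps[a].q < ps[b].q;
    return ps[a].r < ps[b].r;
  });
  std::vector<bool> used_q(qmz.size(), false), used_r(rmz.size(), false);
  std::vector<int> sel;
  double total = 0.0;
  for (int k : idx) {
    const Pair& p = ps[k];
    if (!used_q[p.q] && !used_r[p.r]) {
      used_q[p.q] = used_r[p.r] = true;
      sel.push_back(k);
      total += p.w;
    }
  }
  const int n = (int) sel.size();
  IntegerVector q(n), r(n);
  LogicalVector sh(n);
  NumericVector w(n);
  for (int k = 0; k < n; ++k) {
    const Pair& p = ps[sel[k]];
    q[k] = p.q + 1; r[k] = p.r + 1; sh[k] = p.shifted; w[k] = p.w;
  }
  return List::create(_["q"] = q, _["r"] = r, _["shifted"] = sh,
                      _["w"] = w, _["total"] = total);
}
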