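#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

// Exact per-level best-subset search on centred cross-products.
//
// All candidate models contain an intercept, so predictors and response are
// mean-centred once and every subset RSS is computed from the centred Gram
// matrix:  RSS(S) = y'y - 2 b'c_S + b' A_S b  with  A_S b = c_S.
// The quadratic form (rather than y'y - b'c_S) stays correct when A_S is
// singular and b is a minimum-norm pseudo-inverse solution.
//
// Subsets are visited depth-first in ascending index order, which enumerates
// index lists lexicographically; the first subset achieving a level's minimal
// RSS (within tolerance) is therefore the lexicographically smallest, and a
// later tie never replaces it.  Branch-and-bound pruning uses the monotone
// bound RSS(S) >= RSS(S union R) for any superset: a node whose bound cannot
// improve the incumbent at any reachable level (strictly, beyond tolerance)
// is cut, so pruning is exact and preserves the tie-break.

namespace {

struct LevelSearch {
  const arma::mat& A;   // centred X'X, p x p
  const arma::vec& c;   // centred X'y
  double yty;           // centred y'y (total sum of squares)
  double eps;           // tie / pruning tolerance on the RSS scale
  int p;
  bool prune;           // false = exhaustive enumeration
  int only_level;       // 0 = all levels, otherwise search this level only
  std::vector<std::vector<int>> best;
  std::vector<double> best_rss;
  long long nodes;

  LevelSearch(const arma::mat& A_, const arma::vec& c_, double yty_,
              double eps_, bool prune_, int only_level_)
      : A(A_), c(c_), yty(yty_), eps(eps_), p(A_.n_cols), prune(prune_),
        only_level(only_level_), best(p + 1), best_rss(p + 1, R_PosInf),
        nodes(0) {}

  double rss_of(const std::vector<int>& S) {
    if (S.empty()) return yty;
    arma::uvec id(S.size());
    for (std::size_t i = 0; i < S.size(); ++i) id[i] = (arma::uword)S[i];
    arma::mat As = A.submat(id, id);
    arma::vec cs = c.elem(id);
    arma::vec b;
    bool ok = arma::solve(b, As, cs,
                          arma::solve_opts::likely_sympd +
                          arma::solve_opts::no_approx);
    if (!ok) b = arma::pinv(As) * cs;
    double r = yty - 2.0 * arma::dot(b, cs) + arma::dot(b, As * b);
    return r < 0.0 ? 0.0 : r;
  }

  bool wanted(int k) const { return only_level == 0 || k == only_level; }

  void visit(std::vector<int>& C, int i) {
    ++nodes;
    int k = (int)C.size();
    if (k >= 1 && wanted(k)) {
      double r = rss_of(C);
      if (r < best_rss[k] - eps) {  // ties keep the first (lexicographic) hit
        best_rss[k] = r;
        best[k] = C;
      }
    }
    if (i >= p) return;
    if (only_level > 0 && k + (p - i) < only_level) return;  // cannot reach
    if (only_level > 0 && k >= only_level) return;           // no need deeper
    if (prune) {
      std::vector<int> full(C);
      for (int j = i; j < p; ++j) full.push_back(j);
      double bound = rss_of(full);
      bool keep = false;
      int kmax = k + (p - i);
      for (int kk = k + 1; kk <= kmax; ++kk) {
        if (wanted(kk) && bound < best_rss[kk] - eps) { keep = true; break; }
      }
      if (!keep) return;
    }
    for (int j = i; j < p; ++j) {
      C.push_back(j);
      visit(C, j + 1);
      C.pop_back();
    }
  }
};

}  // namespace

// [[Rcpp::export(name = ".level_search_cpp")]]
Rcpp::List level_search_cpp(const arma::mat& X, const arma::vec& y,
                            bool prune, double tol, int only_level) {
  const int p = X.n_cols;
  arma::mat Xc = X;
  arma::rowvec mu = arma::mean(X, 0);
  Xc.each_row() -= mu;
  arma::vec yc = y - arma::mean(y);
  arma::mat A = Xc.t() * Xc;
  arma::vec c = Xc.t() * yc;
  double yty = arma::dot(yc, yc);
  double eps = tol * std::max(yty, 1.0);

  LevelSearch s(A, c, yty, eps, prune, only_level);
  std::vector<int> C;
  C.reserve(p);
  s.visit(C, 0);

  Rcpp::LogicalMatrix sel(p, p);
  Rcpp::NumericVector rss(p, NA_REAL);
  for (int k = 1; k <= p; ++k) {
    if (only_level > 0 && k != only_level) continue;
    for (int v : s.best[k]) sel(k - 1, v) = TRUE;
    rss[k - 1] = s.best_rss[k];
  }
  return Rcpp::List::create(Rcpp::Named("selected") = sel,
                            Rcpp::Named("rss") = rss,
                            Rcpp::Named("nodes") = (double)s.nodes);
}
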