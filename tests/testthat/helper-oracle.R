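# Independent oracles used across the suite. These never call the package's
# search code: subsets are enumerated with utils::combn and fitted with
# stats::.lm.fit, so they stand apart from the C++ path they check.

# RSS of an OLS fit with intercept on predictor columns `s`
oracle_rss <- function(X, y, s) {
  sum(stats::.lm.fit(cbind(1, X[, s, drop = FALSE]), y)$residuals^2)
}

# exhaustive per-level best subsets: argmin RSS over all C(p, k) subsets,
# exact ties broken by the lexicographically smallest index list (combn
# enumerates in that order, so keeping strict improvements suffices)
oracle_level_best <- function(X, y, tol = 1e-9) {
  p <- ncol(X)
  tss <- sum((y - mean(y))^2)
  eps <- tol * max(tss, 1)
  subsets <- vector("list", p)
  rss <- rep(Inf, p)
  for (k in seq_len(p)) {
    for (s in combn(p, k, simplify = FALSE)) {
      r <- oracle_rss(X, y, s)
      if (r < rss[k] - eps) {
        rss[k] <- r
        subsets[[k]] <- s
      }
    }
  }
  list(subsets = subsets, rss = rss)
}

# normal-equations solution, independent of the qr path in fit_subset
oracle_ols <- function(X, y) {
  Z <- unname(cbind(1, X))
  drop(solve(crossprod(Z), crossprod(Z, y)))
}

# small correlated dataset used by several tests: 2-way ranking tie split at
# the AIC-best boundary (one alternative model), found by seed scan
tie_split_data <- function() {
  generate_synthetic(n = 40, p = 6, true_idx = c(1, 4), beta = c(1, 0.8),
                     rho = 0.5, seed = 22)
}
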