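---
title: "Empirical variable selection for correlated predictors: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Empirical variable selection for correlated predictors: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revs)
```

## The problem

Ecological and environmental studies routinely produce one response variable
(say, offspring condition, occupancy frequency, pollutant load) and a few
dozen candidate predictors that are themselves correlated — habitat
measurements, climate variables, morphometrics. Two standard analyses both
misbehave here. Regressing the response on *all* predictors (the full model)
drowns real effects in noise: the model can be non-significant even when it
contains significant predictors, and approximate multicollinearity makes the
least-squares coefficients unstable. Stepwise selection adds or drops one
variable at a time, so a variable whose value only shows *in combination*
with others is never entered, the result can depend on the order of the
columns in the data file, and the terminal model is a locally — not globally
— optimal choice.

This package implements regression with empirical variable selection (REVS),
which separates two questions that stepwise methods conflate: *how much
evidence does the data carry for each variable* and *how many variables does
the best model need*.

## The procedure

Given $n$ cases, a response $Y$ and predictors $X_1,\dots,X_p$:

1. **Per-level best subsets.** For every level $k = 1,\dots,p$, find the
   size-$k$ subset minimising the residual sum of squares (equivalently,
   maximising $R^2$). The result is a $p \times p$ boolean matrix whose row
   $k$ marks the members of the best $k$-variable model.
2. **Inclusion ranking.** Each variable's *empirical support* is the number
   of level-best models containing it, an integer between 1 (the variable
   appears only in the full model) and $p$ (it appears at every level).
   Because each level is searched independently, a variable that is useless
   alone but essential in combination still accumulates support — precisely
   the case one-at-a-time algorithms miss.
3. **Nested series.** Fit $p$ cumulative models: model $j$ contains the $j$
   most-supported variables. Each model reports adjusted $R^2$, the overall
   F-test $P$, and AIC.
4. **Comparison by delta-AIC.** With
   $\mathrm{AIC} = -2\log\hat L + 2K$ and
   $\Delta_i = \mathrm{AIC}_i - \mathrm{AIC}_{\min}$, the model with
   $\Delta = 0$ is best-supported and models with $\Delta \le 2$ are its
   effective equals. Because the series is nested, all competing models share
   a common core of variables and differ only in one or two additions, which
   keeps interpretation simple.
5. **Ties.** Variables with equal inclusion counts enter in dataset column
   order. That order is arbitrary, so whenever the AIC-best model's cutoff
   splits a tie group, every alternative same-size selection from the group
   is fitted and the best model is re-designated across all of them; this is
   what makes the final result invariant to the column order of the input
   file (a property the test suite exercises directly).

## Exactness of the subset search

The per-level search is exact, not heuristic. For $p \le 15$ (the
`exhaustive_threshold` default) all $2^p - 1$ subsets are enumerated. Above
that, a branch-and-bound search over the lattice of subsets uses the
monotonicity of least squares — adding a variable can only reduce the RSS —
to prune: a node whose candidate pool, taken in full, already has RSS no
better than the incumbent at some level cannot contain an improvement at
that level and is cut. Pruning removes only provably dominated subtrees, so
branch-and-bound and enumeration return identical answers; the suite checks
this equivalence against an independent `combn`-based oracle on dozens of
seeded datasets. Historical branch-and-bound implementations that report the
best model *directly* can miss the optimum when their pathway heuristics are
not exhaustive; here the search guarantees per-level optimality, and REVS
additionally uses the level matrix only as a ranking device, so its final
model never rests on a single search outcome.

Both strategies visit subsets in lexicographic index order, so an exact RSS
tie between subsets (within `tol`, default $10^{-9}$ of the total sum of
squares) resolves to the lexicographically smallest index list — a
deterministic, documented convention; the underlying backends the field has
used historically do not document theirs.

All-subset model counts grow as $2^p - 1$ (15 models at $p = 4$, over
$10^9$ at $p = 30$), which is why the predictor cap defaults to 31 (32
variable columns with the response). The cap mirrors the historical limit of
the field's standard subset-search library rather than anything intrinsic,
and `cap` raises it.

## Statistical conventions

* **AIC parameter count.** The Gaussian log-likelihood is
  $\log\hat L = -\tfrac{n}{2}\left(\log 2\pi + \log(\mathrm{RSS}/n) + 1\right)$
  and $K = k + 2$ counts the intercept and the residual variance along with
  the $k$ slopes, matching `stats::AIC` on `lm` objects. The alternative
  convention $K = k$ shifts every AIC on the same data by the constant 4, so
  all delta-AICs — the only quantities the selection consumes — are
  identical; the suite asserts this invariance on random model sets.
* **Adjusted $R^2$** uses the standard Wherry/Ezekiel form
  $1 - (1 - R^2)(n-1)/(n-k-1)$.
* **Overall $P$** is the model F-test,
  $F = (R^2/k)\,/\,((1-R^2)/(n-k-1))$ on $(k, n-k-1)$ degrees of freedom;
  the intercept-only model returns $P = 1$ by convention.
* **Support categories.** The conventional delta-AIC scale is quoted with
  gaps (0–2 very strong, 3–4 strong, 5–9 considerably less, >10 essentially
  none). The package closes the gaps into contiguous intervals $[0,2]$,
  $(2,4]$, $(4,10]$, $(10,\infty)$ so that categorisation is total, with
  boundaries resolving to the stronger category.
* **Degenerate fits.** Exact multicollinearity inside a subset gives a
  rank-deficient design; the fit falls back to the minimum-norm
  (pseudo-inverse) solution, flags itself, and warns. An RSS below
  $10^{-12}$ of the total sum of squares is treated as a perfect fit, whose
  Gaussian likelihood is unbounded: such models carry `NA` AIC and are
  excluded from delta comparison rather than reported as $-\infty$.
* **Un-fittable levels.** When $n \le k + 1$ the level-$k$ model has no
  residual degrees of freedom. The search still identifies the subset
  (RSS is well-defined), but the model is flagged un-fit and excluded from
  the AIC comparison instead of aborting the run.

## Baselines and honest validation

The comparison table fits four methods on the same data: the REVS best
model, an all-subsets comparator (the lowest-AIC model among the $p$
level-best fits), a stepwise model, and the full model. Stepwise selection
supports forward/backward/both directions under either the classical
p-value criterion (partial-F entry/removal at $\alpha = 0.05$) or the AIC
criterion, under which a step is accepted only if it improves AIC by at
least 2 — the minimum for the gain in fit to outweigh an extra parameter.
Note the asymmetry between criteria: the AIC rule always enters a predictor
whenever any first step clears the threshold, while the p-value rule can
terminate empty (the package then returns the intercept-only model with a
warning).

Split-sample validation removes `h` cases at random (seeded), reruns every
*selection procedure* — not just the final coefficient estimates — on the
remaining training cases, predicts the held-out responses, and regresses
predicted against actual values. That regression's $R^2$ is the honest fit
estimate and its residual sum of squares the honest error rate. The
"regress predicted on actual" reading is the default because it mirrors how
such validations are reported in this literature; the raw prediction-error
sum of squares $\sum(y_\mathrm{actual} - y_\mathrm{predicted})^2$ is
available via `rss_type = "prediction"`. Constant predictions (e.g. an
intercept-only model) have no defined slope, so their honest $R^2$ is 0 by
convention, with a warning. By construction the REVS series contains the
full model, so the REVS best AIC never exceeds the full model's; no such
bound exists against stepwise, whose row is reported, not asserted.

## The synthetic generator

`generate_synthetic()` emulates the structure that motivates the method:
predictors drawn from a multivariate normal with unit variances and either
AR(1) ($\mathrm{cor}(X_i, X_j) = \rho^{|i-j|}$) or exchangeable correlation,
a small set of true effects, and Gaussian noise
$Y = X\beta + \varepsilon$, $\varepsilon \sim N(0, \sigma^2)$. The defaults
— $n = 50$ cases, $p = 25$ predictors, three true effects of standardized
size 1 spread evenly across the columns, AR(1) $\rho = 0.3$, $\sigma = 1$ —
reproduce the shape of a typical nestbox-scale field study (about 50 broods
or plots, 25 habitat variables) with what ecologists would consider moderate
collinearity and signal. `duplicate` appends exact copies of a
signal column, a deliberately degenerate structure for exercising exact
collinearity handling.

What the generator does *not* emulate: non-Gaussian responses, heteroscedastic
noise, factor predictors with more than two levels, missing data, or the
block-correlation structure of real habitat surveys. Passing tests on this
generator therefore demonstrate correctness of the algorithms and the
claimed invariances, not field performance on arbitrary ecological data.

## Problem sizes and determinism

The test suite and the acceptance script size their simulations to what the
method is designed for: exhaustive-oracle comparisons at $p \le 10$ (where
the independent enumeration oracle stays cheap), a parameter-recovery study
at $n = 200$, $p = 10$ over 100 seeds, and a single branch-and-bound run at
the case-study shape $n = 50$, $p = 25$ (a few seconds). Every stochastic
component — the generator, hold-out splits, permutation checks — takes an
explicit seed and restores the caller's RNG state, so whole pipelines are
reproducible byte for byte; report files contain no timestamps for the same
reason.

## Known limitations

* Gaussian linear models only: no GLM families, weights, or robust loss.
* The inclusion ranking is a heuristic ordering device; no theoretical
  guarantee says the best subset of size $k$ is nested in the best of size
  $k + 1$, which is exactly why tie alternatives and the full nested series
  are reported rather than a single terminal model.
* Branch-and-bound worst-case time remains exponential; near-null data with
  many predictors prunes poorly. The cap and the exhaustive threshold keep
  the default envelope predictable.
* Tie groups wider than five are refused by default (`allow_wide = TRUE`
  overrides); such ties essentially never arise in continuous data and
  usually signal duplicated columns.
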