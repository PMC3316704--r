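#' Gaussian log-likelihood of an OLS fit
#'
#' Maximum log-likelihood of the normal linear model given its residual sum
#' of squares: `-(n/2) * (log(2*pi) + log(rss/n) + 1)`.
#'
#' @param rss Residual sum of squares (must be positive).
#' @param n Number of cases.
#' @return The maximised log-likelihood.
#' @export
loglik_gaussian <- function(rss, n) {
  if (n <= 0) stop("n must be positive")
  if (rss <= 0) stop("degenerate likelihood: rss must be positive")
  -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
}

#' Akaike's Information Criterion for a Gaussian linear model
#'
#' `AIC = -2 * log-likelihood + 2 * K`. The parameter count `K` is the number
#' of predictors plus 2, counting the intercept and the residual variance —
#' the convention used by [stats::AIC()] for `lm` fits. Counting only the
#' predictors would shift every AIC on the same data by the same constant, so
#' all delta-AIC values (the quantities model comparison consumes) are
#' identical under either convention.
#'
#' @param rss Residual sum of squares; must be strictly positive (a perfect
#'   fit has no finite AIC).
#' @param n Number of cases (>= 2).
#' @param k_predictors Number of slope parameters in the model.
#' @return The AIC value.
#' @examples
#' aic_gaussian(20, 20, 1)
#' @export
aic_gaussian <- function(rss, n, k_predictors) {
  if (n < 2) stop("n must be at least 2")
  if (k_predictors < 0) stop("k_predictors must be non-negative")
  -2 * loglik_gaussian(rss, n) + 2 * (k_predictors + 2)
}

#' Adjusted R-squared
#'
#' Wherry/Ezekiel adjustment `1 - (1 - r2) * (n - 1) / (n - k - 1)`, which
#' removes the spurious increase in R-squared from adding predictors (but does
#' not penalise complexity the way AIC does).
#'
#' @param r2 Coefficient of determination in `[0, 1]`.
#' @param n Number of cases.
#' @param k Number of predictors.
#' @return The adjusted value (equal to `r2` when `k = 0`).
#' @export
adjusted_r2 <- function(r2, n, k) {
  if (n <= k + 1) stop("insufficient cases: need n > k + 1")
  1 - (1 - r2) * (n - 1) / (n - k - 1)
}

# relative tolerance below which a fit is treated as numerically perfect
.PERFECT_TOL <- 1e-12

#' Fit an OLS model on a subset of predictors
#'
#' Least-squares fit of the response on the given predictor subset plus an
#' intercept, returning every summary statistic the selection machinery
#' consumes. `subset = integer(0)` fits the intercept-only (null) model.
#'
#' Exactly collinear subsets (rank-deficient designs) are fitted with the
#' minimum-norm solution via the pseudo-inverse; the returned object carries
#' `degenerate = TRUE` and a warning is raised. When the residual sum of
#' squares is numerically zero (below `1e-12` of the total sum of squares)
#' the fit is treated as perfect: `r2 = 1` and the log-likelihood/AIC are
#' `NA` (the Gaussian likelihood is unbounded).
#'
#' @param data A [revs_dataset()] object.
#' @param subset Integer column indices or character column names of the
#'   predictors to include (distinct; possibly empty).
#' @return An object of class `revs_fit`: subset indices and names,
#'   `coefficients` (intercept first), `rss`, `tss`, `r2`, `adj_r2`,
#'   `loglik`, `aic`, `K`, `f_stat`, `p_value`, `n`, `k`, flags
#'   `degenerate` and `perfect`.
#' @examples
#' d <- revs_dataset(matrix(1:6, 6, 1, dimnames = list(NULL, "x1")), 2 * (1:6) + 1)
#' fit_subset(d, "x1")
#' @export
fit_subset <- function(data, subset = integer(0)) {
  stopifnot(inherits(data, "revs_data"))
  if (is.character(subset)) {
    idx <- match(subset, colnames(data$X))
    if (anyNA(idx)) stop("unknown predictor name(s): ",
                         paste(subset[is.na(idx)], collapse = ", "))
    subset <- idx
  }
  subset <- as.integer(subset)
  if (anyDuplicated(subset)) stop("subset indices must be distinct")
  if (length(subset) && (min(subset) < 1L || max(subset) > data$p)) {
    stop("subset indices out of range")
  }
  k <- length(subset)
  n <- data$n
  if (n <= k + 1) stop("insufficient cases: need n > k + 1")

  y <- data$y
  tss <- sum((y - mean(y))^2)
  Xs <- cbind(`(Intercept)` = 1, data$X[, subset, drop = FALSE])
  qrX <- qr(Xs)
  degenerate <- qrX$rank < ncol(Xs)
  if (!degenerate) {
    beta <- qr.coef(qrX, y)
    fitted <- drop(Xs %*% beta)
  } else {
    warning("rank-deficient design (exact multicollinearity); minimum-norm fit used")
    sv <- svd(Xs)
    pos <- sv$d > max(sv$d) * 1e-12
    beta <- drop(sv$v[, pos, drop = FALSE] %*%
                   ((crossprod(sv$u[, pos, drop = FALSE], y)) / sv$d[pos]))
    names(beta) <- colnames(Xs)
    fitted <- drop(Xs %*% beta)
  }
  rss <- sum((y - fitted)^2)
  perfect <- rss <= .PERFECT_TOL * max(tss, 1)
  r2 <- if (k == 0L) 0 else if (tss <= 0) 0 else min(max(1 - rss / tss, 0), 1)
  if (perfect && k > 0L) r2 <- 1
  adj <- if (k == 0L) r2 else adjusted_r2(r2, n, k)
  if (perfect) {
    ll <- NA_real_; aic <- NA_real_
  } else {
    ll <- loglik_gaussian(rss, n)
    aic <- -2 * ll + 2 * (k + 2)
  }
  if (k == 0L) {
    fst <- NA_real_; pv <- 1
  } else if (r2 >= 1) {
    fst <- Inf; pv <- 0
  } else {
    fst <- (r2 / k) / ((1 - r2) / (n - k - 1))
    pv <- pf(fst, k, n - k - 1, lower.tail = FALSE)
  }
  structure(list(
    subset = subset, terms = colnames(data$X)[subset],
    coefficients = beta, rss = rss, tss = tss, r2 = r2, adj_r2 = adj,
    loglik = ll, aic = aic, K = k + 2L, f_stat = fst, p_value = pv,
    n = n, k = k, degenerate = degenerate, perfect = perfect,
    response_name = data$response_name
  ), class = "revs_fit")
}

#' @export
print.revs_fit <- function(x, ...) {
  rhs <- if (x$k == 0L) "1" else paste(x$terms, collapse = " + ")
  cat(sprintf("<revs_fit> %s ~ %s\n", x$response_name, rhs))
  cat(sprintf("  n = %d, k = %d, rss = %.6g, R2 = %.4f, adj R2 = %.4f\n",
              x$n, x$k, x$rss, x$r2, x$adj_r2))
  cat(sprintf("  AIC = %.4f (K = %d), P = %.4g%s\n",
              x$aic, x$K, x$p_value,
              if (x$degenerate) " [rank-deficient]" else ""))
  invisible(x)
}

#' Overall model significance
#'
#' p-value of the overall F-test of a fitted model:
#' `F = (r2 / k) / ((1 - r2) / (n - k - 1))` on `(k, n - k - 1)` degrees of
#' freedom. The intercept-only model has no test; 1 is returned by
#' convention.
#'
#' @param fit A `revs_fit` object.
#' @return The p-value.
#' @export
overall_significance <- function(fit) {
  stopifnot(inherits(fit, "revs_fit"))
  fit$p_value
}

#' Predict from a fitted subset model
#'
#' @param object A `revs_fit` object.
#' @param newdata Matrix or data frame containing (at least) the columns named
#'   in the fitted subset.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.revs_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  missing <- setdiff(object$terms, colnames(X))
  if (length(missing)) {
    stop("newdata lacks required column(s): ", paste(missing, collapse = ", "))
  }
  b <- object$coefficients
  if (object$k == 0L) return(rep(b[["(Intercept)"]], nrow(X)))
  drop(b[["(Intercept)"]] + X[, object$terms, drop = FALSE] %*% b[object$terms])
}
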