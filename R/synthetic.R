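#' Generate a correlated synthetic regression dataset
#'
#' Emulates the structure of ecological species–habitat data: moderate sample
#' size, many mutually correlated predictors, a small set of true nonzero
#' effects, Gaussian noise. Predictors are drawn from a multivariate normal
#' with unit variances and either AR(1) correlation (`cor(x_i, x_j) =
#' rho^|i-j|`) or exchangeable (equicorrelation) structure; the response is
#' `y = X beta + N(0, sigma^2)`.
#'
#' Defaults mirror a typical field dataset of this shape: 50 cases, 25
#' predictors, three true effects of standardized size 1 spread evenly across
#' the predictor set, AR(1) correlation 0.3, noise standard deviation 1.
#' `duplicate` appends exact copies of the first true predictor (named
#' `<name>_dup<i>`), a degenerate structure useful for exercising exact
#' collinearity and ranking ties.
#'
#' @param n Number of cases.
#' @param p Number of (non-duplicate) predictors.
#' @param true_idx Indices of the predictors with nonzero effects; default
#'   three indices evenly spaced over `1..p`.
#' @param beta Effect size(s), recycled over `true_idx`.
#' @param correlation `"ar1"` or `"exchangeable"`.
#' @param rho Correlation parameter, `|rho| < 1` (and `rho > -1/(p-1)` for
#'   the exchangeable structure, else the matrix is not positive definite).
#' @param sigma Noise standard deviation (> 0).
#' @param duplicate Number of exact duplicate-signal columns to append.
#' @param seed Integer seed; the dataset is bit-identical for a fixed spec +
#'   seed and the caller's random state is untouched.
#' @param cap Predictor cap forwarded to [revs_dataset()].
#' @return A [revs_dataset()] object with attribute `truth`: the list of
#'   generating parameters (including `true_idx` and `beta`).
#' @examples
#' d <- generate_synthetic(n = 50, p = 25, seed = 1)
#' attr(d, "truth")$true_idx
#' @export
generate_synthetic <- function(n = 50L, p = 25L, true_idx = NULL, beta = 1,
                               correlation = c("ar1", "exchangeable"),
                               rho = 0.3, sigma = 1, duplicate = 0L,
                               seed = NULL, cap = 31L) {
  correlation <- match.arg(correlation)
  if (abs(rho) >= 1) stop("|rho| must be < 1")
  if (sigma <= 0) stop("sigma must be positive")
  if (is.null(true_idx)) true_idx <- unique(round(seq(1, p, length.out = min(3, p))))
  if (any(true_idx < 1 | true_idx > p)) stop("true_idx out of range")
  beta <- rep_len(beta, length(true_idx))
  if (any(!is.finite(beta))) stop("beta must be finite")
  Sigma <- switch(correlation,
    ar1 = rho^abs(outer(seq_len(p), seq_len(p), "-")),
    exchangeable = matrix(rho, p, p) + diag(1 - rho, p))
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) stop("correlation matrix is not positive definite")
  dat <- .with_seed(seed, {
    X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = Sigma)
    b <- rep(0, p); b[true_idx] <- beta
    y <- drop(X %*% b) + rnorm(n, 0, sigma)
    list(X = X, y = y)
  })
  X <- dat$X
  colnames(X) <- paste0("x", seq_len(p))
  if (duplicate > 0L) {
    src <- true_idx[1]
    dup <- X[, rep(src, duplicate), drop = FALSE]
    colnames(dup) <- paste0(colnames(X)[src], "_dup", seq_len(duplicate))
    X <- cbind(X, dup)
  }
  out <- revs_dataset(X, dat$y, cap = cap)
  attr(out, "truth") <- list(n = n, p = p, true_idx = as.integer(true_idx),
                             beta = beta, correlation = correlation, rho = rho,
                             sigma = sigma, duplicate = duplicate, seed = seed)
  out
}
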