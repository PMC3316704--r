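#' Full-model regression
#'
#' Regresses the response against the complete suite of predictors — the
#' traditional comparator. Identical to the level-`p` model of the nested
#' series.
#'
#' @param data A [revs_dataset()] object with `n > p + 1`.
#' @return A [fit_subset()] fit on all predictors.
#' @export
fit_full_model <- function(data) {
  stopifnot(inherits(data, "revs_data"))
  if (data$n <= data$p + 1L) stop("insufficient cases: need n > p + 1")
  fit_subset(data, seq_len(data$p))
}

# partial F-test p-value for adding/removing one variable between nested fits
.partial_f_p <- function(rss_small, rss_big, n, k_big) {
  df2 <- n - k_big - 1L
  if (df2 <= 0 || rss_big <= 0) return(0)
  f <- (rss_small - rss_big) / (rss_big / df2)
  pf(max(f, 0), 1, df2, lower.tail = FALSE)
}

#' Stepwise regression baselines
#'
#' The classical one-at-a-time selection algorithms, provided as comparators.
#' `criterion = "pvalue"`: forward selection repeatedly adds the candidate
#' with the smallest entry p-value (partial F-test) while it is at most
#' `alpha`; backward elimination starts from the full model and removes the
#' least significant variable while its p-value exceeds `alpha`; `"both"`
#' allows removal after each entry. `criterion = "aic"`: a step is accepted
#' only if it lowers AIC by at least `min_drop` (default 2) — in backward
#' mode a variable is retained only when dropping it would raise AIC by at
#' least `min_drop`. Note that the AIC criterion always enters at least one
#' predictor if any first step clears `min_drop`, whereas the p-value
#' criterion may select none: an empty terminal model returns the
#' intercept-only fit with a warning.
#'
#' @param data A [revs_dataset()] object.
#' @param direction `"forward"`, `"backward"` or `"both"`.
#' @param criterion `"pvalue"` or `"aic"`.
#' @param alpha Entry/removal significance level for the p-value criterion.
#' @param min_drop Minimum AIC improvement per accepted step for the AIC
#'   criterion.
#' @return The terminal [fit_subset()] fit, with attributes `steps` (a data
#'   frame logging each accepted step) and `settings`.
#' @export
stepwise <- function(data, direction = c("forward", "backward", "both"),
                     criterion = c("pvalue", "aic"), alpha = 0.05,
                     min_drop = 2) {
  stopifnot(inherits(data, "revs_data"))
  direction <- match.arg(direction)
  criterion <- match.arg(criterion)
  n <- data$n; p <- data$p
  if (direction != "forward" && n <= p + 1L) {
    stop("insufficient cases for a backward start: need n > p + 1")
  }
  rss_of <- function(s) fit_subset(data, s)$rss
  aic_of <- function(s) {
    r <- rss_of(s)
    if (r <= 0) -Inf else aic_gaussian(r, n, length(s))
  }
  current <- if (direction == "backward") seq_len(p) else integer(0)
  steps <- list()
  log_step <- function(action, var, value) {
    steps[[length(steps) + 1L]] <<- data.frame(
      action = action, variable = colnames(data$X)[var], value = value,
      stringsAsFactors = FALSE)
  }

  try_add <- function() {
    cand <- setdiff(seq_len(p), current)
    cand <- cand[n > length(current) + 2L]  # room for one more slope
    if (!length(cand)) return(FALSE)
    if (criterion == "pvalue") {
      rss0 <- rss_of(current)
      pv <- vapply(cand, function(j) {
        .partial_f_p(rss0, rss_of(sort(c(current, j))), n, length(current) + 1L)
      }, 1)
      i <- which.min(pv)
      if (pv[i] <= alpha) {
        current <<- sort(c(current, cand[i])); log_step("add", cand[i], pv[i])
        return(TRUE)
      }
    } else {
      a0 <- aic_of(current)
      av <- vapply(cand, function(j) aic_of(sort(c(current, j))), 1)
      i <- which.min(av)
      if (a0 - av[i] >= min_drop) {
        current <<- sort(c(current, cand[i])); log_step("add", cand[i], av[i])
        return(TRUE)
      }
    }
    FALSE
  }
  try_remove <- function() {
    if (!length(current)) return(FALSE)
    if (criterion == "pvalue") {
      rss1 <- rss_of(current)
      pv <- vapply(current, function(j) {
        .partial_f_p(rss_of(setdiff(current, j)), rss1, n, length(current))
      }, 1)
      i <- which.max(pv)
      if (pv[i] > alpha) {
        log_step("remove", current[i], pv[i])
        current <<- setdiff(current, current[i])
        return(TRUE)
      }
    } else {
      a1 <- aic_of(current)
      av <- vapply(current, function(j) aic_of(setdiff(current, j)), 1)
      i <- which.min(av)
      if (av[i] - a1 < min_drop) {  # dropping it costs less than min_drop
        log_step("remove", current[i], av[i])
        current <<- setdiff(current, current[i])
        return(TRUE)
      }
    }
    FALSE
  }

  max_steps <- 50L * p
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > max_steps) { warning("stepwise did not stabilise; stopping"); break }
    moved <- switch(direction,
      forward = try_add(),
      backward = try_remove(),
      both = {
        m <- try_add()
        while (try_remove()) m <- TRUE
        m
      })
    if (!moved) break
  }
  if (!length(current) && criterion == "pvalue") {
    warning("no predictor met the entry criterion; returning the intercept-only model")
  }
  fit <- fit_subset(data, current)
  attr(fit, "steps") <- if (length(steps)) do.call(rbind, steps) else
    data.frame(action = character(), variable = character(), value = numeric())
  attr(fit, "settings") <- list(direction = direction, criterion = criterion,
                                alpha = alpha, min_drop = min_drop)
  fit
}

#' Split a dataset into training and hold-out cases
#'
#' Draws a uniformly random hold-out subset of size `h`, reproducibly for a
#' fixed seed. The global random-number state is left untouched.
#'
#' @param n Number of cases.
#' @param h Hold-out size, `2 <= h <= n - 3`.
#' @param seed Integer seed; `NULL` uses the current random state.
#' @return An object of class `revs_split`: `train`, `holdout` (disjoint
#'   index vectors covering `1..n`), `seed`.
#' @export
make_holdout_split <- function(n, h, seed = NULL) {
  if (h < 2 || h > n - 3) stop("holdout size h out of range [2, n - 3]")
  holdout <- sort(.with_seed(seed, sample.int(n, h)))
  structure(list(train = setdiff(seq_len(n), holdout), holdout = holdout,
                 seed = seed), class = "revs_split")
}

# run code under a seed without disturbing the caller's RNG
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.subset_rows <- function(data, rows) {
  revs_dataset(data$X[rows, , drop = FALSE], data$y[rows],
               response_name = data$response_name, cap = data$p)
}

#' Honest validation of fitted models on a hold-out sample
#'
#' For each supplied model (fitted on the training cases only), predicts the
#' response for the hold-out cases and regresses the predicted values against
#' the actual values. That regression's R-squared is the honest model-fit
#' estimate and its residual sum of squares the honest error rate: higher
#' R-squared and lower RSS mean better out-of-sample prediction.
#' `rss_type = "prediction"` reports the raw sum of squared prediction errors
#' `sum((actual - predicted)^2)` instead of the regression residual.
#' Constant (degenerate) predictions get honest R-squared 0 with a warning.
#'
#' @param data The full [revs_dataset()].
#' @param split A [make_holdout_split()] result for `data`.
#' @param fits Named list of `revs_fit` objects fitted on `split$train` only.
#' @param rss_type `"regression"` (default) or `"prediction"`.
#' @return Data frame with one row per model: `method`, `honest_r2`,
#'   `honest_rss`.
#' @export
honest_validation <- function(data, split, fits,
                              rss_type = c("regression", "prediction")) {
  stopifnot(inherits(data, "revs_data"), inherits(split, "revs_split"))
  rss_type <- match.arg(rss_type)
  stopifnot(length(intersect(split$train, split$holdout)) == 0L)
  actual <- data$y[split$holdout]
  newX <- data$X[split$holdout, , drop = FALSE]
  rows <- lapply(names(fits), function(nm) {
    pred <- predict(fits[[nm]], newX)
    if (stats::sd(pred) < 1e-12) {
      warning(sprintf("method '%s' produced constant predictions; honest R2 set to 0", nm))
      r2 <- 0
      rss <- if (rss_type == "regression") 0 else sum((actual - pred)^2)
    } else {
      m <- stats::lm(pred ~ actual)
      r2 <- summary(m)$r.squared
      rss <- if (rss_type == "regression") sum(stats::residuals(m)^2) else
        sum((actual - pred)^2)
    }
    data.frame(method = nm, honest_r2 = r2, honest_rss = rss,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare REVS against the standard regression baselines
#'
#' Runs four methods on the same dataset and reports them side by side, in
#' the layout of a published method-comparison table: the REVS best model,
#' the all-subsets comparator (the lowest-AIC model among the p level-best
#' subsets), the best stepwise model, and the full model. Each row carries
#' the adjusted R-squared, AIC, delta-AIC relative to the minimum across
#' methods, and overall P on the complete data. If `holdout` is given, the
#' four methods are refitted on the training cases alone and honest
#' R-squared/RSS from the hold-out protocol are appended (the selection
#' procedures, not just the coefficients, are rerun on the training data, so
#' the hold-out rows never influence model choice).
#'
#' By construction the REVS sequence contains the full model, so the REVS
#' row's AIC never exceeds the full model's. No such guarantee exists against
#' stepwise; its row is reported, not bounded.
#'
#' @param data A [revs_dataset()] object.
#' @param holdout Hold-out size `h`, or `NULL` (default) for no validation.
#' @param seed Seed for the random split.
#' @param stepwise_args List of arguments passed to [stepwise()].
#' @param rss_type Honest-RSS flavour, see [honest_validation()].
#' @param ... Passed to [revs()].
#' @return An object of class `revs_comparison`: a data frame with one row
#'   per method (`REVS`, `all_subsets`, `stepwise`, `full`), with the split
#'   and per-method variable lists as attributes.
#' @export
compare_methods <- function(data, holdout = NULL, seed = NULL,
                            stepwise_args = list(),
                            rss_type = c("regression", "prediction"), ...) {
  stopifnot(inherits(data, "revs_data"))
  rss_type <- match.arg(rss_type)
  run_all <- function(d) {
    r <- revs(d, ...)
    lev <- r$levels
    fitted_lv <- which(d$n > seq_len(d$p) + 1L)
    lv_fits <- lapply(fitted_lv, function(k) fit_subset(d, which(lev$matrix[k, ])))
    lv_aic <- vapply(lv_fits, function(f) f$aic, 1)
    best_lv <- lv_fits[[which.min(lv_aic)]]
    sw <- do.call(stepwise, c(list(data = d), stepwise_args))
    list(REVS = revs_best_fit(r), all_subsets = best_lv, stepwise = sw,
         full = fit_full_model(d), revs = r)
  }
  full_run <- run_all(data)
  fits <- full_run[c("REVS", "all_subsets", "stepwise", "full")]
  tab <- do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    data.frame(method = nm, k = f$k, adj_r2 = f$adj_r2, aic = f$aic,
               p_value = f$p_value, stringsAsFactors = FALSE)
  }))
  tab$delta_aic <- delta_aic(tab$aic)
  tab <- tab[, c("method", "k", "adj_r2", "aic", "delta_aic", "p_value")]
  split <- NULL
  if (!is.null(holdout)) {
    split <- make_holdout_split(data$n, holdout, seed = seed)
    train <- .subset_rows(data, split$train)
    train_fits <- run_all(train)[c("REVS", "all_subsets", "stepwise", "full")]
    hv <- honest_validation(data, split, train_fits, rss_type = rss_type)
    tab <- merge(tab, hv, by = "method", sort = FALSE)
    tab <- tab[match(c("REVS", "all_subsets", "stepwise", "full"), tab$method), ]
    rownames(tab) <- NULL
  }
  structure(tab, class = c("revs_comparison", "data.frame"),
            split = split, seed = seed,
            variables = lapply(fits, function(f) f$terms),
            revs = full_run$revs)
}

#' @export
print.revs_comparison <- function(x, ...) {
  cat("<revs_comparison> methods on the complete data")
  if (!is.null(attr(x, "split"))) {
    cat(sprintf(" + %d-case hold-out validation (seed %s)",
                length(attr(x, "split")$holdout),
                deparse(attr(x, "seed"))))
  }
  cat("\n")
  y <- as.data.frame(x)
  y$adj_r2 <- round(y$adj_r2, 4); y$aic <- round(y$aic, 2)
  y$delta_aic <- round(y$delta_aic, 2); y$p_value <- signif(y$p_value, 3)
  if ("honest_r2" %in% names(y)) {
    y$honest_r2 <- round(y$honest_r2, 4); y$honest_rss <- round(y$honest_rss, 3)
  }
  print(y, row.names = FALSE)
  invisible(x)
}
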