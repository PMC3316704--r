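test_that("the full model equals the level-p member of the series", {
  d <- generate_synthetic(n = 40, p = 5, seed = 90)
  full <- fit_full_model(d)
  lvp <- best_subset_at_level(d, 5)
  expect_equal(lvp$subset, 1:5)
  expect_equal(full$rss, lvp$fit$rss, tolerance = 1e-10)
  expect_equal(full$coefficients, lvp$fit$coefficients, tolerance = 1e-10)
  # p = 1: identical to univariate regression
  d1 <- revs_dataset(d$X[, 2, drop = FALSE], d$y)
  expect_equal(fit_full_model(d1)$coefficients,
               fit_subset(d1, 1)$coefficients)
  expect_error(fit_full_model(generate_synthetic(n = 5, p = 4, seed = 1)),
               "insufficient")
  # coefficients against the normal-equations oracle
  expect_equal(unname(full$coefficients), oracle_ols(d$X, d$y),
               tolerance = 1e-10)
})

test_that("forward selection takes a perfect predictor and stops", {
  set.seed(91)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("x", 1:3)))
  y <- 3 * X[, 2] + rnorm(20, 0, 1e-3)
  d <- revs_dataset(X, y)
  f <- stepwise(d, "forward", "pvalue")
  expect_equal(f$terms, "x2")
  f2 <- stepwise(d, "forward", "aic")
  expect_true("x2" %in% f2$terms)
})

test_that("under the null the p-value criterion usually selects nothing", {
  runs <- 40; empty <- 0
  for (s in 1:runs) {
    d <- generate_synthetic(n = 50, p = 5, true_idx = 1, beta = 0, rho = 0,
                            sigma = 1, seed = 200 + s)
    f <- suppressWarnings(stepwise(d, "forward", "pvalue"))
    if (f$k == 0) empty <- empty + 1
  }
  # with 5 independent candidates at alpha = 0.05 the no-entry probability is
  # about 0.95^5 = 0.774; allow a generous binomial band around it
  expect_gt(empty / runs, 0.55)
  expect_lt(empty / runs, 0.95)
})

test_that("a suppressor pair defeats forward selection but not the ranking", {
  set.seed(7)
  n <- 60
  z <- rnorm(n)
  x1 <- z + rnorm(n, 0, 0.1); x2 <- z + rnorm(n, 0, 0.1); x3 <- rnorm(n)
  y <- 5 * (x1 - x2) + rnorm(n, 0, 1)
  d <- revs_dataset(cbind(x1 = x1, x2 = x2, x3 = x3), y)
  sw <- suppressWarnings(stepwise(d, "forward", "pvalue"))
  expect_equal(sw$k, 0L)                       # nothing clears alpha univariately
  best <- revs_best_fit(revs(d))
  expect_setequal(best$terms, c("x1", "x2"))   # the pair is found jointly
})

test_that("AIC-criterion steps each improve by at least the minimum drop", {
  d <- generate_synthetic(n = 60, p = 8, rho = 0.3, seed = 92)
  f <- stepwise(d, "forward", "aic", min_drop = 2)
  steps <- attr(f, "steps")
  aics <- c(fit_subset(d, integer(0))$aic, steps$value)
  expect_true(all(diff(aics) <= -2))
  # backward and both terminate and return valid fits
  fb <- stepwise(d, "backward", "aic")
  expect_s3_class(fb, "revs_fit")
  fboth <- stepwise(d, "both", "pvalue")
  expect_s3_class(fboth, "revs_fit")
  fbp <- stepwise(d, "backward", "pvalue")
  # every retained term is significant at alpha
  if (fbp$k > 0) {
    rss1 <- fbp$rss
    for (j in fbp$subset) {
      p <- revs:::.partial_f_p(fit_subset(d, setdiff(fbp$subset, j))$rss,
                               rss1, d$n, fbp$k)
      expect_lte(p, 0.05)
    }
  }
})

test_that("hold-out splits are disjoint, sized and reproducible", {
  s <- make_holdout_split(50, 10, seed = 3)
  expect_length(s$train, 40)
  expect_length(s$holdout, 10)
  expect_length(intersect(s$train, s$holdout), 0)
  expect_setequal(c(s$train, s$holdout), 1:50)
  expect_identical(make_holdout_split(50, 10, seed = 3)$holdout, s$holdout)
  expect_error(make_holdout_split(50, 50), "out of range")
  expect_error(make_holdout_split(50, 1), "out of range")
  # global RNG untouched
  set.seed(1); before <- rnorm(1)
  set.seed(1); invisible(make_holdout_split(50, 10, seed = 99))
  expect_identical(rnorm(1), before)
})

test_that("honest validation scores exact and constant predictors correctly", {
  d <- generate_synthetic(n = 40, p = 3, true_idx = 1, beta = 2,
                          sigma = 1, seed = 93)
  split <- make_holdout_split(d$n, 8, seed = 5)
  train <- revs_dataset(d$X[split$train, ], d$y[split$train])
  # a fit predicting y exactly: refit on a noiseless copy of the response
  d_exact <- revs_dataset(d$X, drop(d$X %*% c(2, 0, 0)))
  train_exact <- revs_dataset(d_exact$X[split$train, ], d_exact$y[split$train])
  exact_fit <- fit_subset(train_exact, 1)
  hv <- suppressWarnings(   # lm warns on the (intended) perfect fit
    honest_validation(d_exact, split, list(exact = exact_fit)))
  expect_equal(hv$honest_r2, 1, tolerance = 1e-9)
  expect_equal(hv$honest_rss, 0, tolerance = 1e-9)
  # the training-mean predictor is degenerate: honest R2 = 0 by convention
  null_fit <- fit_subset(train, integer(0))
  expect_warning(hv0 <- honest_validation(d, split, list(null = null_fit)),
                 "constant")
  expect_equal(hv0$honest_r2, 0)
  # prediction-error flavour: raw sum of squared errors
  f <- fit_subset(train, 1)
  hvp <- honest_validation(d, split, list(m = f), rss_type = "prediction")
  pred <- predict(f, d$X[split$holdout, , drop = FALSE])
  expect_equal(hvp$honest_rss, sum((d$y[split$holdout] - pred)^2),
               tolerance = 1e-10)
})

test_that("compare_methods reports the four methods with REVS at delta 0", {
  d <- generate_synthetic(n = 50, p = 6, rho = 0.4, seed = 94)
  cmp <- compare_methods(d, holdout = 10, seed = 4)
  expect_setequal(cmp$method, c("REVS", "all_subsets", "stepwise", "full"))
  expect_equal(min(cmp$delta_aic), 0)
  # the REVS sequence contains the full model: its row is at or shares the min
  expect_equal(cmp$delta_aic[cmp$method == "REVS"], 0, tolerance = 1e-9)
  expect_true(all(c("honest_r2", "honest_rss") %in% names(cmp)))
  split <- attr(cmp, "split")
  expect_length(intersect(split$train, split$holdout), 0)

  # p = 1: all four methods coincide
  d1 <- generate_synthetic(n = 30, p = 1, true_idx = 1, beta = 1, seed = 95)
  cmp1 <- compare_methods(d1)
  expect_equal(length(unique(round(cmp1$aic, 8))), 1L)
})

test_that("REVS usually beats the full model out of sample", {
  wins <- 0; seeds <- 1:20
  for (s in seeds) {
    d <- generate_synthetic(n = 60, p = 12, true_idx = c(1, 6, 12), beta = 1,
                            rho = 0.3, sigma = 1, seed = 100 + s)
    cmp <- suppressWarnings(compare_methods(d, holdout = 10, seed = s))
    rss <- cmp$honest_rss
    names(rss) <- cmp$method
    if (rss[["REVS"]] < rss[["full"]]) wins <- wins + 1
  }
  expect_gt(wins, length(seeds) / 2)
})
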