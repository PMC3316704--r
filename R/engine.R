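#' Delta-AIC values
#'
#' `delta_i = AIC_i - AIC_min` across a set of competing models fitted to the
#' same data. The best-supported model has delta 0; actual AIC values are
#' inconsequential, only the differences matter. `NA` entries (models without
#' a finite AIC) propagate as `NA` and are excluded from the minimum.
#'
#' @param aics Non-empty numeric vector of AIC values.
#' @return Vector of deltas, same length; minimum over non-`NA` entries is 0.
#' @examples
#' delta_aic(c(156.00, 157.40, 160.71, 184.74))
#' @export
delta_aic <- function(aics) {
  if (!length(aics)) stop("empty AIC list")
  if (all(is.na(aics))) stop("no finite AIC values")
  aics - min(aics, na.rm = TRUE)
}

.SUPPORT_LABELS <- c("very strong", "strong", "considerably less",
                     "essentially none")

#' Categorise delta-AIC support
#'
#' Maps delta-AIC to the conventional support scale: `[0, 2]` very strong
#' support, `(2, 4]` strong, `(4, 10]` considerably less, `> 10` essentially
#' none. The scale is usually quoted with gaps (0–2, 3–4, 5–9, >10); the
#' intervals here close those gaps so every non-negative delta gets a
#' category, with boundaries resolved towards the stronger category (a delta
#' of exactly 2 is still "very strong").
#'
#' @param delta Non-negative delta-AIC value(s).
#' @return Factor with levels `very strong`, `strong`, `considerably less`,
#'   `essentially none`.
#' @examples
#' categorize_support(c(0, 1.4, 4.71, 28.74))
#' @export
categorize_support <- function(delta) {
  if (any(is.na(delta))) stop("delta must not be NA")
  if (any(delta < 0)) stop("delta must be non-negative")
  cut(delta, breaks = c(-Inf, 2, 4, 10, Inf), labels = .SUPPORT_LABELS,
      right = TRUE)
}

#' Build the nested model series from an inclusion ranking
#'
#' Fits `p` cumulative models: model `j` contains the `j` highest-ranked
#' variables, so model 1 holds only the variable with the most empirical
#' support, model 2 adds the next most supported, and so on — a manual
#' stepwise series whose entry order comes from empirical evidence, not a
#' one-at-a-time algorithm. Ranking ties enter in dataset column order (see
#' [resolve_tie_alternatives()] for the alternatives fitted when a tie
#' straddles the best-model boundary). Each model records the entered
#' variable and its coefficient sign, adjusted R-squared, AIC, delta-AIC and
#' overall P. Levels too large to fit (`n <= k + 1`) are flagged un-fit and
#' excluded from the delta comparison instead of aborting the series.
#'
#' @param data A [revs_dataset()] object.
#' @param ranking A [rank_by_inclusion()] result for the same dataset.
#' @return An object of class `revs_sequence`; see [revs()] for the fields.
#' @export
build_nested_sequence <- function(data, ranking) {
  stopifnot(inherits(data, "revs_data"), inherits(ranking, "revs_ranking"))
  p <- data$p
  if (length(ranking$order) != p) {
    stop("ranking and dataset disagree on the number of predictors")
  }
  models <- vector("list", p)
  fitted <- logical(p)
  for (j in seq_len(p)) {
    subset <- sort(ranking$order[seq_len(j)])
    if (data$n > j + 1L) {
      models[[j]] <- fit_subset(data, subset)
      fitted[j] <- TRUE
    }
  }
  entered <- ranking$order
  signs <- vapply(seq_len(p), function(j) {
    if (!fitted[j]) return(NA_character_)
    b <- models[[j]]$coefficients[colnames(data$X)[entered[j]]]
    if (is.na(b)) NA_character_ else if (b >= 0) "+" else "-"
  }, character(1))
  aics <- vapply(models, function(m) if (is.null(m)) NA_real_ else m$aic,
                 numeric(1))
  seq_obj <- structure(list(
    models = models, fitted = fitted, entered = as.integer(entered),
    entered_name = colnames(data$X)[entered], sign = signs,
    aic = aics, delta = delta_aic(aics),
    alternatives = list(), ranking = ranking,
    var_names = colnames(data$X), response_name = data$response_name,
    n = data$n, p = p
  ), class = "revs_sequence")
  .designate_best(seq_obj)
}

# recompute delta-AICs (over primaries + alternatives) and best-model
# designations; min delta over all candidate models is 0 by construction
.designate_best <- function(seq) {
  aic_all <- seq$aic
  alt_aic <- vapply(seq$alternatives, function(a) a$fit$aic, numeric(1))
  base <- min(c(aic_all, alt_aic), na.rm = TRUE)
  seq$delta <- seq$aic - base
  if (length(seq$alternatives)) {
    for (i in seq_along(seq$alternatives)) {
      seq$alternatives[[i]]$delta <- seq$alternatives[[i]]$fit$aic - base
    }
  }
  cand <- .candidate_table(seq)
  seq$best_by_aic <- cand$id[which.min(cand$aic)]
  seq$best_by_adj_r2 <- cand$id[which.max(cand$adj_r2)]
  seq$best_by_p <- cand$id[which.min(cand$p_value)]
  seq$competing <- cand$id[cand$delta <= 2]
  seq
}

# one row per fitted candidate model (primary + alternatives)
.candidate_table <- function(seq) {
  rows <- lapply(which(seq$fitted), function(j) {
    m <- seq$models[[j]]
    data.frame(id = paste0("M", j), level = j, alternative = FALSE,
               aic = m$aic, delta = seq$delta[j], adj_r2 = m$adj_r2,
               p_value = m$p_value, stringsAsFactors = FALSE)
  })
  arows <- lapply(seq$alternatives, function(a) {
    data.frame(id = a$id, level = a$level, alternative = TRUE,
               aic = a$fit$aic, delta = a$delta, adj_r2 = a$fit$adj_r2,
               p_value = a$fit$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, arows))
  out[!is.na(out$aic), , drop = FALSE]
}

#' Fit alternative models for ranking ties split by the best model
#'
#' Tie groups entered in dataset column order are harmless when the AIC-best
#' model contains either all or none of the tied variables. When the best
#' model's cutoff falls inside a tie group — some tied variables in, the rest
#' out — the arbitrary entry order could have hidden a better model, so every
#' alternative same-size selection from the tied group is fitted and the best
#' model is re-designated by lowest AIC over primary and alternative models.
#' Tie groups wider than `max_tie` (default 5) raise an error; set
#' `allow_wide = TRUE` to enumerate anyway with a warning.
#'
#' @param seq A `revs_sequence` from [build_nested_sequence()].
#' @param ranking The [rank_by_inclusion()] result used to build `seq`.
#' @param data The [revs_dataset()] the sequence was fitted on.
#' @param max_tie Widest tie group enumerated without `allow_wide` (default 5).
#' @param allow_wide Enumerate wider tie groups with a warning instead of
#'   erroring.
#' @return The sequence with `alternatives` populated (possibly empty) and
#'   best-model designations updated.
#' @export
resolve_tie_alternatives <- function(seq, ranking, data, max_tie = 5L,
                                     allow_wide = FALSE) {
  stopifnot(inherits(seq, "revs_sequence"), inherits(ranking, "revs_ranking"),
            inherits(data, "revs_data"))
  if (!length(ranking$tie_groups)) return(seq)
  b <- suppressWarnings(as.integer(sub("^M", "", seq$best_by_aic)))
  if (is.na(b)) return(seq)  # best already an alternative: ties resolved
  in_best <- ranking$order[seq_len(b)]
  split_groups <- Filter(function(g) {
    nin <- sum(g %in% in_best)
    nin > 0L && nin < length(g)
  }, ranking$tie_groups)
  if (!length(split_groups)) return(seq)
  alts <- list()
  for (g in split_groups) {
    if (length(g) > max_tie) {
      msg <- sprintf("tie too wide: %d variables share an inclusion count (cap %d)",
                     length(g), max_tie)
      if (!allow_wide) stop(msg)
      warning(msg, "; enumerating anyway")
    }
    inside <- intersect(g, in_best)
    core <- setdiff(in_best, g)
    choices <- combn(g, length(inside), simplify = FALSE)
    default <- sort(inside)
    t <- 0L
    for (ch in choices) {
      if (identical(sort(ch), default)) next
      t <- t + 1L
      fit <- fit_subset(data, sort(c(core, ch)))
      alts[[length(alts) + 1L]] <- list(
        id = sprintf("M%d%s", b, letters[t + 1L]), level = b,
        tie_group = as.integer(g), chosen = as.integer(sort(ch)),
        fit = fit, delta = NA_real_)
    }
  }
  seq$alternatives <- c(seq$alternatives, alts)
  .designate_best(seq)
}

#' Best-model designations of a model series
#'
#' Returns the three designations reported for a REVS series — lowest AIC
#' (the primary criterion), highest adjusted R-squared, and lowest overall P
#' — plus the set of competing models within delta-AIC 2 of the best.
#' Alternative (tie) models participate. The R-squared and P designations are
#' reported for reference; delta-AIC is the recommended basis for comparison
#' because it penalises complexity, which adjusted R-squared does not.
#'
#' @param seq A `revs_sequence`.
#' @return A list with `best_by_aic`, `best_by_adj_r2`, `best_by_p`
#'   (model ids such as `"M8"`), and `competing` (ids with delta <= 2).
#' @export
select_best <- function(seq) {
  stopifnot(inherits(seq, "revs_sequence"))
  list(best_by_aic = seq$best_by_aic, best_by_adj_r2 = seq$best_by_adj_r2,
       best_by_p = seq$best_by_p, competing = seq$competing)
}

#' Run the full REVS procedure
#'
#' Regression with Empirical Variable Selection: (1) an exact per-level
#' best-subset search finds the best k-variable model at every level
#' k = 1..p; (2) each predictor is ranked by its inclusion count across
#' those level-best models; (3) a nested series of p models is fitted in
#' rank order (ties entering in dataset column order); (4) if the AIC-best
#' model's boundary splits a tie group, the alternative same-size selections
#' are fitted too; (5) models are compared by delta-AIC, with adjusted
#' R-squared and overall P reported alongside.
#'
#' @param data A [revs_dataset()] object.
#' @param method Subset-search strategy passed to [level_matrix()].
#' @param exhaustive_threshold Largest `p` for which `"auto"` enumerates all
#'   subsets (default 15).
#' @param tol Relative RSS tolerance for search ties/pruning.
#' @param max_tie Widest ranking tie group resolved into alternatives.
#' @param allow_wide Enumerate wider tie groups with a warning.
#' @return An object of class `revs`: `levels` (the [level_matrix()]),
#'   `ranking` (the [rank_by_inclusion()]), `sequence` (the
#'   `revs_sequence`), `best` (the [select_best()] designations) and
#'   `table` (one row per candidate model, mirroring the published report
#'   layout: entered variable, relationship sign, adjusted R-squared,
#'   delta-AIC, P, support category, best-model marker).
#' @examples
#' d <- generate_synthetic(n = 60, p = 6, seed = 1)
#' r <- revs(d)
#' r$best$best_by_aic
#' @export
revs <- function(data, method = "auto", exhaustive_threshold = 15L,
                 tol = 1e-9, max_tie = 5L, allow_wide = FALSE) {
  stopifnot(inherits(data, "revs_data"))
  lev <- level_matrix(data, method = method,
                      exhaustive_threshold = exhaustive_threshold, tol = tol)
  rk <- rank_by_inclusion(lev)
  sq <- build_nested_sequence(data, rk)
  sq <- resolve_tie_alternatives(sq, rk, data, max_tie = max_tie,
                                 allow_wide = allow_wide)
  structure(list(levels = lev, ranking = rk, sequence = sq,
                 best = select_best(sq), table = revs_table(sq)),
            class = "revs")
}

#' Model-series report table
#'
#' One row per candidate model (primary models in entry order, then any tie
#' alternatives): the variable entered at that step and the sign of its
#' relationship, adjusted R-squared, delta-AIC, overall P, the delta-AIC
#' support category, and a marker for the single AIC-best model.
#'
#' @param seq A `revs_sequence` (or a `revs` result).
#' @return A data frame.
#' @export
revs_table <- function(seq) {
  if (inherits(seq, "revs")) seq <- seq$sequence
  stopifnot(inherits(seq, "revs_sequence"))
  prim <- data.frame(
    model = paste0("M", seq_len(seq$p)),
    level = seq_len(seq$p),
    alternative = FALSE,
    entered = seq$entered_name,
    sign = seq$sign,
    adj_r2 = vapply(seq$models, function(m) if (is.null(m)) NA_real_ else m$adj_r2, 1),
    aic = seq$aic,
    delta_aic = seq$delta,
    p_value = vapply(seq$models, function(m) if (is.null(m)) NA_real_ else m$p_value, 1),
    stringsAsFactors = FALSE)
  if (length(seq$alternatives)) {
    alt <- do.call(rbind, lapply(seq$alternatives, function(a) {
      repl <- setdiff(a$chosen, seq$entered[seq_len(a$level)])
      data.frame(model = a$id, level = a$level, alternative = TRUE,
                 entered = paste(seq$var_names[repl], collapse = "+"),
                 sign = NA_character_, adj_r2 = a$fit$adj_r2, aic = a$fit$aic,
                 delta_aic = a$delta, p_value = a$fit$p_value,
                 stringsAsFactors = FALSE)
    }))
    prim <- rbind(prim, alt)
  }
  ok <- !is.na(prim$delta_aic)
  prim$support <- NA_character_
  prim$support[ok] <- as.character(categorize_support(prim$delta_aic[ok]))
  prim$best <- prim$model == seq$best_by_aic
  prim
}

#' Extract the AIC-best fitted model
#'
#' Returns the `revs_fit` designated best by lowest AIC, whether it is a
#' primary member of the nested series or a tie alternative.
#'
#' @param x A `revs` result or a `revs_sequence`.
#' @return A `revs_fit` object.
#' @export
revs_best_fit <- function(x) {
  seq <- if (inherits(x, "revs")) x$sequence else x
  stopifnot(inherits(seq, "revs_sequence"))
  id <- seq$best_by_aic
  j <- suppressWarnings(as.integer(sub("^M", "", id)))
  if (!is.na(j) && id == paste0("M", j)) return(seq$models[[j]])
  Filter(function(a) a$id == id, seq$alternatives)[[1]]$fit
}

#' @export
print.revs <- function(x, ...) {
  sq <- x$sequence
  cat(sprintf("<revs> %d primary models (%d predictors, %s search)\n",
              sq$p, sq$p, x$levels$method))
  if (length(x$ranking$tie_groups)) {
    cat(sprintf("%d ranking tie group(s); %d alternative model(s) fitted\n",
                length(x$ranking$tie_groups), length(sq$alternatives)))
  }
  tab <- x$table
  tab$adj_r2 <- round(tab$adj_r2, 4)
  tab$delta_aic <- round(tab$delta_aic, 3)
  tab$p_value <- signif(tab$p_value, 3)
  tab$best <- ifelse(tab$best, "*", "")
  print(tab[, c("model", "entered", "sign", "adj_r2", "delta_aic",
                "p_value", "support", "best")], row.names = FALSE)
  cat(sprintf("best by AIC: %s; by adj R2: %s; by P: %s; competing (delta <= 2): %s\n",
              x$best$best_by_aic, x$best$best_by_adj_r2, x$best$best_by_p,
              paste(x$best$competing, collapse = ", ")))
  invisible(x)
}

#' @export
summary.revs <- function(object, ...) {
  print(object)
  invisible(object$table)
}
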