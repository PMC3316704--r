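#' Number of candidate models in all-subsets regression
#'
#' With `p` predictors there are `2^p - 1` non-empty predictor subsets, hence
#' that many candidate models: 4 predictors give 15 models, 30 give
#' 1,073,741,823. The count is returned as a double so it does not overflow
#' for `p > 30`.
#'
#' @param p Number of predictors (>= 1).
#' @return `2^p - 1`.
#' @export
count_candidate_models <- function(p) {
  if (length(p) != 1L || !is.finite(p) || p < 1 || p != floor(p)) {
    stop("p must be a positive integer")
  }
  2^p - 1
}

# shared driver for the compiled search
.run_level_search <- function(data, method, exhaustive_threshold, tol,
                              only_level = 0L) {
  method <- match.arg(method, c("auto", "exhaustive", "branch_bound"))
  if (method == "auto") {
    method <- if (data$p <= exhaustive_threshold) "exhaustive" else "branch_bound"
  }
  res <- .level_search_cpp(data$X, data$y, prune = (method == "branch_bound"),
                           tol = tol, only_level = as.integer(only_level))
  res$method <- method
  res
}

#' Best predictor subset at a given level
#'
#' Finds the size-`k` predictor subset with globally minimal residual sum of
#' squares (equivalently maximal R-squared). The search is exact: exhaustive
#' enumeration for small `p` (up to `exhaustive_threshold`), and an RSS-bound
#' branch-and-bound above it. Both strategies return identical answers; the
#' bound only removes subsets that provably cannot beat the incumbent, so —
#' unlike heuristic "pathway" searches — the optimum is never missed. Exact
#' RSS ties between subsets are broken in favour of the lexicographically
#' smallest index list.
#'
#' @param data A [revs_dataset()] object.
#' @param k Level, i.e. subset size, in `1..p`.
#' @param method `"auto"` (default), `"exhaustive"` or `"branch_bound"`.
#' @param exhaustive_threshold Largest `p` for which `"auto"` enumerates all
#'   subsets (default 15).
#' @param tol Relative RSS tolerance for ties and pruning (default `1e-9`).
#' @return A list with `subset` (sorted integer indices), `rss`, and `fit`
#'   (the corresponding [fit_subset()]).
#' @export
best_subset_at_level <- function(data, k, method = "auto",
                                 exhaustive_threshold = 15L, tol = 1e-9) {
  stopifnot(inherits(data, "revs_data"))
  if (length(k) != 1L || k < 1L || k > data$p) stop("level k out of range 1..p")
  k <- as.integer(k)
  if (data$n <= k + 1L) stop("insufficient cases: need n > k + 1")
  res <- .run_level_search(data, method, exhaustive_threshold, tol,
                           only_level = k)
  subset <- which(res$selected[k, ])
  list(subset = subset, rss = res$rss[k], fit = fit_subset(data, subset))
}

#' Level selection matrix of per-level best subsets
#'
#' Runs the exact best-subset search at every level `k = 1..p` and assembles
#' the square boolean matrix with levels as rows and variables as columns:
#' cell `(k, j)` is `TRUE` when variable `j` is in the best `k`-variable
#' model. Row `k` therefore contains exactly `k` `TRUE` entries, row `p` is
#' all `TRUE`, and the per-level R-squared is non-decreasing in `k`.
#'
#' @inheritParams best_subset_at_level
#' @return An object of class `revs_levels`: `matrix` (p x p logical with
#'   variable names as columns), `level_rss`, `level_r2`, `tss`, `method`.
#' @export
level_matrix <- function(data, method = "auto", exhaustive_threshold = 15L,
                         tol = 1e-9) {
  stopifnot(inherits(data, "revs_data"))
  res <- .run_level_search(data, method, exhaustive_threshold, tol)
  m <- res$selected
  dimnames(m) <- list(level = paste0("L", seq_len(data$p)),
                      variable = colnames(data$X))
  tss <- sum((data$y - mean(data$y))^2)
  r2 <- if (tss > 0) pmin(pmax(1 - res$rss / tss, 0), 1) else rep(0, data$p)
  structure(list(matrix = m, level_rss = as.numeric(res$rss),
                 level_r2 = as.numeric(r2), tss = tss, method = res$method),
            class = "revs_levels")
}

#' @export
print.revs_levels <- function(x, ...) {
  p <- ncol(x$matrix)
  cat(sprintf("<revs_levels> %d levels (%s search)\n", p, x$method))
  disp <- ifelse(x$matrix, "TRUE", ".")
  print(data.frame(disp, R2 = round(x$level_r2, 4), check.names = FALSE))
  invisible(x)
}

#' Empirical inclusion ranking of predictors
#'
#' Counts, for each variable, the number of level-best models that contain it
#' (a variable in 20 of 25 level-best models has empirical ranking 20) and
#' orders variables by descending count. Every count lies in `[1, p]`: the
#' least supported variable still appears in the full (level-`p`) model, the
#' most supported can appear in all `p`. Variables with equal counts form a
#' tie group; within a group the original dataset column order is preserved,
#' so entry order is reproducible.
#'
#' @param m A `revs_levels` object from [level_matrix()].
#' @return An object of class `revs_ranking`: `counts` (named integer),
#'   `order` (variable indices by descending count), `tie_groups` (list of
#'   index vectors, only groups of size >= 2).
#' @export
rank_by_inclusion <- function(m) {
  stopifnot(inherits(m, "revs_levels"))
  mat <- m$matrix
  p <- ncol(mat)
  if (nrow(mat) != p || !identical(as.integer(rowSums(mat)), seq_len(p))) {
    stop("malformed level matrix: row k must contain exactly k TRUE entries")
  }
  counts <- as.integer(colSums(mat))
  names(counts) <- colnames(mat)
  ord <- order(-counts, seq_len(p))   # stable: ties keep column order
  groups <- split(seq_len(p), counts)
  tie_groups <- lapply(unname(groups[lengths(groups) >= 2L]), as.integer)
  tie_groups <- tie_groups[order(-vapply(tie_groups, function(g) counts[g[1]], 1L))]
  structure(list(counts = counts, order = as.integer(ord),
                 tie_groups = tie_groups),
            class = "revs_ranking")
}

#' @export
print.revs_ranking <- function(x, ...) {
  cat("<revs_ranking> inclusion counts (descending):\n")
  print(x$counts[x$order])
  if (length(x$tie_groups)) {
    for (g in x$tie_groups) {
      cat("tie group:", paste(names(x$counts)[g], collapse = ", "),
          sprintf("(count %d)\n", x$counts[g[1]]))
    }
  } else cat("no ties\n")
  invisible(x)
}

#' Write the level matrix as CSV
#'
#' Dumps the TRUE/FALSE level matrix (variables as columns, levels as rows)
#' together with each level's R-squared.
#'
#' @param m A `revs_levels` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_level_matrix <- function(m, path) {
  stopifnot(inherits(m, "revs_levels"))
  df <- data.frame(level = seq_len(nrow(m$matrix)), m$matrix,
                   R2 = m$level_r2, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
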