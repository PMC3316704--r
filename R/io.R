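#' Write the full set of run reports
#'
#' Writes, under `outdir`: `sequence.csv` (the model-series table, one row per
#' primary model plus any tie alternatives, AIC-best model marked),
#' `ranking.csv` (per-variable inclusion counts and tie-group ids),
#' `level_matrix.csv` (the TRUE/FALSE level matrix with per-level R-squared),
#' optionally `comparison.csv` (the method-comparison table), and
#' `run_log.txt` (package version, dataset shape, search method, tie groups,
#' seed and configuration). Outputs are plain CSV/text and byte-identical
#' across reruns with the same inputs and configuration.
#'
#' @param x A [revs()] result.
#' @param comparison Optional [compare_methods()] result.
#' @param config Optional named list echoed into the run log (e.g. seed,
#'   input path, stepwise settings).
#' @param outdir Output directory, created if missing.
#' @return Named character vector of the files written, invisibly.
#' @export
write_reports <- function(x, comparison = NULL, config = NULL, outdir = ".") {
  stopifnot(inherits(x, "revs"))
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  if (file.access(outdir, 2) != 0) stop("output directory not writable: ", outdir)
  paths <- c(sequence = file.path(outdir, "sequence.csv"),
             ranking = file.path(outdir, "ranking.csv"),
             level_matrix = file.path(outdir, "level_matrix.csv"),
             log = file.path(outdir, "run_log.txt"))
  write.csv(x$table, paths[["sequence"]], row.names = FALSE)

  rk <- x$ranking
  group_id <- rep(NA_integer_, length(rk$counts))
  for (i in seq_along(rk$tie_groups)) group_id[rk$tie_groups[[i]]] <- i
  write.csv(data.frame(variable = names(rk$counts), count = rk$counts,
                       rank_position = match(seq_along(rk$counts), rk$order),
                       tie_group = group_id, row.names = NULL),
            paths[["ranking"]], row.names = FALSE)
  write_level_matrix(x$levels, paths[["level_matrix"]])
  if (!is.null(comparison)) {
    paths[["comparison"]] <- file.path(outdir, "comparison.csv")
    write.csv(as.data.frame(comparison), paths[["comparison"]], row.names = FALSE)
  }
  p <- x$sequence$p
  lines <- c(
    sprintf("revs version: %s", as.character(utils::packageVersion("revs"))),
    sprintf("cases: %d, predictors: %d", x$sequence$n, p),
    sprintf("search method: %s", x$levels$method),
    sprintf("primary models: %d, alternatives: %d",
            p, length(x$sequence$alternatives)),
    sprintf("tie groups: %s",
            if (length(rk$tie_groups)) {
              paste(vapply(rk$tie_groups, function(g)
                paste(names(rk$counts)[g], collapse = "+"), ""), collapse = "; ")
            } else "none"),
    sprintf("best by AIC: %s; by adj R2: %s; by P: %s",
            x$best$best_by_aic, x$best$best_by_adj_r2, x$best$best_by_p),
    sprintf("competing models (delta <= 2): %s",
            paste(x$best$competing, collapse = ", ")))
  if (!is.null(config)) {
    lines <- c(lines, "config:",
               paste0("  ", names(config), " = ",
                      vapply(config, function(v) paste(deparse(v), collapse = ""), "")))
  }
  writeLines(lines, paths[["log"]])
  invisible(paths)
}
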