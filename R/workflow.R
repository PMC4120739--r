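#' Run the interaction-discovery workflow on a dataset
#'
#' Executes the suggested analysis sequence end to end: (1) choose a loss
#' function (optionally log-transforming a skewed outcome first), (2) tune
#' ensemble size and depth by bootstrap with the one-SE rule, (3) evaluate
#' total interaction strength for the most important variables against
#' parametric-bootstrap nulls, (4) drill into two-way (and optionally
#' higher-order) interactions among the variables flagged in step 3, and
#' (5) write results and figures.  If the tuned depth is 1 the model is
#' additive by construction and interaction evaluation is skipped.
#'
#' @param data data frame with the outcome column and numeric predictors.
#' @param outcome name of the outcome column.
#' @param out_dir output directory (created if needed); `NULL` suppresses
#'   all file output.
#' @param loss `"squared"` or `"absolute"`.
#' @param log_outcome apply a natural-log transform to the outcome before
#'   fitting.
#' @param tune_args list of [tune_gbt()] arguments; set
#'   `tune_args = NULL` and supply `params` to skip tuning.
#' @param params list of [gbt()] parameters used when tuning is skipped
#'   (and as shrinkage defaults when tuning).
#' @param n_top number of most important variables screened for total
#'   interaction strength.
#' @param n_rep null replicates for the H assessments.
#' @param rows H evaluation row subsample (see [h_stat()]).
#' @param max_order highest interaction order to drill into (2-4).
#' @param stability_repeats split-sample repeats for flagged subsets
#'   (0 disables the stability check).
#' @param seed integer seed for the whole run.
#' @return list of class `"mixboost_workflow"` with the tuning object,
#'   fit, importance, H assessments per order, stability results and the
#'   manifest (also written as JSON when `out_dir` is given).
#' @export
run_workflow <- function(data, outcome, out_dir = NULL,
                         loss = c("squared", "absolute"),
                         log_outcome = FALSE,
                         tune_args = list(depths = c(1L, 2L, 3L, 6L),
                                          m.grid = c(100L, 200L, 400L),
                                          n_boot = 10L, shrinkage = 0.05),
                         params = NULL, n_top = 10L, n_rep = 50L,
                         rows = NULL, max_order = 2L,
                         stability_repeats = 0L, seed = NULL) {
  loss <- match.arg(loss)
  if (!outcome %in% names(data)) stop("no outcome column '", outcome, "'")
  if (!is.null(seed)) set.seed(seed)
  y <- data[[outcome]]
  if (log_outcome) {
    if (any(y <= 0)) stop("log transform requires a positive outcome")
    y <- log(y)
  }
  x <- data[setdiff(names(data), outcome)]
  bad <- names(x)[!vapply(x, is.numeric, logical(1))]
  if (length(bad))
    stop("non-numeric predictor column(s): ", paste(bad, collapse = ", "))
  x <- as.matrix(x)

  # step 2: tuning (or fixed parameters)
  tuned <- NULL
  if (!is.null(tune_args)) {
    tuned <- do.call(tune_gbt, c(list(x = x, y = y, loss = loss), tune_args))
    params <- list(n.trees = tuned$one_se$n.trees, depth = tuned$one_se$depth,
                   shrinkage = tuned$shrinkage,
                   bag.fraction = tuned$bag.fraction, loss = loss)
  } else if (is.null(params)) {
    stop("supply either tune_args or params")
  } else {
    params$loss <- loss
  }

  fit <- gbt_fit_params(x, y, params)
  influence <- relative_influence(fit)

  h_orders <- list()
  stability <- NULL
  interactions_evaluated <- params$depth > 1L
  if (!interactions_evaluated) {
    message("tuned depth is 1 (additive model): no interaction evaluation performed")
  } else {
    top <- names(head(influence, n_top))
    totals <- h_null(x, y, as.list(top), params, n_rep = n_rep, rows = rows,
                     fit = fit)
    h_orders[["total"]] <- totals
    flagged <- unlist(totals$subsets[totals$significant])
    if (length(flagged) >= 2 && max_order >= 2) {
      pairs <- combn_list(flagged, 2L)
      h_orders[["2"]] <- h_null(x, y, pairs, params, n_rep = n_rep,
                                rows = rows, fit = fit)
      prev <- h_orders[["2"]]
      for (ord in seq(3L, max_order)) {
        if (ord > length(flagged)) break
        seeds <- unique(unlist(prev$subsets[prev$significant]))
        if (length(seeds) < ord) break
        subs <- combn_list(seeds, ord)
        h_orders[[as.character(ord)]] <-
          h_null(x, y, subs, params, n_rep = n_rep, rows = rows, fit = fit)
        prev <- h_orders[[as.character(ord)]]
      }
    }
    if (stability_repeats > 0 && length(h_orders) > 1) {
      flagged_subs <- unlist(lapply(h_orders[-1], function(h)
        h$subsets[h$significant]), recursive = FALSE)
      if (length(flagged_subs))
        stability <- split_stability(x, y, flagged_subs, params,
                                     n_repeats = stability_repeats,
                                     null_rep = n_rep, rows = rows)
    }
  }

  res <- list(tuned = tuned, params = params, fit = fit,
              influence = influence, h = h_orders, stability = stability,
              interactions_evaluated = interactions_evaluated,
              outcome = outcome, seed = seed)
  class(res) <- "mixboost_workflow"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    files <- c(files, wf_write_csv(
      data.frame(variable = names(influence), influence = influence,
                 row.names = NULL),
      file.path(out_dir, "importance.csv")))
    if (!is.null(tuned))
      files <- c(files, wf_write_csv(tuned$grid,
                                     file.path(out_dir, "tuning_grid.csv")))
    for (nm in names(h_orders))
      files <- c(files, wf_write_csv(as.data.frame(h_orders[[nm]]),
        file.path(out_dir, paste0("h_", nm, ".csv"))))
    if (!is.null(stability))
      files <- c(files, wf_write_csv(stability,
                                     file.path(out_dir, "stability.csv")))
    files <- c(files, wf_figures(res, out_dir))
    manifest <- write_manifest(
      file.path(out_dir, "manifest.json"), command = "analyze",
      config = list(outcome = outcome, loss = loss,
                    log_outcome = log_outcome, params = params,
                    n_top = n_top, n_rep = n_rep, max_order = max_order,
                    stability_repeats = stability_repeats),
      seed = seed, files = files)
    res$manifest <- manifest
  }
  invisible(res)
}

wf_write_csv <- function(df, path) {
  write.csv(df, path, row.names = FALSE)
  path
}

wf_figures <- function(res, out_dir) {
  files <- character(0)
  f <- file.path(out_dir, "importance.png")
  grDevices::png(f, width = 720, height = 540)
  graphics::par(mar = c(4, 8, 1, 1))
  plot(res$fit)
  grDevices::dev.off()
  files <- c(files, f)
  for (nm in names(res$h)) {
    f <- file.path(out_dir, paste0("h_", nm, ".png"))
    grDevices::png(f, width = 720, height = 540)
    graphics::par(mar = c(4, 10, 2, 1))
    plot(res$h[[nm]], main = paste("Interaction strength:", nm))
    grDevices::dev.off()
    files <- c(files, f)
  }
  files
}

#' @export
print.mixboost_workflow <- function(x, ...) {
  cat("mixboost workflow result\n")
  if (!is.null(x$tuned)) print(x$tuned)
  cat("\nTop variables by relative influence:\n")
  print(round(head(x$influence, 10), 1))
  if (!x$interactions_evaluated) {
    cat("\nAdditive model (depth 1): no interaction evaluation performed\n")
  } else {
    for (nm in names(x$h)) {
      cat("\n== H assessment (", nm, ") ==\n", sep = "")
      print(x$h[[nm]])
    }
  }
  if (!is.null(x$stability)) {
    cat("\nSplit-sample stability:\n")
    print(x$stability)
  }
  invisible(x)
}

#' Write a JSON run manifest
#'
#' Records the command, configuration snapshot, seed, package version,
#' timestamp and an MD5 digest for every artifact file, so a run can be
#' audited and reproduced.
#'
#' @param path manifest file path.
#' @param command short command name.
#' @param config configuration list (must be JSON-representable).
#' @param seed integer seed used for the run (or `NULL`).
#' @param files character vector of artifact paths to digest.
#' @param extra optional named list merged into the manifest.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed = NULL,
                           files = character(0), extra = NULL) {
  digests <- if (length(files)) as.list(tools::md5sum(files)) else list()
  manifest <- c(list(
    command = command,
    package = "mixboost",
    version = as.character(utils::packageVersion("mixboost")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config = config,
    artifacts = digests
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(manifest)
}
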