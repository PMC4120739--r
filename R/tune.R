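#' Bootstrap grid tuning of ensemble size and tree depth
#'
#' Evaluates every combination of tree depth and ensemble size on
#' out-of-bootstrap data.  Each replicate draws a bootstrap sample, fits
#' one ensemble per depth to the largest requested size, and scores staged
#' predictions on the observations left out of the bootstrap sample at
#' every size in `m.grid` -- so one fit serves the whole size axis.
#' Performance is summarized as the out-of-bootstrap
#' \eqn{R^2 = 1 - \mathrm{MSE}/\mathrm{Var}(y_{\mathrm{holdout}})} and RMSE,
#' averaged over replicates with a standard error across replicates.
#'
#' Two parameter choices are reported: the grid point with the largest
#' mean \eqn{R^2}, and the one-standard-error choice -- the most
#' parsimonious point (smallest depth, then smallest size) whose mean
#' \eqn{R^2} is within one SE of the maximum.  Shrinkage and the
#' subsampling fraction are held fixed.
#'
#' The default grid is a desk-scale budget; `full = TRUE` switches to the
#' exhaustive grid (sizes 100, 200, ..., 12000; depths 1-10; 250
#' replicates), which is hours of computation on one CPU.
#'
#' @param x predictor data (all numeric).
#' @param y outcome vector.
#' @param depths integer vector of tree depths to evaluate.
#' @param m.grid increasing integer vector of ensemble sizes.
#' @param n_boot number of bootstrap replicates.
#' @param shrinkage,bag.fraction,loss,min.obs passed to [gbt()].
#' @param full use the exhaustive grid and 250 replicates.
#' @return object of class `"gbt_tune"`: list with `grid` (data frame of
#'   `depth`, `n.trees`, `rmse`, `r2`, `r2_se`), `optimal` and `one_se`
#'   (single-row data frames), and the budgets used.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(150 * 4), 150, 4)
#' y <- x[, 1] + x[, 1] * x[, 2] + rnorm(150)
#' tn <- tune_gbt(x, y, depths = 1:2, m.grid = c(50, 100), n_boot = 5,
#'                shrinkage = 0.1)
#' tn$one_se
#' @export
tune_gbt <- function(x, y, depths = 1:8, m.grid = seq(500L, 6000L, 500L),
                     n_boot = 25L, shrinkage = 0.0025, bag.fraction = 0.5,
                     loss = "squared", min.obs = 10L, full = FALSE) {
  if (full) {
    depths <- 1:10; m.grid <- seq(100L, 12000L, 100L); n_boot <- 250L
  }
  m.grid <- sort(unique(as.integer(m.grid)))
  if (n_boot < 2) stop("n_boot must be >= 2")
  xm <- as.matrix(x); storage.mode(xm) <- "double"
  n <- nrow(xm)
  mmax <- max(m.grid)

  r2 <- array(NA_real_, c(n_boot, length(depths), length(m.grid)))
  rmse <- array(NA_real_, c(n_boot, length(depths), length(m.grid)))

  for (b in seq_len(n_boot)) {
    repeat {
      bidx <- sample(n, n, replace = TRUE)
      oob <- setdiff(seq_len(n), bidx)
      if (length(oob) >= 2L) break
    }
    yo <- y[oob]
    vo <- var(yo)
    for (di in seq_along(depths)) {
      fit <- gbt.default(xm[bidx, , drop = FALSE], y[bidx], n.trees = mmax,
                         depth = depths[di], shrinkage = shrinkage,
                         bag.fraction = bag.fraction, loss = loss,
                         min.obs = min.obs)
      pred <- staged_predict(fit, xm[oob, , drop = FALSE], m.grid)
      mse <- colMeans((yo - pred)^2)
      rmse[b, di, ] <- sqrt(mse)
      r2[b, di, ] <- 1 - mse / vo
    }
  }

  grid <- expand.grid(n.trees = m.grid, depth = depths,
                      KEEP.OUT.ATTRS = FALSE)[, c(2, 1)]
  mean_r2 <- as.vector(t(apply(r2, c(2, 3), mean)))
  se_r2 <- as.vector(t(apply(r2, c(2, 3), sd))) / sqrt(n_boot)
  mean_rmse <- as.vector(t(apply(rmse, c(2, 3), mean)))
  grid$rmse <- mean_rmse
  grid$r2 <- mean_r2
  grid$r2_se <- se_r2

  optimal <- grid[one_se_rule(grid, se_factor = 0), , drop = FALSE]
  one_se <- grid[one_se_rule(grid), , drop = FALSE]

  structure(list(grid = grid, optimal = optimal, one_se = one_se,
                 n_boot = n_boot, shrinkage = shrinkage,
                 bag.fraction = bag.fraction, loss = loss),
            class = "gbt_tune")
}

#' One-standard-error selection on a tuning grid
#'
#' Given a tuning grid with mean performance and its standard error,
#' returns the row index of the most parsimonious configuration (smallest
#' `depth`, then smallest `n.trees`) whose mean `r2` is at least the
#' maximum mean `r2` minus `se_factor` times the SE at the maximizing row.
#' `se_factor = 0` returns the maximizing row itself (ties broken by
#' parsimony).
#'
#' @param grid data frame with columns `depth`, `n.trees`, `r2`, `r2_se`.
#' @param se_factor multiple of the SE defining the tolerance band.
#' @return single row index into `grid`.
#' @export
one_se_rule <- function(grid, se_factor = 1) {
  stopifnot(all(c("depth", "n.trees", "r2", "r2_se") %in% names(grid)))
  best <- which(grid$r2 == max(grid$r2))
  # parsimony order among ties at the maximum
  best <- best[order(grid$depth[best], grid$n.trees[best])][1]
  thr <- grid$r2[best] - se_factor * grid$r2_se[best]
  ok <- which(grid$r2 >= thr)
  ok[order(grid$depth[ok], grid$n.trees[ok])][1]
}

#' @export
print.gbt_tune <- function(x, ...) {
  cat("Bootstrap tuning over", nrow(x$grid), "grid points,",
      x$n_boot, "replicates\n")
  cat("  optimal:  depth", x$optimal$depth, ", n.trees", x$optimal$n.trees,
      sprintf(", R2 %.3f (RMSE %.3f)\n", x$optimal$r2, x$optimal$rmse))
  cat("  one SE :  depth", x$one_se$depth, ", n.trees", x$one_se$n.trees,
      sprintf(", R2 %.3f (RMSE %.3f)\n", x$one_se$r2, x$one_se$rmse))
  invisible(x)
}

#' Plot tuning curves
#'
#' Out-of-bootstrap \eqn{R^2} against ensemble size, one line per depth,
#' with the one-SE choice marked.
#'
#' @param x a [tune_gbt()] result.
#' @param ... passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.gbt_tune <- function(x, ...) {
  depths <- sort(unique(x$grid$depth))
  msizes <- sort(unique(x$grid$n.trees))
  z <- matrix(x$grid$r2, length(msizes), length(depths))
  graphics::matplot(msizes, z, type = "l", lty = 1, col = seq_along(depths),
                    xlab = "Number of trees", ylab = "Bootstrap R2", ...)
  graphics::legend("bottomright", legend = paste("depth", depths),
                   col = seq_along(depths), lty = 1, cex = 0.8)
  graphics::points(x$one_se$n.trees, x$one_se$r2, pch = 19)
  invisible(x)
}
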