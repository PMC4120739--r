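#' Fit a stochastic gradient boosted regression-tree ensemble
#'
#' Builds an additive expansion of shallow regression trees by gradient
#' boosting.  Starting from a constant (the mean of `y` for squared-error
#' loss, the median for absolute-error loss), each iteration draws a random
#' subsample of fraction `bag.fraction` without replacement, fits a
#' least-squares tree of maximum depth `depth` to the negative gradient of
#' the loss (the residual for squared error, its sign for absolute error),
#' replaces the terminal values by the loss-optimal constant of each leaf
#' (mean or median of the raw residuals), and adds the tree scaled by
#' `shrinkage`.  A tree of depth \eqn{d} can represent interactions of at
#' most order \eqn{d}; `depth = 1` yields a purely additive model.
#'
#' Every node stores the fraction of the subsample passing through it and
#' the decrease in residual sum of squares achieved by its split.  These
#' statistics drive the data-free partial-dependence recursion
#' ([partial_dependence()]) and the split-improvement variable importance
#' ([relative_influence()]).
#'
#' @param x predictors: a numeric matrix or data frame with no missing
#'   values (for the default method), or a model formula.
#' @param y numeric response vector.
#' @param n.trees number of trees \eqn{M}.
#' @param depth tree complexity \eqn{d}: the number of splits per tree,
#'   placed best-first, giving \eqn{d + 1} terminal nodes and bounding the
#'   representable interaction order by \eqn{d} (no root-to-leaf path has
#'   more than \eqn{d} splits).  `depth = 1` fits stumps.
#' @param shrinkage learning rate \eqn{\lambda} in (0, 1].
#' @param bag.fraction subsampling fraction \eqn{\eta} in (0, 1]; 0.5 is the
#'   customary value.
#' @param loss `"squared"` or `"absolute"` error loss.
#' @param min.obs minimum number of observations in a terminal node.
#' @param seed optional integer; when supplied, `set.seed(seed)` is called
#'   before fitting so that the subsampling sequence is reproducible.
#' @param data data frame for the formula method.
#' @param formula model formula; the response must be numeric and all
#'   predictors numeric (code binary factors as 0/1 beforehand).
#' @param ... passed between methods.
#'
#' @return An object of class `"gbt"`: a list with components `init` (the
#'   constant \eqn{\alpha}), `trees` (one matrix per tree: columns `var`,
#'   `split`, `left`, `right`, `value`, `weight`, `improvement`; `var = 0`
#'   marks a leaf and node indices are 1-based), `fitted`, and the fitting
#'   parameters.  Predictions are
#'   \eqn{\alpha + \lambda \sum_m \mathrm{tree}_m(x)}.
#' @seealso [predict.gbt()], [relative_influence()], [partial_dependence()],
#'   [h_stat()], [tune_gbt()]
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] + x[, 1] * x[, 2] + rnorm(200, sd = 0.5)
#' fit <- gbt(x, y, n.trees = 50, depth = 2, shrinkage = 0.1)
#' fit
#' relative_influence(fit)
#' @export
gbt <- function(x, ...) UseMethod("gbt")

#' @rdname gbt
#' @export
gbt.formula <- function(formula, data, ...) {
  mf <- model.frame(formula, data, na.action = na.fail)
  y <- model.response(mf)
  xcols <- mf[, -1L, drop = FALSE]
  fit <- gbt.default(xcols, y, ...)
  fit$call <- match.call()
  fit
}

#' @rdname gbt
#' @export
gbt.default <- function(x, y, n.trees = 100L, depth = 3L, shrinkage = 0.0025,
                        bag.fraction = 0.5, loss = c("squared", "absolute"),
                        min.obs = 10L, seed = NULL, ...) {
  loss <- match.arg(loss)
  xm <- as.matrix(x)
  if (!is.numeric(xm)) stop("all predictors must be numeric")
  storage.mode(xm) <- "double"
  if (is.null(colnames(xm))) colnames(xm) <- paste0("x", seq_len(ncol(xm)))
  y <- as.numeric(y)
  if (length(y) != nrow(xm)) stop("length(y) must equal nrow(x)")
  if (anyNA(xm) || anyNA(y) || any(!is.finite(y)))
    stop("missing or non-finite values are not supported")
  if (n.trees < 0) stop("n.trees must be >= 0")
  if (depth < 1) stop("depth must be >= 1")
  if (shrinkage <= 0 || shrinkage > 1) stop("shrinkage must be in (0, 1]")
  if (bag.fraction <= 0 || bag.fraction > 1)
    stop("bag.fraction must be in (0, 1]")
  if (nrow(xm) < 2L * min.obs)
    stop("need at least 2 * min.obs observations")
  if (!is.null(seed)) set.seed(seed)

  core <- gbt_fit_cpp(xm, y, as.integer(n.trees), as.integer(depth),
                      shrinkage, bag.fraction, if (loss == "squared") 0L else 1L,
                      as.integer(min.obs))

  structure(list(
    init = core$init,
    trees = core$trees,
    fitted = core$fitted,
    n.trees = as.integer(n.trees),
    depth = as.integer(depth),
    shrinkage = shrinkage,
    bag.fraction = bag.fraction,
    loss = loss,
    min.obs = as.integer(min.obs),
    var.names = colnames(xm),
    y = y,
    call = match.call()
  ), class = "gbt")
}

#' Predict from a boosted tree ensemble
#'
#' @param object a [gbt()] fit.
#' @param newdata matrix or data frame containing the training columns;
#'   omitted means the training data fitted values are returned.
#' @param n.trees number of leading trees to use (staged prediction);
#'   defaults to the full ensemble.  `n.trees = 0` returns the constant
#'   initial fit.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.gbt <- function(object, newdata = NULL, n.trees = NULL, ...) {
  if (is.null(n.trees)) n.trees <- object$n.trees
  if (n.trees > object$n.trees)
    stop("n.trees exceeds the ", object$n.trees, " trees in the ensemble")
  if (is.null(newdata)) {
    if (n.trees == object$n.trees) return(object$fitted)
    stop("supply newdata for staged predictions")
  }
  xm <- gbt_newdata(object, newdata)
  gbt_predict_cpp(object$trees, object$init, object$shrinkage, xm,
                  as.integer(n.trees))
}

# align newdata columns with the training design
gbt_newdata <- function(object, newdata) {
  xm <- as.matrix(newdata)
  if (!is.null(colnames(xm))) {
    missing <- setdiff(object$var.names, colnames(xm))
    if (length(missing))
      stop("newdata lacks columns: ", paste(missing, collapse = ", "))
    xm <- xm[, object$var.names, drop = FALSE]
  } else if (ncol(xm) != length(object$var.names)) {
    stop("newdata must have ", length(object$var.names), " columns")
  }
  storage.mode(xm) <- "double"
  xm
}

#' Predictions after every requested ensemble size
#'
#' Evaluates the boosting path at a set of ensemble sizes in a single pass
#' over the trees, so that one fit at the largest size serves a whole
#' tuning grid.
#'
#' @inheritParams predict.gbt
#' @param sizes increasing integer vector of ensemble sizes, each at most
#'   the number of fitted trees.
#' @return numeric matrix, one column per requested size.
#' @export
staged_predict <- function(object, newdata, sizes) {
  stopifnot(inherits(object, "gbt"))
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes)) stop("sizes must be increasing")
  if (any(sizes < 0) || any(sizes > object$n.trees))
    stop("sizes must lie in [0, n.trees]")
  xm <- gbt_newdata(object, newdata)
  out <- gbt_staged_cpp(object$trees, object$init, object$shrinkage, xm, sizes)
  colnames(out) <- sizes
  out
}

#' Split-improvement variable importance
#'
#' For each predictor, sums the improvement (decrease in residual sum of
#' squares) over every split on that variable across all trees, then scales
#' the scores so that the largest equals 100.  The measure reflects both
#' additive and interaction contributions.  When no split achieved any
#' improvement all scores are zero and no rescaling is applied.
#'
#' @param object a [gbt()] fit.
#' @param n.trees number of leading trees to aggregate over (default all).
#' @param scale rescale so the maximum is 100 (default `TRUE`).
#' @return named numeric vector, sorted decreasing.
#' @export
relative_influence <- function(object, n.trees = NULL, scale = TRUE) {
  stopifnot(inherits(object, "gbt"))
  if (is.null(n.trees)) n.trees <- object$n.trees
  p <- length(object$var.names)
  score <- numeric(p)
  for (m in seq_len(n.trees)) {
    tr <- object$trees[[m]]
    internal <- tr[, 1L] > 0
    if (any(internal)) {
      agg <- tapply(tr[internal, 7L], tr[internal, 1L], sum)
      idx <- as.integer(names(agg))
      score[idx] <- score[idx] + as.numeric(agg)
    }
  }
  names(score) <- object$var.names
  if (scale && max(score) > 0) score <- 100 * score / max(score)
  sort(score, decreasing = TRUE)
}

#' @export
print.gbt <- function(x, ...) {
  cat("Stochastic gradient boosted regression trees\n")
  cat(sprintf("  %d trees, depth %d, shrinkage %g, bag fraction %g, %s loss\n",
              x$n.trees, x$depth, x$shrinkage, x$bag.fraction, x$loss))
  cat(sprintf("  %d predictors, %d observations, init = %.4g\n",
              length(x$var.names), length(x$y), x$init))
  invisible(x)
}

#' @export
summary.gbt <- function(object, n.show = 10L, ...) {
  ri <- relative_influence(object)
  res <- object$y - object$fitted
  out <- list(influence = ri, train.rmse = sqrt(mean(res^2)),
              object = object, n.show = n.show)
  class(out) <- "summary.gbt"
  out
}

#' @export
print.summary.gbt <- function(x, ...) {
  print(x$object)
  cat(sprintf("  training RMSE %.4g\n", x$train.rmse))
  cat("\nRelative influence (top variables, max scaled to 100):\n")
  print(round(head(x$influence, x$n.show), 2))
  invisible(x)
}

#' @export
residuals.gbt <- function(object, ...) object$y - object$fitted

#' @export
fitted.gbt <- function(object, ...) object$fitted

#' Plot a boosted ensemble's variable importance
#'
#' Horizontal bar chart of [relative_influence()] scores.
#'
#' @param x a [gbt()] fit.
#' @param n.show number of top variables displayed.
#' @param ... passed to [graphics::barplot()].
#' @return the influence vector, invisibly.
#' @export
plot.gbt <- function(x, n.show = 10L, ...) {
  ri <- head(relative_influence(x), n.show)
  graphics::barplot(rev(ri), horiz = TRUE, las = 1,
                    xlab = "Relative influence", ...)
  invisible(ri)
}
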