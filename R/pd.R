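#' Partial dependence of a variable subset
#'
#' The partial dependence of a subset \eqn{S} of predictors is the average
#' model output over the empirical distribution of the complementary
#' variables,
#' \deqn{\hat F_S(x_S) = \frac{1}{N}\sum_{i=1}^N \hat F(x_S, x_{-S(i)}).}
#' Two evaluation strategies are available.  `method = "recursion"` uses
#' the weighted tree traversal: at a split on a variable in \eqn{S} the
#' branch dictated by the evaluation point is followed, at a split on any
#' other variable both children are descended and combined by weight
#' fractions.  When reference `data` is supplied the weights are rebuilt
#' by a single routing pass of the reference rows per tree (descending
#' both children at subset splits), which reproduces the definitional
#' average *exactly* while costing one data pass per tree instead of one
#' per evaluation point; without `data` the subsample weight fractions
#' recorded at fit time are used, a fast data-free approximation whose
#' error is of the order of the empirical dependence between the subset
#' and its complement.  `method = "brute"` computes the definitional
#' average directly by overwriting the \eqn{S} columns of the reference
#' data and averaging predictions; it is the arbiter when the two
#' disagree.
#'
#' All values are mean-centered over the evaluation points by default,
#' the convention required for the variance interpretation of the
#' H statistic.
#'
#' @param object a [gbt()] fit.
#' @param vars subset \eqn{S}: column names or indices of the training
#'   design.
#' @param points evaluation points: a matrix or data frame with one column
#'   per variable in `vars` (in that order, or named).  Defaults to the
#'   rows of `data` projected onto `vars`.
#' @param data reference data (required for `method = "brute"` and as the
#'   default source of evaluation points).
#' @param method `"recursion"` or `"brute"`.
#' @param n.trees number of leading trees to use (default all).
#' @param center subtract the mean over evaluation points (default `TRUE`).
#' @return object of class `"gbt_pd"`: list with `vars`, `points`, `values`
#'   (centered when `center = TRUE`), `center` (the constant subtracted)
#'   and `method`.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(100 * 2), 100, 2, dimnames = list(NULL, c("a", "b")))
#' y <- x[, 1] * x[, 2]
#' fit <- gbt(x, y, n.trees = 40, depth = 2, shrinkage = 0.2, bag.fraction = 1)
#' pd <- partial_dependence(fit, "a", data = x)
#' head(pd$values)
#' @export
partial_dependence <- function(object, vars, points = NULL, data = NULL,
                               method = c("recursion", "brute"),
                               n.trees = NULL, center = TRUE) {
  stopifnot(inherits(object, "gbt"))
  method <- match.arg(method)
  if (is.null(n.trees)) n.trees <- object$n.trees
  sidx <- resolve_vars(object, vars)

  if (is.null(points)) {
    if (is.null(data)) stop("supply either points or data")
    dm <- gbt_newdata(object, data)
    points <- dm[, sidx, drop = FALSE]
  } else {
    points <- as.matrix(points)
    if (ncol(points) != length(sidx))
      stop("points must have one column per variable in vars")
    storage.mode(points) <- "double"
  }

  raw <- if (method == "recursion") {
    refdata <- if (is.null(data)) NULL else gbt_newdata(object, data)
    gbt_pd_cpp(object$trees[seq_len(n.trees)], object$init, object$shrinkage,
               points, as.integer(sidx - 1L), length(object$var.names),
               refdata)
  } else {
    pd_brute_values(object, sidx, points, data, n.trees)
  }

  ctr <- if (center) mean(raw) else 0
  structure(list(vars = object$var.names[sidx], points = points,
                 values = raw - ctr, center = ctr, method = method),
            class = "gbt_pd")
}

# definitional average: overwrite S columns with each point, average predictions
pd_brute_values <- function(object, sidx, points, data, n.trees) {
  if (is.null(data)) stop("method = \"brute\" needs reference data")
  dm <- gbt_newdata(object, data)
  vapply(seq_len(nrow(points)), function(i) {
    tmp <- dm
    tmp[, sidx] <- matrix(points[i, ], nrow(dm), length(sidx), byrow = TRUE)
    mean(gbt_predict_cpp(object$trees, object$init, object$shrinkage, tmp,
                         as.integer(n.trees)))
  }, numeric(1))
}

resolve_vars <- function(object, vars) {
  if (is.character(vars)) {
    sidx <- match(vars, object$var.names)
    if (anyNA(sidx))
      stop("unknown variable(s): ",
           paste(vars[is.na(sidx)], collapse = ", "))
  } else {
    sidx <- as.integer(vars)
    if (any(sidx < 1L | sidx > length(object$var.names)))
      stop("variable indices out of range")
  }
  if (length(sidx) == 0) stop("vars must be non-empty")
  if (anyDuplicated(sidx)) stop("vars must be distinct")
  sidx
}

#' Evaluation grid over percentile ranges
#'
#' Builds a regular grid for plotting partial dependence, spanning the
#' 10th to 90th percentile of each variable by default (extreme tails of
#' skewed exposures otherwise dominate the axes).
#'
#' @param data reference data.
#' @param vars variable names.
#' @param n points per variable.
#' @param probs lower/upper percentile bounds.
#' @return matrix with `length(vars)` columns: the full factorial grid.
#' @export
pd_grid <- function(data, vars, n = 40L, probs = c(0.1, 0.9)) {
  axes <- lapply(vars, function(v) {
    q <- quantile(data[[v]], probs, names = FALSE)
    seq(q[1], q[2], length.out = n)
  })
  g <- as.matrix(expand.grid(axes))
  colnames(g) <- vars
  g
}

#' @export
print.gbt_pd <- function(x, ...) {
  cat(sprintf("Partial dependence on {%s}: %d evaluation points (%s)\n",
              paste(x$vars, collapse = ", "), nrow(x$points), x$method))
  invisible(x)
}

#' Plot a partial-dependence function
#'
#' One variable gives a line plot (points sorted by the variable); two
#' variables give a filled level plot on an interpolated grid.  Higher
#' orders are not plotted directly; condition on the extra variables
#' instead.
#'
#' @param x a `"gbt_pd"` object.
#' @param ... passed to the underlying plot function.
#' @return `x`, invisibly.
#' @export
plot.gbt_pd <- function(x, ...) {
  k <- length(x$vars)
  if (k == 1L) {
    ord <- order(x$points[, 1])
    graphics::plot(x$points[ord, 1], x$values[ord], type = "l",
                   xlab = x$vars[1], ylab = "Partial dependence", ...)
  } else if (k == 2L) {
    u1 <- sort(unique(x$points[, 1])); u2 <- sort(unique(x$points[, 2]))
    if (length(u1) * length(u2) == nrow(x$points)) {
      z <- matrix(NA_real_, length(u1), length(u2))
      z[cbind(match(x$points[, 1], u1), match(x$points[, 2], u2))] <- x$values
      graphics::filled.contour(u1, u2, z, xlab = x$vars[1], ylab = x$vars[2], ...)
    } else {
      stop("2-D plotting needs a full grid of points; see pd_grid()")
    }
  } else {
    stop("only 1-D and 2-D partial dependence plots are supported")
  }
  invisible(x)
}
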