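#' Friedman-Popescu H statistic of interaction strength
#'
#' Measures how much of the variance of a (centered) partial-dependence
#' function is not captured by lower-order partial dependences.  For a
#' pair \eqn{(j, k)},
#' \deqn{H_{jk}^2 = \frac{\sum_i [\hat F_{jk}(x_{ij}, x_{ik}) -
#'   \hat F_j(x_{ij}) - \hat F_k(x_{ik})]^2}
#'   {\sum_i \hat F_{jk}^2(x_{ij}, x_{ik})}}
#' evaluated at the data points, with \eqn{H = \sqrt{H^2}} between 0 (the
#' joint effect is additive) and 1 (pure interaction).  For subsets of
#' three or more variables the numerator generalizes by inclusion-
#' exclusion: \eqn{\sum_i [\sum_{T \subseteq S, T \neq \emptyset}
#' (-1)^{|S|-|T|} \hat F_T(x_{iT})]^2}, isolating the pure
#' \eqn{|S|}-way component.  A single variable gives the *total*
#' interaction of that variable with all others, using the decomposition
#' \eqn{\hat F(x) = \hat F_j(x_j) + \hat F_{-j}(x_{-j})} that holds
#' exactly when \eqn{x_j} interacts with nothing, with denominator
#' \eqn{\sum_i \hat F^2(x_i)}.
#'
#' All partial dependences (and the full model fit, for the total
#' statistic) are mean-centered over the evaluation rows before use.
#'
#' @param object a [gbt()] fit.
#' @param vars one variable (total interaction) or two or more (joint
#'   interaction of that subset), as names or indices.
#' @param data evaluation data containing the training columns; the H sums
#'   run over its rows.
#' @param rows optional: integer indices into `data`, or a single number
#'   giving the size of a random row subsample (speed/precision tradeoff).
#' @param n.trees number of leading trees to use (default all).
#' @return the H value (numeric scalar, >= 0 and <= 1 up to numerical
#'   noise).  When the denominator vanishes (the joint partial dependence
#'   is identically zero) the value is 0 with a warning.
#' @examples
#' set.seed(1)
#' x <- matrix(runif(200 * 3), 200, 3, dimnames = list(NULL, c("a", "b", "c")))
#' y <- x[, 1] * x[, 2] + x[, 3]
#' fit <- gbt(x, y, n.trees = 80, depth = 2, shrinkage = 0.2, bag.fraction = 1)
#' h_stat(fit, c("a", "b"), data = x)   # interacting pair
#' h_stat(fit, c("a", "c"), data = x)   # additive pair
#' @export
h_stat <- function(object, vars, data, rows = NULL, n.trees = NULL) {
  stopifnot(inherits(object, "gbt"))
  if (is.null(n.trees)) n.trees <- object$n.trees
  sidx <- resolve_vars(object, vars)
  dm <- gbt_newdata(object, data)
  if (!is.null(rows)) {
    if (length(rows) == 1L && rows < nrow(dm)) rows <- sample(nrow(dm), rows)
    dm <- dm[rows, , drop = FALSE]
  }

  pdv <- function(S) {
    v <- gbt_pd_cpp(object$trees[seq_len(n.trees)], object$init,
                    object$shrinkage, dm[, S, drop = FALSE],
                    as.integer(S - 1L), length(object$var.names), dm)
    v - mean(v)
  }

  if (length(sidx) == 1L) {
    ffull <- gbt_predict_cpp(object$trees, object$init, object$shrinkage,
                             dm, as.integer(n.trees))
    ffull <- ffull - mean(ffull)
    comp <- setdiff(seq_along(object$var.names), sidx)
    num <- sum((ffull - pdv(sidx) - pdv(comp))^2)
    den <- sum(ffull^2)
  } else {
    k <- length(sidx)
    resid <- 0
    for (sz in seq_len(k)) {
      sgn <- (-1)^(k - sz)
      for (Tsub in combn_list(sidx, sz)) resid <- resid + sgn * pdv(Tsub)
    }
    num <- sum(resid^2)
    den <- sum(pdv(sidx)^2)
  }

  if (den <= .Machine$double.eps * length(object$y)) {
    warning("joint partial dependence is identically zero; returning H = 0")
    return(0)
  }
  sqrt(num / den)
}

combn_list <- function(x, m) {
  if (m == length(x)) return(list(x))
  apply(utils::combn(x, m), 2, identity, simplify = FALSE)
}

#' Artificial additive outcome for the H null distribution
#'
#' Constructs the parametric-bootstrap outcome
#' \deqn{\tilde y_i = F_A(x_i) + y_{p(i)} - F_A(x_{p(i)})}
#' where \eqn{F_A} is the closest additive fit to the target (an ensemble
#' of depth-1 trees) and \eqn{p} is a random permutation.  \eqn{\tilde y}
#' preserves the additive structure and the marginal residual distribution
#' of the data while destroying any interaction pattern; refitting the full
#' model to \eqn{(\mathbf{x}, \tilde y)} and recomputing H yields one draw
#' from the null distribution \eqn{H^0}.
#'
#' @param additive the additive reference: a depth-1 [gbt()] fit, or a
#'   numeric vector of its fitted values \eqn{F_A(x_i)}.
#' @param y observed outcome.
#' @param permutation a permutation of `seq_along(y)`; defaults to a
#'   uniform random draw.
#' @param x data at which to evaluate the additive fit (defaults to its
#'   training fitted values).
#' @return numeric vector \eqn{\tilde y}.
#' @export
make_null_outcome <- function(additive, y, permutation = sample(length(y)),
                              x = NULL) {
  fa <- if (inherits(additive, "gbt")) {
    if (additive$depth != 1L)
      stop("the additive reference must be fit with depth = 1")
    if (is.null(x)) fitted(additive) else predict(additive, x)
  } else {
    as.numeric(additive)
  }
  n <- length(y)
  if (length(fa) != n) stop("additive fit and y differ in length")
  if (length(permutation) != n || anyNA(permutation) ||
      !setequal(permutation, seq_len(n)))
    stop("permutation must be a bijection of 1..N")
  fa + y[permutation] - fa[permutation]
}

# internal: fit a gbt from a parameter list
gbt_fit_params <- function(x, y, params) {
  do.call(gbt.default, c(list(x = x, y = y), params))
}

# Fitted values of the additive reference F_A.  `additive` may be a
# depth-1 gbt fit, a numeric vector of fitted values, or NULL, in which
# case the reference is fit here with its ensemble size chosen by a small
# bootstrap one-SE tune over a geometric grid around the full model's
# size.  The size matters: an additive reference matched blindly to the
# full model's size tends to overfit, absorbing noise into F_A and
# shrinking the null residuals (an anti-conservative null), while a
# badly undersized one leaves additive structure in the residuals.
additive_fa <- function(additive, xm, y, params) {
  if (inherits(additive, "gbt")) {
    if (additive$depth != 1L)
      stop("the additive reference must be fit with depth = 1")
    return(fitted(additive))
  }
  if (is.numeric(additive)) {
    if (length(additive) != length(y))
      stop("additive fitted values and y differ in length")
    return(as.numeric(additive))
  }
  base <- if (is.null(params$n.trees)) 100L else params$n.trees
  grid <- unique(pmax(10L, as.integer(round(base * c(1/8, 1/4, 1/2, 1, 2)))))
  tn <- tune_gbt(xm, y, depths = 1L, m.grid = grid, n_boot = 8L,
                 shrinkage = params$shrinkage %||% 0.0025,
                 bag.fraction = params$bag.fraction %||% 0.5,
                 loss = params$loss %||% "squared",
                 min.obs = params$min.obs %||% 10L)
  add_params <- params
  add_params$depth <- 1L
  add_params$n.trees <- tn$one_se$n.trees
  fitted(gbt_fit_params(xm, y, add_params))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Null distribution of the H statistic by parametric bootstrap
#'
#' For each of `n_rep` replicates, draws a random permutation, builds the
#' artificial additive outcome of [make_null_outcome()], refits the full
#' (depth-\eqn{d}) ensemble with the same parameters, and recomputes H for
#' every requested subset.  The observed H values come from a fit to the
#' real outcome; a subset is flagged significant when its observed H
#' exceeds the 95th percentile of its null draws.
#'
#' An advisory resampling p-value (the fraction of null draws at or above
#' the observed value) is also reported, but null distributions of
#' higher-order H can be extremely narrow, so the percentile comparison --
#' ideally inspected graphically on a common axis via
#' [plot.h_assessment()] -- is the primary decision rule.
#'
#' @param x predictor data (matrix or data frame, all numeric).
#' @param y outcome vector.
#' @param subsets a list of variable subsets (each as in [h_stat()]), or a
#'   single subset.
#' @param params list of [gbt()] arguments for the full model
#'   (`n.trees`, `depth`, `shrinkage`, ...); the additive reference
#'   inherits everything but its depth (1) and its own tuned size.
#' @param n_rep number of null replicates (250 gives a stable 95th
#'   percentile; below 20 a warning is issued).
#' @param rows as in [h_stat()]: row indices or subsample size for the H
#'   evaluation sums.
#' @param fit optional pre-computed full fit on `(x, y)` with `params`
#'   (avoids refitting when already available).
#' @param additive the additive reference \eqn{F_A}: a depth-1 [gbt()]
#'   fit, a numeric vector of its fitted values, or `NULL` (default) to
#'   fit one here with its ensemble size selected by a small bootstrap
#'   one-SE tune -- the operational reading of "the closest additive fit";
#'   both an overfit and a badly undersized reference distort the null.
#' @return object of class `"h_assessment"`: list with `subsets`,
#'   `observed`, `null` (matrix, `n_rep` rows), `q95`, `significant`,
#'   `p_advisory`.
#' @export
h_null <- function(x, y, subsets, params, n_rep = 250L, rows = NULL,
                   fit = NULL, additive = NULL) {
  if (!is.list(subsets) || is.character(subsets)) subsets <- list(subsets)
  if (n_rep < 1) stop("n_rep must be >= 1")
  if (n_rep < 20) warning("n_rep < 20: the 95th percentile is unstable")
  xm <- as.matrix(x); storage.mode(xm) <- "double"

  if (is.null(fit)) fit <- gbt_fit_params(xm, y, params)
  fa <- additive_fa(additive, xm, y, params)

  # fix evaluation rows once so observed and null use the same sums
  if (!is.null(rows) && length(rows) == 1L && rows < nrow(xm))
    rows <- sample(nrow(xm), rows)

  observed <- vapply(subsets, function(s) h_stat(fit, s, xm, rows = rows),
                     numeric(1))
  null <- matrix(NA_real_, n_rep, length(subsets))
  for (r in seq_len(n_rep)) {
    ytil <- make_null_outcome(fa, y)
    nfit <- gbt_fit_params(xm, ytil, params)
    null[r, ] <- vapply(subsets, function(s) h_stat(nfit, s, xm, rows = rows),
                        numeric(1))
  }

  q95 <- apply(null, 2, quantile, probs = 0.95, names = FALSE)
  labels <- vapply(subsets, function(s)
    paste(if (is.character(s)) s else colnames(xm)[s], collapse = ":"),
    character(1))
  structure(list(subsets = subsets, labels = labels, observed = observed,
                 null = null, q95 = q95, significant = observed > q95,
                 p_advisory = colMeans(null >= rep(observed, each = n_rep)),
                 n_rep = n_rep, params = params),
            class = "h_assessment")
}

#' @export
print.h_assessment <- function(x, ...) {
  cat("H statistics against a parametric-bootstrap null (",
      x$n_rep, " replicates)\n", sep = "")
  print(as.data.frame(x), digits = 3)
  invisible(x)
}

#' @export
as.data.frame.h_assessment <- function(x, ...) {
  data.frame(subset = x$labels,
             order = lengths(x$subsets),
             h_obs = x$observed,
             null_q5 = apply(x$null, 2, quantile, 0.05, names = FALSE),
             null_q50 = apply(x$null, 2, quantile, 0.50, names = FALSE),
             null_q95 = x$q95,
             significant = x$significant,
             p_advisory = x$p_advisory,
             row.names = NULL)
}

#' Box-percentile style plot of H against its null distribution
#'
#' Draws, for every assessed subset, a horizontal box spanning the 25th to
#' 75th percentile of the null draws, whiskers at the 5th and 95th, tick
#' marks for null draws outside the whiskers, and a filled dot at the
#' observed H.  Because higher-order null distributions can be very
#' narrow, `xlim = c(0, 1)` (the default) keeps the axis range common
#' across interaction orders so that small-but-"significant" values are
#' seen in proportion.
#'
#' @param x an [h_null()] result.
#' @param xlim x-axis range; `NULL` adapts to the data.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.h_assessment <- function(x, xlim = c(0, 1), ...) {
  k <- length(x$subsets)
  if (is.null(xlim)) xlim <- range(0, x$null, x$observed)
  graphics::plot(NA, xlim = xlim, ylim = c(0.5, k + 0.5), yaxt = "n",
                 xlab = "H", ylab = "", ...)
  graphics::axis(2, at = seq_len(k), labels = x$labels, las = 1)
  for (i in seq_len(k)) {
    q <- quantile(x$null[, i], c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE)
    graphics::segments(q[1], i, q[5], i, col = "grey40")
    graphics::rect(q[2], i - 0.18, q[4], i + 0.18, col = "grey85",
                   border = "grey40")
    graphics::segments(q[3], i - 0.18, q[3], i + 0.18, col = "grey20")
    out <- x$null[, i][x$null[, i] < q[1] | x$null[, i] > q[5]]
    if (length(out))
      graphics::segments(out, i - 0.08, out, i + 0.08, col = "grey60")
    graphics::points(x$observed[i], i, pch = 19)
  }
  invisible(x)
}

#' Repeated split-sample stability of detected interactions
#'
#' Randomly splits the sample in half, fits the ensemble to the training
#' half, and evaluates each subset's H on the validation half against a
#' null distribution built on the training half (additive fit, permuted
#' residuals, refit -- with all H sums evaluated on the validation rows so
#' observed and null values are measured identically).  Repeating the
#' split gives a stability fraction per subset: true interactions should
#' be re-detected in most splits, spurious ones should not.
#'
#' @inheritParams h_null
#' @param n_repeats number of random half-splits (10 is customary).
#' @param null_rep null replicates per split.
#' @return object of class `"stability_result"`: data frame with columns
#'   `subset`, `n_detected`, `n_repeats`, `fraction`.
#' @export
split_stability <- function(x, y, subsets, params, n_repeats = 10L,
                            null_rep = 50L, rows = NULL) {
  if (!is.list(subsets) || is.character(subsets)) subsets <- list(subsets)
  xm <- as.matrix(x); storage.mode(xm) <- "double"
  n <- nrow(xm)
  detected <- integer(length(subsets))

  for (rep in seq_len(n_repeats)) {
    tr <- sample(n, floor(n / 2))
    va <- setdiff(seq_len(n), tr)
    xt <- xm[tr, , drop = FALSE]; yt <- y[tr]
    xv <- xm[va, , drop = FALSE]
    vrows <- if (!is.null(rows) && rows < nrow(xv)) sample(nrow(xv), rows)
             else NULL

    fit <- gbt_fit_params(xt, yt, params)
    obs <- vapply(subsets, function(s) h_stat(fit, s, xv, rows = vrows),
                  numeric(1))

    fa <- additive_fa(NULL, xt, yt, params)
    null <- matrix(NA_real_, null_rep, length(subsets))
    for (r in seq_len(null_rep)) {
      ytil <- make_null_outcome(fa, yt)
      nfit <- gbt_fit_params(xt, ytil, params)
      null[r, ] <- vapply(subsets, function(s) h_stat(nfit, s, xv, rows = vrows),
                          numeric(1))
    }
    q95 <- apply(null, 2, quantile, probs = 0.95, names = FALSE)
    detected <- detected + as.integer(obs > q95)
  }

  labels <- vapply(subsets, function(s)
    paste(if (is.character(s)) s else colnames(xm)[s], collapse = ":"),
    character(1))
  structure(data.frame(subset = labels, n_detected = detected,
                       n_repeats = as.integer(n_repeats),
                       fraction = detected / n_repeats),
            class = c("stability_result", "data.frame"))
}
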