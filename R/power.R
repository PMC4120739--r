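#' Generate data for the interaction power study
#'
#' Twenty independent standard-normal predictors and a continuous outcome
#' from one of two generating models:
#' \deqn{y = 1 + x_1 + x_2 + \beta_{12} x_1 x_2 + \varepsilon}
#' (`model = "two_way"`) or
#' \deqn{y = 1 + x_1 + x_2 + x_3 + \beta(x_1 x_2 + x_1 x_3 + x_2 x_3)
#'   + \beta_{123}\, x_1 x_2 x_3 + \varepsilon}
#' (`model = "three_way"`, the three two-way coefficients share the value
#' `beta_two`).  Main-effect coefficients are fixed at 1 and the noise SD
#' is chosen analytically for a signal-to-noise ratio of one: products of
#' independent standard normals are uncorrelated with the main effects and
#' have unit variance, so \eqn{\sigma^2 = 2 + \beta_{12}^2} for the
#' two-way model and \eqn{\sigma^2 = 3 + 3\beta^2 + \beta_{123}^2} for the
#' three-way model.
#'
#' @param model `"two_way"` or `"three_way"`.
#' @param n sample size.
#' @param beta_two two-way interaction coefficient (\eqn{\beta_{12}}, or
#'   the common value of the three two-way terms).
#' @param beta_three three-way coefficient \eqn{\beta_{123}} (three-way
#'   model only).
#' @return list with `x` (n x 20 matrix, columns `x1`..`x20`), `y`,
#'   `sigma` and the coefficients.
#' @export
power_data <- function(model = c("two_way", "three_way"), n,
                       beta_two = 0.5, beta_three = 0.5) {
  model <- match.arg(model)
  x <- matrix(rnorm(n * 20L), n, 20L,
              dimnames = list(NULL, paste0("x", 1:20)))
  if (model == "two_way") {
    signal <- 1 + x[, 1] + x[, 2] + beta_two * x[, 1] * x[, 2]
    sigma <- sqrt(2 + beta_two^2)
  } else {
    signal <- 1 + x[, 1] + x[, 2] + x[, 3] +
      beta_two * (x[, 1] * x[, 2] + x[, 1] * x[, 3] + x[, 2] * x[, 3]) +
      beta_three * x[, 1] * x[, 2] * x[, 3]
    sigma <- sqrt(3 + 3 * beta_two^2 + beta_three^2)
  }
  list(x = x, y = signal + rnorm(n, 0, sigma), sigma = sigma,
       model = model, beta_two = beta_two, beta_three = beta_three)
}

#' Power of the H-based boosted-tree decision rule
#'
#' For each of `n_datasets` simulated datasets, fits the boosted ensemble,
#' builds the parametric-bootstrap null for the target subset (`x1:x2` for
#' the two-way model, `x1:x2:x3` for the three-way model) and declares the
#' interaction significant when the observed H exceeds the null's 95th
#' percentile.  Power is the detection fraction.
#'
#' The default fitting parameters are a desk-scale budget (moderate
#' ensemble with a larger shrinkage rather than thousands of slowly
#' learned trees); pass `params` and `tune_args` for heavier runs with
#' per-dataset grid tuning.
#'
#' @inheritParams power_data
#' @param n_datasets number of simulated datasets.
#' @param params list of [gbt()] parameters for the full model.
#' @param null_rep null replicates per dataset.
#' @param rows H evaluation row subsample (see [h_stat()]).
#' @param tune_args optional list of [tune_gbt()] arguments; when given,
#'   each dataset is tuned and the one-SE parameters are used.
#' @return object of class `"power_result"`: data frame row with the
#'   configuration, method, detection count and power.
#' @export
power_boosted <- function(model = c("two_way", "three_way"), n,
                          beta_two = 0.5, beta_three = 0.5,
                          n_datasets = 20L,
                          params = list(n.trees = 300L, depth = 3L,
                                        shrinkage = 0.05),
                          null_rep = 50L, rows = NULL, tune_args = NULL) {
  model <- match.arg(model)
  target <- if (model == "two_way") c("x1", "x2") else c("x1", "x2", "x3")
  hits <- 0L
  for (d in seq_len(n_datasets)) {
    dat <- power_data(model, n, beta_two, beta_three)
    pars <- params
    if (!is.null(tune_args)) {
      tn <- do.call(tune_gbt, c(list(x = dat$x, y = dat$y), tune_args))
      pars$n.trees <- tn$one_se$n.trees
      pars$depth <- tn$one_se$depth
    }
    ha <- suppressWarnings(
      h_null(dat$x, dat$y, list(target), pars, n_rep = null_rep, rows = rows))
    hits <- hits + as.integer(ha$significant[1])
  }
  power_result(model, "boosted_h", n, beta_two, beta_three, hits, n_datasets)
}

#' Power of product-term regression with FDR-controlled screening
#'
#' The comparator procedure: in every bootstrap resample, (1) screen all
#' twenty predictors for marginal association with the outcome by simple
#' linear regression, (2) adjust the screening p-values so the false
#' discovery rate is controlled at `fdr_level` (Benjamini-Hochberg), (3)
#' if both members of the target pair survive the screen, fit the model
#' with their product term and retain the interaction coefficient,
#' otherwise record 0.  After `B` resamples, the 2.5th and 97.5th
#' percentiles of the retained coefficients form a 95% confidence
#' interval; the interaction is declared significant when the interval
#' excludes zero.
#'
#' For the three-way model an outer bootstrap of `outer_B` resamples is
#' added: within each outer resample the two-way procedure above is run
#' for all three constituent pairs, and the three-way coefficient is
#' estimated (from the model with the triple product and its two-way
#' components) only when at least two of the three pairs are significant,
#' else set to 0.  The 95% percentile interval over the outer resamples
#' decides significance.
#'
#' @inheritParams power_boosted
#' @param B inner bootstrap resamples.
#' @param outer_B outer bootstrap resamples (three-way model).
#' @param fdr_level false discovery rate for the marginal screen.
#' @return object of class `"power_result"` (see [power_boosted()]).
#' @export
power_parametric <- function(model = c("two_way", "three_way"), n,
                             beta_two = 0.5, beta_three = 0.5,
                             n_datasets = 20L, B = 100L, outer_B = 100L,
                             fdr_level = 0.10) {
  model <- match.arg(model)
  hits <- 0L
  for (d in seq_len(n_datasets)) {
    dat <- power_data(model, n, beta_two, beta_three)
    sig <- if (model == "two_way") {
      ci_excludes_zero(pair_boot_ci(dat$x, dat$y, c(1L, 2L), B, fdr_level))
    } else {
      three_way_outer(dat$x, dat$y, B, outer_B, fdr_level)
    }
    hits <- hits + as.integer(sig)
  }
  power_result(model, "parametric_bootstrap", n, beta_two, beta_three,
               hits, n_datasets)
}

power_result <- function(model, method, n, beta_two, beta_three,
                         hits, n_datasets) {
  structure(data.frame(model = model, method = method, n = n,
                       beta_two = beta_two,
                       beta_three = if (model == "three_way") beta_three else NA,
                       n_detected = hits, n_datasets = n_datasets,
                       power = hits / n_datasets),
            class = c("power_result", "data.frame"))
}

# marginal-screen p-values: slope t-tests of y on each column separately,
# computed from correlations for speed
screen_p <- function(x, y) {
  n <- length(y)
  r <- as.vector(suppressWarnings(cor(x, y)))
  r[!is.finite(r)] <- 0
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  2 * pt(-abs(tt), n - 2)
}

# interaction coefficient of the product-term model y ~ xj + xk + xj:xk
product_beta <- function(x, y, j, k) {
  X <- cbind(1, x[, j], x[, k], x[, j] * x[, k])
  qr.solve(X, y, tol = 1e-10)[4]
}

# bootstrap distribution of the screened product-term coefficient for one
# or more pairs; returns a B x npairs matrix (0 where the screen failed)
pair_boot <- function(x, y, pairs, B, fdr_level) {
  if (!is.list(pairs)) pairs <- list(pairs)
  n <- length(y)
  out <- matrix(0, B, length(pairs))
  for (b in seq_len(B)) {
    repeat {
      idx <- sample(n, n, replace = TRUE)
      xb <- x[idx, , drop = FALSE]
      if (all(matrixStats_colSds_ok(xb))) break
    }
    yb <- y[idx]
    padj <- p.adjust(screen_p(xb, yb), method = "BH")
    keep <- padj <= fdr_level
    for (q in seq_along(pairs)) {
      pr <- pairs[[q]]
      if (keep[pr[1]] && keep[pr[2]])
        out[b, q] <- product_beta(xb, yb, pr[1], pr[2])
    }
  }
  out
}

matrixStats_colSds_ok <- function(x) {
  apply(x, 2, function(col) max(col) > min(col))
}

pair_boot_ci <- function(x, y, pair, B, fdr_level) {
  draws <- pair_boot(x, y, pair, B, fdr_level)[, 1]
  quantile(draws, c(0.025, 0.975), names = FALSE)
}

ci_excludes_zero <- function(ci) ci[1] > 0 || ci[2] < 0

three_way_outer <- function(x, y, B, outer_B, fdr_level) {
  n <- length(y)
  pairs <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L))
  b123 <- numeric(outer_B)
  for (ob in seq_len(outer_B)) {
    idx <- sample(n, n, replace = TRUE)
    xo <- x[idx, , drop = FALSE]; yo <- y[idx]
    draws <- pair_boot(xo, yo, pairs, B, fdr_level)
    pairsig <- vapply(seq_len(3), function(q)
      ci_excludes_zero(quantile(draws[, q], c(0.025, 0.975), names = FALSE)),
      logical(1))
    if (sum(pairsig) >= 2) {
      X <- cbind(1, xo[, 1], xo[, 2], xo[, 3],
                 xo[, 1] * xo[, 2], xo[, 1] * xo[, 3], xo[, 2] * xo[, 3],
                 xo[, 1] * xo[, 2] * xo[, 3])
      b123[ob] <- qr.solve(X, yo, tol = 1e-10)[8]
    }
  }
  ci_excludes_zero(quantile(b123, c(0.025, 0.975), names = FALSE))
}

#' Sweep a power study over sample sizes
#'
#' Convenience wrapper running [power_boosted()] and/or
#' [power_parametric()] over a grid of sample sizes and interaction
#' coefficients, returning one stacked data frame suitable for
#' power-versus-n curves.
#'
#' @param model `"two_way"` or `"three_way"`.
#' @param n_values sample sizes.
#' @param beta_values two-way coefficients (each from \{0.25, 0.5, 1\} in
#'   the study design).
#' @param beta_three three-way coefficient (three-way model).
#' @param methods subset of `c("boosted_h", "parametric_bootstrap")`.
#' @param ... further arguments passed to the per-method functions.
#' @return data frame of class `"power_result"`.
#' @export
power_sweep <- function(model = "two_way", n_values = c(250L, 500L, 1000L),
                        beta_values = c(0.25, 0.5, 1),
                        beta_three = 0.5,
                        methods = c("boosted_h", "parametric_bootstrap"),
                        ...) {
  rows <- list()
  dots <- list(...)
  for (nv in n_values) for (bv in beta_values) for (m in methods) {
    rows[[length(rows) + 1L]] <- if (m == "boosted_h") {
      do.call(power_boosted,
              c(list(model = model, n = nv, beta_two = bv,
                     beta_three = beta_three),
                dots[intersect(names(dots),
                               names(formals(power_boosted)))]))
    } else {
      do.call(power_parametric,
              c(list(model = model, n = nv, beta_two = bv,
                     beta_three = beta_three),
                dots[intersect(names(dots),
                               names(formals(power_parametric)))]))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("power_result", "data.frame")
  out
}

#' Plot power curves
#'
#' Detection power against sample size, one line per method, panelled by
#' the interaction coefficient via colour.
#'
#' @param x a `"power_result"` data frame (typically from [power_sweep()]).
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.power_result <- function(x, ...) {
  betas <- sort(unique(x$beta_two))
  methods <- unique(x$method)
  graphics::plot(NA, xlim = range(x$n), ylim = c(0, 1),
                 xlab = "Sample size", ylab = "Power", ...)
  for (bi in seq_along(betas)) for (mi in seq_along(methods)) {
    sub <- x[x$beta_two == betas[bi] & x$method == methods[mi], ]
    sub <- sub[order(sub$n), ]
    if (nrow(sub))
      graphics::lines(sub$n, sub$power, col = bi, lty = mi, type = "b",
                      pch = mi)
  }
  graphics::legend("bottomright",
                   legend = c(paste("beta =", betas), methods),
                   col = c(seq_along(betas), rep(1, length(methods))),
                   lty = c(rep(1, length(betas)), seq_along(methods)),
                   cex = 0.8)
  invisible(x)
}
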