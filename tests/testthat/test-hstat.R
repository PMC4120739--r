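test_that("H vanishes for additive (stump) ensembles", {
  toy <- make_toy(n = 120)
  fit <- gbt(toy$x, toy$y, n.trees = 100, depth = 1, shrinkage = 0.2,
             bag.fraction = 1, min.obs = 5)
  expect_lt(h_stat(fit, c("v1", "v2"), toy$x), 1e-8)
  expect_lt(h_stat(fit, "v1", toy$x), 1e-8)
  expect_lt(h_stat(fit, c("v1", "v2", "v3"), toy$x), 1e-8)
})

test_that("a pure product function has H = 1 (enumeration oracle)", {
  # hand-built tree encoding x1 * x2 on the balanced +-1 design:
  # both centered one-dimensional partial dependences vanish by symmetry
  X <- pm_design(2)
  fit <- manual_gbt(list(product_tree(1, 2)), c("x1", "x2"))
  expect_equal(predict(fit, X), X[, 1] * X[, 2])
  expect_equal(h_stat(fit, c("x1", "x2"), X), 1)
  # total interaction of each member is 1 as well
  expect_equal(h_stat(fit, "x1", X), 1)
})

test_that("a pure three-way parity function has H = 1", {
  X <- pm_design(3)
  fit <- manual_gbt(list(parity_tree()), c("x1", "x2", "x3"))
  expect_equal(predict(fit, X), X[, 1] * X[, 2] * X[, 3])
  # all lower-order centered partial dependences vanish by symmetry
  expect_equal(h_stat(fit, c("x1", "x2", "x3"), X), 1)
  # the pairwise joint effect itself averages to zero, so pairwise H is
  # degenerate and reported as 0 with a warning
  expect_warning(h12 <- h_stat(fit, c("x1", "x2"), X), "identically zero")
  expect_equal(h12, 0)
})

test_that("H is symmetric, bounded, and location invariant", {
  toy <- make_toy(n = 100)
  fit <- gbt(toy$x, toy$y, n.trees = 60, depth = 3, shrinkage = 0.1,
             bag.fraction = 1, min.obs = 5, seed = 8)
  h12 <- h_stat(fit, c("v1", "v2"), toy$x)
  h21 <- h_stat(fit, c("v2", "v1"), toy$x)
  expect_equal(h12, h21, tolerance = 1e-12)
  for (s in list("v1", c("v1", "v3"), c("v1", "v2", "v4"))) {
    h <- h_stat(fit, s, toy$x)
    expect_gte(h, 0); expect_lte(h, 1 + 1e-8)
  }
  # adding a constant to y leaves H unchanged (centered PDs)
  fit2 <- gbt(toy$x, toy$y + 100, n.trees = 60, depth = 3, shrinkage = 0.1,
              bag.fraction = 1, min.obs = 5, seed = 8)
  expect_equal(h_stat(fit2, c("v1", "v2"), toy$x), h12, tolerance = 1e-10)
})

test_that("total interaction is zero for a single-variable model", {
  # b and c are constant, so no split can ever use them and F_{-a} is flat
  x <- cbind(a = rnorm(100), b = rep(1, 100), c = rep(2, 100))
  fit <- gbt(x, sin(2 * x[, 1]), n.trees = 50, depth = 2, shrinkage = 0.2,
             bag.fraction = 1, min.obs = 5)
  expect_equal(unname(relative_influence(fit)[c("b", "c")]), c(0, 0))
  expect_lt(h_stat(fit, "a", x), 1e-8)
})

test_that("null outcomes preserve additive structure and the mean", {
  toy <- make_toy(n = 60)
  add <- gbt(toy$x, toy$y, n.trees = 40, depth = 1, shrinkage = 0.2,
             bag.fraction = 1, min.obs = 5)
  # identity permutation returns the data unchanged
  expect_equal(make_null_outcome(add, toy$y, seq_along(toy$y)), toy$y)
  # permutation-sum cancellation keeps the mean exactly
  set.seed(1)
  yt <- make_null_outcome(add, toy$y)
  expect_equal(mean(yt), mean(toy$y))
  # zero residuals reproduce the additive fit under any permutation
  fa <- fitted(add)
  expect_equal(make_null_outcome(fa, fa, sample(60)), fa)
  expect_error(make_null_outcome(add, toy$y, c(1, 1, 3:60)), "bijection")
  # a depth-2 reference is not an additive model
  deep <- gbt(toy$x, toy$y, n.trees = 5, depth = 2)
  expect_error(make_null_outcome(deep, toy$y), "depth = 1")
})

test_that("null assessment flags a real interaction and not a null pair", {
  set.seed(21)
  n <- 250
  x <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 2 * x[, 1] * x[, 2] + x[, 3] + rnorm(n, 0, 0.3)
  params <- list(n.trees = 150L, depth = 2L, shrinkage = 0.1, min.obs = 5L)
  ha <- h_null(x, y, list(c("v1", "v2"), c("v3", "v4")), params, n_rep = 30)
  expect_equal(dim(ha$null), c(30, 2))
  expect_true(ha$significant[1])
  expect_false(ha$significant[2])
  df <- as.data.frame(ha)
  expect_equal(df$subset, c("v1:v2", "v3:v4"))
  expect_true(all(df$null_q5 <= df$null_q95))
  expect_warning(h_null(x, y, list(c("v1", "v2")), params, n_rep = 5),
                 "unstable")
})

test_that("split-sample stability separates real from spurious interactions", {
  set.seed(31)
  n <- 300
  x <- matrix(runif(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
  y <- 2.5 * x[, 1] * x[, 2] + rnorm(n, 0, 0.3)
  params <- list(n.trees = 120L, depth = 2L, shrinkage = 0.1, min.obs = 5L)
  st <- split_stability(x, y, list(c("v1", "v2"), c("v3", "v4")), params,
                        n_repeats = 4, null_rep = 25)
  expect_true(all(st$n_detected <= st$n_repeats))
  expect_gte(st$fraction[1], 0.75)
  expect_lte(st$fraction[2], 0.5)
})
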