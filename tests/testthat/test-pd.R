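test_that("recursion and brute-force partial dependence agree exactly", {
  # random small ensembles, with and without subsampling
  for (seed in 1:25) {
    set.seed(seed)
    n <- 50
    x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("v", 1:4)))
    y <- x[, 1] * x[, 2] + sin(x[, 3]) + rnorm(n, 0, 0.2)
    eta <- if (seed %% 2) 1 else 0.6
    fit <- gbt(x, y, n.trees = 20, depth = sample(1:3, 1), shrinkage = 0.15,
               bag.fraction = eta, min.obs = 5)
    S <- sample(4, sample(1:3, 1))
    pts <- x[sample(n, 10), S, drop = FALSE]
    a <- partial_dependence(fit, S, points = pts, data = x)$values
    b <- partial_dependence(fit, S, points = pts, data = x,
                            method = "brute")$values
    expect_lt(max(abs(a - b)), 1e-8)
  }
})

test_that("stump ensembles have additive joint partial dependence", {
  toy <- make_toy(n = 100)
  fit <- gbt(toy$x, toy$y, n.trees = 80, depth = 1, shrinkage = 0.2,
             bag.fraction = 1, min.obs = 5)
  pjk <- partial_dependence(fit, c("v1", "v2"), data = toy$x)$values
  pj <- partial_dependence(fit, "v1", data = toy$x)$values
  pk <- partial_dependence(fit, "v2", data = toy$x)$values
  expect_lt(max(abs(pjk - pj - pk)), 1e-10)
})

test_that("partial dependence on never-split variables is constant", {
  x <- matrix(rnorm(200), 100, 2, dimnames = list(NULL, c("a", "b")))
  fit <- gbt(x, x[, 1], n.trees = 10, depth = 1, shrinkage = 0.5,
             bag.fraction = 1, min.obs = 5)
  pd <- partial_dependence(fit, "b", data = x)
  expect_lt(max(abs(pd$values)), 1e-12)
})

test_that("partial dependence over all variables equals centered prediction", {
  toy <- make_toy(n = 60)
  fit <- gbt(toy$x, toy$y, n.trees = 25, depth = 3, shrinkage = 0.1,
             bag.fraction = 1, min.obs = 5, seed = 6)
  pd <- partial_dependence(fit, colnames(toy$x), data = toy$x)
  pr <- predict(fit, toy$x)
  expect_equal(pd$values, pr - mean(pr), tolerance = 1e-10)
})

test_that("centered values average to zero and centering is recorded", {
  toy <- make_toy()
  fit <- gbt(toy$x, toy$y, n.trees = 20, depth = 2, shrinkage = 0.1, seed = 2)
  pd <- partial_dependence(fit, "v1", data = toy$x)
  expect_lt(abs(mean(pd$values)), 1e-10)
  raw <- partial_dependence(fit, "v1", data = toy$x, center = FALSE)
  expect_equal(raw$values - mean(raw$values), pd$values, tolerance = 1e-12)
})

test_that("partial dependence ignores the ordering of reference rows", {
  toy <- make_toy(n = 80)
  fit <- gbt(toy$x, toy$y, n.trees = 15, depth = 2, shrinkage = 0.2, seed = 3)
  pts <- toy$x[1:7, "v1", drop = FALSE]
  a <- partial_dependence(fit, "v1", points = pts, data = toy$x)$values
  b <- partial_dependence(fit, "v1", points = pts,
                          data = toy$x[sample(80), ])$values
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("single-stump partial dependence is the centered step function", {
  x <- matrix(c(rep(-1, 10), rep(1, 10)), ncol = 1, dimnames = list(NULL, "x1"))
  y <- c(rep(0, 10), rep(1, 10))
  fit <- gbt(x, y, n.trees = 1, depth = 1, shrinkage = 1, bag.fraction = 1,
             min.obs = 5)
  pd <- partial_dependence(fit, "x1", points = matrix(c(-1, 1), 2), data = x)
  expect_equal(pd$values, c(-0.5, 0.5))
})

test_that("pd_grid spans the requested percentile range", {
  df <- data.frame(a = 1:100, b = rnorm(100))
  g <- pd_grid(df, c("a", "b"), n = 5)
  expect_equal(dim(g), c(25, 2))
  expect_equal(range(g[, "a"]), unname(quantile(df$a, c(0.1, 0.9))))
})

test_that("unknown subset variables are rejected", {
  toy <- make_toy()
  fit <- gbt(toy$x, toy$y, n.trees = 5)
  expect_error(partial_dependence(fit, "nope", data = toy$x), "unknown")
  expect_error(h_stat(fit, c("v1", "v1"), toy$x), "distinct")
})
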