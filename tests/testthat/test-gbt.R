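test_that("degenerate ensembles reduce to the loss-optimal constant", {
  toy <- make_toy()
  fit0 <- gbt(toy$x, toy$y, n.trees = 0)
  expect_equal(unique(predict(fit0, toy$x)), mean(toy$y))
  fit_abs <- gbt(toy$x, toy$y, n.trees = 0, loss = "absolute")
  expect_equal(fit_abs$init, median(toy$y))
})

test_that("a single stump on a balanced binary design is exact", {
  x <- matrix(c(rep(-1, 20), rep(1, 20)), ncol = 1)
  y <- as.numeric(x > 0)
  fit <- gbt(x, y, n.trees = 1, depth = 1, shrinkage = 1, bag.fraction = 1,
             min.obs = 5)
  expect_equal(sort(unique(predict(fit, x))), c(0, 1))
  expect_equal(predict(fit, x), y)
})

test_that("training error is non-increasing without subsampling", {
  toy <- make_toy(n = 120)
  fit <- gbt(toy$x, toy$y, n.trees = 100, depth = 2, shrinkage = 0.1,
             bag.fraction = 1, min.obs = 5)
  staged <- staged_predict(fit, toy$x, 0:100)
  mse <- colMeans((toy$y - staged)^2)
  expect_true(all(diff(mse) <= 1e-12))
})

test_that("fits are reproducible under a seed and staged-consistent", {
  toy <- make_toy(n = 100)
  f1 <- gbt(toy$x, toy$y, n.trees = 40, depth = 3, shrinkage = 0.1, seed = 7)
  f2 <- gbt(toy$x, toy$y, n.trees = 40, depth = 3, shrinkage = 0.1, seed = 7)
  expect_identical(f1$trees, f2$trees)
  # the first m trees of a longer fit equal a fit stopped at m
  f3 <- gbt(toy$x, toy$y, n.trees = 15, depth = 3, shrinkage = 0.1, seed = 7)
  expect_identical(f1$trees[1:15], f3$trees)
  expect_equal(predict(f1, toy$x, n.trees = 15), predict(f3, toy$x))
})

test_that("staged prediction is additive in tree contributions", {
  toy <- make_toy(n = 90)
  fit <- gbt(toy$x, toy$y, n.trees = 20, depth = 2, shrinkage = 0.3, seed = 2)
  staged <- staged_predict(fit, toy$x, 0:20)
  expect_equal(unname(staged[, 1]), rep(fit$init, 90))
  expect_equal(unname(staged[, 21]), predict(fit, toy$x))
  # each increment is one shrunken tree, reconstructed from the node table
  tr <- fit$trees[[5]]
  manual <- manual_gbt(list(tr), fit$var.names, init = 0, shrinkage = 1)
  expect_equal(unname(staged[, 6] - staged[, 5]),
               fit$shrinkage * predict(manual, toy$x))
})

test_that("tree node tables satisfy their structural invariants", {
  toy <- make_toy(n = 150, p = 5)
  fit <- gbt(toy$x, toy$y, n.trees = 30, depth = 4, shrinkage = 0.1,
             bag.fraction = 0.5, seed = 3)
  for (tr in fit$trees) {
    internal <- tr[, "var"] > 0
    expect_lte(sum(internal), 4)             # at most d splits
    expect_true(all(tr[internal, "improvement"] >= 0))
    # children's weight fractions sum to the parent's
    l <- tr[internal, "left"]; r <- tr[internal, "right"]
    expect_equal(tr[l, "weight"] + tr[r, "weight"], tr[internal, "weight"],
                 tolerance = 1e-12)
    # every leaf carries at least min.obs subsampled observations
    leaves <- !internal
    expect_true(all(tr[leaves, "weight"] * 75 >= 10 - 1e-9))
  }
})

test_that("variable importance sums split improvements and scales to 100", {
  toy <- make_toy(n = 150, p = 5)
  fit <- gbt(toy$x, toy$y, n.trees = 50, depth = 2, shrinkage = 0.1, seed = 1)
  ri <- relative_influence(fit)
  expect_equal(max(ri), 100)
  expect_setequal(names(ri), paste0("v", 1:5))
  # raw scores equal the sum over node tables
  raw <- relative_influence(fit, scale = FALSE)
  byhand <- sapply(fit$var.names, function(v) {
    sum(vapply(fit$trees, function(tr) {
      rows <- tr[, "var"] == match(v, fit$var.names)
      sum(tr[rows, "improvement"])
    }, numeric(1)))
  })
  expect_equal(raw[names(byhand)], byhand)
  # a single-stump ensemble concentrates all influence on one variable
  x1 <- matrix(rnorm(80 * 3), 80, 3)
  fit1 <- gbt(x1, x1[, 1], n.trees = 1, depth = 1, shrinkage = 1,
              bag.fraction = 1)
  ri1 <- relative_influence(fit1)
  expect_equal(unname(ri1), c(100, 0, 0))
})

test_that("absolute-error loss is robust to a gross outlier", {
  set.seed(4)
  x <- matrix(runif(120), ncol = 1)
  y <- 2 * x[, 1] + rnorm(120, 0, 0.05)
  y[1] <- 100
  fit <- gbt(x, y, n.trees = 150, depth = 1, shrinkage = 0.2,
             bag.fraction = 1, loss = "absolute")
  pred <- predict(fit, x)
  expect_lt(max(abs(pred[-1] - 2 * x[-1, 1])), 0.5)
})

test_that("input validation rejects malformed problems", {
  toy <- make_toy()
  expect_error(gbt(toy$x, c(toy$y[-1], NA)), "missing")
  expect_error(gbt(toy$x, toy$y[-1]), "length")
  expect_error(gbt(toy$x, toy$y, shrinkage = 0), "shrinkage")
  expect_error(predict(gbt(toy$x, toy$y, n.trees = 5), toy$x, n.trees = 6),
               "exceeds")
  expect_error(gbt(toy$x[1:10, ], toy$y[1:10], min.obs = 10), "observations")
})

test_that("the formula interface matches the default method", {
  toy <- make_toy(n = 60)
  df <- data.frame(toy$x, y = toy$y)
  f1 <- gbt(y ~ ., data = df, n.trees = 10, depth = 2, seed = 5)
  f2 <- gbt(toy$x, toy$y, n.trees = 10, depth = 2, seed = 5)
  expect_identical(f1$trees, f2$trees)
})

test_that("ensembles round-trip through the JSON serialization", {
  toy <- make_toy(n = 70)
  fit <- gbt(toy$x, toy$y, n.trees = 12, depth = 3, shrinkage = 0.1, seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  gbt_to_json(fit, path)
  back <- gbt_from_json(path)
  expect_equal(predict(back, toy$x), predict(fit, toy$x), tolerance = 1e-12)
  expect_equal(relative_influence(back), relative_influence(fit))
  expect_identical(back$var.names, fit$var.names)
})
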