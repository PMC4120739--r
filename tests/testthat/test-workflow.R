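test_that("the workflow runs end to end and writes its artifacts", {
  set.seed(51)
  n <- 250
  x <- matrix(runif(n * 5), n, 5, dimnames = list(NULL, paste0("v", 1:5)))
  df <- data.frame(x, y = 2 * x[, 1] * x[, 2] + x[, 3] + rnorm(n, 0, 0.3))
  out <- withr::local_tempdir()
  res <- run_workflow(df, "y", out_dir = out,
                      tune_args = list(depths = c(1L, 2L),
                                       m.grid = c(60L, 120L), n_boot = 5,
                                       shrinkage = 0.1, min.obs = 5L),
                      n_top = 4, n_rep = 20, seed = 1)
  expect_s3_class(res, "mixboost_workflow")
  expect_true(res$interactions_evaluated)
  expect_true(file.exists(file.path(out, "manifest.json")))
  for (f in c("importance.csv", "tuning_grid.csv", "h_total.csv",
              "importance.png"))
    expect_true(file.exists(file.path(out, f)))
  # manifest digests cover every declared artifact
  man <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  expect_true(all(file.exists(names(man$artifacts))))
  expect_equal(unlist(man$artifacts),
               tools::md5sum(names(man$artifacts)))
  # importance CSV is consistent with the fitted model
  imp <- read.csv(file.path(out, "importance.csv"))
  expect_equal(imp$influence, unname(relative_influence(res$fit)))
})

test_that("an additive tuned depth skips interaction evaluation", {
  set.seed(52)
  n <- 200
  x <- matrix(rnorm(n * 3), n, 3, dimnames = list(NULL, paste0("v", 1:3)))
  df <- data.frame(x, y = x[, 1] + rnorm(n, 0, 0.2))
  expect_message(
    res <- run_workflow(df, "y", out_dir = NULL, params = list(
      n.trees = 50L, depth = 1L, shrinkage = 0.1), tune_args = NULL),
    "no interaction evaluation")
  expect_false(res$interactions_evaluated)
  expect_length(res$h, 0)
})

test_that("workflow validates its inputs", {
  df <- data.frame(a = 1:30, b = letters[rep(1:3, 10)], y = rnorm(30))
  expect_error(run_workflow(df, "z"), "outcome")
  expect_error(run_workflow(df, "y", params = list(n.trees = 5L, depth = 1L),
                            tune_args = NULL), "non-numeric")
})

test_that("log-outcome transform is applied before fitting", {
  set.seed(53)
  n <- 150
  x <- matrix(runif(n * 2), n, 2, dimnames = list(NULL, c("a", "b")))
  df <- data.frame(x, y = exp(x[, 1] + rnorm(n, 0, 0.1)))
  res <- run_workflow(df, "y", log_outcome = TRUE, tune_args = NULL,
                      params = list(n.trees = 30L, depth = 1L,
                                    shrinkage = 0.2), seed = 2)
  expect_equal(res$fit$y, log(df$y))
  expect_error(run_workflow(data.frame(a = 1:30, y = c(-1, rnorm(29))), "y",
                            log_outcome = TRUE), "positive")
})

test_that("manifests capture command, seed and digests", {
  out <- withr::local_tempdir()
  f <- file.path(out, "x.csv")
  write.csv(data.frame(a = 1), f, row.names = FALSE)
  man <- write_manifest(file.path(out, "manifest.json"), "simulate",
                        config = list(n = 10), seed = 3, files = f)
  expect_equal(man$command, "simulate")
  expect_equal(man$seed, 3)
  back <- jsonlite::fromJSON(file.path(out, "manifest.json"))
  expect_equal(back$config$n, 10)
  expect_equal(unname(unlist(back$artifacts)), unname(tools::md5sum(f)))
})
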