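test_that("s_transform is the mid-rank probability-integral transform", {
  expect_equal(sort(s_transform(c(3, -1, 10, 0.5))),
               c(0.125, 0.375, 0.625, 0.875))
  # mid-rank tie rule: a constant vector maps to 1/2 everywhere
  expect_equal(s_transform(rep(7, 5)), rep(0.5, 5))
  # strictly inside (0,1), monotone, exact mean 1/2 for tie-free input
  set.seed(3)
  for (n in c(1, 2, 17, 100)) {
    x <- rnorm(n)
    s <- s_transform(x)
    expect_true(all(s > 0 & s < 1))
    expect_equal(order(s), order(x))
    expect_equal(mean(s), 0.5)
  }
  expect_error(s_transform(numeric(0)), "empty")
  expect_error(s_transform(c(1, NA)), "finite")
})

test_that("target function matches closed-form values at chosen ranks", {
  f <- mixboost:::mixture_f_s
  # all four product-term ranks at 1, no OCDD contribution, male at BPA = 1
  expect_equal(f(1, 1, 1, 1, 0, 1, 1), 12.0)
  # sin(pi/2) = 1 knocks off 1.6; female with s[BPA] = 0 adds nothing
  expect_equal(f(1, 1, 1, 1, 0.25, 0, 0), 9.4)
  # all product ranks at 0: the product term collapses to 11 e^{-10}
  expect_equal(f(0, 0, 0, 0, 0.5, 0, 0) - 11 * exp(-10), 0,
               tolerance = 1e-12)
})

test_that("target function depends only on its seven named columns", {
  cfg <- mixture_config(n = 150)
  set.seed(11)
  panel <- simulate_panel(cfg)
  f0 <- mixture_f(panel)
  perturbed <- panel
  for (col in c("HCB", "Zn", "PCB126", "MEP"))
    perturbed[[col]] <- sample(perturbed[[col]])
  expect_identical(mixture_f(perturbed), f0)
  expect_error(mixture_f(panel[setdiff(names(panel), "Cd")]), "Cd")
})

test_that("simulated panel has the configured shape and marginals", {
  cfg <- mixture_config(n = 400)
  set.seed(5)
  panel <- simulate_panel(cfg)
  expect_equal(dim(panel), c(400, 28))
  expect_true(all(as.matrix(panel[, 1:27]) > 0))
  expect_true(all(panel$sex %in% c(0, 1)))
  expect_false(anyNA(panel))
  # seeded determinism
  set.seed(5)
  expect_identical(simulate_panel(cfg), panel)
})

test_that("PCB block follows the configured Gaussian copula correlation", {
  R <- default_pcb_correlation()
  R[] <- 0.5; diag(R) <- 1
  cfg <- mixture_config(n = 100000, pcb_correlation = R)
  set.seed(8)
  panel <- simulate_panel(cfg)
  lc <- cor(log(panel$PCB118), log(panel$PCB153))
  expect_lt(abs(lc - 0.5), 0.02)
  # non-block contaminants stay uncorrelated with the block
  expect_lt(abs(cor(log(panel$PCB118), log(panel$Cd))), 0.02)
  # invalid correlation matrices are rejected
  bad <- R; bad[1, 2] <- bad[2, 1] <- 1.2
  expect_error(mixture_config(pcb_correlation = bad), "positive definite")
})

test_that("noise calibration hits the requested signal-to-noise ratio", {
  set.seed(2)
  f <- mixboost:::mixture_f_s(runif(500), runif(500), runif(500), runif(500),
                              runif(500), runif(500), rbinom(500, 1, 0.5))
  expect_equal(calibrate_noise(f, 1)$sigma, sd(f))
  expect_equal(calibrate_noise(f, 2)$sigma, sd(f) / sqrt(2))
  expect_error(calibrate_noise(rep(1, 10), 1), "constant")
})

test_that("realized SNR stays within 10% of target at n = 1000", {
  for (snr in c(2, 1, 0.5, 0.1)) {
    sim <- simulate_mixture(mixture_config(n = 1000, snr = snr), seed = snr * 100)
    expect_lt(abs(sim$realized_snr - snr) / snr, 0.10)
    expect_equal(length(sim$y), 1000)
  }
})

test_that("mean realized SNR converges to the target across seeds", {
  snrs <- vapply(1:40, function(s) {
    cfg <- mixture_config(n = 1000, snr = 1, check_snr = FALSE)
    simulate_mixture(cfg, seed = s)$realized_snr
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 1), 0.02)
})

test_that("mixture CSV round-trips", {
  sim <- simulate_mixture(mixture_config(n = 50), seed = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_mixture_csv(sim, path)
  back <- read.csv(path)
  expect_equal(dim(back), c(50, 29))
  expect_equal(back$y, sim$y, tolerance = 1e-12)
  # byte-identical regeneration under the same seed
  sim2 <- simulate_mixture(mixture_config(n = 50), seed = 4)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_mixture_csv(sim2, path2)
  expect_identical(readLines(path), readLines(path2))
})
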