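test_that("conjugate posterior follows the closed form", {
  counts <- c(8, 7, 6, 9, 7, 8, 7, 6, 8, 7)   # n = 10, sum = 73
  p <- lambda_posterior(counts)
  expect_equal(unname(p), c(73.001, 10.001))
  expect_equal(unname(p["shape"] / p["rate"]), 7.2994, tolerance = 1e-4)
  expect_equal(unname(lambda_posterior(c(1))), c(1.001, 1.001))
  expect_warning(p0 <- lambda_posterior(integer(0)), "prior unchanged")
  expect_equal(unname(p0), c(0.001, 0.001))
})

test_that("count validation names offending rows", {
  expect_error(fit_counts(c(2, 0, 3, 1.5)), "offending rows: 2, 4")
  expect_error(fit_counts_suffstat(10, 5), "at least 1")
})

test_that("MCMC chains target the conjugate posterior", {
  set.seed(10)
  for (rep in 1:3) {
    counts <- simulate_counts(runif(1, 1, 12), sample(5:30, 1))
    fit <- fit_counts(counts, config = quick_cfg(seed = rep, n_iter = 20000))
    conj_mean <- fit$posterior["shape"] / fit$posterior["rate"]
    expect_lt(abs(fit$summary$mean - conj_mean), 0.02)
  }
})

test_that("same seed reproduces identical chains", {
  counts <- c(5, 6, 7, 8, 9)
  f1 <- fit_counts(counts, config = quick_cfg(seed = 99))
  f2 <- fit_counts(counts, config = quick_cfg(seed = 99))
  expect_identical(f1$chains$chains, f2$chains$chains)
})

test_that("highest-fragmenting group reproduces its published interval", {
  fit <- fit_counts_suffstat(
    10, 73, group_label = "Poker:GS65",
    config = sampler_config(n_iter = 50000L, seed = 1L))
  expect_lt(abs(fit$summary$mean - 7.2994), 0.02)
  expect_equal(fit$summary$hdi_low, 5.71, tolerance = 0.05)
  expect_equal(fit$summary$hdi_high, 9.04, tolerance = 0.05)
})

test_that("identical groups give a symmetric null difference", {
  counts <- c(5, 7, 6, 8, 7, 6, 7, 8, 6, 7)
  fa <- fit_counts(counts, "a", config = quick_cfg(seed = 1))
  fb <- fit_counts(counts, "b", config = quick_cfg(seed = 2))
  ct <- compare_lambda(fa, fb)
  expect_lt(abs(ct$mean), 0.2)
  expect_lt(ct$hdi_low, 0)
  expect_gt(ct$hdi_high, 0)
  expect_gt(ct$prob_negative, 0.4)
  expect_lt(ct$prob_negative, 0.6)
})

test_that("low-minus-high rate differences are wholly negative at GS65", {
  cfg <- function(s) quick_cfg(seed = s, n_iter = 20000)
  low <- list(GP = fit_counts_suffstat(10, 19, group_label = "GP",
                                       config = cfg(1)),
              Henni = fit_counts_suffstat(10, 35, group_label = "Henni",
                                          config = cfg(2)))
  high <- list(Poker = fit_counts_suffstat(10, 73, group_label = "Poker",
                                           config = cfg(3)),
               Propino = fit_counts_suffstat(10, 100, group_label = "Propino",
                                             config = cfg(4)))
  for (l in low) for (h in high) {
    ct <- compare_lambda(l, h)
    expect_lt(ct$hdi_high, 0)
  }
})

test_that("paired-draw difference matches the quadrature convolution oracle", {
  fa <- fit_counts_suffstat(10, 73, config = quick_cfg(seed = 5,
                                                       n_iter = 30000))
  fb <- fit_counts_suffstat(10, 35, config = quick_cfg(seed = 6,
                                                       n_iter = 30000))
  ct <- compare_lambda(fa, fb)
  # oracle CDF of D = A - B with A ~ Ga(73.001,10.001), B ~ Ga(35.001,10.001)
  cdf_d <- function(d) {
    f <- function(b) pgamma(d + b, 73.001, 10.001) * dgamma(b, 35.001, 10.001)
    integrate(f, 0, 15, rel.tol = 1e-9)$value
  }
  grid <- seq(1, 7, length.out = 25)
  emp <- ecdf(ct$draws)
  ks <- max(abs(vapply(grid, cdf_d, numeric(1)) - emp(grid)))
  expect_lt(ks, 0.02)
})

test_that("count fit methods behave", {
  fit <- fit_counts(c(5, 6, 7, 8, 9, 7), "demo", config = quick_cfg())
  expect_output(print(fit), "lambda")
  s <- summary(fit)
  expect_true(all(c("mean", "hdi_low", "psrf", "ess") %in% names(s)))
  expect_named(coef(fit), "lambda")
  y <- simulate(fit, nsim = 5, seed = 1)
  expect_equal(dim(y), c(5, 6))
  expect_true(all(y >= 0))
})
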