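# helper: a minimal fitted_model stub for formula-level checks
stub_fit <- function(mu_hat, sigma2_hat, nu, r = 5) {
  structure(list(mu_hat = mu_hat, sigma2_hat = sigma2_hat, nu = nu,
                 r = r, design = make_design(r)),
            class = "fitted_model")
}

test_that("eta_hat adds half the residual mean square for the mean target", {
  f <- stub_fit(rep(1.5, 8), 0, 32)
  expect_equal(eta_hat(f, 1), 1.5)
  f2 <- stub_fit(rep(1, 8), 2, 32)
  expect_equal(eta_hat(f2, 3), 2.0)
  expect_equal(eta_hat(f2, 3, "log_scale_mean"), 1.0)
  expect_error(eta_hat(f2, 0), "1..8")

  # saturated fit recovers observed cell means of the log response
  fx <- sim_data(13, r = 5)
  ff <- fit_model(enumerate_hierarchical_models(fx$design)[[19]],
                  fx$design, fx$data)
  cm <- tapply(log(fx$data$y), mataboot:::.cell_index(fx$data, fx$design),
               mean)
  expect_equal(eta_hat(ff, 2, "log_scale_mean"), unname(cm[2]),
               tolerance = 1e-12)
})

test_that("eta_variance matches its closed form and rejects degenerate fits", {
  f <- stub_fit(rep(0, 8), 1, 32)
  expect_equal(eta_variance(f, 1, h = 1 / 5), 0.2 + 1 / 68,
               tolerance = 1e-12)
  expect_equal(eta_variance(f, 1, h = 1 / 5, parameter_kind = "log_scale_mean"),
               0.2, tolerance = 1e-12)
  f0 <- stub_fit(rep(0, 8), 0, 32)
  expect_error(eta_variance(f0, 1, h = 1 / 5), "degenerate")
  expect_error(eta_variance(f, 1, h = 1.5), "0, 1")
})

test_that("eta_variance is unbiased under the generating model", {
  # moderate-size check; the full-scale version runs in the acceptance suite
  d <- make_design(r = 5)
  full <- enumerate_hierarchical_models(d)[[19]]
  n_mc <- 20000
  set.seed(301)
  v <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    ybar <- rnorm(8, 0, sqrt(1 / 5))
    ssw <- rchisq(1, 32)
    f <- mataboot:::.fit_summary(full, ybar, ssw, d)
    v[i] <- eta_variance(f, 1, h = 1 / 5)
  }
  truth <- 1 / 5 + 1 / (2 * 32)   # sigma^2 h + sigma^4 / (2 nu)
  expect_lt(abs(mean(v) - truth) / truth, 0.02)
})

test_that("back_transform exponentiates limits and preserves coverage", {
  iv <- new_interval(-1, 1, 0.025, "ma_wald")
  bt <- back_transform(iv)
  expect_equal(c(bt$lower, bt$upper), c(exp(-1), exp(1)))
  expect_equal(bt$scale, "theta")
  expect_equal(bt$method, "ma_wald")
  iv0 <- back_transform(new_interval(0, 0, 0.1, "pb"))
  expect_equal(c(iv0$lower, iv0$upper), c(1, 1))

  # monotone map: containment is equivalent on the two scales
  set.seed(8)
  for (i in 1:50) {
    lims <- sort(rnorm(2)); theta <- exp(rnorm(1))
    covered_eta <- log(theta) >= lims[1] && log(theta) <= lims[2]
    b <- back_transform(new_interval(lims[1], lims[2], 0.025, "pb"))
    expect_equal(theta >= b$lower && theta <= b$upper, covered_eta)
  }
})

test_that("draw_effects follows the scenario magnitudes deterministically", {
  scn0 <- scenario(c(0, 0, 0), r = 2)
  set.seed(1)
  e0 <- draw_effects(scn0)
  expect_equal(e0$main, rep(0, 3))
  expect_equal(e0$two_way, rep(0, 3))
  expect_equal(e0$three_way, 0)
  expect_equal(mataboot:::.effect_cell_means(e0, make_design(2)), rep(0, 8))

  scn <- scenario("HML", r = 5, seed = 99)
  set.seed(99); a <- draw_effects(scn)
  set.seed(99); b <- draw_effects(scn)
  expect_identical(a, b)

  set.seed(17)
  draws <- replicate(10000, unlist(draw_effects(scn)[c("main", "two_way",
                                                       "three_way")]))
  expect_equal(sd(draws[1:3, ]), 2, tolerance = 0.05)
  expect_equal(sd(draws[4:6, ]), 1, tolerance = 0.05)
  expect_equal(sd(draws[7, ]), 0.1, tolerance = 0.05)
})

test_that("simulated datasets follow the lognormal factorial model", {
  d <- make_design(r = 5)
  scn_tiny <- scenario("HML", r = 5, sigma2 = 1e-12)
  set.seed(2)
  eff <- draw_effects(scn_tiny)
  dat <- simulate_dataset(eff, d)
  mu <- mataboot:::.effect_cell_means(eff, d)
  idx <- mataboot:::.cell_index(dat, d)
  expect_equal(dat$y, exp(mu[idx]), tolerance = 1e-4)
  expect_equal(nrow(dat), 40L)
  expect_equal(as.integer(table(idx)), rep(5L, 8))

  # log-scale cell means concentrate on mu_ijk (CLT bound)
  scn1 <- scenario("MML", r = 2, sigma2 = 1, seed = 5)
  set.seed(5)
  eff1 <- draw_effects(scn1)
  mu1 <- mataboot:::.effect_cell_means(eff1, make_design(2))
  nrep <- 10000
  tot <- numeric(8)
  for (i in seq_len(nrep)) {
    dd <- simulate_dataset(eff1, make_design(2))
    tot <- tot + rowsum(log(dd$y), mataboot:::.cell_index(dd, make_design(2)))[, 1] / 2
  }
  se <- sqrt(1 / (2 * nrep))
  expect_true(all(abs(tot / nrep - mu1) < 4 * se))
})

test_that("true_parameter reflects the effect set exactly", {
  d <- make_design(r = 2)
  scn0 <- scenario(c(0, 0, 0), r = 2, sigma2 = 1)
  eff <- draw_effects(scn0)
  expect_equal(true_parameter(eff, 1, d), 0.5)
  expect_equal(true_parameter(eff, 1, d, scale = "theta"), exp(0.5))
  expect_equal(true_parameter(eff, 1, d, "log_scale_mean"), 0)
  expect_equal(true_parameter(eff, 1, d, "log_scale_mean", "theta"), 1)

  # relabelling both levels of every factor swaps cell (1,1,1) with
  # (2,2,2): odd-order effect values flip sign, two-way values are invariant
  set.seed(31)
  e1 <- draw_effects(scenario("HMM", r = 2))
  e2 <- e1
  e2$main <- -e1$main; e2$three_way <- -e1$three_way
  expect_equal(true_parameter(e1, 1, d), true_parameter(e2, 8, d),
               tolerance = 1e-12)
})

test_that("estimate and variance of the lognormal mean are positively correlated", {
  d <- make_design(r = 2)
  full <- enumerate_hierarchical_models(d)[[19]]
  set.seed(77)
  n_mc <- 10000
  est <- v <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    f <- mataboot:::.fit_summary(full, rnorm(8, 0, sqrt(1 / 2)), rchisq(1, 8), d)
    est[i] <- eta_hat(f, 1)
    v[i] <- eta_variance(f, 1, h = 1 / 2)
  }
  expect_gt(cor(est, v), 0)
})

test_that("the studentized median-target statistic is exactly t distributed", {
  d <- make_design(r = 2)
  full <- enumerate_hierarchical_models(d)[[19]]
  set.seed(123)
  n_mc <- 10000
  tstat <- numeric(n_mc)
  for (i in seq_len(n_mc)) {
    f <- mataboot:::.fit_summary(full, rnorm(8, 0, sqrt(1 / 2)), rchisq(1, 8), d)
    tstat[i] <- (eta_hat(f, 1, "log_scale_mean") - 0) /
      sqrt(eta_variance(f, 1, h = 1 / 2, parameter_kind = "log_scale_mean"))
  }
  ks <- suppressWarnings(ks.test(tstat, function(q) pt(q, 8)))
  expect_gt(ks$p.value, 0.001)
})

test_that("lognormal_skewness evaluates the closed form", {
  expect_equal(lognormal_skewness(1), (exp(1) + 2) * sqrt(exp(1) - 1),
               tolerance = 1e-12)
})
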