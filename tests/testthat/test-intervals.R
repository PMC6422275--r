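test_that("full-model Wald interval matches t quantiles", {
  est <- model_estimates(0, 1, 10)
  iv <- full_wald(est, alpha = 0.025)
  expect_equal(iv$lower, -qt(0.975, 10), tolerance = 1e-10)
  expect_equal(iv$upper, qt(0.975, 10), tolerance = 1e-10)

  # large df: normal limit
  ivz <- full_wald(model_estimates(0, 1, 1e6), alpha = 0.025)
  expect_equal(ivz$upper, qnorm(0.975), tolerance = 1e-4)

  # width shrinks to zero as alpha approaches 0.5
  ivn <- full_wald(est, alpha = 0.499)
  expect_lt(ivn$upper - ivn$lower, 0.01)

  expect_error(full_wald(model_estimates(0, 0, 10)), "degenerate")
})

test_that("MA-Wald interval composes the averaged estimate and variance", {
  est1 <- model_estimates(1.7, 0.25, 1e6)
  iv <- ma_wald(est1, 1, alpha = 0.025)
  expect_equal(iv$lower, 1.7 - qnorm(0.975) * 0.5, tolerance = 1e-4)

  est2 <- model_estimates(c(0, 2), c(1, 1), c(1e6, 1e6))
  iv2 <- ma_wald(est2, c(0.5, 0.5), alpha = 0.025)
  expect_equal((iv2$lower + iv2$upper) / 2, 1, tolerance = 1e-6)
  expect_equal(iv2$upper - iv2$lower, 2 * qnorm(0.975) * sqrt(2),
               tolerance = 1e-3)

  # adding a disagreeing model at positive weight never narrows the interval
  base <- ma_wald(model_estimates(0, 1, 50), 1)
  mixed <- ma_wald(model_estimates(c(0, 1.5), c(1, 1), c(50, 50)),
                   c(0.8, 0.2))
  expect_gte(mixed$upper - mixed$lower, base$upper - base$lower)
})

test_that("the tail-area equation is monotone and weight-linear", {
  est <- model_estimates(2, 4, 12)
  expect_equal(mata_tail_equation(2, est, 1, "upper", "z"), 0.5)
  expect_equal(mata_tail_equation(2, est, 1, "lower", "t"), 0.5)

  est2 <- model_estimates(c(0, 1), c(1, 2), c(10, 20))
  grid <- seq(-4, 5, length.out = 60)
  gu <- vapply(grid, mata_tail_equation, 0, estimates = est2,
               weights = c(0.3, 0.7), side = "upper", kernel = "t")
  expect_true(all(diff(gu) < 0))

  # zero-weight models do not influence the value
  est3 <- model_estimates(c(0, 99), c(1, 1), c(10, 10))
  expect_equal(
    mata_tail_equation(1.3, est3, c(1, 0), "upper", "t"),
    mata_tail_equation(1.3, model_estimates(0, 1, 10), 1, "upper", "t"),
    tolerance = 1e-12)
})

test_that("single-model MATA-Wald reduces to the classical intervals", {
  est <- model_estimates(0, 1, 10)
  ivt <- mata_wald(est, 1, alpha = 0.025, version = "t")
  expect_equal(ivt$lower, -qt(0.975, 10), tolerance = 1e-7)
  expect_equal(ivt$upper, qt(0.975, 10), tolerance = 1e-7)
  ivz <- mata_wald(est, 1, alpha = 0.025, version = "z")
  expect_equal(ivz$lower, -qnorm(0.975), tolerance = 1e-7)
  expect_equal(ivz$upper, qnorm(0.975), tolerance = 1e-7)

  # degenerate weights reduce the multi-model interval to one model
  est2 <- model_estimates(c(1.2, -5), c(0.3, 7), c(14, 3))
  iv1 <- mata_wald(est2, c(1, 0), version = "t")
  ref <- full_wald(est2[1, ])
  expect_equal(iv1$lower, ref$lower, tolerance = 1e-8)
  expect_equal(iv1$upper, ref$upper, tolerance = 1e-8)
})

test_that("multi-model MATA-Wald agrees with a dense grid-scan oracle", {
  est <- model_estimates(c(0.4, 1.1), c(0.09, 0.2), c(12, 30))
  w <- c(0.35, 0.65)
  alpha <- 0.025
  iv <- mata_wald(est, w, alpha, version = "t")

  grid <- seq(-3, 4, by = 1e-3)
  gu <- vapply(grid, mata_tail_equation, 0, estimates = est, weights = w,
               side = "upper", kernel = "t")
  gl <- vapply(grid, mata_tail_equation, 0, estimates = est, weights = w,
               side = "lower", kernel = "t")
  up_oracle <- approx(gu, grid, xout = alpha)$y   # gu strictly decreasing
  lo_oracle <- approx(gl, grid, xout = alpha)$y
  expect_equal(iv$upper, up_oracle, tolerance = 1e-5)
  expect_equal(iv$lower, lo_oracle, tolerance = 1e-5)

  # solved limits satisfy the tail equations at solver tolerance
  expect_equal(mata_tail_equation(iv$upper, est, w, "upper", "t"), alpha,
               tolerance = 1e-7)
  expect_equal(mata_tail_equation(iv$lower, est, w, "lower", "t"), alpha,
               tolerance = 1e-7)
})

test_that("the t-version MATA-Wald strictly contains the z-version", {
  set.seed(66)
  for (i in 1:10) {
    M <- sample(2:5, 1)
    est <- model_estimates(rnorm(M), exp(rnorm(M)), sample(4:40, M))
    w <- aic_weights(rnorm(M, sd = 2))
    ivt <- mata_wald(est, w, version = "t")
    ivz <- mata_wald(est, w, version = "z")
    expect_lt(ivt$lower, ivz$lower)
    expect_gt(ivt$upper, ivz$upper)
  }
})

test_that("MATA-SBoot solves the empirical tail equations", {
  est <- model_estimates(c(0, 0.8), c(1, 0.5), c(10, 20))
  w <- c(0.4, 0.6)
  set.seed(5)
  tails <- list(sort(rt(999, 10)), sort(rt(999, 20)))
  iv <- mata_sboot(est, w, tails, alpha = 0.05)
  expect_equal(mata_tail_equation(iv$upper, est, w, "upper", "boot", tails),
               0.05, tolerance = 1e-8)
  expect_equal(mata_tail_equation(iv$lower, est, w, "lower", "boot", tails),
               0.05, tolerance = 1e-8)

  # symmetric tails give an interval symmetric about the estimate
  sym <- sort(c(-(1:400) / 100, (1:400) / 100))
  ivs <- mata_sboot(model_estimates(2, 1, 10), 1, list(sym), alpha = 0.05)
  expect_equal(ivs$upper - 2, 2 - ivs$lower, tolerance = 1e-9)

  # degenerate weights reduce to the single-model studentized bootstrap:
  # limits theta_hat - sd * Q(alpha or 1 - alpha) with the interpolated
  # ECDF quantile Q at plotting positions
  est2 <- model_estimates(c(1, -4), c(0.25, 9), c(10, 2))
  B <- 999
  set.seed(6)
  t1 <- sort(rt(B, 10) - 0.7)
  iv1 <- mata_sboot(est2, c(1, 0), list(t1, sort(rnorm(B))), alpha = 0.025)
  qs <- approx(seq_len(B) / (B + 1), t1, xout = c(0.025, 0.975))$y
  expect_equal(iv1$upper, 1 - 0.5 * qs[1], tolerance = 1e-9)
  expect_equal(iv1$lower, 1 - 0.5 * qs[2], tolerance = 1e-9)

  # negatively skewed tails push the upper limit above the t-version's
  skewed <- sort(-(rchisq(5000, 4) - 4) / sqrt(8))
  ivneg <- mata_sboot(model_estimates(0, 1, 10), 1, list(skewed),
                      alpha = 0.025)
  ivt <- mata_wald(model_estimates(0, 1, 10), 1, version = "t")
  expect_gt(ivneg$upper, ivt$upper)

  expect_error(mata_sboot(model_estimates(0, 1, 10), 1,
                          list(sort(rnorm(39))), alpha = 0.01),
               "resolution")
})

test_that("percentile bootstrap uses order-statistic percentiles", {
  fx <- sim_data(77, r = 5)
  models <- enumerate_hierarchical_models(fx$design)

  set.seed(20)
  iv39 <- percentile_bootstrap(fx$data, models, fx$design, 1, B = 39,
                               alpha = 0.025)
  ts <- attr(iv39, "theta_star")
  expect_length(ts, 39L)
  srt <- sort(ts)
  expect_equal(iv39$lower, srt[1])    # ceiling(0.025 * 40) = 1
  expect_equal(iv39$upper, srt[39])   # ceiling(0.975 * 40) = 39

  set.seed(21)
  iv1 <- percentile_bootstrap(fx$data, models, fx$design, 4, B = 199)
  set.seed(21)
  iv2 <- percentile_bootstrap(fx$data, models, fx$design, 4, B = 199)
  expect_identical(attr(iv1, "theta_star"), attr(iv2, "theta_star"))
  # quantile oracle: recompute from the stored estimates
  srt2 <- sort(attr(iv1, "theta_star"))
  expect_equal(iv1$lower, srt2[ceiling(0.025 * 200)])
  expect_equal(iv1$upper, srt2[ceiling(0.975 * 200)])

  expect_error(percentile_bootstrap(fx$data, models[1:5], fx$design, 1, 99),
               "full")
})
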