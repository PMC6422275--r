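# Construction of the six confidence intervals: Full-Wald, MA-Wald,
# MATA-Wald (z and t), percentile bootstrap, and MATA-SBoot.

#' Construct an interval object
#'
#' @param lower,upper Interval limits, `lower <= upper`.
#' @param alpha Per-tail level in (0, 0.5); nominal coverage is
#'   `100 (1 - 2 alpha)%`.
#' @param method Tag: one of `full_wald`, `ma_wald`, `mata_wald_z`,
#'   `mata_wald_t`, `pb`, `mata_sboot`.
#' @param scale `"eta"` (log/working scale) or `"theta"` (response scale).
#' @return Object of class `ma_interval`.
#' @export
new_interval <- function(lower, upper, alpha, method, scale = "eta") {
  if (!is.finite(lower) || !is.finite(upper) || lower > upper)
    stop("invalid interval limits")
  if (alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must lie in (0, 0.5)")
  structure(list(lower = lower, upper = upper, alpha = alpha,
                 method = method, scale = scale),
            class = "ma_interval")
}

#' @export
print.ma_interval <- function(x, ...) {
  cat(sprintf("<%s %d%% interval, %s scale> [%.6g, %.6g]\n",
              x$method, round(100 * (1 - 2 * x$alpha)), x$scale,
              x$lower, x$upper))
  invisible(x)
}

#' Wald interval from the full model
#'
#' The t-based interval `theta_hat +/- t_{nu, 1-alpha} sqrt(var_hat)` using
#' the full (saturated) model's estimate. Equivalent to the MA-Wald or
#' t-version MATA-Wald interval with all weight on the full model.
#'
#' @param estimate One-row data frame from [model_estimates()] (or a list
#'   with `theta_hat`, `var_hat`, `nu`).
#' @param alpha Per-tail level; default 0.025.
#' @return An `ma_interval` on the working scale.
#' @export
full_wald <- function(estimate, alpha = 0.025) {
  if (estimate$var_hat[1L] <= 0)
    stop("degenerate estimate: var_hat <= 0")
  th <- estimate$theta_hat[1L]
  hw <- stats::qt(1 - alpha, estimate$nu[1L]) * sqrt(estimate$var_hat[1L])
  new_interval(th - hw, th + hw, alpha, "full_wald")
}

#' Model-averaged Wald interval
#'
#' `theta_bar +/- z_{1-alpha} sqrt(V(theta_bar))` with the model-averaged
#' estimate and the MA-Wald variance of [ma_wald_variance()].
#'
#' @inheritParams ma_wald_variance
#' @return An `ma_interval` on the working scale.
#' @export
ma_wald <- function(estimates, weights, alpha = 0.025) {
  tb <- model_averaged_estimate(estimates, weights)
  v <- ma_wald_variance(estimates, weights, tb, alpha)
  hw <- stats::qnorm(1 - alpha) * sqrt(v)
  new_interval(tb - hw, tb + hw, alpha, "ma_wald")
}

# per-model tail CDF values at studentized arguments u, for a given kernel
.kernel_cdf <- function(u, estimates, kernel, tails) {
  M <- length(u)
  switch(kernel,
    z = stats::pnorm(u),
    t = stats::pt(u, estimates$nu),
    boot = {
      p <- numeric(M)
      for (m in seq_len(M)) p[m] <- .interp_ecdf(tails[[m]], u[m])
      p
    },
    stop("unknown kernel '", kernel, "'")
  )
}

#' Weighted tail-area equation for MATA intervals
#'
#' Evaluates the function whose roots define the MATA limits. For the upper
#' limit (`side = "upper"`) it is
#' `g(theta) = sum_m w_m Pr(T_m <= (theta_hat_m - theta) / sqrt(var_hat_m))`,
#' and for the lower limit `Pr(T_m >= ...)`; each limit solves
#' `g(theta) = alpha`. `T_m` is standard normal (`kernel = "z"`),
#' t with `nu_m` df (`kernel = "t"`), or the empirical bootstrap
#' distribution of the model's studentized statistic (`kernel = "boot"`,
#' via [tail_probability()]). Both versions are monotone in `theta`, so the
#' roots are unique.
#'
#' @param theta Scalar evaluation point on the working scale.
#' @inheritParams ma_wald_variance
#' @param side `"lower"` or `"upper"` (which limit's equation).
#' @param kernel `"z"`, `"t"` or `"boot"`.
#' @param tails For `kernel = "boot"`: list of `bootstrap_tails` (or sorted
#'   numeric vectors), one per model, aligned with `estimates`.
#' @return Scalar weighted tail probability.
#' @export
mata_tail_equation <- function(theta, estimates, weights,
                               side = c("lower", "upper"), kernel = "t",
                               tails = NULL) {
  side <- match.arg(side)
  .check_estimates(estimates, weights)
  if (kernel == "boot") {
    if (is.null(tails) || length(tails) != nrow(estimates))
      stop("'tails' must supply one bootstrap_tails per model")
    tails <- lapply(tails, function(x)
      if (inherits(x, "bootstrap_tails")) x$sorted_stats else x)
  }
  u <- (estimates$theta_hat - theta) / sqrt(estimates$var_hat)
  p <- .kernel_cdf(u, estimates, kernel, tails)
  if (side == "upper") sum(weights * p) else sum(weights * (1 - p))
}

# Solve g(theta) = alpha for one limit by bracketed root finding.
# side = "upper" solves the upper-limit equation (g decreasing in theta);
# side = "lower" the lower-limit equation (g increasing in theta).
# Lean inner loop: validation happens in the callers, not per evaluation.
.solve_mata <- function(estimates, weights, alpha, kernel, tails, side) {
  th <- estimates$theta_hat
  sd <- sqrt(estimates$var_hat)
  nu <- estimates$nu
  w <- weights
  pfun <- switch(kernel,
    z = stats::pnorm,
    t = function(u) stats::pt(u, nu),
    boot = function(u) {
      p <- numeric(length(u))
      for (m in seq_along(u)) p[m] <- .interp_ecdf(tails[[m]], u[m])
      p
    })
  center <- sum(w * th)
  tol <- 1e-8 * max(1, abs(center))
  half <- 20 * max(sd)
  f <- if (side == "upper")
    function(theta) sum(w * pfun((th - theta) / sd)) - alpha
  else
    function(theta) sum(w * (1 - pfun((th - theta) / sd))) - alpha
  lo <- min(th) - half
  hi <- max(th) + half
  for (e in 0:10) {
    flo <- f(lo); fhi <- f(hi)
    if (flo == 0) return(lo)
    if (fhi == 0) return(hi)
    if (sign(flo) != sign(fhi)) {
      return(stats::uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi,
                            tol = tol)$root)
    }
    width <- hi - lo
    lo <- lo - width / 2
    hi <- hi + width / 2
  }
  stop("MATA root not bracketed after 10 expansions (side = ", side,
       ", kernel = ", kernel, "); g(lo) = ", signif(f(lo), 4),
       ", g(hi) = ", signif(f(hi), 4), ", alpha = ", alpha)
}

#' MATA-Wald interval (z or t version)
#'
#' The model-averaged tail area interval whose limits `[theta_L, theta_U]`
#' solve
#' `sum_m w_m Pr(T_m <= (theta_hat_m - theta_U)/sqrt(var_m)) = alpha` and
#' `sum_m w_m Pr(T_m >= (theta_hat_m - theta_L)/sqrt(var_m)) = alpha`,
#' with `T_m` standard normal (`version = "z"`) or t with `nu_m` df
#' (`version = "t"`). The t-version allows for the uncertainty in each
#' model's variance estimate and always contains the z-version.
#'
#' @inheritParams ma_wald_variance
#' @param version `"t"` (default) or `"z"`.
#' @return An `ma_interval` on the working scale.
#' @export
mata_wald <- function(estimates, weights, alpha = 0.025,
                      version = c("t", "z")) {
  version <- match.arg(version)
  .check_estimates(estimates, weights)
  if (alpha <= 0 || alpha >= 0.5) stop("'alpha' must lie in (0, 0.5)")
  if (version == "t" && any(estimates$nu[weights > 0] < 1))
    stop("t kernel needs residual df >= 1 for all models with weight")
  up <- .solve_mata(estimates, weights, alpha, version, NULL, "upper")
  lo <- .solve_mata(estimates, weights, alpha, version, NULL, "lower")
  new_interval(lo, up, alpha, paste0("mata_wald_", version))
}

#' MATA-SBoot interval
#'
#' The studentized-bootstrap model-averaged tail area interval: the same
#' tail-area equations as [mata_wald()], but each model's tail probabilities
#' are estimated from the empirical distribution of its studentized
#' parametric-bootstrap statistics (from [studentized_boot_tails()]).
#' As in any bootstrap-t construction, the upper limit is driven by the
#' lower tail of `T*` and vice versa, so skewness in `T*` shifts the limits
#' asymmetrically. When `T_m` really is normal or t distributed, the
#' interval converges to the matching MATA-Wald interval as `B` grows.
#'
#' @inheritParams ma_wald_variance
#' @param tails List of `bootstrap_tails`, one per model, aligned with
#'   `estimates`.
#' @return An `ma_interval` on the working scale.
#' @export
mata_sboot <- function(estimates, weights, tails, alpha = 0.025) {
  .check_estimates(estimates, weights)
  if (length(tails) != nrow(estimates))
    stop("'tails' must supply one bootstrap_tails per model")
  tl <- lapply(tails, function(x)
    if (inherits(x, "bootstrap_tails")) x$sorted_stats else as.numeric(x))
  Bmin <- min(vapply(tl, length, 0L))
  if (alpha < 1 / (Bmin + 1))
    stop("alpha = ", alpha, " is below the ECDF resolution 1/(B+1); ",
         "need B >= ", ceiling(1 / alpha) - 1L)
  lim <- .mata_sboot_limits(estimates$theta_hat, sqrt(estimates$var_hat),
                            weights, tl, alpha)
  new_interval(lim[["lower"]], lim[["upper"]], alpha, "mata_sboot")
}

#' Percentile bootstrap interval with per-sample model selection
#'
#' Generates `B` parametric bootstrap samples from the fitted full model,
#' selects the AIC-best candidate model for each sample (ties broken toward
#' fewer parameters, then canonical order), records that model's estimate of
#' the target, and returns the empirical `alpha` and `1 - alpha` percentiles
#' as order statistics at positions `ceiling(alpha (B + 1))` and
#' `ceiling((1 - alpha)(B + 1))`.
#'
#' @param data Long-format dataset.
#' @param models List of `term_set`s; must include the full model.
#' @param design A [factorial_design].
#' @param cell Target cell index.
#' @param B Number of bootstrap samples, at least 39.
#' @param alpha Per-tail level.
#' @param parameter_kind As in [eta_hat()].
#' @param response Response column name.
#' @return An `ma_interval` on the working scale; the bootstrap estimates
#'   are attached as attribute `"theta_star"`.
#' @export
percentile_bootstrap <- function(data, models, design, cell, B,
                                 alpha = 0.025,
                                 parameter_kind = c("lognormal_mean",
                                                    "log_scale_mean"),
                                 response = "y") {
  parameter_kind <- match.arg(parameter_kind)
  B <- as.integer(B)
  if (is.na(B) || B < 39L) stop("'B' must be at least 39")
  p_all <- vapply(models, function(m) m$p, 0L)
  K <- 2L^design$n_factors
  full_i <- which(p_all == K)
  if (length(full_i) != 1L)
    stop("'models' must contain the full (saturated) model")
  fits <- lapply(models, fit_model, design = design, data = data,
                 response = response)
  if (fits[[full_i]]$sigma2_hat <= 0)
    stop("degenerate full-model fit: sigma2_hat = 0")
  theta_star <- .pb_theta_star(fits[[full_i]], models, design, B,
                               parameter_kind)[cell, ]
  srt <- sort(theta_star)
  loi <- ceiling(alpha * (B + 1))
  upi <- ceiling((1 - alpha) * (B + 1))
  iv <- new_interval(srt[loi], srt[upi], alpha, "pb")
  attr(iv, "theta_star") <- theta_star
  iv
}

# K x B matrix of selected-model target estimates over B resamples from the
# full-model fit
.pb_theta_star <- function(full_fit, models, design, B, parameter_kind,
                           Cms = NULL, Ps = NULL) {
  K <- 2L^design$n_factors
  mean_kind <- parameter_kind == "lognormal_mean"
  ss <- .boot_suffstats(full_fit, B)
  M <- length(models)
  aic <- matrix(NA_real_, M, B)
  eta <- vector("list", M)
  for (m in seq_len(M)) {
    Cm <- if (is.null(Cms)) .code_matrix(models[[m]], design) else Cms[[m]]
    rf <- .refit_batch(Cm, ss$ybar, ss$ssw, design$r, design$n,
                       if (is.null(Ps)) NULL else Ps[[m]])
    aic[m, ] <- design$n * log(rf$rss / design$n) + 2 * (rf$p + 1)
    eta[[m]] <- rf$mu + if (mean_kind) rep(rf$sigma2 / 2, each = K) else 0
  }
  sel <- apply(aic, 2, which.min)   # canonical order breaks ties small-first
  out <- matrix(NA_real_, K, B)
  for (m in unique(sel)) {
    cols <- sel == m
    out[, cols] <- eta[[m]][, cols, drop = FALSE]
  }
  out
}
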