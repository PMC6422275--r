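# Parametric bootstrap engine: resampling from a fitted model, studentized
# bootstrap statistics, and empirical tail probabilities.
#
# In a balanced design with Gaussian log-scale errors, a refit of any
# candidate model depends on a resampled dataset only through its cell means
# and within-cell sum of squares, which under the fitted model are exactly
# distributed as N(mu_hat_cell, sigma2_hat / r) (independent across cells)
# and sigma2_hat * chisq(K (r - 1)) respectively, independently of each
# other. The batch resampler draws these sufficient statistics directly,
# which makes B in the tens of thousands cheap without approximation.

#' Draw one parametric bootstrap dataset from a fitted model
#'
#' Log-responses are the fitted cell means plus N(0, sigma2_hat) noise, in
#' the same long-format layout as [simulate_dataset()].
#'
#' @param fitted A `fitted_model` with `sigma2_hat > 0`.
#' @param design The [factorial_design]; defaults to the one stored in the
#'   fit.
#' @return Long-format data frame with factor columns, `replicate` and `y`.
#' @export
parametric_resample <- function(fitted, design = fitted$design) {
  if (fitted$sigma2_hat <= 0)
    stop("degenerate fit: sigma2_hat = 0, cannot resample")
  K <- 2L^design$n_factors
  r <- design$r
  idx <- rep(seq_len(K), each = r)
  lv <- .cell_level_index(design)
  out <- lapply(seq_len(design$n_factors), function(j)
    design$levels[[j]][lv[idx, j]])
  names(out) <- design$factor_names
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$replicate <- rep(seq_len(r), times = K)
  out$y <- exp(fitted$mu_hat[idx] +
                 stats::rnorm(K * r, 0, sqrt(fitted$sigma2_hat)))
  out
}

# batch-draw sufficient statistics of B parametric resamples from `fitted`
.boot_suffstats <- function(fitted, B) {
  K <- length(fitted$mu_hat)
  r <- fitted$r
  list(
    ybar = fitted$mu_hat +
      matrix(stats::rnorm(K * B, 0, sqrt(fitted$sigma2_hat / r)), K, B),
    ssw = fitted$sigma2_hat * stats::rchisq(B, K * (r - 1L))
  )
}

# refit one model to B resamples given its cell code matrix Cm (and,
# optionally, the precomputed projection onto the model's mean space)
.refit_batch <- function(Cm, ybar, ssw, r, n, P = NULL) {
  K <- nrow(Cm)
  if (is.null(P)) P <- Cm %*% t(Cm) / K
  mu <- P %*% ybar                           # K x B fitted cell means
  rss <- ssw + r * colSums((ybar - mu)^2)
  p <- ncol(Cm)
  nu <- n - p
  list(mu = mu, rss = rss, nu = nu, sigma2 = rss / nu, p = p)
}

# studentized bootstrap statistics for one model, all cells at once:
# K x B matrix of T* = (eta*_b - eta_hat) / sqrt(Vhat(eta*_b)), rows sorted.
# Columns with a degenerate refit (zero residual variance) are redrawn.
.sboot_stats <- function(fitted, B, parameter_kind, h, Cm = NULL, P = NULL) {
  design <- fitted$design
  if (is.null(Cm)) Cm <- .code_matrix(fitted$term_set, design)
  K <- nrow(Cm)
  mean_kind <- parameter_kind == "lognormal_mean"
  eta0 <- fitted$mu_hat + if (mean_kind) fitted$sigma2_hat / 2 else 0
  n_redrawn <- 0L
  draw <- function(B) {
    ss <- .boot_suffstats(fitted, B)
    rf <- .refit_batch(Cm, ss$ybar, ss$ssw, design$r, design$n, P)
    V <- rf$sigma2 * h +
      if (mean_kind) rf$sigma2^2 / (2 * (rf$nu + 2)) else 0
    eta <- rf$mu + if (mean_kind) rep(rf$sigma2 / 2, each = K) else 0
    list(T = (eta - eta0) / rep(sqrt(V), each = K), ok = rf$sigma2 > 0)
  }
  d <- draw(B)
  while (!all(d$ok)) {
    bad <- which(!d$ok)
    n_redrawn <- n_redrawn + length(bad)
    d2 <- draw(length(bad))
    d$T[, bad] <- d2$T
    d$ok[bad] <- d2$ok
  }
  if (n_redrawn > 0.001 * B)
    warning(n_redrawn, " of ", B,
            " bootstrap fits were degenerate and redrawn")
  stats <- d$T
  for (i in seq_len(K)) stats[i, ] <- sort.int(stats[i, ], method = "quick")
  attr(stats, "n_redrawn") <- n_redrawn
  stats
}

#' Construct a container of sorted studentized bootstrap statistics
#'
#' Mostly called internally by [studentized_boot_tails()]; exposed so that
#' externally computed (e.g. closed-form quantile) statistics can be fed to
#' [tail_probability()] and [mata_sboot()]. Generated bootstrap tails use
#' B >= 39 so that tail probabilities at or below 2.5% are resolvable;
#' [mata_sboot()] enforces `alpha >= 1/(B+1)` at solve time.
#'
#' @param sorted_stats Ascending numeric vector of studentized statistics.
#' @param model_label Label of the originating model.
#' @param n_redrawn Count of degenerate bootstrap fits that were redrawn.
#' @return Object of class `bootstrap_tails`.
#' @export
new_bootstrap_tails <- function(sorted_stats, model_label = "",
                                n_redrawn = 0L) {
  B <- length(sorted_stats)
  if (B < 1L)
    stop("need at least one bootstrap statistic")
  if (any(!is.finite(sorted_stats)) || is.unsorted(sorted_stats))
    stop("bootstrap statistics must be finite and sorted ascending")
  structure(
    list(sorted_stats = as.numeric(sorted_stats), B = B,
         model_label = model_label, n_redrawn = n_redrawn),
    class = "bootstrap_tails"
  )
}

#' @export
print.bootstrap_tails <- function(x, ...) {
  cat("<bootstrap_tails> model ", x$model_label, ", B = ", x$B, "\n", sep = "")
  invisible(x)
}

#' Studentized parametric-bootstrap statistics for one model
#'
#' Fits `model` to the dataset, generates `B` parametric bootstrap samples
#' from that fit, refits the same model to each, and returns the sorted
#' studentized statistics `T* = (eta*_b - eta_hat) / sqrt(Vhat(eta*_b))`,
#' where the bootstrap variance uses the same estimator
#' ([eta_variance()]) as the original data -- the empirical stand-in for the
#' distribution of the model's studentized estimate when the model is true.
#' Bootstrap fits with zero residual variance are rejected and redrawn (with
#' a warning if more than 0.1% of `B`).
#'
#' For the median target the statistic is exactly t-distributed with `nu`
#' df; for the lognormal-mean target it is negatively skewed when the
#' response is right-skewed and `r` is small.
#'
#' @param data Long-format dataset.
#' @param model A `term_set`.
#' @param design A [factorial_design].
#' @param cell Target cell index.
#' @param B Number of bootstrap samples, at least 39.
#' @param parameter_kind,h_mode As in [eta_variance()].
#' @param response Response column name.
#' @return A `bootstrap_tails` object.
#' @export
studentized_boot_tails <- function(data, model, design, cell, B,
                                   parameter_kind = c("lognormal_mean",
                                                      "log_scale_mean"),
                                   h_mode = c("general", "literal_r"),
                                   response = "y") {
  parameter_kind <- match.arg(parameter_kind)
  h_mode <- match.arg(h_mode)
  B <- as.integer(B)
  if (is.na(B) || B < 39L)
    stop("'B' must be at least 39 (tail probabilities below 2.5% ",
         "need B >= 1/alpha - 1)")
  fitted <- fit_model(model, design, data, response = response)
  if (fitted$sigma2_hat <= 0)
    stop("degenerate fit: sigma2_hat = 0, cannot bootstrap")
  h <- if (h_mode == "literal_r") 1 / design$r else fitted$p / design$n
  stats <- .sboot_stats(fitted, B, parameter_kind, h)
  new_bootstrap_tails(stats[cell, ], fitted$term_set$label,
                      attr(stats, "n_redrawn"))
}

# interpolated plotting-position ECDF: piecewise linear through
# (T*_(b), b/(B+1)), clamped to [1/(B+1), B/(B+1)] outside the range.
# Vectorized over u.
.interp_ecdf <- function(sorted, u) {
  B <- length(sorted)
  i <- findInterval(u, sorted)
  frac <- numeric(length(u))
  inside <- which(i >= 1L & i < B)
  if (length(inside)) {
    ii <- i[inside]
    x1 <- sorted[ii]
    gap <- sorted[ii + 1L] - x1
    f <- (u[inside] - x1) / gap
    f[gap <= 0] <- 0
    frac[inside] <- f
  }
  p <- (i + frac) / (B + 1)
  p[i < 1L] <- 1 / (B + 1)
  p[i >= B] <- B / (B + 1)
  p
}

# Exact MATA-SBoot limits. For the bootstrap kernel the weighted tail sum
# S(theta) = sum_m w_m Fhat_m((eta_m - theta)/sd_m) is piecewise linear and
# nonincreasing in theta, with kinks only at theta = eta_m - sd_m * T*_(b).
# Evaluating S on the union of all kinks and interpolating linearly is
# therefore an exact inversion: the upper limit solves S = alpha, the lower
# limit solves S = 1 - alpha (since sum_m w_m (1 - Fhat_m) = 1 - S).
.mata_sboot_limits <- function(eta, sdv, w, tails, alpha) {
  M <- length(eta)
  grid <- sort.int(unlist(lapply(seq_len(M), function(m)
    eta[m] - sdv[m] * tails[[m]]), use.names = FALSE), method = "quick")
  S <- 0
  for (m in seq_len(M))
    S <- S + w[m] * .interp_ecdf(tails[[m]], (eta[m] - grid) / sdv[m])
  invert <- function(a) {
    j <- findInterval(-a, -S)          # last index with S >= a (S decreasing)
    if (j < 1L) return(grid[1L])
    if (j >= length(S)) return(grid[length(S)])
    dS <- S[j + 1L] - S[j]
    if (dS == 0) return(grid[j])
    grid[j] + (a - S[j]) * (grid[j + 1L] - grid[j]) / dS
  }
  c(lower = invert(1 - alpha), upper = invert(alpha))
}

#' Empirical tail probability from bootstrap statistics
#'
#' Evaluates the interpolated plotting-position ECDF of the sorted bootstrap
#' statistics at `t`: the lower side returns `Fhat(t)`, the upper side
#' `1 - Fhat(t)`. `Fhat` is piecewise linear through the points
#' `(T*_(b), b/(B+1))` and clamped to `[1/(B+1), B/(B+1)]` outside the
#' sample range, so it is continuous and nondecreasing -- the tail equations
#' solved with it have unique roots.
#'
#' @param tails A `bootstrap_tails` object.
#' @param t Numeric vector of evaluation points.
#' @param side `"lower"` or `"upper"`.
#' @return Probabilities in `[1/(B+1), B/(B+1)]`.
#' @export
tail_probability <- function(tails, t, side = c("lower", "upper")) {
  side <- match.arg(side)
  if (!inherits(tails, "bootstrap_tails"))
    stop("'tails' must be a bootstrap_tails object")
  p <- .interp_ecdf(tails$sorted_stats, t)
  if (side == "lower") p else 1 - p
}
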