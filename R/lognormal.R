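# The flagship target parameter: lognormal cell means of a factorial
# design, their unbiased variance estimate, back-transformation, and the
# synthetic-data generator for randomized-effect scenarios.

#' Per-model estimate of a lognormal cell mean (log scale)
#'
#' For treatment combination `cell`, the log of the lognormal cell mean is
#' `eta = mu_cell + sigma^2 / 2`; its estimate under model `m` plugs in the
#' fitted cell mean and the residual mean square:
#' `eta_hat = mu_hat_cell + sigma2_hat / 2`.
#' With `parameter_kind = "log_scale_mean"` the target is the log-scale mean
#' `mu_cell` itself (the lognormal median on the response scale) and the
#' variance-shift term is dropped.
#'
#' @param fitted A `fitted_model` (log-scale fit).
#' @param cell Cell index in 1..2^k.
#' @param parameter_kind `"lognormal_mean"` (default) or `"log_scale_mean"`.
#' @return Scalar estimate on the eta (log) scale.
#' @export
eta_hat <- function(fitted, cell,
                    parameter_kind = c("lognormal_mean", "log_scale_mean")) {
  parameter_kind <- match.arg(parameter_kind)
  K <- length(fitted$mu_hat)
  cell <- as.integer(cell)
  if (length(cell) != 1L || is.na(cell) || cell < 1L || cell > K)
    stop("'cell' must be a single index in 1..", K)
  mu <- fitted$mu_hat[cell]
  if (parameter_kind == "lognormal_mean") mu + fitted$sigma2_hat / 2 else mu
}

#' Unbiased variance of the lognormal cell-mean estimate
#'
#' Returns `sigma2_hat * h + sigma2_hat^2 / (2 (nu + 2))`, which is unbiased
#' for `Var(eta_hat) = sigma^2 h + sigma^4 / (2 nu)` when the fitted model is
#' true: the fitted cell mean contributes `sigma^2 h` exactly, and because
#' `nu sigma2_hat / sigma^2` is chi-squared with `nu` df,
#' `E[sigma2_hat^2] = sigma^4 (nu + 2) / nu`, so dividing by `2 (nu + 2)`
#' removes the bias of the second term. For the median target
#' (`"log_scale_mean"`) only the first term is kept.
#'
#' @inheritParams eta_hat
#' @param h Variance factor from [cell_mean_variance_factor()]; computed
#'   from `fitted` when omitted.
#' @param h_mode Passed to [cell_mean_variance_factor()] when `h` is omitted.
#' @return Scalar variance, strictly positive.
#' @export
eta_variance <- function(fitted, cell, h = NULL,
                         parameter_kind = c("lognormal_mean", "log_scale_mean"),
                         h_mode = c("general", "literal_r")) {
  parameter_kind <- match.arg(parameter_kind)
  if (is.null(h))
    h <- cell_mean_variance_factor(fitted, cell, match.arg(h_mode))
  if (h <= 0 || h > 1)
    stop("'h' must lie in (0, 1]")
  s2 <- fitted$sigma2_hat
  if (s2 <= 0)
    stop("degenerate fit: sigma2_hat = 0, interval construction impossible")
  if (parameter_kind == "lognormal_mean")
    s2 * h + s2^2 / (2 * (fitted$nu + 2))
  else
    s2 * h
}

#' Back-transform an interval from the log (eta) scale to the response scale
#'
#' Exponentiates both limits; because exp is strictly increasing, coverage is
#' preserved: `theta` lies in `[exp(L), exp(U)]` iff `log(theta)` lies in
#' `[L, U]`.
#'
#' @param interval An `ma_interval` on the eta scale.
#' @return The interval on the theta scale, method tag retained.
#' @export
back_transform <- function(interval) {
  if (!inherits(interval, "ma_interval"))
    stop("'interval' must be an ma_interval")
  new_interval(exp(interval$lower), exp(interval$upper),
               alpha = interval$alpha, method = interval$method,
               scale = "theta")
}

#' Define a simulation scenario
#'
#' A scenario fixes the magnitudes (standard deviations) from which the
#' main-effect, two-way and three-way interaction parameters are drawn, the
#' replicate count, the error variance and a seed. Magnitudes are labelled
#' High = 2, Medium = 1, Low = 0.1, chosen respectively above, equal to and
#' below the default error variance `sigma2 = 1`.
#'
#' @param label Three-letter string over H/M/L (e.g. `"HML"`: High main
#'   effects, Medium two-way, Low three-way), or a numeric vector of three
#'   magnitudes.
#' @param r Replicates per cell.
#' @param sigma2 Error variance on the log scale; default 1 (response
#'   skewness about 6.2).
#' @param seed Integer RNG seed for [run_scenario()].
#' @return Object of class `ma_scenario`.
#' @export
scenario <- function(label, r, sigma2 = 1, seed = 1L) {
  if (is.numeric(label)) {
    if (length(label) != 3L || any(label < 0))
      stop("numeric magnitudes must be three nonnegative values")
    magnitudes <- as.numeric(label)
    label <- paste(magnitudes, collapse = "/")
  } else {
    code <- strsplit(toupper(label), "")[[1L]]
    if (length(code) != 3L || !all(code %in% c("H", "M", "L")))
      stop("'label' must be three letters over H, M, L (e.g. \"HML\")")
    magnitudes <- c(H = 2, M = 1, L = 0.1)[code]
  }
  if (sigma2 <= 0) stop("'sigma2' must be positive")
  r <- as.integer(r)
  if (is.na(r) || r < 2L) stop("'r' must be an integer >= 2")
  structure(
    list(label = label, magnitudes = unname(magnitudes), r = r,
         sigma2 = sigma2, seed = as.integer(seed)),
    class = "ma_scenario"
  )
}

#' The ten magnitude scenarios of the simulation study
#'
#' Orderings in which main effects are at least as large as two-way
#' interactions, which are at least as large as the three-way interaction.
#'
#' @return Character vector of scenario labels.
#' @export
default_scenarios <- function() {
  c("LLL", "MLL", "HLL", "MML", "HML", "MMM", "HMM", "HHL", "HHM", "HHH")
}

#' Draw one set of true effects for a scenario
#'
#' Each main effect, two-way interaction and the three-way interaction is
#' drawn independently from a normal distribution with mean zero and
#' standard deviation equal to the term type's magnitude. The overall mean
#' is fixed at `mu` (default 0: interval performance does not depend on it).
#' Effects use sum-to-zero coding: the stored value `v` applies as `+v` at a
#' factor's first level and `-v` at its second.
#'
#' @param scn An `ma_scenario`.
#' @param mu Overall mean on the log scale; default 0.
#' @return Object of class `effect_set` with fields `mu`, `main` (3),
#'   `two_way` (3, ordered PI, PV, IV), `three_way` (1) and `sigma2`.
#' @export
draw_effects <- function(scn, mu = 0) {
  if (!inherits(scn, "ma_scenario")) stop("'scn' must be an ma_scenario")
  m <- scn$magnitudes
  structure(
    list(mu = mu,
         main = stats::rnorm(3, 0, m[1L]),
         two_way = stats::rnorm(3, 0, m[2L]),
         three_way = stats::rnorm(1, 0, m[3L]),
         sigma2 = scn$sigma2),
    class = "effect_set"
  )
}

# log-scale cell means implied by an effect set, in cell-index order
# (first factor fastest), via the full-model effect coding.
.effect_cell_means <- function(effects, design) {
  if (design$n_factors != 3L)
    stop("effect sets are defined for three-factor designs")
  Cm <- .full_code_matrix(design)
  coefs <- c(effects$mu, effects$main, effects$two_way, effects$three_way)
  drop(Cm %*% coefs)
}

# full-model cell code matrix (intercept, 3 mains, PI, PV, IV, PIV)
.full_code_matrix <- function(design) {
  codes <- 3 - 2 * .cell_level_index(design)
  cbind(1, codes[, 1L], codes[, 2L], codes[, 3L],
        codes[, 1L] * codes[, 2L], codes[, 1L] * codes[, 3L],
        codes[, 2L] * codes[, 3L], codes[, 1L] * codes[, 2L] * codes[, 3L])
}

#' Simulate a lognormal factorial dataset
#'
#' Generates `Y = exp(mu_cell + e)` with `e ~ N(0, sigma2)` independently for
#' every cell and replicate, in long format.
#'
#' @param effects An `effect_set` from [draw_effects()].
#' @param design A [factorial_design] with three factors.
#' @return Data frame with the design's factor columns, `replicate`, and
#'   positive response `y`.
#' @export
simulate_dataset <- function(effects, design) {
  mu_cells <- .effect_cell_means(effects, design)
  K <- 2L^design$n_factors
  r <- design$r
  idx <- rep(seq_len(K), each = r)
  lv <- .cell_level_index(design)
  out <- lapply(seq_len(design$n_factors), function(j)
    design$levels[[j]][lv[idx, j]])
  names(out) <- design$factor_names
  out <- as.data.frame(out, stringsAsFactors = FALSE)
  out$replicate <- rep(seq_len(r), times = K)
  out$y <- exp(mu_cells[idx] + stats::rnorm(K * r, 0, sqrt(effects$sigma2)))
  out
}

#' True target parameter implied by an effect set
#'
#' Exact value of the estimand for one treatment combination:
#' `eta = mu_cell + sigma2/2` (lognormal mean, log scale) or `mu_cell`
#' (median target); `theta = exp(eta)` on the response scale.
#'
#' @inheritParams simulate_dataset
#' @param cell Cell index in 1..8.
#' @param parameter_kind `"lognormal_mean"` or `"log_scale_mean"`.
#' @param scale `"eta"` (log scale, default) or `"theta"`.
#' @return Scalar truth.
#' @export
true_parameter <- function(effects, cell, design = factorial_design(r = 2),
                           parameter_kind = c("lognormal_mean", "log_scale_mean"),
                           scale = c("eta", "theta")) {
  parameter_kind <- match.arg(parameter_kind)
  scale <- match.arg(scale)
  mu_cells <- .effect_cell_means(effects, design)
  cell <- as.integer(cell)
  if (length(cell) != 1L || is.na(cell) || cell < 1L || cell > length(mu_cells))
    stop("'cell' must be a single index in 1..", length(mu_cells))
  eta <- mu_cells[cell] +
    if (parameter_kind == "lognormal_mean") effects$sigma2 / 2 else 0
  if (scale == "eta") eta else exp(eta)
}

#' Skewness of a lognormal distribution
#'
#' Closed form `(exp(s2) + 2) * sqrt(exp(s2) - 1)`; about 6.2 at `s2 = 1`.
#'
#' @param sigma2 Log-scale variance.
#' @return Skewness coefficient.
#' @export
lognormal_skewness <- function(sigma2) {
  (exp(sigma2) + 2) * sqrt(exp(sigma2) - 1)
}
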