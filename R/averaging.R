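# AIC model weights, the model-averaged point estimate, and the MA-Wald
# variance estimator.

#' AIC model weights
#'
#' Computes normalized weights `w_m = exp(-(AIC_m - min AIC)/2) /
#' sum_j exp(-(AIC_j - min AIC)/2)`. The minimum is subtracted before
#' exponentiation for overflow safety; the result is invariant to any
#' additive constant in the AIC convention.
#'
#' @param aics Numeric vector of AIC values, all finite, at least one model.
#' @return Numeric weight vector: nonnegative, summing to 1, aligned with
#'   the input order.
#' @examples
#' aic_weights(c(0, 2))  # c(0.731..., 0.268...)
#' @export
aic_weights <- function(aics) {
  if (length(aics) < 1L)
    stop("'aics' must contain at least one model")
  if (any(!is.finite(aics)))
    stop("all AIC values must be finite")
  w <- exp(-(aics - min(aics)) / 2)
  w / sum(w)
}

#' Bundle per-model estimates for interval construction
#'
#' Each row holds one model's estimate of the common parameter (on the
#' working scale), its estimated conditional variance, and the model's
#' residual degrees of freedom -- the triple every interval formula consumes.
#'
#' @param theta_hat,var_hat,nu Equal-length numeric vectors.
#' @return Data frame with columns `theta_hat`, `var_hat`, `nu`.
#' @export
model_estimates <- function(theta_hat, var_hat, nu) {
  n <- length(theta_hat)
  if (length(var_hat) != n || length(nu) != n)
    stop("'theta_hat', 'var_hat' and 'nu' must have equal length")
  data.frame(theta_hat = theta_hat, var_hat = var_hat, nu = nu)
}

.check_estimates <- function(estimates, weights) {
  if (!all(c("theta_hat", "var_hat", "nu") %in% names(estimates)))
    stop("'estimates' needs columns theta_hat, var_hat, nu (see model_estimates())")
  if (nrow(estimates) != length(weights))
    stop("'estimates' and 'weights' lengths differ")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8)
    stop("'weights' must be nonnegative and sum to 1")
  invisible(TRUE)
}

#' Model-averaged point estimate
#'
#' The weighted mean of the per-model estimates,
#' `theta_bar = sum_m w_m theta_hat_m`.
#'
#' @param estimates Data frame from [model_estimates()].
#' @param weights Weight vector from [aic_weights()].
#' @return Scalar estimate.
#' @export
model_averaged_estimate <- function(estimates, weights) {
  .check_estimates(estimates, weights)
  sum(weights * estimates$theta_hat)
}

#' MA-Wald variance of the model-averaged estimate
#'
#' Computes
#' `V(theta_bar) = sum_m w_m [ (t_{nu_m, 1-alpha} / z_{1-alpha})^2
#'   V(theta_hat_m) + (theta_hat_m - theta_bar)^2 ]`.
#' The t/z ratio inflates each model's variance to allow for the uncertainty
#' in its variance estimate; the spread term accounts for between-model
#' disagreement. The ratio uses the same `alpha` as the requested interval.
#' Models carrying zero weight are skipped, so degenerate residual df there
#' are harmless.
#'
#' @inheritParams model_averaged_estimate
#' @param theta_bar Optional precomputed model-averaged estimate.
#' @param alpha Per-tail level in (0, 0.5); default 0.025.
#' @return Scalar variance.
#' @export
ma_wald_variance <- function(estimates, weights, theta_bar = NULL,
                             alpha = 0.025) {
  .check_estimates(estimates, weights)
  if (alpha <= 0 || alpha >= 0.5)
    stop("'alpha' must lie in (0, 0.5)")
  if (is.null(theta_bar))
    theta_bar <- model_averaged_estimate(estimates, weights)
  act <- weights > 0
  if (any(estimates$nu[act] < 1))
    stop("all models with positive weight need residual df >= 1")
  ratio <- stats::qt(1 - alpha, estimates$nu[act]) / stats::qnorm(1 - alpha)
  sum(weights[act] * (ratio^2 * estimates$var_hat[act] +
                        (estimates$theta_hat[act] - theta_bar)^2))
}
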