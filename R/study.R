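# Scenario-based simulation study: per-method lower/upper error rates and
# relative half-widths, averaged over the eight treatment combinations.

.all_methods <- c("full_wald", "ma_wald", "mata_wald_z", "mata_wald_t",
                  "pb", "mata_sboot")

#' Lower and upper error rates of a set of intervals
#'
#' The lower error rate is the fraction of (replicate, cell) pairs with
#' `lower > truth`; the upper error rate the fraction with `upper < truth`.
#' Each is nominally `alpha`; together with coverage they partition 1.
#'
#' @param lower,upper Numeric vectors or matrices of interval limits.
#' @param truth Matching numeric vector or matrix of true values.
#' @return Named vector `c(lower, upper)`.
#' @export
error_rates <- function(lower, upper, truth) {
  if (length(lower) != length(truth) || length(upper) != length(truth))
    stop("'lower', 'upper' and 'truth' must have matching shapes")
  c(lower = mean(lower > truth), upper = mean(upper < truth))
}

#' Relative half-widths of an interval
#'
#' `(limit - truth) / truth` for each limit: a scale-free width summary.
#' The lower half-width is typically negative.
#'
#' @param interval An `ma_interval` on the response (theta) scale, or a
#'   list with `lower` and `upper`.
#' @param truth Positive true parameter value.
#' @return Named vector `c(lower_rhw, upper_rhw)`.
#' @export
relative_half_widths <- function(interval, truth) {
  if (any(truth <= 0)) stop("'truth' must be positive")
  c(lower_rhw = (interval$lower - truth) / truth,
    upper_rhw = (interval$upper - truth) / truth)
}

# deterministic per-replicate substream seed (kept below 2^31)
.substream <- function(seed, i) {
  (as.double(seed) + 48271 * as.double(i)) %% 2147483647
}

#' Run one simulation scenario
#'
#' For each replicate: draw a fresh set of true effects for the scenario,
#' simulate a lognormal factorial dataset, fit every candidate model,
#' compute AIC weights, build the requested intervals for all eight
#' treatment combinations on the log scale, back-transform, and score
#' against the exact truth. Results are aggregated per method into mean
#' lower/upper error rates and mean relative half-widths over all
#' (replicate, cell) pairs.
#'
#' Replicates use deterministic substreams derived from `scn$seed`, so a
#' run is reproducible from `(seed, n_sim, B)` and replicates are
#' independent of execution order. A replicate whose full-model fit is
#' degenerate (zero residual variance; probability zero for continuous
#' data) raises an error rather than being silently dropped, keeping the
#' error-rate denominators honest.
#'
#' @param scn An [scenario()].
#' @param methods Subset of
#'   `c("full_wald", "ma_wald", "mata_wald_z", "mata_wald_t", "pb",
#'   "mata_sboot")`.
#' @param n_sim Number of simulation replicates.
#' @param B Bootstrap samples per replicate (bootstrap methods only).
#' @param alpha Per-tail level; default 0.025 (95% nominal coverage).
#' @param parameter_kind Target: lognormal mean (default) or log-scale mean.
#' @param h_mode Variance-factor mode, see [cell_mean_variance_factor()].
#' @param models Candidate models; default all hierarchical models of the
#'   three-factor design. Restricting to the full model only gives the
#'   no-model-uncertainty benchmark (weight 1 on the full model).
#' @return Data frame, one row per method, with columns `scenario`,
#'   `method`, `r`, `n_sim`, `B`, `lower_error`, `upper_error`,
#'   `mean_lower_rhw`, `mean_upper_rhw`.
#' @export
run_scenario <- function(scn, methods = .all_methods, n_sim, B = 199L,
                         alpha = 0.025,
                         parameter_kind = c("lognormal_mean",
                                            "log_scale_mean"),
                         h_mode = c("general", "literal_r"),
                         models = NULL) {
  if (!inherits(scn, "ma_scenario")) stop("'scn' must be an ma_scenario")
  parameter_kind <- match.arg(parameter_kind)
  h_mode <- match.arg(h_mode)
  methods <- match.arg(methods, .all_methods, several.ok = TRUE)
  if (n_sim < 1L) stop("'n_sim' must be at least 1")
  boot_methods <- intersect(methods, c("pb", "mata_sboot"))
  if (length(boot_methods) && B < ceiling(1 / alpha) - 1L)
    stop("bootstrap methods need B >= 1/alpha - 1 = ",
         ceiling(1 / alpha) - 1L)
  design <- factorial_design(r = scn$r)
  if (is.null(models)) models <- enumerate_hierarchical_models(design)
  K <- 2L^design$n_factors
  M <- length(models)
  mean_kind <- parameter_kind == "lognormal_mean"
  h_all <- if (h_mode == "literal_r") rep(1 / design$r, M)
           else vapply(models, function(m) m$p, 0L) / design$n
  full_i <- which(vapply(models, function(m) m$p, 0L) == K)
  if (any(c("pb", "full_wald") %in% methods) && length(full_i) != 1L)
    stop("'models' must include the full model for the requested methods")
  Cms <- lapply(models, .code_matrix, design = design)
  Ps <- lapply(Cms, function(Cm) Cm %*% t(Cm) / K)

  nm <- length(methods)
  L <- array(NA_real_, c(n_sim, K, nm), dimnames = list(NULL, NULL, methods))
  U <- L
  TR <- matrix(NA_real_, n_sim, K)

  for (i in seq_len(n_sim)) {
    set.seed(.substream(scn$seed, i))
    eff <- draw_effects(scn)
    dat <- simulate_dataset(eff, design)
    log_y <- log(dat$y)
    idx <- .cell_index(dat, design)
    s <- .summarize_log_response(log_y, idx, design)
    fits <- lapply(seq_len(M), function(m)
      .fit_summary(models[[m]], s$ybar, s$ssw, design, Cms[[m]]))
    s2 <- vapply(fits, `[[`, 0, "sigma2_hat")
    if (any(s2 <= 0))
      stop("replicate ", i, ": degenerate fit (sigma2_hat = 0) for model ",
           models[[which(s2 <= 0)[1L]]]$label)
    aics <- vapply(fits, `[[`, 0, "aic")
    w <- aic_weights(aics)
    nu <- vapply(fits, `[[`, 0, "nu")
    Vm <- s2 * h_all + if (mean_kind) s2^2 / (2 * (nu + 2)) else 0
    Eta <- vapply(fits, function(f)
      f$mu_hat + if (mean_kind) f$sigma2_hat / 2 else 0, numeric(K))  # K x M
    mu_cells <- .effect_cell_means(eff, design)
    TR[i, ] <- exp(mu_cells + if (mean_kind) eff$sigma2 / 2 else 0)

    tails <- NULL
    if ("mata_sboot" %in% methods)
      tails <- lapply(seq_len(M), function(m)
        .sboot_stats(fits[[m]], B, parameter_kind, h_all[m],
                     Cms[[m]], Ps[[m]]))
    pb_star <- NULL
    if ("pb" %in% methods)
      pb_star <- .pb_theta_star(fits[[full_i]], models, design, B,
                                parameter_kind, Cms, Ps)
    loi <- ceiling(alpha * (B + 1))
    upi <- ceiling((1 - alpha) * (B + 1))

    for (cc in seq_len(K)) {
      est <- data.frame(theta_hat = Eta[cc, ], var_hat = Vm, nu = nu)
      for (me in methods) {
        iv <- switch(me,
          full_wald = full_wald(est[full_i, ], alpha),
          ma_wald = ma_wald(est, w, alpha),
          mata_wald_z = mata_wald(est, w, alpha, "z"),
          mata_wald_t = mata_wald(est, w, alpha, "t"),
          mata_sboot = {
            tl <- lapply(tails, function(x) x[cc, ])
            lim <- .mata_sboot_limits(Eta[cc, ], sqrt(Vm), w, tl, alpha)
            list(lower = lim[["lower"]], upper = lim[["upper"]])
          },
          pb = {
            srt <- sort(pb_star[cc, ])
            list(lower = srt[loi], upper = srt[upi])
          })
        L[i, cc, me] <- exp(iv$lower)
        U[i, cc, me] <- exp(iv$upper)
      }
    }
  }

  out <- lapply(methods, function(me) {
    er <- error_rates(L[, , me], U[, , me], TR)
    data.frame(scenario = scn$label, method = me, r = design$r,
               n_sim = n_sim,
               B = if (me %in% c("pb", "mata_sboot")) B else NA_integer_,
               lower_error = er[["lower"]], upper_error = er[["upper"]],
               mean_lower_rhw = mean((L[, , me] - TR) / TR),
               mean_upper_rhw = mean((U[, , me] - TR) / TR))
  })
  do.call(rbind, out)
}

#' Write study results as tidy TSV and/or JSON
#'
#' @param results Data frame from [run_scenario()] (rows may be stacked
#'   across scenarios).
#' @param tsv,json Optional output paths.
#' @return `results`, invisibly.
#' @export
write_study_results <- function(results, tsv = NULL, json = NULL) {
  if (!is.null(tsv))
    utils::write.table(results, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(json))
    jsonlite::write_json(results, json, dataframe = "rows", digits = NA,
                         auto_unbox = TRUE, pretty = TRUE)
  invisible(results)
}
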