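# File I/O and reporting: the reproducibility surface for factorial
# lognormal analyses.

#' Read a long-format factorial dataset from CSV
#'
#' Validates that every factor column is present with exactly two observed
#' levels, that the response is strictly positive (the analysis fits on the
#' log scale), and that the design is balanced (equal replicates per cell).
#'
#' @param path CSV file with a header row: one column per factor plus a
#'   positive response column.
#' @param factors Factor column names, in order; default `c("P","I","V")`.
#' @param response Response column name; default `"y"`.
#' @param levels Optional list of two level labels per factor fixing the
#'   coding orientation; inferred (sorted unique values) when omitted.
#' @return List with `data` (validated data frame) and `design`
#'   (a [factorial_design] with `r` taken from the cell counts).
#' @export
read_dataset <- function(path, factors = c("P", "I", "V"), response = "y",
                         levels = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  data <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(c(factors, response), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  y <- data[[response]]
  if (!is.numeric(y))
    stop("response column '", response, "' must be numeric")
  bad <- which(!is.finite(y) | y <= 0)
  if (length(bad))
    stop("response must be strictly positive and finite; first offending ",
         "row: ", bad[1L])
  if (is.null(levels))
    levels <- lapply(factors, function(f) {
      lv <- sort(unique(as.character(data[[f]])))
      if (length(lv) != 2L)
        stop("factor '", f, "' has ", length(lv),
             " observed level(s); exactly 2 required")
      lv
    })
  counts <- table(interaction(lapply(factors, function(f) data[[f]]),
                              drop = FALSE))
  k <- length(factors)
  if (length(counts) != 2L^k || length(unique(as.integer(counts))) != 1L)
    stop("unbalanced design: per-cell counts are (",
         paste(as.integer(counts), collapse = ", "),
         "); every cell of the full cross must appear equally often")
  r <- as.integer(counts[1L])
  if (r < 2L) stop("need at least r = 2 replicates per cell")
  design <- factorial_design(factors, r = r, levels = levels)
  .cell_index(data, design)  # validates levels against the data
  list(data = data, design = design)
}

#' Write a long-format dataset to CSV
#'
#' Inverse of [read_dataset()] on valid tables.
#'
#' @param data Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' AIC weight table over all candidate models
#'
#' Fits every hierarchical candidate model and reports its AIC and AIC
#' weight, in canonical model order. Weights are kept at full precision;
#' round for display.
#'
#' @param data Long-format dataset.
#' @param design A [factorial_design].
#' @param response Response column name.
#' @return Data frame with columns `model`, `p`, `aic`, `weight`.
#' @export
weight_table <- function(data, design, response = "y") {
  models <- enumerate_hierarchical_models(design)
  fits <- lapply(models, fit_model, design = design, data = data,
                 response = response)
  aic <- vapply(fits, `[[`, 0, "aic")
  data.frame(model = vapply(models, `[[`, "", "label"),
             p = vapply(models, `[[`, 0L, "p"),
             aic = aic,
             weight = aic_weights(aic))
}

# human-readable label for a cell: factor levels pasted in factor order
.cell_labels <- function(design) {
  lv <- .cell_level_index(design)
  apply(lv, 1, function(row)
    paste0(mapply(function(j, l) design$levels[[j]][l],
                  seq_len(design$n_factors), row),
           collapse = ""))
}

#' Confidence intervals for every treatment combination
#'
#' Computes the requested intervals for each of the `2^k` cells on the log
#' scale and back-transforms them to the response scale. Bootstrap-based
#' methods (percentile bootstrap, MATA-SBoot) are controlled by `B` and
#' `seed`.
#'
#' @param data Long-format dataset.
#' @param design A [factorial_design].
#' @param methods Interval methods to report; default all six.
#' @param alpha Per-tail level; default 0.025.
#' @param B Bootstrap samples for bootstrap-based methods; default 9999.
#' @param seed RNG seed for bootstrap-based methods.
#' @param parameter_kind,h_mode As in [eta_variance()].
#' @param response Response column name.
#' @return Data frame with one row per (cell, method): columns `cell`
#'   (label), `method`, `lower`, `upper` on the response scale.
#' @export
intervals_report <- function(data, design,
                             methods = c("full_wald", "ma_wald",
                                         "mata_wald_z", "mata_wald_t",
                                         "pb", "mata_sboot"),
                             alpha = 0.025, B = 9999L, seed = 1L,
                             parameter_kind = c("lognormal_mean",
                                                "log_scale_mean"),
                             h_mode = c("general", "literal_r"),
                             response = "y") {
  parameter_kind <- match.arg(parameter_kind)
  h_mode <- match.arg(h_mode)
  methods <- match.arg(methods, several.ok = TRUE)
  models <- enumerate_hierarchical_models(design)
  M <- length(models)
  K <- 2L^design$n_factors
  fits <- lapply(models, fit_model, design = design, data = data,
                 response = response)
  aics <- vapply(fits, `[[`, 0, "aic")
  w <- aic_weights(aics)
  nu <- vapply(fits, `[[`, 0, "nu")
  s2 <- vapply(fits, `[[`, 0, "sigma2_hat")
  if (any(s2 <= 0))
    stop("degenerate fit (sigma2_hat = 0) for model ",
         models[[which(s2 <= 0)[1L]]]$label)
  h_all <- if (h_mode == "literal_r") rep(1 / design$r, M)
           else vapply(models, `[[`, 0L, "p") / design$n
  mean_kind <- parameter_kind == "lognormal_mean"
  Vm <- s2 * h_all + if (mean_kind) s2^2 / (2 * (nu + 2)) else 0
  Eta <- vapply(fits, function(f)
    f$mu_hat + if (mean_kind) f$sigma2_hat / 2 else 0, numeric(K))
  full_i <- which(vapply(models, `[[`, 0L, "p") == K)

  set.seed(seed)
  tails <- NULL
  if ("mata_sboot" %in% methods)
    tails <- lapply(seq_len(M), function(m)
      .sboot_stats(fits[[m]], B, parameter_kind, h_all[m]))
  pb_star <- NULL
  if ("pb" %in% methods)
    pb_star <- .pb_theta_star(fits[[full_i]], models, design, B,
                              parameter_kind)
  loi <- ceiling(alpha * (B + 1))
  upi <- ceiling((1 - alpha) * (B + 1))

  labels <- .cell_labels(design)
  rows <- list()
  for (cc in seq_len(K)) {
    est <- model_estimates(Eta[cc, ], Vm, nu)
    for (me in methods) {
      iv <- switch(me,
        full_wald = full_wald(est[full_i, ], alpha),
        ma_wald = ma_wald(est, w, alpha),
        mata_wald_z = mata_wald(est, w, alpha, "z"),
        mata_wald_t = mata_wald(est, w, alpha, "t"),
        mata_sboot = mata_sboot(est, w,
                                lapply(tails, function(x) x[cc, ]), alpha),
        pb = {
          srt <- sort(pb_star[cc, ])
          new_interval(srt[loi], srt[upi], alpha, "pb")
        })
      rows[[length(rows) + 1L]] <-
        data.frame(cell = labels[cc], method = me,
                   lower = exp(iv$lower), upper = exp(iv$upper))
    }
  }
  do.call(rbind, rows)
}
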