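# Candidate-model enumeration and least-squares fitting for balanced
# two-level factorial designs, using effect (+1/-1) coding throughout so the
# full balanced design is orthogonal and cell-mean variances have closed
# forms.

#' Describe a balanced two-level factorial design
#'
#' A design holds the factor names, the number of replicates per treatment
#' combination (cell), and the level labels used when reading or simulating
#' data. Only fully crossed, balanced designs with two levels per factor are
#' supported; unbalanced data are rejected at fit time.
#'
#' @param factor_names Ordered character vector of factor labels. The default
#'   `c("P", "I", "V")` reflects the flagship three-factor application
#'   (pH, irradiance, water velocity).
#' @param r Integer number of replicates per cell, at least 2 (so the
#'   saturated model retains positive residual degrees of freedom).
#' @param levels Optional list, one character vector of two level labels per
#'   factor; the first label codes +1, the second -1. Defaults to
#'   `c("1", "2")` for every factor.
#' @return An object of class `factorial_design` with fields `n_factors`,
#'   `factor_names`, `r`, `n` (total observations) and `levels`.
#' @examples
#' d <- factorial_design(r = 5)
#' d$n  # 40 observations
#' @export
factorial_design <- function(factor_names = c("P", "I", "V"), r,
                             levels = NULL) {
  k <- length(factor_names)
  if (k < 1L || k > 4L)
    stop("between 1 and 4 factors are supported")
  if (anyDuplicated(factor_names))
    stop("factor names must be unique")
  r <- as.integer(r)
  if (length(r) != 1L || is.na(r) || r < 2L)
    stop("'r' (replicates per cell) must be a single integer >= 2")
  if (is.null(levels))
    levels <- rep(list(c("1", "2")), k)
  if (length(levels) != k || any(vapply(levels, length, 0L) != 2L))
    stop("'levels' must list exactly two level labels per factor")
  names(levels) <- factor_names
  structure(
    list(n_factors = k, factor_names = factor_names, r = r,
         n = r * 2L^k, levels = levels),
    class = "factorial_design"
  )
}

# All candidate effect terms for k factors, in canonical order: by
# interaction degree, then by the (sorted) indices of the constituent
# factors. For P, I, V this gives P, I, V, PI, PV, IV, PIV -- the term order
# used in the application's weight tables.
.all_terms <- function(factor_names) {
  k <- length(factor_names)
  factors <- list()
  for (d in seq_len(k)) {
    cmb <- utils::combn(k, d, simplify = FALSE)
    factors <- c(factors, cmb)
  }
  labels <- vapply(factors, function(ix) paste0(factor_names[ix], collapse = ""),
                   character(1))
  list(labels = labels, factors = factors,
       degree = vapply(factors, length, 0L))
}

.term_set <- function(ranks, terms_all, factor_names) {
  ranks <- sort(ranks)
  label <- if (length(ranks) == 0L) "Null"
           else paste(terms_all$labels[ranks], collapse = "+")
  structure(
    list(terms = terms_all$labels[ranks],
         term_ranks = ranks,
         term_factors = terms_all$factors[ranks],
         label = label,
         p = length(ranks) + 1L),
    class = "term_set"
  )
}

#' @export
print.term_set <- function(x, ...) {
  cat("<term_set> ", x$label, "  (p = ", x$p, ")\n", sep = "")
  invisible(x)
}

# TRUE if the ranks (indices into terms_all) are closed under marginality:
# every interaction's lower-order terms are present.
.is_hierarchical <- function(ranks, terms_all) {
  if (length(ranks) == 0L) return(TRUE)
  present <- terms_all$labels[ranks]
  for (i in ranks) {
    fx <- terms_all$factors[[i]]
    d <- length(fx)
    if (d < 2L) next
    for (dd in seq_len(d - 1L)) {
      subs <- utils::combn(fx, dd, simplify = FALSE)
      for (s in subs) {
        lab <- paste0(attr(terms_all, "factor_names")[s], collapse = "")
        if (!(lab %in% present)) return(FALSE)
      }
    }
  }
  TRUE
}

#' Enumerate all hierarchical candidate models
#'
#' Generates every subset of main effects and interactions that respects
#' marginality (an interaction appears only when all lower-order terms formed
#' from its factors are present), including the null (intercept-only) model.
#' For a three-factor design this yields the 19 candidate models of the
#' two-level factorial application.
#'
#' Models are returned in canonical order: by number of terms, then by the
#' canonical ranks of their terms (main effects before interactions, each
#' block ordered by factor indices). Ties in AIC-based selection are broken
#' by this order, so smaller models win.
#'
#' @param n_factors Integer between 1 and 4, or a [factorial_design].
#' @param factor_names Optional factor labels; defaults to `P`, `I`, `V` for
#'   three factors and `A`, `B`, ... otherwise.
#' @return List of `term_set` objects.
#' @examples
#' length(enumerate_hierarchical_models(3))  # 19
#' @export
enumerate_hierarchical_models <- function(n_factors, factor_names = NULL) {
  if (inherits(n_factors, "factorial_design")) {
    factor_names <- n_factors$factor_names
    n_factors <- n_factors$n_factors
  }
  n_factors <- as.integer(n_factors)
  if (length(n_factors) != 1L || is.na(n_factors) ||
      n_factors < 1L || n_factors > 4L)
    stop("'n_factors' must be an integer between 1 and 4")
  if (is.null(factor_names))
    factor_names <- if (n_factors == 3L) c("P", "I", "V")
                    else LETTERS[seq_len(n_factors)]
  terms_all <- .all_terms(factor_names)
  attr(terms_all, "factor_names") <- factor_names
  nt <- length(terms_all$labels)
  keep <- list()
  for (mask in 0:(2L^nt - 1L)) {
    ranks <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(nt) - 1L)) != 0L)
    if (.is_hierarchical(ranks, terms_all))
      keep[[length(keep) + 1L]] <- ranks
  }
  # canonical order: size, then lexicographic on the term-rank sequence
  key <- vapply(keep, function(rk)
    paste(sprintf("%02d", rk), collapse = ""), character(1))
  sz <- vapply(keep, length, 0L)
  ord <- order(sz, key)
  lapply(keep[ord], .term_set, terms_all = terms_all,
         factor_names = factor_names)
}

# level codes per cell: 2^k x k matrix of +1/-1, first factor varying
# fastest; cell index 1 has every factor at its first level.
.cell_level_index <- function(design) {
  k <- design$n_factors
  as.matrix(expand.grid(rep(list(1:2), k)))
}

# effect-coded model matrix over the 2^k cells (one row per cell),
# intercept first, then the model's terms in canonical order.
.code_matrix <- function(term_set, design) {
  lv <- .cell_level_index(design)
  codes <- 3 - 2 * lv                       # level 1 -> +1, level 2 -> -1
  K <- nrow(codes)
  C <- matrix(1, K, term_set$p)
  cn <- "(Intercept)"
  j <- 1L
  for (fx in term_set$term_factors) {
    j <- j + 1L
    C[, j] <- apply(codes[, fx, drop = FALSE], 1, prod)
  }
  colnames(C) <- c(cn, term_set$terms)
  C
}

# map each observation row to its cell index; errors on unknown levels.
.cell_index <- function(data, design) {
  k <- design$n_factors
  idx <- rep(1L, nrow(data))
  for (j in seq_len(k)) {
    nm <- design$factor_names[j]
    if (!nm %in% names(data))
      stop("data is missing factor column '", nm, "'")
    m <- match(as.character(data[[nm]]), design$levels[[j]])
    if (anyNA(m)) {
      bad <- unique(as.character(data[[nm]])[is.na(m)])
      stop("unknown level(s) for factor '", nm, "': ",
           paste(bad, collapse = ", "))
    }
    idx <- idx + (m - 1L) * 2L^(j - 1L)
  }
  idx
}

# cell means + within-cell sum of squares of the log response: the
# sufficient statistics for every candidate model in a balanced design.
.summarize_log_response <- function(log_y, cell_idx, design) {
  K <- 2L^design$n_factors
  counts <- tabulate(cell_idx, K)
  if (any(counts != design$r))
    stop("unbalanced design: cell counts are (",
         paste(counts, collapse = ", "), ") but r = ", design$r)
  sums <- rowsum(log_y, cell_idx)[, 1L]
  ybar <- sums / design$r
  ssw <- sum(log_y^2) - design$r * sum(ybar^2)
  ssw <- max(ssw, 0)                        # guard tiny negative round-off
  list(ybar = ybar, ssw = ssw)
}

# least squares from sufficient statistics; exact for balanced designs
# because the effect-coded columns are orthogonal (X'X = n I).
.fit_summary <- function(term_set, ybar, ssw, design, Cm = NULL) {
  if (is.null(Cm)) Cm <- .code_matrix(term_set, design)
  K <- nrow(Cm)
  b <- drop(crossprod(Cm, ybar)) / K
  mu <- drop(Cm %*% b)
  rss <- ssw + design$r * sum((ybar - mu)^2)
  p <- term_set$p
  nu <- design$n - p
  if (nu <= 0L)
    stop("saturated model leaves no residual degrees of freedom; use r >= 2")
  sigma2 <- rss / nu
  aic <- design$n * log(rss / design$n) + 2 * (p + 1)
  structure(
    list(term_set = term_set, coefficients = stats::setNames(b, colnames(Cm)),
         mu_hat = mu, rss = rss, nu = nu, sigma2_hat = sigma2, aic = aic,
         n = design$n, p = p, r = design$r, design = design),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat("<fitted_model> ", x$term_set$label,
      sprintf("  rss = %.5g, nu = %d, sigma2_hat = %.5g, AIC = %.4f\n",
              x$rss, x$nu, x$sigma2_hat, x$aic), sep = "")
  invisible(x)
}

#' Effect-coded design matrix for one candidate model
#'
#' Builds the observation-level model matrix with an intercept column and one
#' +1/-1 column per term; a main-effect column is +1 at the factor's first
#' level and -1 at its second, interaction columns are elementwise products.
#'
#' @param term_set A `term_set` from [enumerate_hierarchical_models()].
#' @param design A [factorial_design].
#' @param data Data frame containing the design's factor columns.
#' @return Numeric matrix with `nrow(data)` rows.
#' @export
design_matrix <- function(term_set, design, data) {
  idx <- .cell_index(data, design)
  Cm <- .code_matrix(term_set, design)
  Cm[idx, , drop = FALSE]
}

#' Fit one candidate model by least squares on the log scale
#'
#' Fits the normal linear model `log(Y) = X beta + e` for the given term set
#' on a balanced factorial dataset. The residual variance estimate is the
#' residual mean square `rss / nu` (unbiased), and
#' `AIC = n log(rss/n) + 2 (p + 1)`, the Gaussian profile-likelihood form
#' counting the error variance as a parameter. Only AIC differences matter
#' for model weights, so the additive convention is harmless.
#'
#' @param term_set A `term_set`.
#' @param design A [factorial_design].
#' @param data Data frame with the factor columns and a positive response
#'   column (ignored when `log_response` is given).
#' @param response Name of the response column; default `"y"`.
#' @param log_response Optional numeric vector of log-scale responses, one
#'   per row of `data`, overriding `log(data[[response]])`.
#' @return A `fitted_model` with coefficients, fitted cell means (`mu_hat`),
#'   `rss`, residual df `nu`, `sigma2_hat` and `aic`.
#' @export
fit_model <- function(term_set, design, data, response = "y",
                      log_response = NULL) {
  if (is.null(log_response)) {
    if (!response %in% names(data))
      stop("data is missing response column '", response, "'")
    y <- data[[response]]
    if (any(!is.finite(y)) || any(y <= 0))
      stop("response must be finite and strictly positive (log scale fit); ",
           "first offending row: ",
           which(!is.finite(y) | y <= 0)[1L])
    log_response <- log(y)
  }
  if (length(log_response) != nrow(data))
    stop("'log_response' length must match the number of rows")
  if (any(!is.finite(log_response)))
    stop("log response must be finite")
  idx <- .cell_index(data, design)
  s <- .summarize_log_response(log_response, idx, design)
  .fit_summary(term_set, s$ybar, s$ssw, design)
}

#' Variance factor of a fitted cell mean
#'
#' Returns `h = x0' (X'X)^-1 x0` for the covariate row `x0` of the requested
#' treatment combination, so that `Var(mu_hat_cell) = sigma^2 h` under the
#' fitted model. For a balanced design with effect coding this equals `p / n`
#' for every cell (`1/r` for the saturated model, `1/n` for the null model).
#' `h_mode = "literal_r"` returns `1/r` for every model, a sensitivity mode
#' matching the saturated-model closed form.
#'
#' @param fitted A `fitted_model`.
#' @param cell Cell index in 1..2^k (first factor varying fastest).
#' @param h_mode `"general"` (default) or `"literal_r"`.
#' @return Scalar in (0, 1].
#' @export
cell_mean_variance_factor <- function(fitted, cell,
                                      h_mode = c("general", "literal_r")) {
  h_mode <- match.arg(h_mode)
  design <- fitted$design
  K <- 2L^design$n_factors
  cell <- as.integer(cell)
  if (length(cell) != 1L || is.na(cell) || cell < 1L || cell > K)
    stop("'cell' must be a single index in 1..", K)
  if (h_mode == "literal_r") return(1 / design$r)
  Cm <- .code_matrix(fitted$term_set, design)
  x0 <- Cm[cell, ]
  XtX <- design$r * crossprod(Cm)
  drop(x0 %*% solve(XtX, x0))
}
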