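# Shared fixtures and independent oracles, built in code at test time.

make_design <- function(r = 5) factorial_design(c("P", "I", "V"), r = r)

# a reproducible lognormal factorial dataset
sim_data <- function(seed, r = 5, label = "HML", sigma2 = 1) {
  set.seed(seed)
  scn <- scenario(label, r = r, sigma2 = sigma2, seed = seed)
  eff <- draw_effects(scn)
  list(effects = eff, design = factorial_design(r = r),
       data = simulate_dataset(eff, factorial_design(r = r)))
}

# dense normal-equations least-squares oracle (independent of the
# sufficient-statistic fitting path)
lm_oracle <- function(X, y) {
  b <- solve(crossprod(X), crossprod(X, y))
  list(coef = drop(b), rss = sum((y - X %*% b)^2))
}

# brute-force enumeration oracle: subsets of term labels closed under
# marginality, counted independently of the package's generator
count_hierarchical_oracle <- function(factor_names) {
  k <- length(factor_names)
  subsets_of <- function(x) {
    out <- list(character(0))
    for (e in x) out <- c(out, lapply(out, c, e))
    out
  }
  terms <- unlist(lapply(seq_len(k), function(d)
    combn(factor_names, d, paste0, collapse = "")), use.names = FALSE)
  closed <- function(s) {
    for (t in s) {
      fx <- strsplit(t, "")[[1]]
      if (length(fx) < 2) next
      for (d in seq_len(length(fx) - 1)) {
        subs <- combn(fx, d, paste0, collapse = "")
        if (!all(subs %in% s)) return(FALSE)
      }
    }
    TRUE
  }
  sum(vapply(subsets_of(terms), closed, TRUE))
}

# moment-based sample skewness
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / mean((x - m)^2)^1.5
}

table1_labels <- c(
  "Null", "P", "I", "V", "P+I", "P+V", "I+V", "P+I+V", "P+I+PI",
  "P+V+PV", "I+V+IV", "P+I+V+PI", "P+I+V+PV", "P+I+V+IV",
  "P+I+V+PI+PV", "P+I+V+PI+IV", "P+I+V+PV+IV", "P+I+V+PI+PV+IV",
  "P+I+V+PI+PV+IV+PIV")
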