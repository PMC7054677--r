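# Independent oracles used across the suite. These deliberately re-derive
# results from first principles (exhaustive search, textbook formulas) and
# never call the implementation paths they check.

# exhaustive Otsu: try every distinct value as threshold, maximise the
# between-class variance of {<= t} vs {> t}; ties -> lowest threshold
brute_otsu <- function(v, w = rep(1, length(v))) {
  keep <- w > 0
  v <- v[keep]; w <- w[keep]
  v <- as.numeric(v)
  cand <- sort(unique(v))
  if (length(cand) == 1) return(cand)
  N <- sum(w)
  best <- -Inf; bt <- NA_real_
  for (t in cand) {
    ia <- v <= t
    if (all(ia)) next
    wa <- sum(w[ia]); wb <- N - wa
    bcv <- (wa / N) * (wb / N) *
      (sum(w[ia] * v[ia]) / wa - sum(w[!ia] * v[!ia]) / wb)^2
    if (bcv > best + 1e-12) { best <- bcv; bt <- t }
  }
  bt
}

# textbook equal-variance two-sample t-test
formula_t_test <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

# Pearson r and its t-transform p-value from the defining sums
formula_pearson <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(t), n - 2))
}

# one-way ANOVA F from sums of squares, plus Tukey HSD adjusted p-values via
# the studentised range distribution
formula_anova_tukey <- function(values, group) {
  group <- factor(group)
  k <- nlevels(group); n <- length(values)
  gm <- tapply(values, group, mean); gn <- tapply(values, group, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[group])^2)
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  mse <- ssw / df2
  prs <- utils::combn(levels(group), 2)
  padj <- apply(prs, 2, function(pr) {
    d <- abs(gm[pr[2]] - gm[pr[1]])
    se <- sqrt(mse / 2 * (1 / gn[pr[1]] + 1 / gn[pr[2]]))
    stats::ptukey(d / se, k, df2, lower.tail = FALSE)
  })
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       tukey_p = padj,
       comparison = apply(prs, 2, function(pr) paste(pr[2], pr[1], sep = "-")))
}

# Grubbs critical value from the t-quantile formula
grubbs_crit <- function(n, alpha = 0.05) {
  tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
  ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
}
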