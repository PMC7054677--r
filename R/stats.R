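#' Significance stars
#'
#' The reporting convention used throughout: `*` for p <= 0.05, `**` for
#' p <= 0.01, `***` for p <= 0.001, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector of star strings.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "")))
}

#' Mean and standard error of the mean
#'
#' SEM = sd / sqrt(n) with the n-1 sample standard deviation; n is the number
#' of animals after per-animal median pooling, never the number of images.
#'
#' @param x numeric vector.
#' @return named vector `mean`, `sem`, `n`.
#' @export
mean_sem <- function(x) {
  x <- x[!is.na(x)]
  c(mean = mean(x), sem = stats::sd(x) / sqrt(length(x)), n = length(x))
}

new_test_result <- function(method, statistic, df, p, groups = NULL,
                            extra = NULL) {
  structure(c(list(method = method, statistic = statistic, df = df,
                   p_value = p, stars = significance_stars(p),
                   groups = groups), extra),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, df = %s, p = %.4g %s\n", x$method,
              x$statistic, paste(signif(x$df, 6), collapse = ", "),
              x$p_value, x$stars))
  invisible(x)
}

#' Two-tailed unpaired t-test
#'
#' Student's equal-variance t-test for pairwise comparison of two groups
#' (the default for all pairwise group comparisons here); a Welch option is
#' available but off by default. With zero pooled variance the test is
#' degenerate: equal means give p = 1 by convention, unequal means are an
#' error.
#'
#' @param a,b numeric samples (each n >= 2).
#' @param welch use the Welch unequal-variance form (default `FALSE`).
#' @return a `test_result` with `statistic` (t), `df`, `p_value`, `stars`,
#'   and per-group `n`, `mean`, `sem`.
#' @export
unpaired_t_test <- function(a, b, welch = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 2 || length(b) < 2) stop("each sample needs n >= 2")
  groups <- rbind(a = mean_sem(a), b = mean_sem(b))
  pooled_var <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) /
    (length(a) + length(b) - 2)
  if (pooled_var == 0) {
    if (isTRUE(all.equal(mean(a), mean(b))))
      return(new_test_result("Two-tailed unpaired t-test (Student)", 0,
                             length(a) + length(b) - 2, 1, groups))
    stop("zero pooled variance with unequal means")
  }
  ht <- stats::t.test(a, b, var.equal = !welch, alternative = "two.sided")
  new_test_result(paste0("Two-tailed unpaired t-test (",
                         if (welch) "Welch" else "Student", ")"),
                  unname(ht$statistic), unname(ht$parameter), ht$p.value,
                  groups)
}

#' Bonferroni correction applied per bin
#'
#' For curves and histograms compared bin by bin, each bin's p-value is
#' multiplied by the number of tested bins and capped at 1.
#'
#' @param p numeric vector of per-bin p-values.
#' @param m number of bins corrected for (default `length(p)`).
#' @return adjusted p-values, same length as `p`.
#' @export
bonferroni_per_bin <- function(p, m = length(p)) {
  stopifnot(m >= 1)
  pmin(1, m * p)
}

#' Pearson correlation with two-sided p-value
#'
#' r and the two-sided p-value from the t-transform with n - 2 degrees of
#' freedom.
#'
#' @param x,y numeric vectors of equal length (n >= 3), both with nonzero
#'   variance.
#' @return a `test_result` with `estimate` (r), `statistic` (t), `df`,
#'   `p_value`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("need n >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance")
  ht <- stats::cor.test(x, y, method = "pearson",
                        alternative = "two.sided")
  new_test_result("Pearson correlation", unname(ht$statistic),
                  unname(ht$parameter), ht$p.value,
                  extra = list(estimate = unname(ht$estimate), n = length(x)))
}

#' One-way ANOVA with Tukey HSD post hoc comparisons
#'
#' F-test across >= 3 groups followed by Tukey's multiple comparison test
#' (studentised-range distribution) for every pair. Three identical groups
#' give F = 0, p = 1.
#'
#' @param values numeric vector of observations.
#' @param group factor or character vector of group labels (>= 3 levels,
#'   each n >= 2).
#' @return list: `anova` (a `test_result` with F, df1, df2, p) and `tukey`
#'   (data.frame: comparison, diff, lwr, upr, p_adj, stars).
#' @export
anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 3) stop("need >= 3 groups")
  if (any(table(group) < 2)) stop("every group needs n >= 2")
  fit <- stats::aov(values ~ group)
  s <- summary(fit)[[1]]
  fstat <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (!is.finite(fstat) || stats::var(values) == 0) {
    fstat <- 0; p <- 1                            # identical groups
  }
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      stars = significance_stars(tk[, "p adj"]),
                      row.names = NULL)
  if (any(!is.finite(tukey$p_adj))) tukey$p_adj[!is.finite(tukey$p_adj)] <- 1
  list(anova = new_test_result("One-way ANOVA", fstat,
                               c(s[["Df"]][1], s[["Df"]][2]), p),
       tukey = tukey)
}

#' Iterative two-sided Grubbs outlier removal
#'
#' Applies the single-outlier Grubbs test (the extreme studentised deviate
#' against the t-based critical value
#' `((N-1)/sqrt(N)) * sqrt(t^2 / (N-2+t^2))` with `t = t_{alpha/(2N), N-2}`)
#' and removes the most extreme value while the test rejects, stopping when
#' it no longer does or fewer than 3 values remain.
#'
#' @param values numeric vector (n >= 3).
#' @param alpha significance level per iteration (default 0.05, two-sided).
#' @return list: `retained` values, `removed_idx` (indices into the input,
#'   in removal order), `g` and `g_crit` of the first test.
#' @export
grubbs_outlier <- function(values, alpha = 0.05) {
  if (length(values) < 3) stop("Grubbs test needs n >= 3")
  if (anyNA(values)) stop("missing values not allowed")
  active <- seq_along(values)
  removed <- integer(0)
  g1 <- NA_real_; c1 <- NA_real_
  repeat {
    x <- values[active]
    n <- length(x)
    if (n < 3) break
    s <- stats::sd(x)
    if (s == 0) break
    dev <- abs(x - mean(x))
    g <- max(dev) / s
    tq <- stats::qt(alpha / (2 * n), df = n - 2, lower.tail = FALSE)
    gcrit <- ((n - 1) / sqrt(n)) * sqrt(tq^2 / (n - 2 + tq^2))
    if (is.na(g1)) { g1 <- g; c1 <- gcrit }
    if (g > gcrit) {
      worst <- active[which.max(dev)]
      removed <- c(removed, worst)
      active <- setdiff(active, worst)
    } else break
  }
  list(retained = values[active], removed_idx = removed,
       g = g1, g_crit = c1)
}

#' Group comparison table for a set of metrics
#'
#' Runs the two-tailed unpaired t-test for every metric and pair of groups on
#' animal-level values, returning one row per comparison in the layout of the
#' exported stats table.
#'
#' @param animals data.frame of animal-level values with `group` plus metric
#'   columns.
#' @param metrics metric column names (default: all numeric columns).
#' @return data.frame: metric, group_a, group_b, n_a, n_b, mean_a, mean_b,
#'   sem_a, sem_b, statistic, df, p, stars.
#' @export
compare_groups <- function(animals, metrics = NULL) {
  if (is.null(metrics))
    metrics <- names(animals)[vapply(animals, is.numeric, logical(1))]
  gs <- sort(unique(as.character(animals$group)))
  rows <- list()
  for (m in metrics) {
    for (i in seq_along(gs)) for (j in seq_along(gs)) {
      if (j <= i) next
      a <- animals[[m]][animals$group == gs[i]]
      b <- animals[[m]][animals$group == gs[j]]
      a <- a[!is.na(a)]; b <- b[!is.na(b)]
      if (length(a) < 2 || length(b) < 2) next
      tt <- tryCatch(unpaired_t_test(a, b), error = function(e) NULL)
      if (is.null(tt)) next   # degenerate comparison (e.g. zero variance)
      rows[[length(rows) + 1]] <- data.frame(
        metric = m, group_a = gs[i], group_b = gs[j],
        n_a = length(a), n_b = length(b),
        mean_a = mean(a), mean_b = mean(b),
        sem_a = stats::sd(a) / sqrt(length(a)),
        sem_b = stats::sd(b) / sqrt(length(b)),
        statistic = tt$statistic, df = tt$df, p = tt$p_value,
        stars = tt$stars)
    }
  }
  do.call(rbind, rows)
}
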