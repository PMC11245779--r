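# Scalar statistics for cohort comparisons of gait metrics: single-pass
# outlier removal, normality-gated two-group tests (Student t vs
# Mann-Whitney U), within-subject three-condition tests (repeated-measures
# ANOVA with Bonferroni post hocs vs Friedman with Conover post hocs),
# paired Wilcoxon signed-rank tests and Pearson chi-squared tests.

shapiro_p <- function(x) {
  if (length(unique(x)) < 3 || diff(range(x)) == 0) return(0)
  shapiro.test(x)$p.value
}

new_report <- function(test_name, statistic, p_value, effect_direction = NA,
                       post_hoc = NULL, normality_gate = NA_character_,
                       n_removed_outliers = 0L) {
  structure(list(test_name = test_name, statistic = unname(statistic),
                 p_value = unname(p_value),
                 effect_direction = effect_direction, post_hoc = post_hoc,
                 normality_gate = normality_gate,
                 n_removed_outliers = n_removed_outliers),
            class = "gait_test_report")
}

#' @export
print.gait_test_report <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g", x$test_name, x$statistic,
              x$p_value))
  if (!is.na(x$normality_gate)) cat(sprintf("  [gate: %s]", x$normality_gate))
  cat("\n")
  if (!is.null(x$post_hoc) && nrow(x$post_hoc)) {
    cat("  post hoc (adjusted):\n")
    for (i in seq_len(nrow(x$post_hoc)))
      cat(sprintf("    %s: p = %.4g\n", x$post_hoc$pair[i],
                  x$post_hoc$p_adjusted[i]))
  }
  invisible(x)
}

#' Single-pass outlier removal
#'
#' For normally distributed samples, removes values more than 3 standard
#' deviations from the mean (z-score rule); otherwise removes values outside
#' the Tukey fences `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]` (type-7 quartiles).
#' Statistics are computed once on the original sample (no iteration).
#'
#' @param x numeric sample, n >= 4.
#' @param normal logical: use the z-score rule?  Default `NULL` decides by a
#'   Shapiro-Wilk test at the 0.05 level.
#' @return List with `values` (kept), `removed` (indices into `x`) and
#'   `method` (`"zscore"` or `"tukey"`).
#' @export
remove_outliers <- function(x, normal = NULL) {
  if (length(x) < 4) stop("outlier removal needs n >= 4")
  if (is.null(normal)) normal <- shapiro_p(x) >= 0.05
  if (normal) {
    s <- sd(x)
    out <- if (s == 0) rep(FALSE, length(x)) else abs(x - mean(x)) / s > 3
    method <- "zscore"
  } else {
    q <- quantile(x, c(0.25, 0.75), type = 7, names = FALSE)
    iqr <- q[2] - q[1]
    out <- x < q[1] - 1.5 * iqr | x > q[2] + 1.5 * iqr
    method <- "tukey"
  }
  list(values = x[!out], removed = which(out), method = method)
}

#' Normality-gated two-group comparison
#'
#' Shapiro-Wilk on both samples: if both are compatible with normality
#' (p >= 0.05) a two-sample Student t-test is used, otherwise a Mann-Whitney
#' U test.  If the samples disagree on normality the nonparametric branch
#' wins.
#'
#' @param a,b numeric samples, n >= 3 each.
#' @param alpha significance level (recorded; default 0.05).
#' @return A `gait_test_report`.
#' @export
compare_two_groups <- function(a, b, alpha = 0.05) {
  if (length(a) < 3 || length(b) < 3) stop("need n >= 3 per group")
  if (diff(range(a)) == 0 && diff(range(b)) == 0)
    stop("both samples are degenerate (zero variance)")
  normal <- shapiro_p(a) >= 0.05 && shapiro_p(b) >= 0.05
  if (normal) {
    tt <- t.test(a, b, var.equal = TRUE)
    new_report("two-sample t", tt$statistic, tt$p.value,
               effect_direction = sign(mean(a) - mean(b)),
               normality_gate = "normal")
  } else {
    wt <- suppressWarnings(wilcox.test(a, b))
    new_report("Mann-Whitney U", wt$statistic, wt$p.value,
               effect_direction = sign(median(a) - median(b)),
               normality_gate = "non-normal")
  }
}

# Conover-Iman all-pairs post hoc on Friedman (within-block) ranks:
# t statistics on rank-sum differences with the Conover variance, df
# (n-1)(k-1), Bonferroni adjustment.
conover_posthoc <- function(m) {
  n <- nrow(m); k <- ncol(m)
  Rk <- t(apply(m, 1, rank))
  Rj <- colSums(Rk)
  A <- sum(Rk^2)
  B <- sum(Rj^2) / n
  dfree <- (n - 1) * (k - 1)
  se <- sqrt(2 * n * (A - B) / dfree)
  pairs <- utils::combn(k, 2)
  lab <- colnames(m) %||% paste0("cond", seq_len(k))
  res <- apply(pairs, 2, function(ij) {
    tstat <- abs(Rj[ij[1]] - Rj[ij[2]]) / se
    2 * pt(tstat, dfree, lower.tail = FALSE)
  })
  data.frame(pair = apply(pairs, 2, function(ij) paste(lab[ij], collapse = " vs ")),
             p_unadjusted = res,
             p_adjusted = pmin(1, p.adjust(res, "bonferroni")),
             stringsAsFactors = FALSE)
}

#' Within-subject comparison of three walking conditions
#'
#' Complete-case subjects x conditions matrix.  If every condition's sample
#' is compatible with normality (Shapiro-Wilk p >= 0.05), a repeated-
#' measures ANOVA is used with Bonferroni-adjusted paired t post hocs;
#' otherwise a Friedman test with Conover-Iman post hocs (Bonferroni-
#' adjusted).  Post hocs are reported only when the omnibus test is
#' significant at `alpha`.
#'
#' @param m numeric matrix, rows = subjects (complete cases), columns = the
#'   three conditions (named).
#' @param alpha significance level (default 0.05).
#' @return A `gait_test_report`.
#' @export
compare_three_conditions <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  if (ncol(m) != 3) stop("expected exactly 3 conditions")
  m <- m[complete.cases(m), , drop = FALSE]
  n <- nrow(m)
  if (n < 5) stop("need at least 5 complete-case subjects")
  lab <- colnames(m) %||% paste0("cond", 1:3)
  colnames(m) <- lab
  if (all(m == rowMeans(m))) {
    # no within-subject condition differences at all: no evidence
    return(new_report("RM-ANOVA", 0, 1, normality_gate = "degenerate"))
  }
  normal <- all(apply(m, 2, shapiro_p) >= 0.05)
  if (normal) {
    dat <- data.frame(y = as.vector(m),
                      cond = factor(rep(lab, each = n), levels = lab),
                      subj = factor(rep(seq_len(n), times = 3)))
    fit <- aov(y ~ cond + Error(subj), data = dat)
    tab <- summary(fit)[["Error: Within"]][[1]]
    fstat <- tab["cond", "F value"]
    pval <- tab["cond", "Pr(>F)"]
    ph <- NULL
    if (pval < alpha) {
      pairs <- utils::combn(3, 2)
      praw <- apply(pairs, 2, function(ij)
        t.test(m[, ij[1]], m[, ij[2]], paired = TRUE)$p.value)
      ph <- data.frame(
        pair = apply(pairs, 2, function(ij) paste(lab[ij], collapse = " vs ")),
        p_unadjusted = praw,
        p_adjusted = pmin(1, p.adjust(praw, "bonferroni")),
        stringsAsFactors = FALSE)
    }
    new_report("RM-ANOVA", fstat, pval, post_hoc = ph,
               normality_gate = "normal")
  } else {
    fr <- friedman.test(m)
    ph <- if (fr$p.value < alpha) conover_posthoc(m) else NULL
    new_report("Friedman", fr$statistic, fr$p.value, post_hoc = ph,
               normality_gate = "non-normal")
  }
}

#' Paired comparison of medication on vs off
#'
#' Wilcoxon signed-rank test on matched samples; exact null distribution for
#' n <= 25 without ties (the default of [wilcox.test()]), normal
#' approximation with continuity correction otherwise.  Zero differences are
#' dropped (standard convention); if all differences are zero, p = 1 by
#' convention.
#'
#' @param on,off matched numeric samples of equal length, n >= 5.
#' @param alpha significance level (recorded; default 0.05).
#' @return A `gait_test_report`.
#' @export
compare_paired <- function(on, off, alpha = 0.05) {
  if (length(on) != length(off)) stop("paired samples must have equal length")
  if (length(on) < 5) stop("need at least 5 pairs")
  d <- on - off
  if (all(d == 0)) {
    return(new_report("Wilcoxon signed-rank", 0, 1,
                      effect_direction = 0))
  }
  wt <- suppressWarnings(wilcox.test(on, off, paired = TRUE,
                                     correct = TRUE))
  new_report("Wilcoxon signed-rank", wt$statistic, wt$p.value,
             effect_direction = sign(median(d)))
}

#' Pearson chi-squared comparison of categorical counts
#'
#' @param counts 2 x k matrix of nonnegative integer counts (e.g. gender by
#'   group), with no zero margins.
#' @return A `gait_test_report`.
#' @export
compare_categorical <- function(counts) {
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero margin in contingency table")
  ct <- suppressWarnings(chisq.test(counts, correct = FALSE))
  new_report("chi-squared", ct$statistic, ct$p.value)
}
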