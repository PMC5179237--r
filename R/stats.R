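#' Training gain scores
#'
#' Gain is always the post-training minus pre-training score, so improvement
#' is positive; it is computed on demand and never stored as an independent
#' column.
#'
#' @param cohort data frame with at least `subject_id`, `score_pre` and
#'   `score_post` columns.
#' @return named numeric vector of gains (names = subject ids).
#' @export
gain_scores <- function(cohort) {
  need <- c("subject_id", "score_pre", "score_post")
  if (!all(need %in% names(cohort)))
    stop("cohort needs columns: ", paste(need, collapse = ", "))
  miss <- !is.finite(cohort$score_pre) | !is.finite(cohort$score_post)
  if (any(miss))
    stop("missing score for subject(s): ",
         paste(cohort$subject_id[miss], collapse = ", "))
  setNames(cohort$score_post - cohort$score_pre,
           as.character(cohort$subject_id))
}

.new_cor_result <- function(estimate, n, df, p, kind, ci = NULL) {
  structure(list(estimate = estimate, n = n, df = df, p = p,
                 ci = ci, kind = kind),
            class = "netgain_cor")
}

#' @export
print.netgain_cor <- function(x, ...) {
  lab <- if (x$kind == "spearman") "rho" else "r_p"
  cat(sprintf("%s(%d) = %.3f, p = %.4g", lab, x$df, x$estimate, x$p))
  if (!is.null(x$ci))
    cat(sprintf(", %g%% BCa CI [%.3f, %.3f]",
                100 * attr(x$ci, "level"), x$ci[1], x$ci[2]))
  cat("\n")
  invisible(x)
}

# fast Spearman rho (average ranks for ties)
.rho <- function(x, y) cor(rank(x), rank(y))

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The two-sided p-value uses
#' the t approximation on `n - 2` degrees of freedom by default (the
#' convention behind "rho(df)" reporting); `p_method = "permutation"` gives
#' a seeded permutation p-value instead.
#'
#' @param x,y paired numeric vectors, n >= 4, finite.
#' @param p_method `"t"` (default) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param seed RNG seed for the permutation test.
#' @return `netgain_cor` object (fields `estimate`, `n`, `df = n - 2`, `p`,
#'   `kind = "spearman"`).
#' @export
spearman_cor <- function(x, y, p_method = c("t", "permutation"),
                         n_perm = 10000, seed = NULL) {
  p_method <- match.arg(p_method)
  .check_pairs(x, y, 4)
  n <- length(x)
  rho <- .rho(x, y)
  if (p_method == "t") {
    p <- if (1 - rho^2 < 1e-15) 0 else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      2 * pt(-abs(tstat), n - 2)
    }
  } else {
    p <- with_seed(seed, {
      rx <- rank(x)
      ry <- rank(y)
      perm <- replicate(n_perm, cor(rx, sample(ry)))
      (1 + sum(abs(perm) >= abs(rho) - 1e-12)) / (n_perm + 1)
    })
  }
  .new_cor_result(rho, n, n - 2, p, "spearman")
}

.check_pairs <- function(x, y, min_n) {
  if (length(x) != length(y)) stop("x and y differ in length")
  if (length(x) < min_n) stop("need n >= ", min_n, ", got ", length(x))
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("x and y must be finite")
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation undefined for a constant vector")
  invisible(TRUE)
}

#' Partial Pearson correlation
#'
#' Pearson correlation between the residuals of `x` and `y` after
#' least-squares regression on the control covariates (plus intercept); the
#' p-value is two-sided on `n - 2 - k` degrees of freedom for `k` controls.
#' Controls enter as raw values by default, matching the usual contrast with
#' rank-based simple correlations; `on = "ranks"` rank-transforms all
#' variables first.
#'
#' @param x,y paired numeric vectors.
#' @param controls numeric vector, matrix or data frame of control
#'   covariates (one column each).
#' @param on `"values"` (default) or `"ranks"`.
#' @return `netgain_cor` object with `kind = "partial-pearson"` and
#'   `df = n - 2 - k`.
#' @export
partial_pearson <- function(x, y, controls, on = c("values", "ranks")) {
  on <- match.arg(on)
  C <- as.matrix(as.data.frame(controls))
  n <- length(x)
  k <- ncol(C)
  if (n <= k + 2) stop("need n > #controls + 2 (n = ", n, ", k = ", k, ")")
  .check_pairs(x, y, 4)
  if (nrow(C) != n) stop("controls must have one row per observation")
  if (any(!is.finite(C))) stop("controls must be finite")
  if (on == "ranks") {
    x <- rank(x); y <- rank(y); C <- apply(C, 2, rank)
  }
  X <- cbind(1, C)
  if (qr(X)$rank < ncol(X)) stop("collinear controls")
  rx <- lm.fit(X, x)$residuals
  ry <- lm.fit(X, y)$residuals
  if (sd(rx) < 1e-12 * max(sd(x), 1) || sd(ry) < 1e-12 * max(sd(y), 1))
    stop("degenerate partial correlation: a variable is fully explained ",
         "by the controls")
  r <- cor(rx, ry)
  df <- n - 2 - k
  p <- if (1 - r^2 < 1e-15) 0 else {
    tstat <- r * sqrt(df / (1 - r^2))
    2 * pt(-abs(tstat), df)
  }
  .new_cor_result(r, n, df, p, "partial-pearson")
}

#' Bias-corrected and accelerated (BCa) bootstrap CI for a correlation
#'
#' Resamples subjects (x, y pairs jointly) with replacement, computes the
#' chosen correlation on each resample, and returns the BCa interval: the
#' percentile interval with endpoints shifted by the bias correction `z0`
#' (from the proportion of bootstrap values below the observed statistic)
#' and the acceleration `a` (from the jackknife skewness). With `z0 = 0`
#' and `a = 0` it reduces to the plain percentile interval. Resamples on
#' which the statistic is undefined (a constant vector) are redrawn, up to
#' `max_redraw` attempts each.
#'
#' @param x,y paired numeric vectors, n >= 5.
#' @param statistic `"spearman"` or `"pearson"`.
#' @param B bootstrap resamples (>= 200; 2000 is the conventional default).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed; the interval is reproducible given (data, B, seed).
#' @param max_redraw redraw cap per degenerate resample.
#' @return numeric `c(lo, hi)` with attributes `z0`, `a`, `B`, `level`.
#' @export
bca_ci <- function(x, y, statistic = c("spearman", "pearson"), B = 2000,
                   level = 0.95, seed = NULL, max_redraw = 100) {
  statistic <- match.arg(statistic)
  .check_pairs(x, y, 5)
  if (B < 200) stop("B must be >= 200")
  stat <- if (statistic == "spearman") .rho else cor
  n <- length(x)
  t0 <- stat(x, y)
  tb <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      for (try in seq_len(max_redraw)) {
        idx <- sample.int(n, n, replace = TRUE)
        if (sd(x[idx]) > 0 && sd(y[idx]) > 0) return(stat(x[idx], y[idx]))
      }
      stop("degenerate bootstrap resamples persisted after ", max_redraw,
           " redraws")
    }, numeric(1))
  })
  z0 <- 0; a <- 0
  if (all(abs(tb - t0) < 1e-15)) {
    ci <- c(t0, t0)       # e.g. perfectly monotone data: every resample ties
  } else {
    z0 <- qnorm((sum(tb < t0) + 0.5 * sum(tb == t0)) / B)
    jack <- vapply(seq_len(n), function(i) stat(x[-i], y[-i]), numeric(1))
    d <- mean(jack) - jack
    a <- if (sum(d^2) == 0) 0 else sum(d^3) / (6 * sum(d^2)^1.5)
    alpha <- c((1 - level) / 2, 1 - (1 - level) / 2)
    zal <- qnorm(alpha)
    adj <- pnorm(z0 + (z0 + zal) / (1 - a * (z0 + zal)))
    ci <- unname(quantile(tb, probs = adj, type = 6, names = FALSE))
  }
  structure(ci, z0 = z0, a = a, B = B, level = level)
}

#' Compare two correlations from independent samples
#'
#' Spearman estimates are first converted to Pearson scale with the
#' Myers-Sirois relation `r = 2 sin(pi * rho / 6)` (which maps 0 to 0 and 1
#' to 1); both correlations are then Fisher z-transformed and compared with
#' the normal statistic `z = (z1 - z2) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' two-sided.
#'
#' @param r1,r2 `netgain_cor` objects, or lists with `estimate`, `n` and
#'   `kind` (`"spearman"` entries are converted; anything else is used
#'   as-is).
#' @return list with `statistic`, `p`, `r1`, `r2` (the converted Pearson
#'   values) and `n1`, `n2`.
#' @export
compare_correlations <- function(r1, r2) {
  conv <- function(r) {
    est <- r$estimate
    if (identical(r$kind, "spearman")) est <- 2 * sin(pi * est / 6)
    if (abs(est) >= 1)
      stop("|r| = 1: Fisher z is infinite, comparison undefined")
    list(z = atanh(est), n = r$n, r = est)
  }
  a <- conv(r1); b <- conv(r2)
  if (a$n < 4 || b$n < 4) stop("need n >= 4 in both samples")
  zstat <- (a$z - b$z) / sqrt(1 / (a$n - 3) + 1 / (b$n - 3))
  list(statistic = zstat, p = 2 * pnorm(-abs(zstat)),
       r1 = a$r, r2 = b$r, n1 = a$n, n2 = b$n)
}

#' 2x2 mixed ANOVA (group x time) with partial eta-squared
#'
#' Repeated-measures ANOVA with a within-subject factor of time (pre/post)
#' and a between-subject factor of group; reports the group-by-time
#' interaction F on (1, N - 2) degrees of freedom and its partial
#' eta-squared `SS_effect / (SS_effect + SS_error)`. For this design the
#' interaction F is algebraically the square of the pooled-variance
#' independent-samples t on the gain scores.
#'
#' @param cohort data frame with `subject_id`, `group` (two levels),
#'   `score_pre`, `score_post`; every group needs >= 2 subjects.
#' @return list with `F`, `df` (c(1, N - 2)), `p`, `eta_p2`.
#' @export
mixed_anova_2x2 <- function(cohort) {
  gain_scores(cohort)                      # validates score columns
  grp <- factor(cohort$group)
  if (nlevels(grp) != 2)
    stop("need exactly two groups, got ", nlevels(grp))
  if (any(table(grp) < 2))
    stop("each group needs >= 2 subjects")
  N <- nrow(cohort)
  long <- data.frame(
    subject = factor(rep(cohort$subject_id, 2)),
    group = factor(rep(as.character(grp), 2)),
    time = factor(rep(c("pre", "post"), each = N), levels = c("pre", "post")),
    score = c(cohort$score_pre, cohort$score_post))
  fit <- aov(score ~ group * time + Error(subject), data = long)
  within <- summary(fit)[["Error: Within"]][[1]]
  ss <- within[["Sum Sq"]]
  rn <- trimws(rownames(within))
  ss_int <- ss[rn == "group:time"]
  ss_err <- ss[rn == "Residuals"]
  Fstat <- within[["F value"]][rn == "group:time"]
  p <- within[["Pr(>F)"]][rn == "group:time"]
  list(F = Fstat, df = c(1, N - 2), p = p,
       eta_p2 = ss_int / (ss_int + ss_err))
}

#' Baseline group-matching tests
#'
#' Pooled-variance two-sample t-test for a continuous variable, or a 2x2
#' chi-square test of independence without continuity correction for a
#' binary categorical variable, comparing the two groups at baseline.
#'
#' @param cohort data frame with a two-level `group` column.
#' @param variable name of the column to test.
#' @return list with `method`, `statistic`, `df`, `p`.
#' @export
group_baseline_tests <- function(cohort, variable) {
  if (!variable %in% names(cohort)) stop("no column '", variable, "'")
  grp <- factor(cohort$group)
  if (nlevels(grp) != 2) stop("need exactly two groups")
  v <- cohort[[variable]]
  if (is.numeric(v) && length(unique(v)) > 2) {
    ht <- stats::t.test(v ~ grp, var.equal = TRUE)
    list(method = "t", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value)
  } else {
    tab <- table(grp, factor(v))
    if (!all(dim(tab) == c(2, 2)))
      stop("categorical variable must have exactly two levels")
    exp_cnt <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_cnt == 0)) stop("empty expected cell")
    ht <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    list(method = "chisq", statistic = unname(ht$statistic),
         df = unname(ht$parameter), p = ht$p.value)
  }
}
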