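make_cohort <- function(pre, post, group = NULL, ids = NULL) {
  n <- length(pre)
  data.frame(subject_id = ids %||% paste0("s", seq_len(n)),
             group = group %||% rep(c("Control", "SMART"), length.out = n),
             score_pre = pre, score_post = post,
             stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("gain is post minus pre, with missing scores rejected by name", {
  ct <- make_cohort(c(35, 52.1, 10), c(40, 49.8, 10))
  expect_equal(unname(gain_scores(ct)), c(5, -2.3, 0))
  ct$score_post[2] <- NA
  expect_error(gain_scores(ct), "s2")
})

test_that("spearman rho matches the rank formula and is monotone-invariant", {
  res <- spearman_cor(1:5, c(2, 1, 4, 3, 5))
  # d = (-1, 1, -1, 1, 0): rho = 1 - 6 * 4 / (5 * 24) = 0.8
  expect_equal(res$estimate, 0.8, tolerance = 1e-14)
  expect_equal(res$estimate, cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"))
  expect_equal(res$df, 3)
  # t-approximation p-value on df = n - 2
  tstat <- 0.8 * sqrt(3 / (1 - 0.64))
  expect_equal(res$p, 2 * pt(-tstat, 3), tolerance = 1e-12)

  set.seed(30)
  x <- rnorm(12)
  expect_equal(spearman_cor(x, exp(2 * x) + 5)$estimate, 1)
  expect_equal(spearman_cor(x, -x^3)$estimate, -1)
  expect_equal(spearman_cor(x, rev(sort(x))[rank(x)])$estimate, -1)
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "constant")
  expect_error(spearman_cor(1:3, 1:3), "n >= 4")

  # seeded permutation p is reproducible and detects a real association
  y_perm <- 2 * x + rnorm(12)
  pp <- spearman_cor(x, y_perm, "permutation", n_perm = 4000, seed = 1)
  expect_identical(pp$p,
                   spearman_cor(x, y_perm, "permutation", n_perm = 4000,
                                seed = 1)$p)
  expect_lt(pp$p, 0.05)
})

test_that("partial correlation equals plain Pearson under orthogonal controls", {
  set.seed(31)
  x <- rnorm(30); y <- 0.5 * x + rnorm(30)
  c0 <- rnorm(30)
  c_orth <- lm.fit(cbind(1, x, y), c0)$residuals   # orthogonal by construction
  plain <- cor(x, y)
  pc <- partial_pearson(x, y, c_orth)
  expect_equal(pc$estimate, plain, tolerance = 1e-10)
  expect_equal(pc$df, 30 - 3)
})

test_that("partial correlation matches the single-control closed form", {
  set.seed(32)
  for (rep in 1:10) {
    x <- rnorm(25); c1 <- rnorm(25)
    y <- 0.4 * x + 0.5 * c1 + rnorm(25)
    r_xy <- cor(x, y); r_xc <- cor(x, c1); r_yc <- cor(y, c1)
    closed <- (r_xy - r_xc * r_yc) / sqrt((1 - r_xc^2) * (1 - r_yc^2))
    expect_equal(partial_pearson(x, y, c1)$estimate, closed,
                 tolerance = 1e-12)
  }
})

test_that("degenerate and collinear control sets are rejected", {
  set.seed(33)
  x <- rnorm(20); y <- rnorm(20)
  expect_error(partial_pearson(x, y, y), "degenerate")
  expect_error(partial_pearson(x, y, cbind(x, 2 * x)), "collinear")
  expect_error(partial_pearson(rnorm(4), rnorm(4), cbind(rnorm(4), rnorm(4))),
               "#controls")
})

test_that("BCa interval is seeded-deterministic and collapses for exact monotone data", {
  set.seed(34)
  x <- rnorm(15); y <- 0.6 * x + rnorm(15)
  ci1 <- bca_ci(x, y, "spearman", B = 500, seed = 99)
  ci2 <- bca_ci(x, y, "spearman", B = 500, seed = 99)
  expect_identical(as.numeric(ci1), as.numeric(ci2))
  ci3 <- bca_ci(x, y, "spearman", B = 500, seed = 100)
  expect_false(identical(as.numeric(ci1), as.numeric(ci3)))
  rho_hat <- cor(rank(x), rank(y))
  expect_lte(ci1[1], rho_hat)
  expect_gte(ci1[2], rho_hat)

  # y = 2x: every resample has rho = 1
  exact <- bca_ci(x, 2 * x, "spearman", B = 300, seed = 1)
  expect_equal(as.numeric(exact), c(1, 1))

  expect_error(bca_ci(x[1:4], y[1:4]), "n >= 5")
  expect_error(bca_ci(x, y, B = 100), "B must be >= 200")
})

test_that("BCa endpoints agree with the boot package on the same data", {
  skip_if_not_installed("boot")
  set.seed(35)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  ours <- bca_ci(x, y, "pearson", B = 8000, seed = 7)
  bt <- boot::boot(cbind(x, y),
                   function(d, i) cor(d[i, 1], d[i, 2]), R = 8000)
  # jackknife influence so boot's acceleration matches our jackknife-based a
  bci <- boot::boot.ci(bt, type = "bca",
                       L = boot::empinf(bt, type = "jack"))$bca[4:5]
  expect_equal(as.numeric(ours), bci, tolerance = 0.04)
})

test_that("independent-correlation comparison uses the rank conversion and Fisher z", {
  r1 <- list(estimate = 0.4, n = 15, kind = "spearman")
  expect_equal(compare_correlations(r1, r1)$p, 1)

  # conversion endpoints: 0 -> 0 and (near) 1 -> (near) 1
  z <- compare_correlations(list(estimate = 0, n = 15, kind = "spearman"),
                            list(estimate = 0.5, n = 15, kind = "spearman"))
  expect_equal(z$r1, 0)
  r_hi <- compare_correlations(
    list(estimate = 1 - 1e-9, n = 15, kind = "spearman"),
    list(estimate = 0, n = 15, kind = "spearman"))$r1
  expect_equal(r_hi, 1, tolerance = 1e-8)

  # frozen hand computation: rho1 = 0.65 (n 15) vs rho2 = -0.12 (n 14)
  cmp <- compare_correlations(list(estimate = 0.65, n = 15, kind = "spearman"),
                              list(estimate = -0.12, n = 14, kind = "spearman"))
  expect_equal(cmp$r1, 0.6676137185, tolerance = 1e-9)
  expect_equal(cmp$r2, -0.1255810391, tolerance = 1e-9)
  expect_equal(cmp$statistic, 2.2343566845, tolerance = 1e-9)
  expect_equal(cmp$p, 0.0254596134, tolerance = 1e-8)

  expect_error(compare_correlations(
    list(estimate = 1, n = 10, kind = "pearson"),
    list(estimate = 0, n = 10, kind = "pearson")), "infinite")
})

test_that("mixed ANOVA interaction equals the brute-force SS oracle on a toy cohort", {
  ct <- make_cohort(pre = c(10, 12, 11, 20, 22, 19),
                    post = c(12, 15, 11, 21, 22, 18),
                    group = rep(c("A", "B"), each = 3))
  res <- mixed_anova_2x2(ct)
  orc <- oracle_mixed_anova(ct)
  expect_equal(res$F, orc$F, tolerance = 1e-10)
  expect_equal(res$eta_p2, orc$eta_p2, tolerance = 1e-10)
  expect_equal(res$df, c(1, 4))
})

test_that("interaction F equals t-squared of the gain-score t-test", {
  set.seed(36)
  for (rep in 1:20) {
    n1 <- sample(4:10, 1); n2 <- sample(4:10, 1)
    ct <- make_cohort(pre = rnorm(n1 + n2, 50, 8),
                      post = rnorm(n1 + n2, 52, 8),
                      group = rep(c("A", "B"), c(n1, n2)))
    res <- mixed_anova_2x2(ct)
    tt <- t.test(gain_scores(ct) ~ ct$group, var.equal = TRUE)
    expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-9)
    expect_equal(res$p, tt$p.value, tolerance = 1e-9)
  }
})

test_that("no group-by-time interaction when gains are distribution-identical", {
  gains <- c(1, -2, 0, 3, 2)
  ct <- make_cohort(pre = c(rep(10, 5), rep(30, 5)),
                    post = c(10 + gains, 30 + gains),
                    group = rep(c("A", "B"), each = 5))
  res <- mixed_anova_2x2(ct)
  expect_equal(res$F, 0, tolerance = 1e-12)
  expect_equal(res$eta_p2, 0, tolerance = 1e-12)
  expect_error(mixed_anova_2x2(make_cohort(1:3, 2:4,
                                           group = c("A", "A", "B"))),
               ">= 2 subjects")
})

test_that("baseline matching tests: pooled t and uncorrected chi-square", {
  ct <- make_cohort(pre = c(1, 2, 3, 1, 2, 3), post = rep(0, 6),
                    group = rep(c("A", "B"), each = 3))
  res <- group_baseline_tests(ct, "score_pre")
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)
  expect_equal(res$df, 4)

  ct2 <- data.frame(group = rep(c("A", "B"), each = 10),
                    sex = c(rep(c("f", "m"), each = 5),
                            rep(c("f", "m"), each = 5)))
  even <- group_baseline_tests(ct2, "sex")
  expect_equal(even$statistic, 0)

  ct3 <- data.frame(group = rep(c("A", "B"), each = 10),
                    sex = c(rep("f", 6), rep("m", 4), rep("f", 3), rep("m", 7)))
  res3 <- group_baseline_tests(ct3, "sex")
  expect_equal(res3$statistic, 20 * (6 * 7 - 4 * 3)^2 / (10 * 10 * 9 * 11),
               tolerance = 1e-12)    # hand E-table: 1.8181...
  expect_equal(res3$statistic, 1.818181818, tolerance = 1e-8)
})
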