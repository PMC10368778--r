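make_twoway <- function(n = 8, a = 2, b = 3, effect = 0, seed = 1) {
  set.seed(seed)
  d <- tidyr::expand_grid(
    id = factor(sprintf("s%02d", 1:n)),
    A = factor(letters[1:a]), B = factor(LETTERS[1:b])
  )
  d$y <- rnorm(nrow(d)) + effect * (as.integer(d$A) - 1)
  d
}

test_that("two-way RM-ANOVA matches the longhand sums-of-squares oracle", {
  for (seed in 1:3) {
    d <- make_twoway(n = 10, a = 2, b = 4, effect = 0.4, seed = seed)
    res <- rm_anova_twoway(d, y, A, B, id)
    oracle <- rm_anova_twoway_oracle(d)
    for (i in 1:3) {
      o <- oracle[[c("A", "B", "AB")[i]]]
      expect_equal(res$statistic[i], o$F, tolerance = 1e-10)
      expect_equal(res$df1[i], o$df1)
      expect_equal(res$df2[i], o$df2)
      expect_equal(res$p.value[i], o$p, tolerance = 1e-10)
    }
    # partial eta squared is consistent with its own F and dfs
    expect_equal(res$pes,
                 res$statistic * res$df1 /
                   (res$statistic * res$df1 + res$df2))
  }
})

test_that("constant data yield zero F for every effect", {
  d <- make_twoway(n = 6)
  d$y <- 5
  res <- rm_anova_twoway(d, y, A, B, id)
  expect_equal(res$statistic, rep(0, 3))
})

test_that("one-way RM-ANOVA with two conditions equals the squared paired t", {
  for (seed in 4:6) {
    set.seed(seed)
    d <- tidyr::expand_grid(id = factor(1:12),
                            cond = c("before", "after"))
    d$y <- rnorm(nrow(d)) + (d$cond == "after") * 0.3
    res <- rm_anova_oneway(d, y, cond, id)
    wide <- tidyr::pivot_wider(d, names_from = "cond",
                               values_from = "y")
    tt <- t.test(wide$after, wide$before, paired = TRUE)
    expect_equal(res$statistic, unname(tt$statistic)^2,
                 tolerance = 1e-10)
    expect_equal(res$p.value, tt$p.value, tolerance = 1e-10)
    expect_equal(res$df1, 1)
    expect_equal(res$df2, 11)
  }
  # identical condition columns -> F = 0
  d0 <- tidyr::expand_grid(id = factor(1:6), cond = c("x", "y"))
  d0$y <- rep(rnorm(6), each = 2)
  expect_equal(rm_anova_oneway(d0, y, cond, id)$statistic, 0)
})

test_that("incomplete designs are rejected, not imputed", {
  d <- make_twoway(n = 5)
  expect_error(rm_anova_twoway(d[-1, ], y, A, B, id), "Incomplete")
  d1 <- tidyr::expand_grid(id = factor(1:5), cond = c("a", "b"))
  d1$y <- rnorm(10)
  expect_error(rm_anova_oneway(d1[-3, ], y, cond, id), "Incomplete")
})

test_that("Greenhouse-Geisser correction shrinks dfs, epsilon in (1/(k-1), 1]", {
  set.seed(8)
  d <- tidyr::expand_grid(id = factor(1:12),
                          cond = factor(c("a", "b", "c", "d")))
  d$y <- rnorm(nrow(d)) + as.integer(d$cond) * 0.2
  plain <- rm_anova_oneway(d, y, cond, id)
  gg <- rm_anova_oneway(d, y, cond, id, gg = TRUE)
  eps <- gg$gg_epsilon
  expect_gt(eps, 1 / 3)
  expect_lte(eps, 1 + 1e-12)
  expect_equal(gg$df1, plain$df1 * eps)
  expect_equal(gg$df2, plain$df2 * eps)
  expect_equal(gg$statistic, plain$statistic) # F itself unchanged
  expect_gte(gg$p.value, plain$p.value - 1e-12)
})

test_that("Welch t-test matches the closed-form computation", {
  set.seed(9)
  x <- rnorm(40, 0.3, 1.2)
  y <- rnorm(43, 0, 0.8)
  res <- ttest_two_sample(x, y)
  nx <- length(x); ny <- length(y)
  se <- sqrt(var(x) / nx + var(y) / ny)
  t_hand <- (mean(x) - mean(y)) / se
  df_hand <- se^4 / ((var(x) / nx)^2 / (nx - 1) +
                       (var(y) / ny)^2 / (ny - 1))
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p.value,
               2 * pt(abs(t_hand), df_hand, lower.tail = FALSE),
               tolerance = 1e-12)
  sp <- sqrt(((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2))
  expect_equal(res$cohens_d, (mean(x) - mean(y)) / sp)
  # fractional df, as reported for unequal-variance comparisons
  expect_false(res$df == round(res$df))
})

test_that("Welch t-test edge cases: identity, antisymmetry, constants", {
  x <- c(1, 2, 3, 4)
  same <- ttest_two_sample(x, x)
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)
  set.seed(10)
  a <- rnorm(15); b <- rnorm(20, 0.4)
  ab <- ttest_two_sample(a, b)
  ba <- ttest_two_sample(b, a)
  expect_equal(ab$statistic, -ba$statistic)
  expect_equal(ab$p.value, ba$p.value)
  const <- ttest_two_sample(rep(2, 5), rep(2, 7))
  expect_equal(const$statistic, 0)
  expect_equal(const$p.value, 1)
})

test_that("3-SD outlier removal is single-pass, grouped and idempotent", {
  vals <- c(rnorm(100), 50) # one gross outlier
  d <- tibble::tibble(g = rep("a", 101), v = vals)
  out <- remove_outliers_3sd(d, v, group = "g")
  expect_equal(n_removed(out), 1L)
  expect_false(50 %in% out$v)
  # constant group: nothing removed (z undefined -> kept)
  dc <- tibble::tibble(g = "b", v = rep(3, 10))
  expect_equal(n_removed(remove_outliers_3sd(dc, v, group = "g")), 0L)
  # single pass: re-applying to its own output uses fresh statistics,
  # but the rule with statistics estimated once does not re-trim here
  out2 <- remove_outliers_3sd(out, v, group = "g")
  expect_lte(n_removed(out2), 1L)
})

test_that("Bonferroni post-hocs multiply raw p-values by the number of pairs", {
  set.seed(11)
  d <- tidyr::expand_grid(id = factor(1:10),
                          cond = factor(c("a", "b", "c")))
  d$y <- rnorm(nrow(d)) + (d$cond == "c") * 1.5
  ph <- posthoc_pairwise(d, y, cond, id)
  expect_equal(nrow(ph), 3L)
  expect_equal(ph$p.adjusted, pmin(1, ph$p.value * 3))
  expect_true(all(ph$p.adjusted >= ph$p.value))
})
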