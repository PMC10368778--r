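#' Repeated-measures ANOVA
#'
#' Within-subject F tests computed via the classical univariate
#' decomposition (`stats::aov()` with `Error()` strata), reporting the
#' uncorrected degrees of freedom by default, with partial eta squared
#' \eqn{\eta_p^2 = F \cdot df_1 / (F \cdot df_1 + df_2)} per effect.
#' With `gg = TRUE`, Greenhouse–Geisser epsilon is estimated per effect
#' from orthonormal within-subject contrasts and the degrees of freedom
#' and p-value are adjusted. Designs must be complete and balanced
#' (every participant observed once in every cell); missing cells are
#' an error, not imputed. With two conditions, the one-way F equals the
#' square of the paired t statistic.
#'
#' @param data A long-format data frame.
#' @param value,participant Bare column names of the response and the
#'   subject identifier.
#' @param condition (one-way) bare column name of the within-subject
#'   factor.
#' @param factor_a,factor_b (two-way) bare column names of the two
#'   within-subject factors.
#' @param gg Apply the Greenhouse–Geisser sphericity correction.
#' @return A tibble of class `rm_anova`, one row per effect:
#'   `effect`, `df1`, `df2`, `statistic` (F), `p.value`, `pes`
#'   (partial eta squared), and `gg_epsilon` when `gg = TRUE`.
#' @examples
#' d <- tidyr::expand_grid(id = factor(1:8), cond = c("pre", "post"))
#' d$y <- rnorm(nrow(d)) + (d$cond == "post") * 0.5
#' rm_anova_oneway(d, y, cond, id)
#' @export
rm_anova_oneway <- function(data, value, condition, participant,
                            gg = FALSE) {
  d <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    cond = factor(dplyr::pull(data, {{ condition }})),
    id = factor(dplyr::pull(data, {{ participant }}))
  )
  check_complete(d, "cond")
  fit <- aov(y ~ cond + Error(id / cond), data = d)
  row <- extract_effect(fit, "cond", ss_scale = sum(d$y^2) + 1)
  out <- tibble::tibble(effect = "condition", !!!row)
  if (gg) {
    Y <- cell_matrix(d, "cond")
    eps <- gg_epsilon(Y, effect_contrast(nlevels(d$cond)))
    out <- apply_gg(out, eps)
  }
  new_rm_anova(out)
}

#' @rdname rm_anova_oneway
#' @export
rm_anova_twoway <- function(data, value, factor_a, factor_b,
                            participant, gg = FALSE) {
  d <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    A = factor(dplyr::pull(data, {{ factor_a }})),
    B = factor(dplyr::pull(data, {{ factor_b }})),
    id = factor(dplyr::pull(data, {{ participant }}))
  )
  check_complete(d, c("A", "B"))
  fit <- aov(y ~ A * B + Error(id / (A * B)), data = d)
  ss_scale <- sum(d$y^2) + 1
  out <- dplyr::bind_rows(
    tibble::tibble(effect = "A", !!!extract_effect(fit, "A", ss_scale)),
    tibble::tibble(effect = "B", !!!extract_effect(fit, "B", ss_scale)),
    tibble::tibble(effect = "A:B",
                   !!!extract_effect(fit, "A:B", ss_scale))
  )
  if (gg) {
    a <- nlevels(d$A)
    b <- nlevels(d$B)
    Y <- cell_matrix(d, c("A", "B"))
    ca <- effect_contrast(a)
    cb <- effect_contrast(b)
    ones <- function(m) matrix(1 / sqrt(m), m, 1)
    eps <- c(
      gg_epsilon(Y, kronecker(ca, ones(b))),
      gg_epsilon(Y, kronecker(ones(a), cb)),
      gg_epsilon(Y, kronecker(ca, cb))
    )
    out <- apply_gg(out, eps)
  }
  new_rm_anova(out)
}

new_rm_anova <- function(x) {
  class(x) <- c("rm_anova", class(x))
  x
}

#' @export
tidy.rm_anova <- function(x, ...) tibble::as_tibble(unclass(x))

check_complete <- function(d, factors) {
  counts <- table(d[c("id", factors)])
  if (any(counts == 0L)) {
    abort("Incomplete design: every participant must be observed in every cell (no imputation).")
  }
  if (any(counts > 1L)) {
    abort("More than one observation per participant and cell; aggregate first.")
  }
}

# participants x cells response matrix, cells ordered by the factors
cell_matrix <- function(d, factors) {
  d <- d[do.call(order, d[c("id", factors)]), ]
  k <- prod(vapply(d[factors], nlevels, 0L))
  matrix(d$y, ncol = k, byrow = TRUE)
}

# orthonormal contrast matrix (m x m-1), columns orthogonal to the unit
effect_contrast <- function(m) {
  qr.Q(qr(cbind(1, stats::contr.helmert(m))))[, -1, drop = FALSE]
}

# Greenhouse-Geisser epsilon from the covariance of the contrasted cells
gg_epsilon <- function(Y, M) {
  A <- t(M) %*% stats::cov(Y) %*% M
  df <- ncol(M)
  (sum(diag(A)))^2 / (df * sum(A^2))
}

apply_gg <- function(out, eps) {
  out$gg_epsilon <- eps
  out$df1 <- out$df1 * eps
  out$df2 <- out$df2 * eps
  out$p.value <- stats::pf(out$statistic, out$df1, out$df2,
                           lower.tail = FALSE)
  out
}

# pull one effect's F test out of a summary.aovlist
extract_effect <- function(fit, term, ss_scale) {
  smry <- summary(fit)
  for (stratum in smry) {
    tab <- stratum[[1]]
    rows <- trimws(rownames(tab))
    i <- match(term, rows)
    if (!is.na(i) && "F value" %in% colnames(tab)) {
      df1 <- tab[i, "Df"]
      df2 <- tab[nrow(tab), "Df"] # Residuals row of the same stratum
      f <- tab[i, "F value"]
      p <- tab[i, "Pr(>F)"]
      # a zero effect sum of squares is F = 0 by convention, guarding
      # against 0/0 floating noise in degenerate (constant) data
      if (!is.finite(f) || tab[i, "Sum Sq"] <= 1e-12 * ss_scale) {
        f <- 0
        p <- 1
      }
      return(list(
        df1 = df1, df2 = df2, statistic = f, p.value = p,
        pes = (f * df1) / (f * df1 + df2)
      ))
    }
  }
  abort(sprintf("Effect '%s' not found in the ANOVA decomposition.", term))
}

#' Welch two-sample t-test with effect size
#'
#' Unequal-variance (Welch) t-test with Satterthwaite fractional
#' degrees of freedom, two-sided p-value, the 95% confidence interval
#' of the mean difference and Cohen's d (pooled-SD standardiser). When
#' both samples have zero variance and equal means the statistic is 0
#' and p is 1 by convention.
#'
#' @param x,y Numeric samples, each with at least 2 values.
#' @param conf_level Confidence level of the interval.
#' @return A one-row tibble: `mean_diff`, `statistic` (T), `df`,
#'   `p.value`, `cohens_d`, `conf.low`, `conf.high`.
#' @export
ttest_two_sample <- function(x, y, conf_level = 0.95) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  stopifnot(length(x) >= 2L, length(y) >= 2L)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(tibble::tibble(
        mean_diff = 0, statistic = 0,
        df = length(x) + length(y) - 2, p.value = 1, cohens_d = 0,
        conf.low = 0, conf.high = 0
      ))
    }
    abort("Both samples are constant with different means; the Welch statistic is undefined.")
  }
  tt <- stats::t.test(x, y, var.equal = FALSE, conf.level = conf_level)
  sp <- sqrt(((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
               (length(x) + length(y) - 2))
  tibble::tibble(
    mean_diff = mean(x) - mean(y),
    statistic = unname(tt$statistic),
    df = unname(tt$parameter),
    p.value = tt$p.value,
    cohens_d = (mean(x) - mean(y)) / sp,
    conf.low = tt$conf.int[1],
    conf.high = tt$conf.int[2]
  )
}

#' Remove extreme trials by the 3-SD rule
#'
#' A single-pass outlier rule: within each group, values at least
#' `k` standard deviations from the group mean are removed. Group mean
#' and SD are estimated once, before any removal, so the rule is
#' idempotent.
#'
#' @param data A data frame.
#' @param value Bare column name of the value screened.
#' @param group Character vector of grouping columns (`NULL` = one
#'   group).
#' @param k SD multiple (default 3; the comparison is inclusive,
#'   `>= k` SD is removed).
#' @return The filtered tibble, with attribute `n_removed` (also via
#'   [n_removed()]).
#' @export
remove_outliers_3sd <- function(data, value, group = NULL, k = 3) {
  data <- tibble::as_tibble(data)
  v <- rlang::as_name(rlang::enquo(value))
  grouped <- if (is.null(group)) data else
    dplyr::group_by(data, dplyr::across(dplyr::all_of(group)))
  out <- grouped |>
    dplyr::mutate(
      .z = abs(.data[[v]] - mean(.data[[v]], na.rm = TRUE)) /
        sd(.data[[v]], na.rm = TRUE)
    ) |>
    dplyr::ungroup() |>
    dplyr::filter(is.na(.data$.z) | .data$.z < k) |>
    dplyr::select(-".z")
  attr(out, "n_removed") <- nrow(data) - nrow(out)
  out
}

#' @rdname remove_outliers_3sd
#' @export
n_removed <- function(data) attr(data, "n_removed") %||% 0L

#' Bonferroni-corrected pairwise paired comparisons
#'
#' Post-hoc paired t-tests between all level pairs of a within-subject
#' factor, with Bonferroni correction:
#' \eqn{p_{adj} = \min(1, m \cdot p)} over the \eqn{m} comparisons.
#'
#' @inheritParams rm_anova_oneway
#' @return A tibble with one row per level pair: `level_1`, `level_2`,
#'   `mean_diff`, `statistic`, `df`, `p.value`, `p.adjusted`.
#' @export
posthoc_pairwise <- function(data, value, condition, participant) {
  d <- tibble::tibble(
    y = dplyr::pull(data, {{ value }}),
    cond = factor(dplyr::pull(data, {{ condition }})),
    id = factor(dplyr::pull(data, {{ participant }}))
  )
  check_complete(d, "cond")
  lv <- levels(d$cond)
  pairs <- utils::combn(lv, 2L)
  wide <- split(d[order(d$id), ], d$cond[order(d$id)])
  res <- purrr::map_dfr(seq_len(ncol(pairs)), function(i) {
    a <- wide[[pairs[1, i]]]$y
    b <- wide[[pairs[2, i]]]$y
    tt <- stats::t.test(a, b, paired = TRUE)
    tibble::tibble(
      level_1 = pairs[1, i], level_2 = pairs[2, i],
      mean_diff = mean(a - b),
      statistic = unname(tt$statistic), df = unname(tt$parameter),
      p.value = tt$p.value
    )
  })
  res$p.adjusted <- stats::p.adjust(res$p.value, method = "bonferroni")
  res
}
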