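#' Plot per-trial melodic scores
#'
#' Individual trial scores as jittered dots with the mean and standard
#' error of the mean per condition.
#'
#' @param scores Output of [score_melodic()].
#' @param x Bare column name for the x-axis grouping (default
#'   `condition`).
#' @return A ggplot object.
#' @export
plot_melodic_scores <- function(scores, x = condition) {
  plot_scores_(scores, rlang::enquo(x), "melodic_ratio",
               "Levenshtein ratio (1 = errorless)")
}

#' Plot per-trial rhythm scores
#'
#' Eligible trials' percentage deviance, dots plus mean and SEM per
#' condition; 0 is perfectly proportional timing.
#'
#' @param scores Output of [score_rhythm()].
#' @inheritParams plot_melodic_scores
#' @return A ggplot object.
#' @export
plot_rhythm_scores <- function(scores, x = condition) {
  scores <- dplyr::filter(scores, !is.na(.data$rhythm_deviance_pct))
  plot_scores_(scores, rlang::enquo(x), "rhythm_deviance_pct",
               "Rhythm deviance (% of expected note duration)")
}

plot_scores_ <- function(scores, xq, yvar, ylab) {
  ggplot2::ggplot(scores, ggplot2::aes(x = factor(!!xq),
                                       y = .data[[yvar]])) +
    ggplot2::geom_jitter(width = 0.12, alpha = 0.45, size = 1.2) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se,
                          geom = "pointrange", colour = "black",
                          shape = 4, size = 0.6, linewidth = 0.8) +
    ggplot2::labs(x = NULL, y = ylab) +
    ggplot2::theme_minimal()
}

#' Plot post-error slowing
#'
#' Per-participant mean inter-press intervals before and after the
#' altered-feedback target key, joined by participant.
#'
#' @param summary Output of [post_error_slowing_summary()].
#' @return A ggplot object.
#' @export
plot_slowing <- function(summary) {
  long <- summary |>
    tidyr::pivot_longer(
      c("mean_before_ms", "mean_after_ms"),
      names_to = "window", values_to = "ioi_ms"
    ) |>
    dplyr::mutate(window = factor(
      ifelse(.data$window == "mean_before_ms", "before", "after"),
      levels = c("before", "after")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$window, y = .data$ioi_ms)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       alpha = 0.35) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se,
                          geom = "pointrange", colour = "black",
                          shape = 4, size = 0.6, linewidth = 0.8) +
    ggplot2::labs(x = "window relative to altered-feedback key",
                  y = "mean inter-press interval (ms)") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.latency_fit <- function(object, samples = NULL, ...) {
  dens <- function(x) {
    rowSums(vapply(
      seq_along(object$means_ms),
      function(j) object$weights[j] *
        stats::dnorm(x, object$means_ms[j], object$sds_ms[j]),
      numeric(length(x))
    ))
  }
  lo <- min(object$means_ms) - 4 * max(object$sds_ms)
  hi <- max(object$means_ms) + 4 * max(object$sds_ms)
  grid <- tibble::tibble(x = seq(lo, hi, length.out = 400))
  grid$density <- dens(grid$x)
  p <- ggplot2::ggplot(grid, ggplot2::aes(x = .data$x,
                                          y = .data$density))
  if (!is.null(samples)) {
    p <- p + ggplot2::geom_histogram(
      data = tibble::tibble(s = samples),
      ggplot2::aes(x = .data$s, y = ggplot2::after_stat(density)),
      inherit.aes = FALSE, bins = 60, fill = "grey80"
    )
  }
  p + ggplot2::geom_line(colour = "firebrick", linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = object$bound_ms,
                        linetype = "dashed") +
    ggplot2::labs(x = "latency (ms)", y = "density") +
    ggplot2::theme_minimal()
}
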