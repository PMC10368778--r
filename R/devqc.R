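#' Fit a Gaussian mixture to latency samples by EM
#'
#' Maximum-likelihood fit of a k-component univariate Gaussian mixture
#' by expectation-maximisation, used to characterise the key-to-sound
#' latency distribution of the instrument (two components in practice).
#' Several restarts from perturbed initialisations are run and the best
#' log-likelihood kept; the log-likelihood is checked to be
#' non-decreasing at every iteration. Components are reported in
#' ascending order of their means.
#'
#' @param samples Numeric latency samples (ms); at least `10 * k`.
#' @param k Number of components.
#' @param max_iter Maximum EM iterations per restart.
#' @param tol Convergence tolerance on the relative log-likelihood
#'   change.
#' @param n_restarts Number of random restarts (the first is a
#'   quantile-based initialisation).
#' @param seed Integer seed for the restart draws; `NULL` uses the
#'   current RNG state.
#' @param bound_ms Latency bound used to report the fraction of samples
#'   within specification (default 25 ms, inclusive).
#' @return An object of class `latency_fit`: `means_ms`, `sds_ms`,
#'   `weights`, `loglik`, `converged`, `n_iter`,
#'   `fraction_within_bound`, `bound_ms`, `n`.
#' @examples
#' x <- simulate_latencies(2000, seed = 1)
#' fit <- fit_latency_mixture(x, seed = 1)
#' tidy(fit)
#' @export
fit_latency_mixture <- function(samples, k = 2L, max_iter = 500L,
                                tol = 1e-8, n_restarts = 5L,
                                seed = NULL, bound_ms = 25) {
  samples <- as.numeric(samples)
  stopifnot(!anyNA(samples), k >= 1L)
  if (length(samples) < 10L * k) {
    abort(sprintf("Need at least %d samples to fit %d components.",
                  10L * k, k))
  }
  if (!is.null(seed)) set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- em_init(samples, k, quantile_based = (r == 1L))
    fit <- em_run(samples, init, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  if (!best$converged) {
    warn("EM did not converge within `max_iter`; best fit returned.")
  }
  ord <- order(best$means)
  structure(
    list(
      means_ms = best$means[ord], sds_ms = best$sds[ord],
      weights = best$weights[ord], loglik = best$loglik,
      converged = best$converged, n_iter = best$n_iter,
      fraction_within_bound = exceedance_fraction(samples, bound_ms),
      bound_ms = bound_ms, n = length(samples)
    ),
    class = "latency_fit"
  )
}

em_init <- function(x, k, quantile_based = TRUE) {
  if (quantile_based) {
    means <- as.numeric(
      stats::quantile(x, probs = (seq_len(k) - 0.5) / k)
    )
  } else {
    means <- sample(x, k) + rnorm(k, 0, sd(x) / 10)
  }
  list(means = means, sds = rep(max(sd(x) / k, 1e-3), k),
       weights = rep(1 / k, k))
}

em_run <- function(x, init, max_iter, tol) {
  n <- length(x)
  k <- length(init$means)
  means <- init$means
  sds <- init$sds
  weights <- init$weights
  loglik <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    # E step: responsibilities via log-sum-exp
    logd <- vapply(
      seq_len(k),
      function(j) stats::dnorm(x, means[j], sds[j], log = TRUE) +
        log(weights[j]),
      numeric(n)
    )
    m <- apply(logd, 1, max)
    lse <- m + log(rowSums(exp(logd - m)))
    new_loglik <- sum(lse)
    if (new_loglik < loglik - 1e-6 * (abs(loglik) + 1)) {
      abort("EM log-likelihood decreased; this is a bug.")
    }
    resp <- exp(logd - lse)
    # M step
    nk <- colSums(resp)
    weights <- nk / n
    means <- colSums(resp * x) / nk
    sds <- sqrt(colSums(resp * (outer(x, means, "-")^2)) / nk)
    sds <- pmax(sds, 1e-6)
    if (is.finite(loglik) &&
        (new_loglik - loglik) < tol * (abs(loglik) + 1)) {
      loglik <- new_loglik
      converged <- TRUE
      break
    }
    loglik <- new_loglik
  }
  list(means = means, sds = sds, weights = weights, loglik = loglik,
       converged = converged, n_iter = iter)
}

#' @export
print.latency_fit <- function(x, ...) {
  cat(sprintf("<latency_fit> %d components, n = %d%s\n",
              length(x$means_ms), x$n,
              if (x$converged) "" else " (not converged)"))
  for (j in seq_along(x$means_ms)) {
    cat(sprintf("  mean %.2f ms, sd %.2f ms, weight %.3f\n",
                x$means_ms[j], x$sds_ms[j], x$weights[j]))
  }
  cat(sprintf("  %.3f%% of samples within %g ms\n",
              100 * x$fraction_within_bound, x$bound_ms))
  invisible(x)
}

#' @export
tidy.latency_fit <- function(x, ...) {
  tibble::tibble(
    component = seq_along(x$means_ms),
    mean_ms = x$means_ms, sd_ms = x$sds_ms, weight = x$weights
  )
}

#' @export
glance.latency_fit <- function(x, ...) {
  tibble::tibble(
    loglik = x$loglik, converged = x$converged, n_iter = x$n_iter,
    fraction_within_bound = x$fraction_within_bound,
    bound_ms = x$bound_ms, n = x$n
  )
}

#' Fraction of latency samples within a bound
#'
#' @param samples Numeric latency samples (ms).
#' @param bound_ms Inclusive upper bound (default 25 ms, the maximum
#'   acceptable key-to-sound latency).
#' @return Fraction of samples `<= bound_ms`, in `[0, 1]`.
#' @export
exceedance_fraction <- function(samples, bound_ms = 25) {
  if (length(samples) == 0L) abort("No samples.")
  mean(samples <= bound_ms)
}

#' Motion exclusion by framewise displacement
#'
#' A participant's run is excluded for excessive head motion when
#' `max_volumes` or more volumes exceed the framewise-displacement
#' threshold (one voxel dimension, 2.5 mm, by default). The FD
#' comparison is strict (`>`); the volume-count comparison is
#' inclusive (`>=`).
#'
#' @param fd_series Non-negative FD values in mm, one per volume.
#' @param threshold_mm FD threshold (default 2.5).
#' @param max_volumes Minimum number of suprathreshold volumes that
#'   triggers exclusion (default 10).
#' @return A one-row tibble: `n_volumes`, `n_exceeding`,
#'   `threshold_mm`, `excluded`.
#' @export
motion_exclusion <- function(fd_series, threshold_mm = 2.5,
                             max_volumes = 10L) {
  fd_series <- as.numeric(fd_series)
  if (anyNA(fd_series) || any(fd_series < 0)) {
    abort("FD values must be non-negative and non-missing.")
  }
  n_exceeding <- sum(fd_series > threshold_mm)
  tibble::tibble(
    n_volumes = length(fd_series), n_exceeding = n_exceeding,
    threshold_mm = threshold_mm,
    excluded = n_exceeding >= max_volumes
  )
}

sample_skewness <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  mean((x - m)^3) / m2^1.5
}

sample_kurtosis_raw <- function(x) {
  m <- mean(x)
  mean((x - m)^4) / mean((x - m)^2)^2
}

#' Distributional robustness check for repeated-measures ANOVA
#'
#' The F test tolerates moderate non-normality; a common rule accepts
#' data whose skewness does not exceed 2.31 in magnitude and whose
#' kurtosis does not exceed 8. Skewness and kurtosis are computed from
#' raw moments; kurtosis is reported both raw (`m4/m2^2`, bound 8
#' applied here) and as excess (raw minus 3), since published values
#' use either convention.
#'
#' @param values Numeric vector, at least 4 values.
#' @param skew_bound,kurtosis_bound The robustness limits (defaults
#'   2.31 and 8).
#' @return A one-row tibble: `skewness`, `kurtosis` (raw),
#'   `kurtosis_excess`, `within_bounds`.
#' @export
robustness_check <- function(values, skew_bound = 2.31,
                             kurtosis_bound = 8) {
  values <- values[!is.na(values)]
  if (length(values) < 4L) abort("Need at least 4 values.")
  sk <- sample_skewness(values)
  ku <- sample_kurtosis_raw(values)
  tibble::tibble(
    skewness = sk, kurtosis = ku, kurtosis_excess = ku - 3,
    within_bounds = within_robustness_bounds(sk, ku, skew_bound,
                                             kurtosis_bound)
  )
}

#' @rdname robustness_check
#' @param skewness,kurtosis Already-computed shape statistics to check
#'   against the bounds.
#' @export
within_robustness_bounds <- function(skewness, kurtosis,
                                     skew_bound = 2.31,
                                     kurtosis_bound = 8) {
  abs(skewness) <= skew_bound & kurtosis <= kurtosis_bound
}
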