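#' Collapse a performance to chord-group onsets
#'
#' Rhythm is scored on note onsets, so simultaneously played notes must
#' count once: only the first keypress of each chord group (simultaneity
#' window, see [group_simultaneous()]) is kept.
#'
#' @inheritParams group_simultaneous
#' @return A numeric vector of onset times in milliseconds, one per
#'   chord group.
#' @export
collapse_to_onsets <- function(events, threshold_ms = 30,
                               anchor = c("group", "previous")) {
  anchor <- match.arg(anchor)
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0L) return(numeric())
  grouped <- group_simultaneous(events, threshold_ms, anchor)
  as.numeric(tapply(grouped$press_ms, grouped$chord_group, min))
}

#' Rhythm-score eligibility
#'
#' The proportion-deviance score compares each keystroke with its
#' expected counterpart one-to-one, so a trial is eligible only when the
#' number of performed onset groups equals the number of template
#' groups (both chord-collapsed). Extra or missing notes make the
#' pairing undefined.
#'
#' @param onsets Numeric vector of performed onsets
#'   (see [collapse_to_onsets()]).
#' @param template The errorless [key_template()].
#' @return `TRUE` or `FALSE`.
#' @export
check_eligibility <- function(onsets, template) {
  stopifnot(inherits(template, "key_template"))
  length(onsets) == nrow(template$groups)
}

#' Proportion-deviance rhythm score
#'
#' Performed and expected onsets are both rescaled to proportions of
#' their own total span, anchored at the first onset:
#' \eqn{q_i = (t_i - t_1)/(t_n - t_1)} and
#' \eqn{p_i = (e_i - e_1)/(e_n - e_1)}. For each interior note
#' (\eqn{i = 2, \ldots, n-1}) the absolute proportion error is related
#' to the expected interval preceding that note:
#' \deqn{d_i = \frac{|q_i - p_i|}{p_i - p_{i-1}}}
#' and the score is \eqn{100 \times} the mean of the \eqn{d_i}: the
#' percentage deviance of each keystroke relative to the expected timing
#' and note duration. 0 means timing proportional to the template; the
#' construction makes the score invariant to tempo (scale) and start
#' time (shift). The first and last onsets are pinned to 0 and 1 on
#' both sides, so only interior notes are scored.
#'
#' @param onsets Performed onsets, strictly increasing, same length as
#'   `expected_onsets`.
#' @param expected_onsets Template onsets, strictly increasing.
#' @param denominator Which expected interval normalises note *i*'s
#'   error: the one `"preceding"` it (default) or the one
#'   `"succeeding"` it.
#' @return An object of class `rhythm_score`: a list with `eligible`,
#'   `n_onsets`, `per_note_deviance` (interior notes) and
#'   `mean_deviance_pct` (`NA` when fewer than 3 onsets).
#' @examples
#' # four isochronous expected notes: proportions 0, 1/3, 2/3, 1
#' rhythm_deviance(c(0, 400, 667, 1000) / 1, c(0, 1, 2, 3))
#' @export
rhythm_deviance <- function(onsets, expected_onsets,
                            denominator = c("preceding", "succeeding")) {
  denominator <- match.arg(denominator)
  n <- length(onsets)
  if (length(expected_onsets) != n) {
    abort("`onsets` and `expected_onsets` must have equal length.")
  }
  if (anyNA(expected_onsets) || any(diff(expected_onsets) <= 0)) {
    abort("`expected_onsets` must be strictly increasing.")
  }
  if (n < 3L) {
    return(new_rhythm_score(eligible = n >= 1L, n_onsets = n,
                            per_note_deviance = numeric(),
                            mean_deviance_pct = NA_real_))
  }
  if (anyNA(onsets) || any(diff(onsets) < 0)) {
    abort("`onsets` must be non-decreasing with no missing values.")
  }
  q <- (onsets - onsets[1]) / (onsets[n] - onsets[1])
  p <- (expected_onsets - expected_onsets[1]) /
    (expected_onsets[n] - expected_onsets[1])
  interior <- 2:(n - 1L)
  width <- switch(denominator,
    preceding  = p[interior] - p[interior - 1L],
    succeeding = p[interior + 1L] - p[interior]
  )
  dev <- abs(q[interior] - p[interior]) / width
  new_rhythm_score(eligible = TRUE, n_onsets = n,
                   per_note_deviance = dev,
                   mean_deviance_pct = 100 * mean(dev))
}

new_rhythm_score <- function(eligible, n_onsets, per_note_deviance,
                             mean_deviance_pct) {
  structure(
    list(eligible = eligible, n_onsets = n_onsets,
         per_note_deviance = per_note_deviance,
         mean_deviance_pct = mean_deviance_pct),
    class = "rhythm_score"
  )
}

#' @export
print.rhythm_score <- function(x, ...) {
  if (!x$eligible || is.na(x$mean_deviance_pct)) {
    cat(sprintf("<rhythm_score> ineligible (%d onsets)\n", x$n_onsets))
  } else {
    cat(sprintf("<rhythm_score> %d onsets, mean deviance %.2f%%\n",
                x$n_onsets, x$mean_deviance_pct))
  }
  invisible(x)
}

#' @export
tidy.rhythm_score <- function(x, ...) {
  tibble::tibble(
    note = if (length(x$per_note_deviance)) 2:(x$n_onsets - 1L)
           else integer(),
    deviance = x$per_note_deviance
  )
}

#' @export
glance.rhythm_score <- function(x, ...) {
  tibble::tibble(eligible = x$eligible, n_onsets = x$n_onsets,
                 mean_deviance_pct = x$mean_deviance_pct)
}

#' Rhythmic accuracy of logged performances against a template
#'
#' Per trial: drop incomplete events, collapse chords to onsets, check
#' eligibility (onset-group count must equal the template's group
#' count), then compute the proportion-deviance score
#' ([rhythm_deviance()]). Ineligible trials keep `eligible = FALSE` and
#' a missing score.
#'
#' @inheritParams score_melodic
#' @inheritParams rhythm_deviance
#' @return A tibble with one row per trial: identifiers, `eligible`,
#'   `n_onsets`, `rhythm_deviance_pct` and `n_events_dropped`.
#' @export
score_rhythm <- function(log, template, threshold_ms = 30,
                         denominator = c("preceding", "succeeding"),
                         anchor = c("group", "previous")) {
  denominator <- match.arg(denominator)
  anchor <- match.arg(anchor)
  expected <- template_onsets(template)
  log |>
    dplyr::group_by(.data$participant, .data$task, .data$trial,
                    .data$condition) |>
    dplyr::group_modify(function(ev, key) {
      ev <- drop_incomplete_events(ev)
      onsets <- collapse_to_onsets(ev, threshold_ms, anchor)
      eligible <- check_eligibility(onsets, template)
      score <- if (eligible && length(onsets) >= 3L) {
        rhythm_deviance(onsets, expected, denominator)$mean_deviance_pct
      } else {
        NA_real_
      }
      tibble::tibble(
        eligible = eligible, n_onsets = length(onsets),
        rhythm_deviance_pct = score,
        n_events_dropped = n_dropped(ev)
      )
    }) |>
    dplyr::ungroup()
}
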