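major_steps <- c(2L, 2L, 1L, 2L, 2L, 2L, 1L)
natural_minor_steps <- c(2L, 1L, 2L, 2L, 1L, 2L, 2L)

#' Build an ascending-then-descending scale template
#'
#' A heptatonic scale played up from the tonic to the octave and back
#' down: 8 ascending notes, then 8 descending notes with the octave
#' struck again at the turnaround, 16 single-note groups in total. Minor
#' scales use the natural minor step pattern (2-1-2-2-1-2-2 semitones);
#' major scales use 2-2-1-2-2-2-1. Expected onsets are isochronous.
#'
#' @param tonic_key_index Key index of the tonic (0-based within the
#'   keymap register); the octave (`tonic_key_index + 12`) must also lie
#'   within the keymap.
#' @param mode `"major"` or `"natural_minor"`.
#' @param keymap Keymap the scale must fit in.
#' @param ioi Expected inter-onset interval, in the template's arbitrary
#'   time units (default 1).
#' @param turnaround `"double"` (default; the octave is pressed at the
#'   end of the ascent and again at the start of the descent, giving 16
#'   presses) or `"single"` (one press at the top, 15).
#' @return A [key_template()] of single-note groups.
#' @examples
#' tpl <- build_scale_template(0, "major")
#' encode_template(tpl, build_default_keymap(), separated = FALSE)
#' # "ACEFHJLMMLJHFECA"
#' @export
build_scale_template <- function(tonic_key_index,
                                 mode = c("major", "natural_minor"),
                                 keymap = build_default_keymap(), ioi = 1,
                                 turnaround = c("double", "single")) {
  mode <- match.arg(mode)
  turnaround <- match.arg(turnaround)
  tonic_key_index <- as.integer(tonic_key_index)
  if (tonic_key_index < 0L ||
      tonic_key_index + 12L > keymap_size(keymap) - 1L) {
    abort(sprintf(
      "Scale octave (keys %d-%d) outside the %d-key register.",
      tonic_key_index, tonic_key_index + 12L, keymap_size(keymap)
    ))
  }
  steps <- switch(mode, major = major_steps,
                  natural_minor = natural_minor_steps)
  ascent <- tonic_key_index + cumsum(c(0L, steps))
  keys <- switch(turnaround,
    double = c(ascent, rev(ascent)),
    single = c(ascent, rev(ascent)[-1])
  )
  key_template(
    tibble::tibble(keys = as.list(keys),
                   onset = (seq_along(keys) - 1) * ioi),
    template_id = sprintf("scale_%d_%s", tonic_key_index, mode),
    register_start_index = attr(keymap, "register_start_index")
  )
}

#' Inter-press intervals around an altered-feedback target key
#'
#' For one trial, averages the three consecutive inter-onset intervals
#' ending at the target onset ("before") and the three following it
#' ("after"). With the default `window = "into-target"`, the interval
#' that completes at the target press counts as "before" — it is over
#' before the altered sound is heard; `window = "strict-pre"` instead
#' uses the three intervals that end strictly before the target press.
#'
#' @param events Keypress events of one trial (complete press times).
#' @param target_position 1-based ordinal of the target keypress in the
#'   chord-collapsed onset sequence; must leave 3 intervals on each side.
#' @param window `"into-target"` or `"strict-pre"` (see above).
#' @inheritParams group_simultaneous
#' @return A one-row tibble: `mean_before_ms`, `mean_after_ms`,
#'   `delta_ms = mean_after_ms - mean_before_ms`.
#' @export
post_error_intervals <- function(events, target_position,
                                 window = c("into-target", "strict-pre"),
                                 threshold_ms = 30) {
  window <- match.arg(window)
  onsets <- collapse_to_onsets(events, threshold_ms)
  k <- as.integer(target_position)
  need_before <- if (window == "into-target") 3L else 4L
  if (k - need_before < 1L) {
    abort(sprintf(
      "target_position %d leaves fewer than 3 'before' intervals.", k
    ))
  }
  if (k + 3L > length(onsets)) {
    abort(sprintf(
      "target_position %d leaves fewer than 3 'after' intervals (%d onsets).",
      k, length(onsets)
    ))
  }
  ioi <- diff(onsets) # ioi[i] = interval from onset i to i+1
  before_idx <- if (window == "into-target") (k - 3L):(k - 1L)
                else (k - 4L):(k - 2L)
  mean_before <- mean(ioi[before_idx])
  mean_after <- mean(ioi[k:(k + 2L)])
  tibble::tibble(
    mean_before_ms = mean_before,
    mean_after_ms = mean_after,
    delta_ms = mean_after - mean_before
  )
}

#' Post-error slowing across an altered-feedback session
#'
#' `aaf_slowing()` applies [post_error_intervals()] to every altered
#' trial listed in the manifest (only the first altered key of a trial
#' is analysed; standard-feedback trials carry no target).
#' `post_error_slowing_summary()` averages the before/after means per
#' participant, the unit of analysis for the one-way repeated-measures
#' ANOVA ([rm_anova_oneway()]).
#'
#' @param log Multi-trial keypress-event tibble.
#' @param manifest Trial manifest: columns `participant`, `trial`,
#'   `target_position`, `alteration_semitones`, `feedback`
#'   (`"standard"` or `"altered"`).
#' @inheritParams post_error_intervals
#' @return `aaf_slowing()`: one row per altered trial with the
#'   before/after means and `delta_ms`. `post_error_slowing_summary()`:
#'   one row per participant with `mean_before_ms`, `mean_after_ms`,
#'   `delta_ms` and `n_trials`.
#' @export
aaf_slowing <- function(log, manifest,
                        window = c("into-target", "strict-pre"),
                        threshold_ms = 30) {
  window <- match.arg(window)
  altered <- manifest |>
    dplyr::filter(.data$feedback == "altered") |>
    dplyr::select("participant", "trial", "target_position",
                  "alteration_semitones")
  log |>
    dplyr::inner_join(altered, by = c("participant", "trial")) |>
    dplyr::group_by(.data$participant, .data$trial,
                    .data$target_position,
                    .data$alteration_semitones) |>
    dplyr::group_modify(function(ev, key) {
      post_error_intervals(drop_incomplete_events(ev),
                           key$target_position, window, threshold_ms)
    }) |>
    dplyr::ungroup()
}

#' @rdname aaf_slowing
#' @param trial_results Output of `aaf_slowing()`.
#' @export
post_error_slowing_summary <- function(trial_results) {
  trial_results |>
    dplyr::group_by(.data$participant) |>
    dplyr::summarise(
      mean_before_ms = mean(.data$mean_before_ms),
      mean_after_ms = mean(.data$mean_after_ms),
      delta_ms = mean(.data$delta_ms),
      n_trials = dplyr::n(),
      .groups = "drop"
    )
}
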