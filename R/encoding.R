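#' Group near-simultaneous keypresses into chords
#'
#' Keypresses whose onsets fall within the simultaneity window are treated
#' as a single chord. An event joins the current group when its press time
#' is strictly less than `threshold_ms` after the group's reference time;
#' otherwise it opens a new group. With `anchor = "group"` (default) the
#' reference is the group's first event, which bounds a chord's total
#' spread by the window; `anchor = "previous"` chains consecutive pairs
#' instead, so slow arpeggiated runs can merge into one group.
#'
#' @param events Keypress events for a single performance, sorted by
#'   `press_ms`, none missing.
#' @param threshold_ms Simultaneity window in milliseconds (default 30;
#'   the comparison is strict, so a 30 ms gap starts a new group).
#' @param anchor `"group"` or `"previous"` (see above).
#' @return `events` with an integer `chord_group` column (1-based,
#'   contiguous, non-decreasing).
#' @export
group_simultaneous <- function(events, threshold_ms = 30,
                               anchor = c("group", "previous")) {
  anchor <- match.arg(anchor)
  events <- tibble::as_tibble(events)
  t <- events$press_ms
  if (anyNA(t)) {
    abort("Events with missing press_ms cannot be grouped; drop them first.")
  }
  if (is.unsorted(t)) abort("Events must be sorted by press_ms.")
  events$chord_group <- assign_chord_groups(t, threshold_ms, anchor)
  events
}

assign_chord_groups <- function(t, threshold_ms, anchor = "group") {
  n <- length(t)
  if (n == 0L) return(integer())
  g <- integer(n)
  g[1] <- 1L
  ref <- t[1]
  for (i in seq_len(n)[-1]) {
    if (t[i] - ref < threshold_ms) {
      g[i] <- g[i - 1L]
    } else {
      g[i] <- g[i - 1L] + 1L
      ref <- t[i]
    }
    if (anchor == "previous") ref <- t[i]
  }
  g
}

# sort single characters by code point (locale-independent)
sort_chars <- function(chars) chars[order(vapply(chars, utf8ToInt, 0L))]

#' Encode a performance as a character string
#'
#' Each keypress becomes one character via the keymap; keypresses grouped
#' by the simultaneity window form one token, sorted in ascending
#' character order so that chord spelling does not depend on within-chord
#' press order. With `separated = TRUE` tokens are joined by single
#' spaces, distinguishing a chord ("MQT") from a run of single notes
#' ("M Q T"); monophonic material is conventionally encoded without
#' separators.
#'
#' @inheritParams group_simultaneous
#' @param keymap A [build_default_keymap()]-style keymap covering every
#'   `key_index` present.
#' @param separated Join chord tokens with spaces (`TRUE`) or concatenate
#'   (`FALSE`).
#' @return A single character string (empty for an empty event list).
#' @examples
#' km <- build_default_keymap()
#' ev <- tibble::tibble(key_index = c(12L, 16L, 19L),
#'                      press_ms = c(0, 5, 10))
#' encode_performance(ev, km) # "MQT": a C-major triad
#' @export
encode_performance <- function(events, keymap, threshold_ms = 30,
                               separated = TRUE,
                               anchor = c("group", "previous")) {
  anchor <- match.arg(anchor)
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0L) return("")
  events <- group_simultaneous(events, threshold_ms, anchor)
  chars <- map_keys(events$key_index, keymap)
  tokens <- vapply(
    split(chars, events$chord_group),
    function(ch) paste(sort_chars(ch), collapse = ""),
    ""
  )
  paste(tokens, collapse = if (separated) " " else "")
}

#' @describeIn encode_performance Encode an errorless template with the
#'   same rules (each template group is one token).
#' @param template A [key_template()].
#' @export
encode_template <- function(template, keymap, separated = TRUE) {
  stopifnot(inherits(template, "key_template"))
  tokens <- vapply(template$groups$keys, function(k) {
    paste(sort_chars(map_keys(k, keymap)), collapse = "")
  }, "")
  paste(tokens, collapse = if (separated) " " else "")
}

#' Encode every trial in a keypress log
#'
#' @param log A multi-trial keypress-event tibble (see
#'   [read_keypress_log()]); incomplete events are dropped per trial
#'   before encoding.
#' @inheritParams encode_performance
#' @return A tibble with one row per (participant, task, trial):
#'   identifiers, `encoding`, `n_events` and `n_events_dropped`.
#' @export
encode_log <- function(log, keymap, threshold_ms = 30, separated = TRUE,
                       anchor = c("group", "previous")) {
  anchor <- match.arg(anchor)
  log |>
    dplyr::group_by(.data$participant, .data$task, .data$trial,
                    .data$condition) |>
    dplyr::group_modify(function(ev, key) {
      ev <- drop_incomplete_events(ev)
      tibble::tibble(
        encoding = encode_performance(ev, keymap, threshold_ms,
                                      separated, anchor),
        n_events = nrow(ev),
        n_events_dropped = n_dropped(ev)
      )
    }) |>
    dplyr::ungroup()
}
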