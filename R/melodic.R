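#' Levenshtein distance and ratio
#'
#' `levenshtein_distance()` computes the minimal number of
#' single-character insertions, deletions (omissions) and substitutions
#' transforming one string into the other, each edit costing 1 (the
#' dynamic programme is implemented in C). `levenshtein_ratio()` turns
#' the distance into the similarity score used for melodic accuracy:
#'
#' \deqn{ratio = 1 - \frac{L_{distance}}{L_{sum}}}
#'
#' where \eqn{L_{sum}} is the sum of the lengths of the two strings.
#' Identical non-empty strings score 1 (perfect similarity); a string
#' against an empty string scores 0. The ratio of two empty strings is
#' undefined and raises an error.
#'
#' @param a,b Character vectors (recycled to a common length). Strings
#'   are compared byte-wise; the encoding alphabets are single-byte.
#' @param substitution_cost Cost of a substitution: 1 (default, the
#'   plain edit distance matching the published formula) or 2, which
#'   prices a substitution as one insertion plus one deletion — the
#'   convention of classic library `ratio()` functions, provided for
#'   sensitivity analysis.
#' @return An integer (distance) or numeric (ratio) vector.
#' @examples
#' levenshtein_distance("MOQR", "MOQT") # 1
#' levenshtein_ratio("MOQR", "MOQT")    # 1 - 1/8 = 0.875
#' @export
levenshtein_distance <- function(a, b, substitution_cost = 1L) {
  stopifnot(substitution_cost %in% c(1L, 2L))
  lev_distance_cpp(as.character(a), as.character(b),
                   as.integer(substitution_cost))
}

#' @rdname levenshtein_distance
#' @export
levenshtein_ratio <- function(a, b, substitution_cost = 1L) {
  a <- as.character(a)
  b <- as.character(b)
  n <- max(length(a), length(b))
  len_sum <- nchar(rep_len(a, n), type = "bytes") +
    nchar(rep_len(b, n), type = "bytes")
  if (any(len_sum == 0, na.rm = TRUE)) {
    abort("levenshtein_ratio() is undefined for two empty strings.")
  }
  d <- levenshtein_distance(a, b, substitution_cost)
  pmin(1, pmax(0, 1 - d / len_sum))
}

#' Melodic accuracy of logged performances against a template
#'
#' Encodes the template and every trial of the log with identical
#' settings (keymap, simultaneity window, separator convention) and
#' scores each trial with the Levenshtein ratio. Space-separated
#' encoding is the convention for polyphonic material, where the
#' separator distinguishes chords from runs; monophonic material (e.g.
#' scales) is encoded with `separated = FALSE`. Both sides carry the
#' same convention, so at a perfect match the separators cancel.
#'
#' @param log A keypress-event tibble covering one or more trials.
#' @param template The errorless [key_template()].
#' @inheritParams encode_performance
#' @inheritParams levenshtein_distance
#' @return A tibble with one row per trial: identifiers, `encoding`,
#'   `distance`, `len_sum`, `melodic_ratio` and `n_events_dropped`.
#' @export
score_melodic <- function(log, template, keymap = build_default_keymap(),
                          threshold_ms = 30, separated = TRUE,
                          substitution_cost = 1L,
                          anchor = c("group", "previous")) {
  anchor <- match.arg(anchor)
  ref <- encode_template(template, keymap, separated)
  if (!nzchar(ref)) abort("Template encodes to an empty string.")
  encode_log(log, keymap, threshold_ms, separated, anchor) |>
    dplyr::mutate(
      distance = levenshtein_distance(.data$encoding, ref,
                                      substitution_cost),
      len_sum = nchar(.data$encoding, type = "bytes") +
        nchar(ref, type = "bytes"),
      melodic_ratio = pmin(1, pmax(0, 1 - .data$distance / .data$len_sum))
    )
}
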