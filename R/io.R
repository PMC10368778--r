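log_columns <- c("participant", "task", "trial", "condition",
                 "key_index", "press_ms", "release_ms", "velocity")

#' Read a keypress log
#'
#' Reads a tab-separated keypress log with header columns `participant`,
#' `task`, `trial`, `condition`, `key_index`, `press_ms`, `release_ms`,
#' `velocity`. Empty fields are missing values. Events with a missing
#' press or release time are retained on read (so the dropped fraction
#' can be reported later by [drop_incomplete_events()]) and flagged in
#' the `incomplete` column. Within each trial, events are ordered by
#' press time; ties keep input order, then ascending key index; events
#' with no press time sort last within their trial.
#'
#' @param path Path to the TSV log.
#' @param keymap_size Number of keys on the instrument; rows whose
#'   `key_index` falls outside `[0, keymap_size - 1]` are an error.
#' @return A tibble with one row per keypress event, columns as above
#'   plus `incomplete` (logical).
#' @seealso [write_keypress_log()], [drop_incomplete_events()]
#' @export
read_keypress_log <- function(path, keymap_size = 25L) {
  if (!file.exists(path)) abort(sprintf("No such file: '%s'", path))
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0L) abort("Empty keypress log (no header).")
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(header, log_columns)) {
    unknown <- setdiff(header, log_columns)
    if (length(unknown)) {
      abort(sprintf("Unknown column(s) in log header: %s.",
                    paste(unknown, collapse = ", ")))
    }
    abort(sprintf("Log header must be exactly: %s.",
                  paste(log_columns, collapse = ", ")))
  }
  body <- lines[-1]
  body <- body[nzchar(body)]
  fields <- strsplit(body, "\t", fixed = TRUE)
  # strsplit drops trailing empty fields; pad (missing velocity etc.)
  n_fields <- lengths(fields)
  fields <- lapply(fields, function(f) c(f, rep("", 8L - length(f))))
  if (any(n_fields > 8L)) {
    abort(sprintf("Malformed row at line %d: %d fields (expected 8).",
                  which(n_fields > 8L)[1] + 1L, max(n_fields)))
  }
  mat <- do.call(rbind, c(fields, list(matrix(character(), 0, 8))))
  num <- function(j) suppressWarnings(as.numeric(ifelse(mat[, j] == "",
                                                        NA, mat[, j])))
  events <- tibble::tibble(
    participant = mat[, 1], task = mat[, 2], trial = mat[, 3],
    condition = mat[, 4],
    key_index = num(5), press_ms = num(6), release_ms = num(7),
    velocity = num(8)
  )
  bad_num <- (mat[, 5] != "" & is.na(events$key_index)) |
    (mat[, 6] != "" & is.na(events$press_ms)) |
    (mat[, 7] != "" & is.na(events$release_ms)) |
    (mat[, 8] != "" & is.na(events$velocity))
  if (any(bad_num)) {
    abort(sprintf("Malformed numeric field at line %d.",
                  which(bad_num)[1] + 1L))
  }
  if (anyNA(events$key_index)) {
    abort(sprintf("Missing key_index at line %d.",
                  which(is.na(events$key_index))[1] + 1L))
  }
  events$key_index <- as.integer(events$key_index)
  out_of_range <- events$key_index < 0L | events$key_index >= keymap_size
  if (any(out_of_range)) {
    abort(sprintf(
      "key_index out of range [0, %d] at line %d (value %d).",
      keymap_size - 1L, which(out_of_range)[1] + 1L,
      events$key_index[which(out_of_range)[1]]
    ))
  }
  neg <- !is.na(events$press_ms) & events$press_ms < 0
  if (any(neg)) {
    abort(sprintf("Negative press_ms at line %d.", which(neg)[1] + 1L))
  }
  inverted <- !is.na(events$press_ms) & !is.na(events$release_ms) &
    events$release_ms < events$press_ms
  if (any(inverted)) {
    abort(sprintf("release_ms earlier than press_ms at line %d.",
                  which(inverted)[1] + 1L))
  }
  events$incomplete <- is.na(events$press_ms) | is.na(events$release_ms)
  events$.row <- seq_len(nrow(events))
  events <- events |>
    dplyr::arrange(
      .data$participant, .data$task, .data$trial,
      is.na(.data$press_ms), .data$press_ms, .data$.row, .data$key_index
    ) |>
    dplyr::select(-".row")
  events
}

#' @rdname read_keypress_log
#' @param events A keypress-event tibble as returned by
#'   `read_keypress_log()` (or [simulate_performance()]).
#' @export
write_keypress_log <- function(events, path) {
  events <- tibble::as_tibble(events)
  stopifnot(all(log_columns %in% names(events)))
  fmt <- function(x) ifelse(is.na(x), "", format(x, trim = TRUE,
                                                 scientific = FALSE))
  out <- vapply(seq_len(nrow(events)), function(i) {
    paste(
      events$participant[i], events$task[i], events$trial[i],
      events$condition[i], fmt(events$key_index[i]),
      fmt(events$press_ms[i]), fmt(events$release_ms[i]),
      fmt(events$velocity[i]),
      sep = "\t"
    )
  }, "")
  writeLines(c(paste(log_columns, collapse = "\t"), out), path,
             useBytes = TRUE)
  invisible(path)
}

#' Remove events with missing press or release times
#'
#' Events lacking a press or a release timestamp carry no usable timing
#' and are removed before scoring; the number removed is kept so the
#' dropped fraction can be reported. Ordering of the remaining events is
#' preserved.
#'
#' @param events A keypress-event tibble.
#' @return The filtered tibble, with attribute `n_dropped` giving the
#'   number of removed events (also available via [n_dropped()]).
#' @export
drop_incomplete_events <- function(events) {
  events <- tibble::as_tibble(events)
  keep <- !is.na(events$press_ms) & !is.na(events$release_ms)
  out <- events[keep, , drop = FALSE]
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' @rdname drop_incomplete_events
#' @export
n_dropped <- function(events) {
  attr(events, "n_dropped") %||% 0L
}

#' Read and write score tables
#'
#' One row per scored trial, tab-separated, with empty fields for missing
#' scores (e.g. the rhythm deviance of an ineligible trial).
#'
#' @param scores A tibble of per-trial scores.
#' @param path File path.
#' @export
write_score_table <- function(scores, path) {
  scores <- tibble::as_tibble(scores)
  mat <- vapply(scores, function(col) {
    ifelse(is.na(col), "", format(col, trim = TRUE, scientific = FALSE))
  }, character(nrow(scores)))
  mat <- matrix(mat, nrow = nrow(scores))
  writeLines(
    c(paste(names(scores), collapse = "\t"),
      apply(mat, 1, paste, collapse = "\t")),
    path, useBytes = TRUE
  )
  invisible(path)
}

#' @rdname write_score_table
#' @export
read_score_table <- function(path) {
  df <- utils::read.delim(path, na.strings = "", check.names = FALSE,
                          colClasses = NA, stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}

#' Read plain-text numeric series
#'
#' `read_latency_samples()` reads latency measurements (one millisecond
#' value per line); `read_fd_series()` reads a framewise-displacement
#' series (one value in mm per fMRI volume), as found in the
#' `framewise_displacement` column of standard confounds tables.
#'
#' @param path File path.
#' @return A numeric vector.
#' @export
read_latency_samples <- function(path) {
  x <- scan(path, what = numeric(), quiet = TRUE)
  if (length(x) == 0L) abort("No latency samples found.")
  x
}

#' @rdname read_latency_samples
#' @export
read_fd_series <- function(path) {
  x <- scan(path, what = character(), quiet = TRUE)
  x <- suppressWarnings(as.numeric(ifelse(x %in% c("n/a", "NA"), NA, x)))
  x[!is.na(x)]
}
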