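# Small in-code fixtures shared across test files.

# events tibble shorthand
make_events <- function(key_index, press_ms,
                        release_ms = press_ms + 200,
                        participant = "P01", task = "task1",
                        trial = "T001", condition = "right") {
  tibble::tibble(
    participant = participant, task = task, trial = trial,
    condition = condition, key_index = as.integer(key_index),
    press_ms = press_ms, release_ms = release_ms,
    velocity = 64, incomplete = is.na(press_ms) | is.na(release_ms)
  )
}

# three single-note groups C4, D4, E4 one unit apart
simple_template <- function() {
  key_template(
    tibble::tibble(keys = list(12L, 14L, 16L), onset = c(0, 1, 2)),
    template_id = "simple"
  )
}

# polyphonic: single note, triad, dyad, single note
poly_template <- function() {
  key_template(
    tibble::tibble(
      keys = list(12L, c(12L, 16L, 19L), c(14L, 17L), 24L),
      onset = c(0, 1, 2, 3)
    ),
    template_id = "poly"
  )
}

write_log_file <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

log_header <- paste(
  c("participant", "task", "trial", "condition", "key_index",
    "press_ms", "release_ms", "velocity"),
  collapse = "\t"
)
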