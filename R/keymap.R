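#' Key-to-character maps
#'
#' A keymap assigns one printable, non-space character to each key of the
#' instrument, in ascending chromatic order, so that a performance can be
#' written down as a character string and compared to an errorless template
#' by edit distance. The default map covers a 25-key C3--C5 register with
#' the capital letters A--Y (key 0 = C3 = "A", key 12 = C4 = "M",
#' key 24 = C5 = "Y"). The extended map appends the remaining capitals,
#' small letters, digits and twelve punctuation marks, enough for all 74
#' keys of a six-octave piano.
#'
#' @param n_keys Number of keys to map (extended map only), at most 74.
#' @param register_start_index Key index of the first mapped key on the
#'   physical instrument (defaults to 0: the map is indexed from the lowest
#'   mapped key).
#'
#' @return An object of class `keymap`: a character vector with one entry
#'   per key (names are the key indices as strings) and attribute
#'   `register_start_index`.
#'
#' @examples
#' km <- build_default_keymap()
#' unname(km[c("0", "12", "24")]) # "A" "M" "Y"
#' build_extended_keymap(74)
#' @export
build_default_keymap <- function(register_start_index = 0L) {
  new_keymap(LETTERS[1:25], register_start_index)
}

# canonical extended alphabet: capitals, smalls, digits, then the printed
# punctuation sequence with typographic spaces removed
extended_alphabet <- function() {
  c(LETTERS, letters, as.character(0:9),
    strsplit(".,?!+-=/*@#$", "", fixed = TRUE)[[1]])
}

#' @rdname build_default_keymap
#' @export
build_extended_keymap <- function(n_keys, register_start_index = 0L) {
  stopifnot(is.numeric(n_keys), length(n_keys) == 1L)
  alphabet <- extended_alphabet()
  if (n_keys < 1 || n_keys > length(alphabet)) {
    abort(sprintf(
      "`n_keys` must be between 1 and %d (alphabet exhausted), got %s.",
      length(alphabet), format(n_keys)
    ))
  }
  new_keymap(alphabet[seq_len(n_keys)], register_start_index)
}

new_keymap <- function(characters, register_start_index = 0L) {
  stopifnot(
    is.character(characters),
    all(nchar(characters) == 1L),
    !anyDuplicated(characters),
    !any(characters == " ")
  )
  structure(
    setNames(characters, seq_along(characters) - 1L),
    register_start_index = as.integer(register_start_index),
    class = "keymap"
  )
}

#' @export
print.keymap <- function(x, ...) {
  cat(sprintf(
    "<keymap> %d keys (register start index %d)\n",
    length(x), attr(x, "register_start_index")
  ))
  cat(" ", paste0(unclass(x), collapse = ""), "\n")
  invisible(x)
}

#' @export
`[.keymap` <- function(x, i, ...) unclass(x)[i]

keymap_size <- function(keymap) length(unclass(keymap))

# map integer key indices (0-based) to characters; errors on unmapped keys
map_keys <- function(key_index, keymap) {
  stopifnot(inherits(keymap, "keymap"))
  chars <- unclass(keymap)[key_index + 1L]
  if (anyNA(chars) || any(key_index < 0L)) {
    bad <- unique(key_index[key_index < 0L | key_index >= keymap_size(keymap)])
    abort(sprintf(
      "key_index value(s) %s not covered by the %d-key keymap.",
      paste(bad, collapse = ", "), keymap_size(keymap)
    ))
  }
  chars
}
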