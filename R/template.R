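#' Errorless performance templates
#'
#' A template is the errorless reference a performance is scored against:
#' an ordered sequence of note groups, each holding one or more key indices
#' (a single note or a chord) and an expected onset time. Onsets are in
#' arbitrary but consistent units — only their proportions matter for
#' rhythm scoring, and melodic scoring ignores them entirely.
#'
#' @param groups A data frame with one row per group and columns `keys`
#'   (a list column of integer key indices) and `onset` (numeric, strictly
#'   increasing across groups).
#' @param template_id Label for the template.
#' @param register_start_index Key index offset of the instrument register.
#'
#' @return An object of class `key_template`: a list with fields
#'   `template_id`, `register_start_index`, `groups` (tibble) and
#'   `n_expected_keypresses`.
#'
#' @examples
#' tpl <- key_template(
#'   tibble::tibble(keys = list(12L, c(12L, 16L), 19L), onset = c(0, 1, 2))
#' )
#' tpl$n_expected_keypresses
#' @export
key_template <- function(groups, template_id = "template",
                         register_start_index = 0L) {
  groups <- tibble::as_tibble(groups)
  stopifnot(all(c("keys", "onset") %in% names(groups)))
  groups$keys <- lapply(groups$keys, function(k) as.integer(k))
  groups$onset <- as.numeric(groups$onset)
  if (nrow(groups) == 0L) {
    abort("A template must contain at least one group.")
  }
  sizes <- lengths(groups$keys)
  if (any(sizes == 0L)) {
    abort("Template groups must be non-empty.")
  }
  dup <- vapply(groups$keys, anyDuplicated, 0L) > 0L
  if (any(dup)) {
    abort(sprintf(
      "Duplicate key index within template group(s) %s.",
      paste(which(dup), collapse = ", ")
    ))
  }
  if (anyNA(groups$onset) || any(diff(groups$onset) <= 0)) {
    abort("Template onsets must be strictly increasing.")
  }
  structure(
    list(
      template_id = as.character(template_id),
      register_start_index = as.integer(register_start_index),
      groups = groups[c("keys", "onset")],
      n_expected_keypresses = sum(sizes)
    ),
    class = "key_template"
  )
}

#' @export
print.key_template <- function(x, ...) {
  cat(sprintf(
    "<key_template> '%s': %d groups, %d expected keypresses\n",
    x$template_id, nrow(x$groups), x$n_expected_keypresses
  ))
  invisible(x)
}

#' @describeIn key_template Expected onset times, one per group.
#' @param template A `key_template`.
#' @export
template_onsets <- function(template) {
  stopifnot(inherits(template, "key_template"))
  template$groups$onset
}

#' Read and write templates as JSON
#'
#' The on-disk form is a JSON object with fields `template_id`,
#' `register_start_index` and `groups`, the latter an array of
#' `{"keys": [...], "onset": ...}` objects. Writing then reading
#' reproduces all fields.
#'
#' @param path File path.
#' @param template A [key_template()].
#' @return `read_template()` returns a `key_template`;
#'   `write_template()` returns `path` invisibly.
#' @export
read_template <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                            simplifyVector = FALSE)
  if (!all(c("template_id", "groups") %in% names(obj))) {
    abort("Template JSON must contain 'template_id' and 'groups'.")
  }
  groups <- tibble::tibble(
    keys = lapply(obj$groups, function(g) as.integer(unlist(g$keys))),
    onset = vapply(obj$groups, function(g) as.numeric(g$onset), 0)
  )
  key_template(
    groups,
    template_id = obj$template_id,
    register_start_index = obj$register_start_index %||% 0L
  )
}

#' @rdname read_template
#' @export
write_template <- function(template, path) {
  stopifnot(inherits(template, "key_template"))
  obj <- list(
    template_id = template$template_id,
    register_start_index = template$register_start_index,
    groups = purrr::map2(
      template$groups$keys, template$groups$onset,
      function(k, o) list(keys = as.list(k), onset = o)
    )
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
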