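km <- build_default_keymap()

test_that("simultaneity grouping uses a strict 30 ms window on the group anchor", {
  g <- function(t, ...) {
    keyscore:::assign_chord_groups(t, threshold_ms = 30, ...)
  }
  expect_equal(g(c(0, 29)), c(1L, 1L))       # under the window: one chord
  expect_equal(g(c(0, 30)), c(1L, 2L))       # boundary is exclusive
  expect_equal(g(c(0, 20, 40)), c(1L, 1L, 2L)) # anchored at first event
  # pairwise chaining merges the same run into one group
  expect_equal(g(c(0, 20, 40), anchor = "previous"), c(1L, 1L, 1L))
  expect_equal(g(numeric()), integer())
})

test_that("grouping is a partition preserving order and total count", {
  set.seed(71)
  for (i in 1:25) {
    t <- sort(runif(sample(1:40, 1), 0, 2000))
    g <- keyscore:::assign_chord_groups(t, 30)
    expect_length(g, length(t))
    expect_true(all(diff(g) %in% c(0L, 1L))) # contiguous, non-decreasing
  }
})

test_that("raising the window never increases the number of groups", {
  set.seed(72)
  for (i in 1:20) {
    t <- sort(runif(30, 0, 1500))
    n_groups <- vapply(
      c(5, 15, 30, 60, 120),
      function(th) max(keyscore:::assign_chord_groups(t, th)),
      0L
    )
    expect_true(all(diff(n_groups) <= 0L))
  }
})

test_that("performances encode to sorted chord tokens", {
  # C4+E4+G4 within the window: one chord, alphabetical
  chord <- make_events(c(19L, 12L, 16L), c(0, 5, 10))
  expect_identical(encode_performance(chord, km), "MQT")
  # sequential single notes, space-separated
  run <- make_events(c(12L, 14L, 16L), c(0, 500, 1000))
  expect_identical(encode_performance(run, km), "M O Q")
  # C-major ascent, no separators
  ascent <- make_events(c(12L, 14L, 16L, 17L, 19L, 21L, 23L, 24L),
                        seq(0, by = 400, length.out = 8))
  expect_identical(encode_performance(ascent, km, separated = FALSE),
                   "MOQRTVXY")
  expect_identical(encode_performance(make_events(integer(), numeric()),
                                      km), "")
})

test_that("encoding is invariant to within-chord input order", {
  set.seed(73)
  for (i in 1:10) {
    keys <- sample(0:24, 4)
    perm <- sample(4)
    a <- make_events(keys, c(0, 3, 6, 9))
    b <- make_events(keys[perm], c(0, 3, 6, 9))
    expect_identical(encode_performance(a, km),
                     encode_performance(b, km))
  }
})

test_that("separated encodings have clean tokens and conserve event count", {
  set.seed(74)
  for (i in 1:10) {
    n <- sample(3:30, 1)
    ev <- make_events(sample(0:24, n, replace = TRUE),
                      sort(runif(n, 0, 3000)))
    enc <- encode_performance(ev, km)
    expect_false(grepl("^ | $|  ", enc))
    expect_equal(nchar(gsub(" ", "", enc)), n)
    # token characters ascend
    for (tok in strsplit(enc, " ")[[1]]) {
      ch <- strsplit(tok, "")[[1]]
      expect_identical(ch, ch[order(vapply(ch, utf8ToInt, 0L))])
    }
  }
})

test_that("templates encode with the same rules as performances", {
  tpl <- poly_template()
  expect_identical(encode_template(tpl, km), "M MQT OR Y")
  expect_identical(encode_template(tpl, km, separated = FALSE),
                   "MMQTORY")
  single <- simple_template()
  expect_identical(encode_template(single, km), "M O Q")
  # dyad {C4, E4} sorts to "MQ"
  dyad <- key_template(tibble::tibble(keys = list(c(16L, 12L)),
                                      onset = 0))
  expect_identical(encode_template(dyad, km), "MQ")
})

test_that("encoding errors on unmapped keys and unsorted input", {
  ev <- make_events(40L, 0)
  expect_error(encode_performance(ev, km), "not covered")
  unsorted <- make_events(c(12L, 14L), c(500, 0))
  expect_error(group_simultaneous(unsorted), "sorted")
})

test_that("encode_log scores each trial independently", {
  log <- dplyr::bind_rows(
    make_events(c(12L, 14L), c(0, 400), trial = "T001"),
    make_events(c(12L, 16L), c(0, 5), trial = "T002")
  )
  out <- encode_log(log, km)
  expect_equal(nrow(out), 2L)
  expect_setequal(out$encoding, c("M O", "MQ"))
})
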