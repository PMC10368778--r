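test_that("edit distance matches the recursive definition on short strings", {
  strings <- all_strings(c("M", "O", "Q", "R"), 3)
  pairs <- expand.grid(a = strings, b = strings,
                       stringsAsFactors = FALSE)
  expected <- mapply(lev_recursive, pairs$a, pairs$b)
  expect_equal(levenshtein_distance(pairs$a, pairs$b),
               unname(expected))
})

test_that("edit distance agrees with an independent implementation at length 5", {
  set.seed(41)
  a <- replicate(400, paste(sample(c("A", "M", "Q", "Y"), sample(0:5, 1),
                                   replace = TRUE), collapse = ""))
  b <- replicate(400, paste(sample(c("A", "M", "Q", "Y"), sample(0:5, 1),
                                   replace = TRUE), collapse = ""))
  expect_equal(levenshtein_distance(a, b),
               as.integer(diag(utils::adist(a, b))))
})

test_that("distance anchors: identity, pure deletion, single substitution", {
  expect_equal(levenshtein_distance("M O Q", "M O Q"), 0L)
  expect_equal(levenshtein_distance("MOQ", ""), 3L)
  expect_equal(levenshtein_distance("MOQR", "MOQT"), 1L)
})

test_that("distance is a metric on random short strings", {
  set.seed(42)
  rs <- function() paste(sample(LETTERS[1:6], sample(0:6, 1),
                                replace = TRUE), collapse = "")
  for (i in 1:60) {
    a <- rs(); b <- rs(); c <- rs()
    dab <- levenshtein_distance(a, b)
    expect_gte(dab, 0L)
    expect_identical(dab == 0L, a == b)
    expect_equal(dab, levenshtein_distance(b, a))
    expect_lte(dab,
               levenshtein_distance(a, c) + levenshtein_distance(c, b))
    expect_lte(dab, max(nchar(a), nchar(b)))
  }
})

test_that("ratio implements 1 - distance/length-sum with its edge cases", {
  expect_equal(levenshtein_ratio("MOQ", "MOQ"), 1)
  expect_equal(levenshtein_ratio("MOQ", ""), 0)
  expect_equal(levenshtein_ratio("MOQR", "MOQT"), 0.875)
  expect_error(levenshtein_ratio("", ""), "undefined")
  set.seed(43)
  for (i in 1:30) {
    a <- paste(sample(LETTERS[1:5], sample(1:8, 1), replace = TRUE),
               collapse = "")
    expect_equal(levenshtein_ratio(a, a), 1)
    expect_equal(levenshtein_ratio(a, ""), 0)
  }
})

test_that("substitution-cost-2 compatibility mode prices substitutions as indel pairs", {
  expect_equal(levenshtein_distance("MOQR", "MOQT",
                                    substitution_cost = 2L), 2L)
  # equals deletion+insertion, so never exceeds twice the unit distance
  set.seed(44)
  for (i in 1:30) {
    a <- paste(sample(LETTERS[1:4], sample(0:6, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(LETTERS[1:4], sample(0:6, 1), replace = TRUE),
               collapse = "")
    d1 <- levenshtein_distance(a, b)
    d2 <- levenshtein_distance(a, b, substitution_cost = 2L)
    expect_gte(d2, d1)
    expect_lte(d2, 2L * d1)
  }
})

test_that("score_melodic compares template and trials under one convention", {
  km <- build_default_keymap()
  tpl <- simple_template() # encodes to "M O Q"
  exact <- make_events(c(12L, 14L, 16L), c(0, 500, 1000))
  wrong_last <- make_events(c(12L, 14L, 19L), c(0, 500, 1000))
  log <- dplyr::bind_rows(
    dplyr::mutate(exact, trial = "T001"),
    dplyr::mutate(wrong_last, trial = "T002")
  )
  scores <- score_melodic(log, tpl, km)
  expect_equal(scores$melodic_ratio[scores$trial == "T001"], 1)
  # "M O Q" vs "M O T": distance 1, length sum 10
  expect_equal(scores$melodic_ratio[scores$trial == "T002"], 0.9)
  expect_equal(scores$len_sum[scores$trial == "T002"], 10L)

  empty <- make_events(integer(), numeric())
  s0 <- score_melodic(empty, tpl, km)
  expect_equal(s0$melodic_ratio, 0) # empty performance scores 0
})

test_that("incomplete events are dropped and counted before scoring", {
  km <- build_default_keymap()
  tpl <- simple_template()
  ev <- make_events(c(12L, 14L, 16L, 19L), c(0, 500, 1000, 1500))
  ev$release_ms[4] <- NA
  ev$incomplete[4] <- TRUE
  s <- score_melodic(ev, tpl, km)
  expect_equal(s$n_events_dropped, 1L)
  expect_equal(s$melodic_ratio, 1) # the flagged event never reaches scoring
})
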