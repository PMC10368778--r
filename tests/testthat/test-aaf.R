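test_that("scale templates have 16 presses and a palindromic key sequence", {
  km <- build_default_keymap()
  specs <- keyscore:::study_scales()
  for (i in seq_len(nrow(specs))) {
    tpl <- build_scale_template(specs$tonic_key_index[i], specs$mode[i])
    keys <- unlist(tpl$groups$keys)
    expect_length(keys, 16L)
    expect_equal(tpl$n_expected_keypresses, 16L)
    expect_identical(keys, rev(keys)) # up then down mirrors itself
    expect_equal(keys[1], specs$tonic_key_index[i])
    expect_equal(max(keys), specs$tonic_key_index[i] + 12L)
    expect_equal(diff(template_onsets(tpl)),
                 rep(1, 15)) # isochronous
  }
})

test_that("scale step patterns follow major and natural-minor intervals", {
  c_major <- build_scale_template(0, "major")
  expect_identical(
    encode_template(c_major, build_default_keymap(), separated = FALSE),
    "ACEFHJLMMLJHFECA"
  )
  ascent_steps <- function(tpl) diff(unlist(tpl$groups$keys)[1:8])
  expect_equal(ascent_steps(c_major), c(2, 2, 1, 2, 2, 2, 1))
  a_minor <- build_scale_template(9, "natural_minor")
  expect_equal(ascent_steps(a_minor), c(2, 1, 2, 2, 1, 2, 2))
})

test_that("scales that overrun the register are rejected; single turnaround drops one press", {
  expect_error(build_scale_template(14, "major"), "outside")
  expect_error(build_scale_template(13, "major"), "outside")
  tpl15 <- build_scale_template(0, "major", turnaround = "single")
  expect_equal(tpl15$n_expected_keypresses, 15L)
})

test_that("post-error intervals average three IOIs on each side", {
  iso <- make_events(rep(12L, 12), seq(0, by = 500, length.out = 12))
  res <- post_error_intervals(iso, target_position = 6)
  expect_equal(res$mean_before_ms, 500)
  expect_equal(res$mean_after_ms, 500)
  expect_equal(res$delta_ms, 0)

  # +50 ms on each of the three post-target intervals
  t <- seq(0, by = 500, length.out = 12)
  k <- 6
  t <- t + 50 * pmin(pmax(seq_along(t) - k, 0), 3)
  slowed <- make_events(rep(12L, 12), t)
  res2 <- post_error_intervals(slowed, target_position = k)
  expect_equal(res2$delta_ms, 50)
  expect_equal(res2$mean_before_ms, 500)
  expect_equal(res2$mean_after_ms, 550)
})

test_that("windows and bounds behave at the edges", {
  iso <- make_events(rep(12L, 10), seq(0, by = 400, length.out = 10))
  expect_error(post_error_intervals(iso, target_position = 3),
               "before")
  expect_error(post_error_intervals(iso, target_position = 9),
               "after")
  # strict-pre window needs one more preceding onset
  expect_error(post_error_intervals(iso, 4, window = "strict-pre"),
               "before")
  ok <- post_error_intervals(iso, 5, window = "strict-pre")
  expect_equal(ok$delta_ms, 0)
})

test_that("delta is invariant to a global time shift", {
  set.seed(61)
  t <- cumsum(c(0, runif(11, 300, 700)))
  ev <- make_events(rep(12L, 12), t)
  shifted <- make_events(rep(12L, 12), t + 12345)
  a <- post_error_intervals(ev, 6)
  b <- post_error_intervals(shifted, 6)
  expect_equal(a$delta_ms, b$delta_ms)
  expect_equal(a$mean_before_ms, b$mean_before_ms)
})

test_that("aaf_slowing analyses altered trials and summarises per participant", {
  cohort <- simulate_aaf_cohort(
    n_participants = 4, trials_per_participant = 6,
    slowing_delta_ms = 50,
    config = sim_config(onset_jitter_sd_ms = 0), seed = 11
  )
  res <- aaf_slowing(cohort$log, cohort$manifest)
  expect_equal(nrow(res),
               sum(cohort$manifest$feedback == "altered"))
  expect_equal(res$delta_ms, rep(50, nrow(res)))

  smry <- post_error_slowing_summary(res)
  expect_equal(nrow(smry), 4L)
  expect_equal(smry$delta_ms, rep(50, 4))
  expect_equal(smry$n_trials, rep(3L, 4)) # half of 6 trials altered
  # one trial per participant: summary equals the trial values
  one <- post_error_slowing_summary(res[!duplicated(res$participant), ])
  expect_equal(one$mean_before_ms,
               res$mean_before_ms[!duplicated(res$participant)])
})
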