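#' Simulation configuration
#'
#' Collects the error and timing processes of the synthetic-performance
#' generator. Rates apply per expected keypress (substitution, omission)
#' or per gap between consecutive note groups (insertion). Defaults
#' describe an accurate, professionally played performance: no errors,
#' 20 ms Gaussian onset jitter, 5 ms chord asynchrony, 500 ms base
#' inter-onset interval.
#'
#' @param substitution_rate,omission_rate,insertion_rate Error
#'   probabilities in `[0, 1)`; `substitution_rate + omission_rate`
#'   must stay below 1.
#' @param onset_jitter_sd_ms SD of i.i.d. Gaussian onset jitter (ms).
#' @param chord_asynchrony_sd_ms SD of within-chord member offsets (ms);
#'   offsets are folded positive and capped below the 30 ms simultaneity
#'   window so chords stay intact.
#' @param base_ioi_ms Target mean inter-onset interval (ms) the template
#'   onsets are rescaled to.
#' @param slowing_delta_ms Post-target slowing (ms per interval) added
#'   to altered trials by [simulate_aaf_cohort()].
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(substitution_rate = 0, omission_rate = 0,
                       insertion_rate = 0, onset_jitter_sd_ms = 20,
                       chord_asynchrony_sd_ms = 5, base_ioi_ms = 500,
                       slowing_delta_ms = 0) {
  stopifnot(
    substitution_rate >= 0, substitution_rate < 1,
    omission_rate >= 0, omission_rate <= 1,
    insertion_rate >= 0, insertion_rate < 1,
    substitution_rate + omission_rate <= 1,
    onset_jitter_sd_ms >= 0, chord_asynchrony_sd_ms >= 0,
    base_ioi_ms > 0
  )
  structure(
    list(
      substitution_rate = substitution_rate,
      omission_rate = omission_rate,
      insertion_rate = insertion_rate,
      onset_jitter_sd_ms = onset_jitter_sd_ms,
      chord_asynchrony_sd_ms = chord_asynchrony_sd_ms,
      base_ioi_ms = base_ioi_ms,
      slowing_delta_ms = slowing_delta_ms
    ),
    class = "sim_config"
  )
}

# neighbouring key within [0, n_keys-1], +/- 1 or 2 semitones, uniform
# over the admissible offsets (mimics pianistic slips and mirrors the
# altered-feedback magnitudes)
substitute_key <- function(key, n_keys) {
  offsets <- c(-2L, -1L, 1L, 2L)
  ok <- key + offsets >= 0L & key + offsets <= n_keys - 1L
  key + sample(offsets[ok], 1L)
}

#' Simulate a performance of a template
#'
#' Generates one trial's keypress events conditioned on an errorless
#' template. Template onsets are rescaled so the mean inter-group
#' interval equals `base_ioi_ms`, then each expected keypress is
#' independently omitted, substituted by a neighbouring key (1 or 2
#' semitones away, within the register), or played as written; extra
#' keypresses are inserted between note groups; group onsets receive
#' i.i.d. Gaussian jitter and chord members a small positive
#' asynchrony offset. Identical `config` + `seed` give identical
#' output.
#'
#' @param template A [key_template()].
#' @param config A [sim_config()].
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @param n_keys Size of the simulated instrument register.
#' @param participant,task,trial,condition Identifier columns of the
#'   returned log.
#' @return A keypress-event tibble (columns as in
#'   [read_keypress_log()]), sorted by press time.
#' @export
simulate_performance <- function(template, config = sim_config(),
                                 seed = NULL, n_keys = 25L,
                                 participant = "sim", task = "task1",
                                 trial = "t1", condition = "standard") {
  stopifnot(inherits(template, "key_template"))
  if (!is.null(seed)) set.seed(seed)
  e <- template$groups$onset
  n_groups <- length(e)
  scale_ms <- if (n_groups > 1L) config$base_ioi_ms / mean(diff(e)) else 1
  group_t <- (e - e[1]) * scale_ms +
    rnorm(n_groups, 0, config$onset_jitter_sd_ms)

  key <- integer(0)
  press <- numeric(0)
  for (g in seq_len(n_groups)) {
    members <- template$groups$keys[[g]]
    off <- c(0, pmin(abs(rnorm(length(members) - 1L, 0,
                                config$chord_asynchrony_sd_ms)), 25))
    u <- runif(length(members))
    for (j in seq_along(members)) {
      if (u[j] < config$omission_rate) next
      k <- members[j]
      if (u[j] < config$omission_rate + config$substitution_rate) {
        k <- substitute_key(k, n_keys)
      }
      key <- c(key, k)
      press <- c(press, group_t[g] + off[j])
    }
    # insertion in the gap following this group
    if (g < n_groups && config$insertion_rate > 0 &&
        runif(1) < config$insertion_rate) {
      gap <- c(group_t[g], group_t[g + 1L])
      at <- gap[1] + diff(gap) * runif(1, 0.35, 0.65)
      key <- c(key, substitute_key(members[1], n_keys))
      press <- c(press, at)
    }
  }
  press <- press - min(c(press, 0)) # keep press times non-negative
  dur <- pmax(30, 0.6 * config$base_ioi_ms +
                rnorm(length(press), 0, 0.05 * config$base_ioi_ms))
  ord <- order(press, key)
  n <- length(press)
  tibble::tibble(
    participant = rep(participant, n), task = rep(task, n),
    trial = rep(trial, n), condition = rep(condition, n),
    key_index = key[ord], press_ms = press[ord],
    release_ms = press[ord] + dur[ord],
    velocity = pmin(127, pmax(1, round(rnorm(n, 70, 10)))),
    incomplete = rep(FALSE, n)
  )
}

# the eight study scales, playable with the right hand in a 25-key
# C3-C5 register: F major, F# minor, G major, G minor, A minor,
# Bb major, B minor, C major
study_scales <- function() {
  tibble::tibble(
    tonic_key_index = c(5L, 6L, 7L, 7L, 9L, 10L, 11L, 12L),
    mode = c("major", "natural_minor", "major", "natural_minor",
             "natural_minor", "major", "natural_minor", "major")
  )
}

#' Simulate an altered-auditory-feedback cohort
#'
#' Generates scale performances for a cohort: each participant plays
#' the eight study scales in rotation, half the trials with altered
#' feedback on one target key. On altered trials, `slowing_delta_ms`
#' is added to each of the three inter-onset intervals following the
#' target onset (so the post-target notes shift by delta, 2*delta,
#' then 3*delta for all later notes), emulating post-error slowing.
#' Per-trial seeds are derived from `seed`, so cohorts are reproducible
#' trial-wise.
#'
#' @param n_participants Cohort size (at least 2).
#' @param trials_per_participant Number of scale trials per participant
#'   (default 24: eight scales, three repetitions, half altered).
#' @param slowing_delta_ms Injected slowing in ms per post-target
#'   interval.
#' @param config A [sim_config()]; its `slowing_delta_ms` is overridden
#'   by the argument.
#' @param seed Integer master seed.
#' @return A list with `log` (all trials' events, one tibble) and
#'   `manifest` (one row per trial: `participant`, `trial`,
#'   `target_position`, `alteration_semitones`, `feedback`).
#' @export
simulate_aaf_cohort <- function(n_participants = 16L,
                                trials_per_participant = 24L,
                                slowing_delta_ms = 0,
                                config = sim_config(), seed = NULL) {
  stopifnot(n_participants >= 2L, trials_per_participant >= 2L)
  if (!is.null(seed)) set.seed(seed)
  scales <- study_scales()
  templates <- purrr::map2(
    scales$tonic_key_index, scales$mode,
    function(t0, m) build_scale_template(t0, m)
  )
  n_onsets <- 16L
  n_trials <- n_participants * trials_per_participant
  trial_seed <- sample.int(.Machine$integer.max - 1L, n_trials)

  grid <- tidyr::expand_grid(
    p = seq_len(n_participants),
    i = seq_len(trials_per_participant)
  )
  grid$scale <- ((grid$i - 1L) %% 8L) + 1L
  grid$altered <- (grid$i %% 2L) == 0L # half of each participant's trials
  grid$target_position <- ifelse(
    grid$altered, sample(4:(n_onsets - 3L), n_trials, replace = TRUE),
    NA_integer_
  )
  grid$alteration <- ifelse(
    grid$altered,
    sample(c(-2L, -1L, 1L, 2L), n_trials, replace = TRUE),
    NA_integer_
  )

  logs <- vector("list", n_trials)
  for (r in seq_len(n_trials)) {
    ev <- simulate_performance(
      templates[[grid$scale[r]]], config, seed = trial_seed[r],
      participant = sprintf("P%02d", grid$p[r]), task = "task2",
      trial = sprintf("T%03d", grid$i[r]),
      condition = if (grid$altered[r]) "altered" else "standard"
    )
    if (grid$altered[r] && slowing_delta_ms != 0 &&
        nrow(ev) > grid$target_position[r]) {
      k <- grid$target_position[r]
      pos <- seq_len(nrow(ev))
      shift <- slowing_delta_ms * pmin(pmax(pos - k, 0), 3L)
      ev$press_ms <- ev$press_ms + shift
      ev$release_ms <- ev$release_ms + shift
    }
    logs[[r]] <- ev
  }
  manifest <- tibble::tibble(
    participant = sprintf("P%02d", grid$p),
    trial = sprintf("T%03d", grid$i),
    target_position = grid$target_position,
    alteration_semitones = grid$alteration,
    feedback = ifelse(grid$altered, "altered", "standard")
  )
  list(log = dplyr::bind_rows(logs), manifest = manifest)
}

#' Simulate latency samples from a two-component Gaussian mixture
#'
#' Draws key-to-sound latencies from a mixture of two Gaussians, the
#' model that describes the measured latency distribution of the
#' instrument (means near 8.77 and 12.67 ms, weights near 0.82/0.18).
#'
#' @param n Number of samples.
#' @param means_ms,sds_ms,weights Component means (ms), SDs (ms) and
#'   mixing weights (summing to 1).
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A numeric vector of length `n`.
#' @export
simulate_latencies <- function(n, means_ms = c(8.77, 12.67),
                               sds_ms = c(0.5, 0.5),
                               weights = c(0.82, 0.18), seed = NULL) {
  stopifnot(n >= 1, length(means_ms) == length(sds_ms),
            length(sds_ms) == length(weights), all(sds_ms > 0),
            all(weights >= 0), abs(sum(weights) - 1) < 1e-8)
  if (!is.null(seed)) set.seed(seed)
  z <- sample.int(length(weights), n, replace = TRUE, prob = weights)
  rnorm(n, means_ms[z], sds_ms[z])
}

#' Simulate a framewise-displacement series
#'
#' Baseline head motion (small positive FD values) with exactly
#' `n_spikes` volumes strictly exceeding `spike_magnitude`, placed at
#' random positions — input material for the [motion_exclusion()] rule.
#'
#' @param n_volumes Number of fMRI volumes.
#' @param n_spikes Number of suprathreshold motion spikes.
#' @param spike_magnitude Spike floor in mm (spikes exceed it strictly).
#' @param seed Integer seed.
#' @param baseline_mean,baseline_sd Baseline FD distribution (mm);
#'   baseline values are folded positive and capped at 0.5 mm.
#' @return A numeric vector of length `n_volumes`.
#' @export
simulate_fd_series <- function(n_volumes, n_spikes = 0,
                               spike_magnitude = 2.6, seed = NULL,
                               baseline_mean = 0.15, baseline_sd = 0.08) {
  stopifnot(n_volumes >= 1, n_spikes >= 0, n_spikes <= n_volumes,
            spike_magnitude > 0.5)
  if (!is.null(seed)) set.seed(seed)
  fd <- pmin(abs(rnorm(n_volumes, baseline_mean, baseline_sd)), 0.5)
  if (n_spikes > 0) {
    at <- sample.int(n_volumes, n_spikes)
    fd[at] <- spike_magnitude + abs(rnorm(n_spikes, 0.2, 0.1)) + 1e-6
  }
  fd
}
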