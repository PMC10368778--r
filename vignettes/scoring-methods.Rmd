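---
title: "Scoring naturalistic keyboard performance: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring naturalistic keyboard performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(keyscore)
library(dplyr)
```

`keyscore` quantifies how well a performance played on a keyboard — for
instance an MRI-compatible MIDI keyboard during scanning — matches an
errorless reference. This vignette explains the scoring models, the
parameters that matter and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical and
design decisions a maintainer should know about.

## The string encoding

A keypress log is reduced to a character string. Each key maps to one
printable, non-space character: the default 25-key map covers the C3–C5
register with the capitals A–Y (C3 = "A", C4 = "M", C5 = "Y"), and the
extended map appends the remaining capitals, small letters, digits and
twelve punctuation marks (`.,?!+-=/*@#$`), enough for the 74 keys of a
six-octave piano. Two keypresses belong to one chord when the later press
falls strictly within 30 ms of the chord's *first* press. Chord characters
are sorted in ascending code-point order so that the spelling of a chord
does not depend on the (physiologically arbitrary) micro-order of its
presses. With separators enabled, chords become space-delimited tokens:
`"M Q T"` is a three-note run, `"MQT"` a C-major triad.

Two choices here were genuinely open:

* **Simultaneity anchor.** "Within 30 ms of each other" can mean within
  30 ms of the chord's first note, or of the immediately preceding note.
  The second (pairwise chaining) lets a slow arpeggio of arbitrary length
  collapse into one chord; the first bounds a chord's spread by the
  window. We default to the group anchor (`anchor = "group"`) and expose
  chaining as `anchor = "previous"` for sensitivity analysis.
* **Strictness.** The window is strict: a gap of exactly 30 ms starts a
  new group. Raising the threshold can only merge groups, never split
  them — a property the tests exercise.

## Melodic accuracy: the Levenshtein ratio

The encoded performance $s$ and the encoded reference $r$ are compared
with the Levenshtein edit distance $L_{dist}(s, r)$ — the minimal number
of single-character insertions, omissions and substitutions turning one
into the other, each costing 1 — and summarised as

$$\mathrm{ratio} = 1 - \frac{L_{dist}(s, r)}{|s| + |r|},$$

which is 1 for an errorless performance and 0 for an empty one. The
dynamic programme is implemented in C (two rolling rows, $O(|s||r|)$
time). Points worth noting:

* **Substitution cost.** The definition above prices a substitution at 1.
  Some classic library `ratio()` functions price it at 2 (a deletion plus
  an insertion); `substitution_cost = 2L` reproduces that convention for
  sensitivity analysis, but the unit-cost formula is the package's
  definition.
* **Separators are compared too.** Template and performance are encoded
  by the same function with the same settings, so the separator
  convention cancels at a perfect match and penalises structural
  (chord-vs-run) disagreements otherwise — intended behaviour.
* **Floor of the ratio.** For equal-length non-empty strings the ratio
  cannot fall below 0.5 under unit substitution cost; 0 is attained only
  through length mismatch (e.g. an empty performance). We implement the
  formula literally rather than rescaling.
* The ratio of two empty strings is an error, not 1: no performance
  against no reference is meaningless.

## Rhythmic accuracy: proportion deviance

Rhythm is scored only on note onsets: chords are collapsed to their first
keypress. A trial is **eligible** only when the number of performed onset
groups equals the number of reference groups — the score pairs keystrokes
one-to-one and is undefined otherwise. This is a real limitation: extra
or missing notes, common in difficult material, remove trials from
rhythmic analysis entirely.

For an eligible trial with onsets $t_1 < \dots < t_n$ and expected onsets
$e_1 < \dots < e_n$, both are mapped to proportions of their own span,
$q_i = (t_i - t_1)/(t_n - t_1)$ and $p_i = (e_i - e_1)/(e_n - e_1)$ (four
isochronous notes are expected at proportions 0, 1/3, 2/3, 1). Each
interior note is scored as

$$d_i = \frac{|q_i - p_i|}{p_i - p_{i-1}}, \qquad i = 2, \dots, n - 1,$$

and the trial score is $100 \times \bar d$: the mean deviance as a
percentage of the expected note duration. The construction makes the
score exactly invariant to tempo (scale) and starting time (shift).

Two decisions were open and are recorded here:

* **Denominator direction.** The "expected interval between the
  consecutive keypresses" could be the interval preceding or succeeding
  note $i$. We default to the preceding interval and expose
  `denominator = "succeeding"`.
* **Endpoints.** $q_1 = p_1 = 0$ and $q_n = p_n = 1$ by construction, so
  the first and last notes carry no information; including their zero
  terms would only dilute the mean. Only interior notes are averaged.

## Altered auditory feedback and post-error slowing

For the scale task, templates are built programmatically: ascending from
the tonic to the octave and back (major pattern 2-2-1-2-2-2-1 semitones,
natural-minor 2-1-2-2-1-2-2), with the octave struck at the end of the
ascent and again at the start of the descent. That turnaround convention
is what produces the expected 16 keypresses; a 15-press
`turnaround = "single"` variant exists but is not the default.

Post-error slowing is measured per trial around the *first*
altered-feedback target key: the mean of the three inter-onset intervals
ending at the target onset ("before") versus the mean of the three
following it ("after"). The interval that completes *at* the target press
is counted as "before" because it is over before the altered sound can
influence motor output; the alternative windowing (three intervals ending
strictly before the target) is available as `window = "strict-pre"`.
Participant means of before and after feed a one-way repeated-measures
ANOVA, which for two conditions is exactly the squared paired t-test.

## The statistics layer

Repeated-measures ANOVAs use the classical univariate within-subject
decomposition with uncorrected degrees of freedom by default; a
Greenhouse–Geisser option estimates the sphericity correction per effect
from orthonormal within-subject contrasts. Partial eta squared is
reported as $F \cdot df_1 / (F \cdot df_1 + df_2)$. The two-sample
comparison is the Welch test (unequal variances, fractional Satterthwaite
degrees of freedom) with a pooled-SD Cohen's d. Outlier screening is a
single pass: group mean and SD are estimated once and values at least
3 SD away are removed, making the rule idempotent by construction.
Post-hoc comparisons are paired t-tests with Bonferroni correction,
$p_{adj} = \min(1, m p)$.

Normality robustness is screened by sample skewness and kurtosis against
the limits 2.31 and 8. Kurtosis conventions differ across sources, so the
package reports both the raw moment ratio $m_4/m_2^2$ and its excess form
(raw minus 3) and applies the bound 8 to the raw value. Note that a
sample with skewness $-1.56$ necessarily has raw kurtosis
$\ge 1.56^2 + 1 \approx 3.4$, so published shape values around 2.3 are
necessarily excess-form; either convention leaves such data comfortably
inside the bounds.

## Device QC

The key-to-sound latency distribution of the instrument is modelled as a
two-component Gaussian mixture, fitted by expectation-maximisation with
several seeded restarts (first quantile-based, then randomly perturbed),
keeping the best log-likelihood. The log-likelihood is asserted to be
non-decreasing at every iteration; non-convergence returns the best fit
so far with a warning. Component SDs are free parameters. The fraction of
samples at or below the 25 ms latency bound is reported alongside.

Motion QC implements the framewise-displacement rule: a run is excluded
when 10 or more volumes exceed 2.5 mm (one voxel dimension). The FD
comparison is strict (`> 2.5`), the count comparison inclusive (`>= 10`),
matching the rule's wording.

## The synthetic-performance generator

The simulator is the package's test bed: it generates keypress logs
conditioned on a template with controlled error and timing processes, so
every scoring stage can be validated against known ground truth.

Per expected keypress it applies omission, neighbour substitution (±1 or
±2 semitones within the register — plausible pianistic slips, and the
same magnitudes as the altered-feedback manipulation) and per-gap
insertion; group onsets are the template onsets rescaled to the base
tempo plus i.i.d. Gaussian jitter, and chord members receive small
positive asynchrony offsets capped below the simultaneity window.

The defaults are fixed study conditions, not tuning knobs:

| parameter | default | rationale |
|---|---|---|
| `base_ioi_ms` | 500 | a comfortable two-notes-per-second scale/melody tempo |
| `onset_jitter_sd_ms` | 20 | skilled-player timing variability at this tempo |
| `chord_asynchrony_sd_ms` | 5 | typical within-chord onset spread, well inside 30 ms |
| error rates | 0 | accurate professional performance unless errors are the object of study |
| AAF cohorts | 16 participants, 24 trials (8 scales × 3 reps), half altered | the scale-task design |
| target position | uniform on 4–13 of 16 onsets | leaves three intervals on each side |

Simulated latencies come from the two-Gaussian mixture with means
8.77 and 12.67 ms and weights 0.82/0.18 (SDs 0.5 ms, free in the model
but fixed in the generator so recovery can be tested); simulated FD
series are small baseline motion plus an exact number of suprathreshold
spikes.

**What the generator does not emulate** — and hence what passing tests do
*not* establish about real data: expressive timing (rubato, phrase-final
lengthening), velocity dynamics, hand-dependent error structure,
perceptual coupling between feedback alteration and subsequent errors
(simulated slowing is a pure time shift), or drifts in tempo. Tests built
on it validate the *scoring machinery*, not behavioural claims.

## Problem sizes used in validation

The test-bed simulations use sizes chosen to give stable Monte-Carlo
estimates: 200 simulated performances per error-rate level for the
degradation checks, 200 cohorts of 16 participants (4 scale trials each)
per slowing level for recovery, 1000 cohorts (2 trials per participant)
for the type-I-error check of the before/after ANOVA, and $10^4$ latency
draws for mixture recovery. Exhaustive edit-distance validation covers
every string pair up to length 5 over a 4-letter alphabet (1.9 million
pairs) against an independent implementation, plus the recursive
definition on the shorter strings.

## Known limitations

* The keypress-log TSV dialect is this package's own; instrument vendors'
  logging formats must be converted (columns: participant, task, trial,
  condition, key_index, press_ms, release_ms, velocity).
* The rhythm score requires exact note-count matches; performances of
  hard polyphonic material lose many trials to the eligibility rule.
* The EM fit is univariate and assumes a fixed component count; model
  selection (choosing k) is out of scope.
* RM-ANOVA helpers require complete balanced designs and do not impute.
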