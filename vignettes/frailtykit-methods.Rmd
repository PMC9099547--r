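---
title: "Ambient-sensor frailty indicators: models, parameters and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ambient-sensor frailty indicators: models, parameters and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(frailtykit)
```

## The problem

Frailty in older adults is commonly assessed with the Fried phenotype: a
person meeting three to five of the phenotypic criteria (weakness, slowness,
exhaustion, low activity, shrinking) is *frail*, one or two *pre-frail*,
none *non-frail*.  Clinic-based assessment misses the slow, insidious onset
of frailty; unobtrusive ambient sensors in the home can surface behavioural
precursors continuously.  `frailtykit` implements the software core of such
a toolkit for a **single-occupant** dwelling:

* a pressure **mat** on a chair bounds sedentary bouts,
* two ultrasonic **distance** sensors at the first and last step of a
  flight of stairs bound stair-climbing time,
* one PIR **motion** sensor per functional room yields room-presence
  durations and transitions,
* a magnetic **door** contact at the entrance delimits candidate outings
  (life-space mobility),
* a smart **weight scale** tracks the shrinking criterion, and
* a smart **speaker** runs a three-question self-report exhaustion
  conversation.

All derived durations are plain subtractions of two selected event times,
in seconds:

* sedentary duration `s = t_unoccupied − t_pre_occupied`,
* stair-climbing time `sc = |t_distance2 − t_distance1|`,
* room-presence duration `r = t_next_motion − t_pre_motion`,
* outing duration `od = t_door − t_pre_door`, confirmed as an outing
  (`o = 1`) iff `od > 5 min` **and** no other sensor fired strictly inside
  the absence.

Concurrent validity against ground truth uses Cohen's kappa
`k = (p_o − p_e)/(1 − p_e)` for categorical room labels, Bland–Altman
limits of agreement `bias ± 1.96·sd` with a "more than 20% outside means no
agreement" rule for continuous durations, detection rates for event
counting, and Pearson correlation for the weight channel.

## Numerical and design choices

**Timestamps.** ISO-8601 UTC at millisecond resolution.  The source system
timestamps events in the cloud without a stated resolution; milliseconds
cover that comfortably and keep file round trips lossless (formatting goes
through integer millisecond arithmetic because `strftime("%OS3")`
truncates).  All intervals are half-open `[start, end)`, which prevents
double counting at boundaries.

**Sedentary debounce.** Pressure mats flicker when a sitter shifts weight.
Vacancy gaps shorter than `debounce_s` (default 2 s) are merged into the
surrounding bout; raising the debounce can only reduce the number of bouts
(a tested monotonicity property).  The default is inert on clean data.

**Stair pairing.** A trigger pairs greedily with the earliest
opposite-position trigger within `pairing_window_s` (default 120 s, inert
on clean data).  The raw subtraction is negative for downward climbs under
the fixed sensor ordering, and descending the stairs is still a
stair-climbing event, so the package reports the absolute duration plus a
`direction` flag.  Unpaired triggers are kept with `complete = FALSE` and
excluded from agreement statistics.

**Room confirmation.** The "first confirmed time" a motion sensor detects a
person is not defined operationally in the source description.  We define
confirmation as the first trigger of a maximal same-room run, with an
optional `confirm_quiet_s` parameter (default 0) that lets a re-trigger of
the previous room within the quiet period veto a transition — a hook for
noisy PIR re-trigger behaviour.  Consecutive presences then tile the
session exactly (a conservation property the suite checks).

**Outings.** The interior-event window is the *open* interval strictly
between the two door events: firings at the door instants belong to the
departure or arrival itself.  The five-minute threshold is strict
(`od > 300 s`); a 300 s absence is not an outing.  Interior events *cancel*
the outing (presence inside means no true absence) rather than confirm a
return.  An optional coalescing window for open/close pairs exists but is
off by default, since the source treats both payloads as door events.

**Kappa alignment.** How categorical room pairs were formed in the source
study is unstated; we sample the derived and true room label on a 1 s grid
restricted to instants covered by a ground-truth room-presence interval.
Kappa significance uses the standard marginal-based null standard error and
a normal approximation.  Bland–Altman uses the sample SD (n−1); "outside
the limits" is strict inequality; proportional bias is the regression of
differences on pair means.

**Frailty thresholds.** The source work validates sensors, not clinical
cut-offs, so numeric thresholds for flagging criteria were left open.  By
default only two criteria are enabled: weight loss of at least 5% (the
Fried shrinking criterion) and exhaustion (scored directly from the
dialogue: frequency "sometimes" or "always" is positive, "rare" negative,
anything else missing).  The remaining criteria ship disabled with
documented placeholder values and a `"demo"` profile that enables all six
for end-to-end demonstrations; enabling them for clinical use is a
deliberate user decision, not a package default.  Missing criteria are
excluded from the positive count, never imputed.

**Dialogue.** The speaker asks availability, the CES-D exhaustion item, and
the frequency item, each with a single fallback repeat on an unrecognized
or silent answer.  The exhaustion yes/no answer does not gate the frequency
question, and categorization uses only the frequency token; a "no" to
exhaustion followed by a frail-range frequency is categorized positive per
the stated rule but flagged `inconsistent` on the transcript.  Speech
recognition is out of scope — the machine consumes normalized lowercase
tokens, with an optional synonym table (strict by default).

## What the simulator emulates — and what it does not

`generate_session()` replays the three-run HomeLab protocol: run 1 guided
at normal pace, run 2 self-paced, run 3 self-paced and slow, mimicking
frail older adults.  Each run performs all six activity types at least
once; room visits target the protocol's 2 minutes (SD 5 s guided, 15 s
self-paced), sitting averages 90 s, stair climbs 12 s, and run 3 multiplies
stair and sitting durations by 2 (the source states only "slow"; ×2 is our
single fixed choice).  Inter-activity gaps are exponential with mean 20 s
— the real distribution of break periods is unreported, and this is the
simplest renewal assumption.  Each run's absence for the outing test is
301 s plus an exponential with mean 420 s, guaranteeing one confirmed
outing per run.

`observe()` corrupts ground truth through per-sensor observation models.
Defaults restate the study's observed failure rates: door miss 0.125
(87.5% detection) and distance miss 0.5 (50% detection, the
out-of-range failure mode).  The distance miss applies **per climb**, not
per trigger: the documented failure is a participant climbing on the far
side of the stairs for the whole climb, and a per-trigger reading would
square the miss rate and contradict the reported 50% event-level rate.
All other misses, jitter and flicker default to zero, matching the
near-perfect agreement reported for those channels.  One pseudo-random
stream per sensor type is keyed from the seed, so ablating one sensor's
noise leaves the other streams byte-identical (tested).

The simulator does *not* model ultrasonic beam geometry, PIR optics,
battery behaviour, multi-occupant households, or speech audio.  A green
zero-noise test therefore establishes that the *derivation pipeline* is
exact on clean event streams — not that any physical sensor behaves this
way.  Conversely, the parameter-recovery tests establish that the
validation statistics faithfully measure the noise that was injected, with
99% binomial bands at n = 400–500.

The study's raw-data-dependent results (weight correlation r = 0.942,
n = 580 activities, the real kappa p-value, the 100% speaker agreement at
n = 27) depend on unpublished sessions and are covered only structurally:
the report contains the same blocks, computed from simulated data.

## Degenerate inputs and edge cases

* An empty event file is an empty log, not an error; an empty log derives
  an empty indicator set.
* A trailing mat occupancy or a final room presence is an open interval
  flagged incomplete, with `NA` duration.
* Kappa with a single category on both sides has `p_e = 1` and raises a
  degenerate-agreement error; zero-variance Bland–Altman collapses the
  limits to the bias, which is valid, not an error.
* Weight-change windows with fewer than two readings produce no record.

## Verification strategy

Every derivation is checked against an independent oracle: enumeration of
all mat transition sequences (length ≤ 6) and distance trigger sequences
(length ≤ 5), a rule-table oracle for outings, a hand-written transition
table for the dialogue (exhaustive over all 5-token sequences of length
≤ 6), brute-force marginal products for every 2×2 kappa table with cells
≤ 6, a direct covariance formula for correlation, and exhaustive bipartite
matching for interval alignment.  The acceptance suite additionally pins
the published worked examples (kappa 0.938; limits −16.057/15.485 and
−7.848/8.901 — reproduced to within one unit of the third decimal, the
residue of rounding the printed bias/sd inputs), the zero-noise identity of
the full pipeline, and binomial parameter recovery at the published 87.5%
and 50% detection rates.
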