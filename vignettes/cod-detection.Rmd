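---
title: "Detecting changes of direction in V-cut agility trials"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting changes of direction in V-cut agility trials}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codseg)
```

## The problem

The V-cut agility test is a 25 m sprint over a V-shaped cone course with
four changes of direction (COD), each a roughly 135° cut (45° internal
angle), two on each leg; a variant adds ball dribbling. Full-body inertial
motion capture records trunk kinematics and, per frame, whether each foot
contact point (heel, toe) touches the ground. For kinematic analysis each
COD must be delimited by two events:

* **IF (initial frame)** — heel strike of the *penultimate* foot contact
  (PFC), the braking step of the non-cutting foot;
* **FF (final frame)** — toe off of the *final* foot contact (FFC), the
  plant step of the cutting foot.

Annotating these by video is accurate but slow. `codseg` automates it with
a heuristic, rule-based pipeline, and quantifies how closely the automatic
events agree with manual annotation.

## The detection model

1. **Trunk horizontal speed.** $V_{hor}[t] = \sqrt{v_x[t]^2 + v_y[t]^2}$
   from the trunk-segment velocity components in the global horizontal
   plane. Every cut forces a braking trough in $V_{hor}$; the transition
   from the eccentric (braking) to the concentric (push-off) phase happens
   near the trough.
2. **Zero-phase low-pass filter.** A 4th-order Butterworth design with a
   1.5 Hz cut-off, applied forward and backward ("two-way"), so the output
   has no phase lag and trough positions are not displaced. The effective
   magnitude response is that of an 8th-order filter; no cut-off correction
   is applied. Step-response steady-state initial conditions plus odd
   (point-mirrored) reflection padding suppress the start/stop transients of
   an abruptly starting sprint.
3. **Prominence-qualified minima.** Interior local minima whose prominence —
   trough depth relative to the lower of the two enclosing higher flanks,
   i.e. standard peak prominence on the negated trace — reaches 1.5 m/s.
   Prominence (not raw depth) distinguishes genuine braking troughs from
   stride-level speed ripple.
4. **Search region.** Around each qualifying minimum at frame $m$, the
   inclusive interval $[m-40,\, m+25]$ in frames at the 60 Hz reference
   rate, rescaled proportionally at other rates and clipped to the trial.
5. **Edge logic.** The cutting (FFC) foot is the foot with the earliest toe
   falling edge at or after the minimum inside the region; the PFC is the
   contralateral foot. IF is the *latest* rising edge (contact value 1 with
   unit backward difference) of the PFC heel in $[lo, m]$; FF is the
   *earliest* falling edge (value 0, unit-magnitude difference) of the FFC
   toe in $[m, hi]$. Events missing either edge are flagged
   (`IF_MISSING`, `FF_MISSING`, `BOTH_MISSING`) rather than dropped.

All frame indices are 0-based over the motion frames (calibration poses are
excluded at parse time).

```{r pipeline}
st <- generate_trial(synthetic_spec())
detect_cods(st$trial)$events
```

## Parameters that matter

| parameter | default | unit | role |
|---|---|---|---|
| `prominence` | 1.5 | m/s | trough qualification threshold |
| `region_before` / `region_after` | 40 / 25 | frames @ 60 Hz | search window around the minimum |
| `cutoff` | 1.5 | Hz | low-pass cut-off |
| `filter_order` | 4 | – | Butterworth order per pass |
| `reference_rate` | 60 | Hz | rate at which region bounds are defined |

The prominence and region defaults are the optimum of the grid-search
tuning protocol (below). Region bounds are defined at a 60 Hz reference
rate — recordings of this kind run at 60 Hz (a 2-frame error corresponds to
about 33 ms) — and are rescaled for other rates so the window stays
physically constant.

Design choices that were genuinely open:

* **Trunk segment.** Readers default to the pelvis segment as the proxy of
  whole-body horizontal momentum; any segment label can be substituted
  (`trunk_segment = "T8"` for a thoracic segment).
* **Filter order reading.** "4th-order two-way" is read literally: an
  order-4 design per pass, no cut-off correction.
* **FF edge convention.** A toe-off step 1→0 has backward difference −1;
  the FF rule is therefore a unit-*magnitude* transition with value 0 (the
  first flight frame). The IF rule is the plain 0→1 rising edge.
* **IF/FF sub-intervals.** IF is searched only at or before the minimum,
  FF only at or after it, mirroring the eccentric/concentric split of the
  cut around the velocity minimum.
* **Tie-breaks.** IF takes the latest qualifying edge (the heel strike
  nearest the trough, i.e. the PFC rather than an earlier step); FF the
  earliest (the FFC toe off rather than the next stride); plateau minima
  report their first frame; a toe-off tie between feet resolves to the left
  foot. All choices are deterministic.
* **Cutting-foot resolution** is inferred from the earliest toe off after
  the minimum; a known cut schedule can override it per event
  (`detect_cods(..., cut_sides = )`).

## Agreement statistics

Signed differences are always **automatic − manual**, in frames. Per event
kind (IF, FF) the package reports the median, the mode (ties toward the
smallest absolute value), the IQR (Q3 − Q1, linear interpolation), the mean
absolute error $|E|$, the error standard deviation $s(E)$ (n−1 denominator),
and average precision $AP_k$ — the percentage of manual events whose
automatic counterpart lies within $k$ frames; undetected or unmatched
events count in the denominator only. Bland–Altman bias and limits of
agreement use the standard 1.96 multiplier. Total cutting time per COD,
$(FF - IF) \cdot 1000 / f_s$ ms, is compared across methods with Pearson's
$r$; the primary $R^2$ is $r^2$, with an identity-line variant
($1 - SS_{auto-manual}/SS_{manual}$) exposed via
`cutting_time_correlation(method = "identity_line")` since the two differ
whenever there is a systematic offset.

When event counts differ between methods, pairing is an order-preserving
alignment that first maximizes the number of matches within one
search-region width and then minimizes total minimum-to-label distance —
for time-ordered events this equals the exhaustive minimum-cost assignment,
which a greedy nearest-first rule does not always achieve.

The pooled RMSE used for tuning takes one IF and one FF term per manual
event: the squared signed difference when the automatic frame exists,
otherwise a penalty of the squared search-region width (an unmatched event
contributes two penalty terms). This makes the tuning objective penalize
parameter sets that drop events instead of rewarding them.

## Tuning protocol

`split_dataset()` splits whole trials, stratified by gender × team category
× test type, assigning each stratum the smallest training count whose
fraction reaches the target (a ceiling rule; 80:20 by default) with
seed-controlled membership. With 248 trials of 4 CODs in one pooled
stratum this yields 199 training trials (796 CODs) and 49 test trials
(196 CODs). `tune_parameters()` then evaluates every cell of a
user-specified grid — the shipped default spans prominence
{0.5, 1, 1.5, 2, 2.5} × before {20, 30, 40, 50} × after {15, 25, 35},
bracketing the tuned optimum — and returns the cell with minimal pooled
RMSE, ties resolved toward the smaller prominence, then the smaller region.

## The synthetic generator

There is no public corpus of labeled V-cut recordings, so the package
generates its own test bed. `generate_trial()` emulates:

* a trunk-speed profile ramping up over a 1 s lead-in, cruising at 4 m/s,
  with four raised-cosine troughs to 0.8 m/s spaced 1.2 s apart (one per
  5 m segment at roughly 4 m/s), ramping down over a 1 s tail;
* velocity components along a path whose heading swings ±67.5°, the
  45°-internal-angle geometry;
* alternating-foot stance trains at 3.5 steps/s with a 0.35 duty factor,
  with anchor stances placing the PFC heel strike 18 frames before each
  trough and the FFC toe off 10 frames after (plausible values inside the
  default search region; the true inter-event timing distribution is not
  publicly reported, so both are parameters);
* additive Gaussian speed noise (0.1 m/s) and optional integer jitter on
  the edges. Ground truth records the *realized* (post-jitter) edges, so
  end-to-end zero-error recovery is a meaningful oracle.

Background ("fill") steps keep out of a protected window around each COD's
anchor edges; edges outside that window cannot disturb the
latest-before/earliest-after rules, so clean trials are recovered exactly.
`make_failure_fixture()` reproduces the two documented misdetection modes of
minimum-anchored detection: a heel strike placed beyond the region's reach
(IF missed or mislabeled) and a trough displaced past the true toe off (the
detector latches the subsequent toe off, a late FF).

What the generator does **not** emulate: genuine joint kinematics, ball
dribbling (the dribbling variant differs only in metadata and slightly
lower cruise speed), double support irregularities, annotator disagreement,
or sensor misalignment. Passing tests therefore demonstrate the algorithm's
correctness and its documented failure modes, not field accuracy on real
cohorts; the published agreement tables come from a 62-player cohort whose
recordings are not deposited.

## Numerical choices and degenerate inputs

* Filtering requires at least `3 * (order + 1) + 1` samples and a cut-off
  strictly below Nyquist; shorter series or invalid cut-offs fail with a
  message rather than returning garbage. MVNX trials shorter than 1 s of
  motion frames are rejected at parse time.
* Constant series are fixed points of the filter to ~1e−9 (steady-state
  initialization), and symmetric pulses keep their extremum position
  exactly (zero phase).
* Region scaling uses `round()` at the trial rate; at 60 Hz the bounds are
  the familiar −40/+25 frames.
* An empty minima list, an all-zero contact channel, or a speed trace that
  never dips are all valid inputs yielding empty or flagged results, not
  errors.

## Problem sizes in the shipped checks

The test suite and the acceptance script run entirely on generated data:
grids of a few dozen cells on datasets of 4–6 trials, property suites on
series up to length 500, a 200-trial jitter contract, and a 248-trial
cohort for the split arithmetic — sizes chosen so the whole battery runs in
well under a minute while still exercising every code path at realistic
trial lengths (about 480 frames at 60 Hz).

## Known limitations

* The detector requires binary foot-contact channels; there is no
  velocity-only fallback when contacts are absent.
* Events whose true edges fall outside the search region are missed by
  construction (this is the documented failure mode, kept as a regression
  fixture rather than patched away).
* Sides are inferred from toe-off order; atypical stutter steps could
  mislabel the cutting foot — a known cut schedule should be passed when
  available.
* No COD angle/direction geometry, no inferential statistics beyond the
  agreement battery, no real-time streaming.
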