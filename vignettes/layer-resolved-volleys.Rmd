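---
title: "Resolving sub-millisecond components of the corticospinal volley"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Resolving sub-millisecond components of the corticospinal volley}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminaprobe)
```

## The problem

The first indirect (I1) corticospinal volley evoked by motor-cortex
stimulation is not monolithic: its earliest part reflects trans-synaptic
activation of layer-5 corticospinal neurons by neighbouring deep-layer
cells, while input from superficial layers 2/3 — arriving through distal
apical dendrites with slower EPSP rise times — can contribute only about
0.6 ms later. That sub-millisecond offset makes it possible, in principle,
to probe deep- and superficial-layer excitability separately in humans by
conditioning an H-reflex with TMS at delays differing by 0.6 ms.

`laminaprobe` implements the complete analysis chain for this idea across
three preparations, together with seeded generators that emulate each
preparation's recordings:

1. **In vitro** (brain-slice): population PSTH analysis of layer-5 spiking
   evoked by superficial versus deep extracellular stimulation, with a
   Monte Carlo shuffle test for the first-peak latency difference, plus
   EPSP and passive-membrane measurements.
2. **In vivo** (anaesthetised, epidural recording): D and I1 volley
   latencies as a function of stimulation depth.
3. **Human**: the two-step earliest-facilitation-delay (EFD) search on
   TMS-conditioned H-reflexes, and facilitation statistics across task
   epochs of a random-dot-motion discrimination task.

No public recordings exist for any of the three preparations, so the
synthetic generators are first-class components: their defaults *are* the
study conditions, and every acceptance-level check runs against them.

## Models in the generators

### EPSPs and spikes

Compound EPSPs are difference-of-exponentials kernels normalised to their
peak amplitude. Deep (basal-dendrite) input uses a fast rise
(`rise_tau = 1.4` ms); the superficial rise constant is solved by
root-finding so that the analytic peak-time difference between sites is
exactly 2.0 ms — the population-level contrast the in vitro calibration
targets. Dendritic cable filtering is thus summarised by a single rise-time
parameter; no compartmental modelling is attempted (a stated non-goal).

Spiking uses a threshold-crossing rule on the noiseless deep-site EPSP:
each cell's deep first-spike latency is where its EPSP crosses the
(per-cell jittered) threshold, which lands near 2 ms post-stimulus with
~0.13 ms across-cell spread. The superficial first spike trails it by
`superficial_extra_delay` (default 0.6 ms), while later response waves
recur at `i_wave_period` (default 1.7 ms) and are *shared* between the two
sites within a trial — reproducing the observation that only the first
response peak shifts with stimulation depth while the second overlaps.
Wave-retention draws and per-trial spike jitter are also shared between
sites, so the generator's only systematic site contrast is the timing
offset under study.

### PSTH analysis and the shuffle test

PSTHs use 0.1 ms bins over 0–10 ms; per-cell histograms are divided by the
cell's trial count *before* cells are averaged with equal weight (cells,
not trials, are the unit of analysis). Band-pass filtering (400–2000 Hz)
uses a forward–backward order-2 Butterworth filter: zero phase, so peak
latencies are unbiased; the series is padded by even reflection (30
samples) and trimmed, which keeps the residual of a constant input below
1 % of its amplitude.

The first-peak rule is: the first local maximum after a 0.5 ms blanking
interval whose height reaches 25 % of the post-blanking maximum, ties to
the earliest bin. Both parameters are configurable; the qualification
fraction guards against filter ringing and the blanking against stimulus
artifacts. The apex is refined by three-point parabolic interpolation.
This sub-bin refinement is a deliberate design choice: without it the
shuffle-test's null distribution of latency differences is quantised to
whole 0.1 ms bins, which makes permutation p-values too discrete to be
calibrated; with it, the test's empirical type-I error at alpha = 0.05
sits inside [0.03, 0.07] over 500 null simulations (checked in the
acceptance suite).

The Monte Carlo test shuffles whole-cell PSTHs between two groups of the
original sizes, re-averages, re-filters and re-measures each shuffle
exactly as the observed data. Because averaging and zero-phase filtering
are linear, cells are filtered once and shuffles only re-average — an
algebraic identity, not an approximation. The p-value uses the add-one
rule, two-sided by default (the direction of the physiological hypothesis
is known, so a one-sided value is also reported; two-sided is kept as the
conservative default).

### Epidural volleys

Waves are Gaussian deflections (SD 0.15 ms) centred on their configured
latencies, so the zero-phase-filtered peak sits on the configured latency
in the noiseless case. Defaults: D wave at 2.0 ms independent of depth;
I1 grading linearly from 4.0 ms (most superficial contact) to 3.5 ms
(deepest) across 16 contacts, i.e. a 0.5 ms shallow-minus-deep difference
with the D–I1 interval inside the physiological 1.4–2 ms band at every
depth. Intensity scales amplitudes, never latencies. I1 is identified as
the next qualifying peak at least 1 ms after D; a missing I1 is flagged
absent rather than guessed.

### Motoneuron pool and conditioning

The pool holds 120 units with truncated-normal recruitment thresholds
(mean 1.0, SD 0.25, floor 0.05, arbitrary excitability units). The
afferent drive is solved by root-finding on the truncated-normal CDF so
that the unconditioned recruitment fraction — the simulated H/Mmax — sits
at 20 %, the middle of the 15–25 % target band; if a realized pool drifts
outside the band the drive is pinned to the empirical quantile instead.

The delay convention is: delay d means TMS fires at (PNS time − d), so
negative delays put TMS after PNS. `coincidence_delay` (default −3.5 ms)
is the delay at which the fastest descending component arrives exactly
with the afferent volley — the subject's ground-truth EFD 0 ms. Descending
components (`deep_early` at offset 0, `superficial_late` at +0.6 ms, two
later waves at the I-wave period) add their strength to the drive when
they arrive no later than the afferent volley and no earlier than the
3 ms summation window before it. This step-function coincidence rule makes
recruitment non-decreasing as the delay becomes less negative, the
temporal-summation behaviour the conditioning technique exploits, and
gives the EFD search a sharp truth to recover.

Discharging units contribute a biphasic Hanning-windowed MUAP (3 ms,
40 uV) at a per-unit conduction delay (normal, mean 16.5 ms post-PNS, SD
0.3 ms); a fixed 8 % of units also fire directly at 4 ms, giving a small
conditioning-invariant M-wave. Component strengths (0.12, 0.08, 0.10,
0.05) were chosen so that conditioned recruitment roughly doubles at
EFD 0 ms — strong, clearly detectable facilitation of the kind the
protocol requires — while per-trial noise (common drive SD 0.03, per-unit
threshold jitter SD 0.05) keeps trial-to-trial H-reflex variability
realistic without starving the 15-trial paired t-tests of power.

### H-reflex quantification and the EFD search

H-reflex size is the RMS of the *unrectified* EMG over the first 0.5 ms
from onset (5 samples at 10 kHz), after setting the value at the onset
sample to zero — confining the measure to the earliest, monosynaptic
reflex component. The onset is determined once per dataset from the
unconditioned traces (mean rectified EMG exceeding baseline mean + 3 SD,
sustained 0.3 ms, searched 8–25 ms post-stimulus) and reused everywhere; a
manual override is accepted verbatim, standing in for the visual
determination used with real recordings.

The two-step search tests the rough grid −5…−2 ms in 0.5 ms steps (7
delays + 1 unconditioned condition per block, 15 randomized blocks), then
a fine grid of 11 delays at 0.1 ms anchored at the rough hit. The earliest
facilitation is the first delay (scanning from most negative) whose
conditioned RMS is significantly *higher* than the unconditioned RMS
(paired t by block, p < 0.05 uncorrected) with the next two scheduled
delays also significant — the protocol's own multiplicity guard, so the
individual tests stay uncorrected by design. Two open points were resolved
as follows and are exposed as options:

* The fine grid extends 1 ms towards *more negative* delays from the rough
  hit (matching the worked protocol example where a rough hit at −3.5 ms
  leads to a fine grid of −4.5…−3.5 ms), despite wording that could be
  read the other way; `fine_direction = "positive"` flips it.
* A qualifying delay too close to the schedule edge for two successors is accepted
  when all remaining successors are significant, with `edge_warning = TRUE`
  rather than returning nothing; discarding an otherwise clean hit at the
  schedule edge would bias the search against late coincidence times.

Recovery behaviour: over 100 synthetic subjects with ground-truth onsets
uniform in [−4.5, −2.5] ms, the search returns EFD 0 ms within 0.1 ms of
truth in ≥ 90 % of runs (96 % at the suite's seed). The residual misses
are the procedure's own statistics — e.g. an unusually small unconditioned
sample makes several delays look facilitated at once — not implementation
artifacts.

### Task simulation and analysis

The adaptive controller is a weighted up/down staircase per difficulty
(update every trial: coherence −step·(1−target) after a correct response,
+step·target after an error, step 1.5 %), which equilibrates where the
observer's accuracy equals the target — 55 % for difficult and 80 % for
easy cues. The observer is a lapse-adjusted logistic in coherence
(c50 = 25 %, slope = 8 %, lapse = 0.01), optionally with a practice drift
that lowers c50 over trials so coherence trajectories decline across a
session. The controller type is a package choice; the protocol being
emulated specifies only the targets.

The probed experiment crosses epochs x delay conditions (unconditioned,
EFD 0 ms, EFD +0.6 ms) x cue difficulty x cue direction, 20 trials per
condition, pseudo-randomly interleaved. Task-related excitability
modulation multiplies the `superficial_late` strength by 1.6 for easy
cues at (cue + 400 ms, flexion) only; the `deep_early` circuit is never
modulated. The gain's magnitude is a calibration choice — only its sign
and epoch/effector specificity are constrained — and because the
superficial-late component has not yet arrived at EFD 0 ms, the
insensitivity of EFD 0 ms facilitation to difficulty is structural, not
tuned. Analysis then proceeds blind to all of this: trials whose 50 ms
pre-stimulus background EMG exceeds the resting mean + 2 SD are excluded
(with reasons retained), facilitation is the per-subject ratio of mean
conditioned to mean unconditioned RMS within a cell (subjects, not trials,
are the unit of group analysis, matching the subject-mean presentation of
such experiments), cue modulation is the easy/difficult facilitation
ratio, and easy-versus-difficult differences are tested with paired t
tests under a Bonferroni family of the four pre-planned comparisons per
direction.

## What passing tests do and do not show

The generators reproduce the *timing structure* and *statistical design*
of the recordings: calibrated latency offsets, recruitment gain under
coincident drive, staircase equilibria, contaminated-trial rates. They do
not emulate drifting electrode contact, post-activation depression,
fatigue, correlated background EMG, bimodal motor-unit populations, or
observer lapses correlated with task state. Passing tests therefore
demonstrate that the analysis chain measures what it claims to measure on
data with known ground truth — not that real recordings would be as clean.
In particular the EFD-recovery rate and the type-I calibration of the
shuffle test are statements about the procedures under the stated noise
model.

## Numerical choices and degenerate inputs

* Time is stored in ms (floats) in tables; sample indices only in trace
  structures; 10 kHz EMG and 0.1 ms PSTH bins make the conversions exact.
* All randomness flows from explicit integer seeds; composite simulations
  derive per-component child seeds via a multiplicative hash kept below
  2^31, recorded in the pipeline manifest.
* Flat traces yield amplitude 0 with an explicit no-peak flag; degenerate
  filtered traces in more than 10 % of shuffles abort the Monte Carlo test
  with a diagnostic; an all-constant ANOVA input is flagged degenerate;
  a missing I1 is reported absent; a rough-stage search that finds no
  facilitation stops the two-step procedure with an instructive error.
* Problem sizes used by the test suite (24 cells x 100 trials, 500 null
  simulations for the calibration check, 100 synthetic EFD subjects, 13
  task subjects x 480 trials) match the study conditions being emulated
  while keeping a full run of the suite around three minutes.

## Known limitations

* The motoneuron model is a static threshold pool: no persistent inward
  currents, no post-activation depression, no recurrent inhibition.
* The coincidence rule is binary within the summation window; graded
  EPSP summation at the motoneuron is not modelled, which makes the EFD
  truth sharper than in real subjects.
* H-reflex onset detection assumes the background noise level of the
  resting session; strongly contaminated datasets need the manual
  override.
* The staircase models stationary or slowly improving observers only.
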