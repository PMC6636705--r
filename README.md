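# laminaprobe

Layer-resolved analysis of corticospinal volleys: population PSTH latency
analysis, epidural D/I1 volley measurement, and TMS-conditioned H-reflex
facilitation during a visuo-motor discrimination task — together with the
seeded synthetic-data generators the analyses are validated against.

## The scientific problem

The first indirect (I1) corticospinal volley evoked by stimulating motor
cortex has two parts. The earliest part arises when deep-layer (layer 5)
cells trans-synaptically activate corticospinal neurons through proximal
basal dendrites; roughly 0.6 ms later, superficial layers 2/3 can
contribute through distal apical dendrites, whose slower EPSP rise delays
threshold crossing at the soma. That timing offset suggests a non-invasive
way to read out deep- versus superficial-circuit excitability in humans:
condition an H-reflex with TMS and compare delays that differ by 0.6 ms.

`laminaprobe` implements the full analysis chain for this logic, for
people developing or stress-testing such protocols:

* **PSTH stage** — trial-normalized population PSTHs (0.1 ms bins,
  0–10 ms), zero-phase 400–2000 Hz band-pass, first-peak latency with a
  configurable qualification rule, and a Monte Carlo shuffle test for the
  superficial-minus-deep latency difference with the add-one permutation
  p-value

  p = (#{|d_null| >= |d_obs|} + 1) / (n_shuffles + 1).

* **Volley stage** — D and I1 latencies of (simulated) epidural traces
  across stimulation depths and intensities, with one-way ANOVA summaries.
* **EFD stage** — H-reflex RMS over the first 0.5 ms from onset
  (onset-zeroed, unrectified EMG), and the two-step earliest-facilitation-
  delay search: rough grid −5…−2 ms in 0.5 ms steps, fine grid of 11
  delays at 0.1 ms, earliest facilitation = first delay with conditioned >
  unconditioned (paired t, p < 0.05, uncorrected) and two significant
  successors.
* **Task stage** — background-EMG trial exclusion (resting mean + 2 SD),
  reaction times (4 SD sustained rule), facilitation
  (conditioned/unconditioned × 100 %), cue modulation (easy/difficult
  × 100 %), and Bonferroni-adjusted pre-planned paired comparisons.
* **Generators** — EPSP traces (difference-of-exponentials kernels),
  evoked spike trains, depth-graded volley sweeps, a 120-unit motoneuron
  pool with coincidence-gated recruitment, and an adaptive dot-motion
  staircase with a simulated logistic observer. Every generator takes an
  explicit seed and its defaults are the calibrated study conditions.

## Worked example

```r
library(laminaprobe)

## in vitro: 24 simulated layer-5 cells, 100 trials per stimulation site
spikes <- simulate_population_spikes(cell_sim_config(), n_cells = 24, seed = 1)
deep <- bandpass_psth(compile_population_psth(spikes, "deep"))
sup  <- bandpass_psth(compile_population_psth(spikes, "superficial"))
first_peak_latency(deep); first_peak_latency(sup)
#> first peak: deep 2.03 ms, superficial 2.63 ms, shift 0.59 ms

monte_carlo_latency_test(psth_by_cell(spikes, "superficial"),
                         psth_by_cell(spikes, "deep"), seed = 2)
#> <latency_test_result> observed difference 0.595 ms, p = 0.01099 (two-sided, 1000 shuffles)

## human: two-step EFD search on a synthetic subject whose true
## coincidence delay is -3.73 ms
pool <- motoneuron_pool(coincidence_delay = -3.73, seed = 3)
h_over_mmax(pool)
#> [1] 0.19
simulate_efd_subject(pool, seed = 11)
#> <efd_result> rough -3.5 ms, EFD 0 ms = -3.7 ms (EFD +0.6 ms = -3.1 ms)

## task: adaptive staircase against the default simulated observer
session <- simulate_staircase_session(task_sim_config(), seed = 1)
round(100 * staircase_accuracy(session, last = 1000), 1)
#> difficult      easy
#>      55.1      80.2
```

Reading the numbers: the band-passed population PSTH places the first
response peak 0.59 ms later for superficial than for deep stimulation
(the generator's calibrated 0.6 ms offset, recovered to within one PSTH
bin), and the shuffle test rejects the hypothesis that the two sites share
a first-peak latency. The EFD search brackets the subject's true
coincidence delay of −3.73 ms at −3.7 ms on the 0.1 ms grid, so EFD
+0.6 ms probes the later volley component at −3.1 ms. The staircases hold
the observer at the 55 %/80 % accuracy targets.

The end-to-end task analysis is one call chain:

```r
cohort <- simulate_cohort(n_subjects = 13, seed = 5)
analyse_task_experiment(cohort)
#> <facilitation_summary>
#>   8 pre-planned comparisons, 1 significant after Bonferroni
#>    * cue_400|efd0_p06|flexion
```

i.e. the easy-versus-difficult facilitation difference appears only 400 ms
after cue onset, only at EFD +0.6 ms, and only for flexion cues — the
signature of a selectively modulated superficial circuit, recovered by an
analysis that never sees the generator's modulation settings.

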