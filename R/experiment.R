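#' Default task-epoch excitability modulation
#'
#' Returns the modulation rule applied to descending-circuit strengths
#' during the task: a multiplicative gain on the `superficial_late` circuit
#' for easy cues relative to difficult cues, applied only in the early
#' discrimination epoch (400 ms after cue onset) and only when the cue
#' instructs a flexion movement (the recorded flexor is the effector). The
#' `deep_early` circuit is left unmodulated everywhere, so the earliest
#' volley component is insensitive to cue difficulty by construction.
#'
#' @param easy_gain gain on `superficial_late` for easy cues at
#'   (cue + 400 ms, flexion); default 1.6. The magnitude is a package
#'   calibration choice - only the sign and epoch/effector specificity of
#'   the effect are constrained by the physiology being emulated.
#' @return function(epoch, difficulty, direction) -> named gains vector.
#' @export
default_modulation <- function(easy_gain = 1.6) {
  force(easy_gain)
  function(epoch, difficulty, direction) {
    g <- c(deep_early = 1, superficial_late = 1, later_waves = 1)
    if (epoch == "cue_400" && difficulty == "easy" &&
        direction == "flexion") {
      g["superficial_late"] <- easy_gain
    }
    g
  }
}

#' Simulate one subject's probed dot-motion experiment
#'
#' Composes the motoneuron-pool conditioning simulator and the task
#' structure: for every condition (epoch x delay condition x cue difficulty
#' x cue direction) `trials_per_condition` trials are generated in
#' pseudo-randomized interleaved order. Delay conditions are
#' `unconditioned`, `efd0` (the pool's ground-truth coincidence delay) and
#' `efd0_p06` (0.6 ms less negative). A `contamination` fraction of trials
#' carries inflated background EMG to exercise the exclusion rule. A
#' resting delay-identification session (unconditioned trials) is simulated
#' first and provides the H-reflex onset and the resting background-EMG
#' baseline.
#'
#' @param pool a [motoneuron_pool()].
#' @param protocol list with `epochs`, `delays`, `difficulties`,
#'   `directions`, `trials_per_condition`.
#' @param modulation rule from [default_modulation()].
#' @param contamination fraction of trials with inflated background EMG.
#' @param contamination_scale background-noise multiplier on contaminated
#'   trials.
#' @param rt_params named list per difficulty with `mean` and `sd` (ms) of
#'   the reaction-time distribution (movement trials only).
#' @param accuracy named accuracy per difficulty used for the simulated
#'   responses.
#' @param n_resting trials in the resting delay-identification session.
#' @param subject subject identifier stored in the trial table.
#' @param seed integer root seed.
#' @return object of class `probed_experiment`: `trials` (trial table, one
#'   row per trial with `trial_id`, `subject`, `epoch`, `delay_condition`,
#'   `delay_ms`, `cue_difficulty`, `cue_direction`, `response`, `correct`,
#'   `coherence_pct`, `rt_ms`, `emg_file`, `stimulus_sample`), `traces`
#'   (list of `emg_trace`), `resting` (traces, baseline mean/SD of
#'   background EMG, onset) and `efd` (delay values used).
#' @export
simulate_experiment <- function(pool,
                                protocol = list(
                                  epochs = c("cue_onset", "cue_400"),
                                  delays = c("unconditioned", "efd0",
                                             "efd0_p06"),
                                  difficulties = c("difficult", "easy"),
                                  directions = c("flexion", "extension"),
                                  trials_per_condition = 20
                                ),
                                modulation = default_modulation(),
                                contamination = 0.05,
                                contamination_scale = 4,
                                rt_params = list(
                                  easy = c(mean = 175, sd = 20),
                                  difficult = c(mean = 225, sd = 25)
                                ),
                                accuracy = c(difficult = 0.55, easy = 0.80),
                                n_resting = 50, subject = 1L, seed = 1) {
  stopifnot(inherits(pool, "motoneuron_pool"))
  if (length(protocol$epochs) == 0 || protocol$trials_per_condition < 1) {
    stop("empty protocol", call. = FALSE)
  }
  delay_value <- c(unconditioned = NA_real_,
                   efd0 = pool$coincidence_delay,
                   efd0_p06 = pool$coincidence_delay + 0.6)
  unknown <- setdiff(protocol$delays, names(delay_value))
  if (length(unknown)) {
    stop("unknown delay condition(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  local_seed(child_seed(seed, "experiment"), {
    resting_traces <- lapply(seq_len(n_resting), function(i) {
      simulate_conditioning_trial(pool, delay = NULL)$trace
    })
    onset <- detect_onset(resting_traces)
    resting_bg <- vapply(resting_traces, function(tr) {
      quantify_hreflex(tr, onset)$background_emg
    }, numeric(1))
    grid <- expand.grid(epoch = protocol$epochs,
                        delay_condition = protocol$delays,
                        cue_difficulty = protocol$difficulties,
                        cue_direction = protocol$directions,
                        rep = seq_len(protocol$trials_per_condition),
                        stringsAsFactors = FALSE)
    grid <- grid[sample.int(nrow(grid)), ]
    n <- nrow(grid)
    traces <- vector("list", n)
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      g <- grid[i, ]
      gains <- modulation(g$epoch, g$cue_difficulty, g$cue_direction)
      contaminated <- runif(1) < contamination
      trial <- simulate_conditioning_trial(
        pool,
        delay = if (g$delay_condition == "unconditioned") NULL else
          delay_value[[g$delay_condition]],
        gains = gains,
        background_scale = if (contaminated) contamination_scale else 1
      )
      traces[[i]] <- trial$trace
      rp <- rt_params[[g$cue_difficulty]]
      correct <- runif(1) < accuracy[[g$cue_difficulty]]
      response <- if (correct) g$cue_direction else
        setdiff(protocol$directions, g$cue_direction)[1]
      rows[[i]] <- data.frame(
        trial_id = i, subject = subject, epoch = g$epoch,
        delay_condition = g$delay_condition,
        delay_ms = delay_value[[g$delay_condition]],
        cue_difficulty = g$cue_difficulty,
        cue_direction = g$cue_direction,
        response = response, correct = correct,
        coherence_pct = if (g$cue_difficulty == "easy") 30 else 8,
        rt_ms = rnorm(1, rp[["mean"]], rp[["sd"]]),
        emg_file = sprintf("trace_%04d", i),
        stimulus_sample = trial$trace$stimulus_marker,
        contaminated = contaminated
      )
    }
    structure(
      list(trials = do.call(rbind, rows), traces = traces,
           resting = list(traces = resting_traces,
                          baseline_mean = mean(resting_bg),
                          baseline_sd = sd(resting_bg), onset = onset),
           efd = delay_value, subject = subject, seed = seed),
      class = "probed_experiment"
    )
  })
}

#' Simulate a cohort of probed subjects
#'
#' Each subject gets an independently realized motoneuron pool (new unit
#' thresholds, a jittered ground-truth coincidence delay) and an
#' independent experiment seed derived from the root seed.
#'
#' @param n_subjects number of subjects; default 13.
#' @param seed integer root seed.
#' @param coincidence_range subjects' ground-truth EFD 0 ms delays are drawn
#'   uniformly from this interval, ms.
#' @param pool_args extra arguments passed to [motoneuron_pool()].
#' @param ... passed to [simulate_experiment()].
#' @return list of `probed_experiment` objects (class `probed_cohort`).
#' @export
simulate_cohort <- function(n_subjects = 13, seed = 1,
                            coincidence_range = c(-4.2, -2.8),
                            pool_args = list(), ...) {
  subjects <- local_seed(child_seed(seed, "cohort"), {
    runif(n_subjects, coincidence_range[1], coincidence_range[2])
  })
  out <- lapply(seq_len(n_subjects), function(s) {
    pool <- do.call(motoneuron_pool, c(
      list(coincidence_delay = subjects[s],
           seed = child_seed(seed, paste0("pool-", s))),
      pool_args
    ))
    simulate_experiment(pool, subject = s,
                        seed = child_seed(seed, paste0("subject-", s)), ...)
  })
  class(out) <- "probed_cohort"
  out
}

#' Simulate a movement-epoch EMG trace with a known reaction time
#'
#' Baseline noise up to `fixation_offset + rt`, then a sustained rectified
#' EMG burst, used to exercise [reaction_time()].
#'
#' @param rt_ms true reaction time, ms after fixation offset.
#' @param fixation_offset_ms fixation-offset marker, ms from trace start.
#' @param duration_ms trace length, ms.
#' @param burst_amplitude EMG burst SD, uV.
#' @param noise_sd baseline noise SD, uV.
#' @param sampling_rate kHz; default 10.
#' @param seed integer seed or NULL.
#' @return `emg_trace`-like list with `samples`, `fixation_offset_sample`,
#'   `sampling_rate`.
#' @export
simulate_movement_trace <- function(rt_ms, fixation_offset_ms = 200,
                                    duration_ms = 800,
                                    burst_amplitude = 60, noise_sd = 4,
                                    sampling_rate = 10, seed = NULL) {
  n <- round(duration_ms * sampling_rate)
  onset <- round((fixation_offset_ms + rt_ms) * sampling_rate)
  local_seed(seed, {
    x <- rnorm(n, 0, noise_sd)
    if (onset < n) {
      burst <- rnorm(n - onset, 0, burst_amplitude)
      x[(onset + 1):n] <- x[(onset + 1):n] + burst
    }
    list(samples = x,
         fixation_offset_sample = round(fixation_offset_ms * sampling_rate),
         sampling_rate = sampling_rate)
  })
}
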