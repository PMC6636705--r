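#' Motoneuron pool for TMS-conditioned H-reflex simulation
#'
#' The pool holds `n_units` motoneurons with fixed recruitment thresholds
#' drawn from a truncated normal distribution (arbitrary excitability
#' units). A peripheral-nerve stimulus delivers `afferent_strength` of
#' synaptic drive; a unit discharges on a trial when the total coincident
#' drive exceeds its (trial-jittered) threshold. TMS adds descending volley
#' components (`deep_early`, `superficial_late`, `later_wave_*`) that count
#' towards the drive only when they arrive at the motoneurons no later than
#' the afferent volley and no earlier than `summation_window` before it.
#'
#' The TMS-PNS delay convention follows the conditioning protocol: delay `d`
#' means TMS fires at (PNS time - d), so negative delays put TMS after PNS,
#' and less negative delays let progressively more descending components
#' coincide with the afferent volley. `coincidence_delay` is the delay at
#' which the fastest component (offset 0) arrives exactly with the afferent
#' volley - the ground-truth EFD 0 ms of the simulated subject. The
#' `superficial_late` component trails it by 0.6 ms by default.
#'
#' `afferent_strength`, when not given, is solved by root-finding on the
#' truncated-normal threshold distribution so that the unconditioned
#' recruitment fraction (the simulated H/Mmax) sits at `target_h_fraction`,
#' the middle of the 15-25 % target band.
#'
#' Discharging units contribute a biphasic Hanning-windowed motor-unit
#' action potential at the unit's conduction delay (normal, SD
#' `conduction_sd`) after the afferent arrival; a fixed fraction of units is
#' also activated directly by the nerve stimulus, producing a small M-wave.
#'
#' @param n_units number of motoneurons (>= 50).
#' @param threshold_mean,threshold_sd,threshold_min truncated-normal
#'   threshold distribution (excitability units).
#' @param target_h_fraction target unconditioned recruitment fraction.
#' @param afferent_strength afferent drive; `NULL` solves it from
#'   `target_h_fraction`.
#' @param coincidence_delay ground-truth EFD 0 ms for this subject, ms
#'   (negative: TMS after PNS).
#' @param volley_components data.frame with columns `circuit`,
#'   `arrival_offset` (ms after the fastest component) and `strength`.
#' @param summation_window temporal summation window at the motoneurons, ms
#'   (> 0).
#' @param drive_noise_sd per-trial common excitability noise SD.
#' @param unit_jitter_sd per-trial per-unit threshold jitter SD.
#' @param muap_amplitude,muap_duration MUAP kernel peak (uV) and duration
#'   (ms).
#' @param conduction_mean,conduction_sd motoneuron-to-muscle conduction
#'   delay distribution, ms after PNS (EMG H-reflex onset region).
#' @param m_latency,m_fraction M-wave latency (ms) and directly activated
#'   unit fraction.
#' @param emg_noise_sd background EMG noise SD, uV.
#' @param sampling_rate EMG sampling rate, kHz (default 10).
#' @param seed integer seed fixing the realized unit thresholds and
#'   conduction delays.
#' @return object of class `motoneuron_pool`.
#' @export
motoneuron_pool <- function(n_units = 120, threshold_mean = 1.0,
                            threshold_sd = 0.25, threshold_min = 0.05,
                            target_h_fraction = 0.20,
                            afferent_strength = NULL,
                            coincidence_delay = -3.5,
                            volley_components = data.frame(
                              circuit = c("deep_early", "superficial_late",
                                          "later_wave_1", "later_wave_2"),
                              arrival_offset = c(0, 0.6, 1.7, 3.4),
                              strength = c(0.12, 0.08, 0.10, 0.05)
                            ),
                            summation_window = 3.0,
                            drive_noise_sd = 0.03, unit_jitter_sd = 0.05,
                            muap_amplitude = 40, muap_duration = 3,
                            conduction_mean = 16.5, conduction_sd = 0.3,
                            m_latency = 4.0, m_fraction = 0.08,
                            emg_noise_sd = 3, sampling_rate = 10,
                            seed = 1) {
  if (n_units < 50) stop("`n_units` must be >= 50", call. = FALSE)
  stop_if_not_scalar(summation_window, "summation_window",
                     min = .Machine$double.eps)
  stopifnot(all(volley_components$strength >= 0),
            all(volley_components$arrival_offset >= 0))
  units <- local_seed(child_seed(seed, "pool-units"), {
    thr <- numeric(0)
    while (length(thr) < n_units) {
      cand <- rnorm(2 * n_units, threshold_mean, threshold_sd)
      thr <- c(thr, cand[cand > threshold_min])
    }
    list(threshold = sort(thr[seq_len(n_units)]),
         conduction = rnorm(n_units, conduction_mean, conduction_sd))
  })
  if (is.null(afferent_strength)) {
    # truncated-normal CDF; solve P(threshold < s) = target
    p0 <- pnorm(threshold_min, threshold_mean, threshold_sd)
    cdf <- function(s) {
      (pnorm(s, threshold_mean, threshold_sd) - p0) / (1 - p0)
    }
    afferent_strength <- uniroot(
      function(s) cdf(s) - target_h_fraction,
      c(threshold_min, threshold_mean + 6 * threshold_sd), tol = 1e-9
    )$root
    frac <- mean(units$threshold < afferent_strength)
    if (frac < 0.15 || frac > 0.25) {
      # realized pool drifted outside the target band: pin to the empirical
      # quantile instead
      afferent_strength <-
        quantile(units$threshold, target_h_fraction, names = FALSE) + 1e-9
    }
  }
  pool <- structure(
    list(n_units = n_units, threshold = units$threshold,
         conduction = units$conduction, threshold_mean = threshold_mean,
         threshold_sd = threshold_sd, threshold_min = threshold_min,
         target_h_fraction = target_h_fraction,
         afferent_strength = afferent_strength,
         coincidence_delay = coincidence_delay,
         volley_components = volley_components,
         summation_window = summation_window,
         drive_noise_sd = drive_noise_sd, unit_jitter_sd = unit_jitter_sd,
         muap_amplitude = muap_amplitude, muap_duration = muap_duration,
         conduction_mean = conduction_mean, conduction_sd = conduction_sd,
         m_latency = m_latency,
         m_units = seq_len(max(1L, round(m_fraction * n_units))),
         emg_noise_sd = emg_noise_sd, sampling_rate = sampling_rate,
         seed = seed),
    class = "motoneuron_pool"
  )
  pool
}

#' Expected unconditioned recruitment fraction (H/Mmax) of a pool
#'
#' @param pool a [motoneuron_pool()].
#' @return fraction of units recruited by the afferent volley alone.
#' @export
h_over_mmax <- function(pool) {
  mean(pool$threshold < pool$afferent_strength)
}

# biphasic Hanning-windowed MUAP kernel sampled at the pool's EMG rate
muap_kernel <- function(pool) {
  n <- max(4L, round(pool$muap_duration * pool$sampling_rate))
  ph <- seq(0, 1, length.out = n)
  pool$muap_amplitude * sin(2 * pi * ph) * 0.5 * (1 - cos(2 * pi * ph))
}

# descending components coincident with the afferent volley at delay d
coincident_components <- function(pool, delay) {
  rel <- (pool$coincidence_delay + pool$volley_components$arrival_offset) -
    delay # arrival time relative to the afferent volley, ms
  rel <= 1e-9 & rel >= -pool$summation_window
}

#' Simulate one (un)conditioned H-reflex trial
#'
#' Generates a 10 kHz unrectified EMG trace containing a small M-wave and an
#' H-reflex whose size reflects motoneuron recruitment under the coincident
#' afferent + descending drive (see [motoneuron_pool()]). `delay = NULL`
#' gives an unconditioned (PNS-only) trial.
#'
#' @param pool a [motoneuron_pool()].
#' @param delay TMS-PNS delay in ms (negative: TMS after PNS), or `NULL`.
#' @param gains named multiplicative gains on circuit strengths; names among
#'   `deep_early`, `superficial_late`, `later_waves` (the latter applies to
#'   every `later_wave_*` component). All gains must be > 0.
#' @param seed integer seed or NULL.
#' @param pre_ms,post_ms trace extent around the PNS stimulus, ms.
#' @param background_scale multiplier on the background EMG noise SD
#'   (values > 1 emulate contaminated trials).
#' @return list of class `conditioning_trial` with `trace` (class
#'   `emg_trace`: `samples` uV, `stimulus_marker`, `tms_marker`,
#'   `sampling_rate`) and `record` (delay, recruited count, drive,
#'   background scale).
#' @export
simulate_conditioning_trial <- function(pool, delay = NULL,
                                        gains = c(deep_early = 1,
                                                  superficial_late = 1,
                                                  later_waves = 1),
                                        seed = NULL, pre_ms = 100,
                                        post_ms = 60,
                                        background_scale = 1) {
  stopifnot(inherits(pool, "motoneuron_pool"))
  if (pool$n_units == 0) stop("pool has zero units", call. = FALSE)
  if (any(gains <= 0)) stop("`gains` must be > 0", call. = FALSE)
  if (!is.null(delay)) {
    stop_if_not_scalar(delay, "delay", min = -pre_ms, max = post_ms)
  }
  fs <- pool$sampling_rate # kHz == samples per ms
  n_samples <- round((pre_ms + post_ms) * fs)
  stim_sample <- round(pre_ms * fs) + 1L
  gain_of <- function(circuit) {
    key <- ifelse(grepl("^later_wave", circuit), "later_waves", circuit)
    g <- gains[key]
    ifelse(is.na(g), 1, g)
  }
  local_seed(seed, {
    drive <- pool$afferent_strength + rnorm(1, 0, pool$drive_noise_sd)
    if (!is.null(delay)) {
      comp <- pool$volley_components
      on <- coincident_components(pool, delay)
      if (any(on)) {
        drive <- drive +
          sum(comp$strength[on] * gain_of(comp$circuit[on]))
      }
    }
    thr <- pool$threshold +
      if (pool$unit_jitter_sd > 0) {
        rnorm(pool$n_units, 0, pool$unit_jitter_sd)
      } else 0
    fired <- which(thr < drive)
    samples <- if (pool$emg_noise_sd > 0) {
      rnorm(n_samples, 0, pool$emg_noise_sd * background_scale)
    } else numeric(n_samples)
    kern <- muap_kernel(pool)
    add_muap <- function(samples, onset_ms, unit) {
      s0 <- stim_sample + round(onset_ms * fs)
      idx <- s0:(s0 + length(kern) - 1L)
      ok <- idx >= 1 & idx <= n_samples
      samples[idx[ok]] <- samples[idx[ok]] + kern[ok]
      samples
    }
    for (u in pool$m_units) { # direct motor response, conditioning-invariant
      samples <- add_muap(samples, pool$m_latency +
                            (pool$conduction[u] - pool$conduction_mean), u)
    }
    for (u in fired) {
      samples <- add_muap(samples, pool$conduction[u], u)
    }
    tms_marker <- if (is.null(delay)) {
      NA_integer_
    } else {
      as.integer(stim_sample - round(delay * fs))
    }
    trace <- structure(
      list(samples = samples, stimulus_marker = stim_sample,
           tms_marker = tms_marker, sampling_rate = fs),
      class = "emg_trace"
    )
    structure(
      list(trace = trace,
           record = list(
             delay_ms = if (is.null(delay)) NA_real_ else delay,
             conditioned = !is.null(delay), recruited = length(fired),
             drive = drive, background_scale = background_scale
           )),
      class = "conditioning_trial"
    )
  })
}
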