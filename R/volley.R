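#' Configuration for simulating depth-graded epidural volley sweeps
#'
#' An epidural recording after cortical stimulation contains a D wave whose
#' latency is independent of stimulation depth (direct axonal activation)
#' and an I1 wave whose latency shortens as the stimulating contact moves
#' deeper, plus later I waves at `i_wave_period`. Waves are modelled as
#' Gaussian-windowed deflections centred on their configured latencies, so
#' the measured (zero-phase filtered) peak sits exactly on the configured
#' latency in the noiseless case.
#'
#' @param d_latency D-wave latency, ms (> 0).
#' @param i_wave_period interval between successive I waves, ms; the
#'   physiological default range is 1.4-2 ms and values outside it warn.
#' @param i1_latency_by_depth data.frame with columns `depth` (contact
#'   index or micrometres, increasing = deeper) and `i1_latency` (ms),
#'   non-increasing with depth. Default: 16 contacts grading from 4.0 ms
#'   (most superficial) to 3.5 ms (deepest), i.e. a 0.5 ms shallow-deep
#'   difference with the D-I1 interval inside 1.4-2 ms everywhere.
#' @param noise_sd additive trace noise SD (trace units).
#' @param sampling_rate sampling rate in kHz; default 25.
#' @param d_amplitude,i1_amplitude,later_amplitudes wave amplitudes (trace
#'   units); `later_amplitudes` sets the number of later I waves.
#' @param wavelet_sd Gaussian wave width (SD), ms.
#' @return object of class `volley_sim_config`.
#' @export
volley_sim_config <- function(d_latency = 2.0, i_wave_period = 1.7,
                              i1_latency_by_depth = data.frame(
                                depth = 1:16,
                                i1_latency = seq(4.0, 3.5, length.out = 16)
                              ),
                              noise_sd = 0.05, sampling_rate = 25,
                              d_amplitude = 1.0, i1_amplitude = 0.8,
                              later_amplitudes = c(0.5, 0.25),
                              wavelet_sd = 0.15) {
  stop_if_not_scalar(d_latency, "d_latency", min = .Machine$double.eps)
  stop_if_not_scalar(noise_sd, "noise_sd", min = 0)
  if (i_wave_period < 1.4 || i_wave_period > 2.0) {
    warning("`i_wave_period` outside the physiological 1.4-2 ms range")
  }
  m <- i1_latency_by_depth
  stopifnot(is.data.frame(m), all(c("depth", "i1_latency") %in% names(m)))
  m <- m[order(m$depth), ]
  if (any(diff(m$i1_latency) > 1e-12)) {
    stop("`i1_latency` must be non-increasing with depth", call. = FALSE)
  }
  structure(
    list(d_latency = d_latency, i_wave_period = i_wave_period,
         i1_latency_by_depth = m, noise_sd = noise_sd,
         sampling_rate = sampling_rate, d_amplitude = d_amplitude,
         i1_amplitude = i1_amplitude, later_amplitudes = later_amplitudes,
         wavelet_sd = wavelet_sd),
    class = "volley_sim_config"
  )
}

gaussian_wave <- function(t, center, amplitude, sd) {
  amplitude * exp(-(t - center)^2 / (2 * sd^2))
}

#' Simulate an epidural volley sweep over depths and intensities
#'
#' For every (depth, intensity) pair, `n_trials` traces are generated as the
#' configured wave train plus white noise; the trial average is stored
#' alongside. Stimulus intensity scales wave amplitudes (relative to the
#' middle intensity) but never latencies, mirroring the latency-invariance
#' of volleys across stimulus strengths.
#'
#' @param config a [volley_sim_config()].
#' @param depths depth keys to simulate; must exist in the configured
#'   latency map.
#' @param intensities stimulus intensities (mA).
#' @param n_trials trials averaged per condition.
#' @param duration trace duration, ms.
#' @param seed integer seed or NULL.
#' @return object of class `volley_sweep`: `time` (ms) and `records`, a list
#'   with one element per condition holding `depth`, `intensity`,
#'   `average` (trace), `traces` (trials x samples matrix) and the true
#'   `i1_latency`.
#' @export
simulate_volley_sweep <- function(config = volley_sim_config(),
                                  depths = config$i1_latency_by_depth$depth,
                                  intensities = c(2, 2.5, 3, 4, 5),
                                  n_trials = 100, duration = 10,
                                  seed = NULL) {
  stopifnot(inherits(config, "volley_sim_config"))
  map <- config$i1_latency_by_depth
  missing_depth <- setdiff(depths, map$depth)
  if (length(missing_depth)) {
    stop(sprintf("unknown depth key(s): %s",
                 paste(missing_depth, collapse = ", ")), call. = FALSE)
  }
  dt <- 1 / config$sampling_rate
  t <- seq(0, duration, by = dt)
  ref_intensity <- median(intensities)
  local_seed(seed, {
    records <- list()
    for (d in depths) {
      i1 <- map$i1_latency[match(d, map$depth)]
      centers <- c(config$d_latency, i1,
                   i1 + seq_along(config$later_amplitudes) *
                     config$i_wave_period)
      amps <- c(config$d_amplitude, config$i1_amplitude,
                config$later_amplitudes)
      clean <- rowSums(mapply(gaussian_wave, center = centers,
                              amplitude = amps,
                              MoreArgs = list(t = t, sd = config$wavelet_sd)))
      for (intensity in intensities) {
        scale <- intensity / ref_intensity
        mu <- clean * scale
        traces <- matrix(rnorm(n_trials * length(t), 0, config$noise_sd),
                         nrow = n_trials, byrow = TRUE)
        traces <- sweep(traces, 2, mu, "+")
        records[[length(records) + 1L]] <- list(
          depth = d, intensity = intensity, average = colMeans(traces),
          traces = traces, i1_latency = i1
        )
      }
    }
    structure(list(time = t, records = records, config = config),
              class = "volley_sweep")
  })
}

#' D and I1 wave latencies of an epidural volley trace
#'
#' The trace is band-pass filtered (zero phase, default 400-2000 Hz) and
#' peaks are measured with the same qualification rule as
#' [first_peak_latency()]: the D wave is the first qualifying peak after the
#' blanking interval, and I1 the next qualifying peak at least `i1_min_gap`
#' ms later. Latencies are relative to the stimulus at t = 0.
#'
#' @param trace numeric trace (ideally an average over >= 50 trials).
#' @param sampling_rate sampling rate in kHz.
#' @param band filter band, Hz; `NULL` skips filtering.
#' @param blank_ms initial blanking interval, ms.
#' @param min_frac peak qualification fraction of the post-blanking maximum.
#' @param i1_min_gap minimum D-to-I1 separation, ms; default 1.0.
#' @param interpolate parabolic apex refinement, see [first_peak_latency()].
#' @return list with `d_latency`, `i1_latency` (ms; `NA` when absent) and
#'   `i1_present`.
#' @export
volley_latencies <- function(trace, sampling_rate = 25, band = c(400, 2000),
                             blank_ms = 0.5, min_frac = 0.25,
                             i1_min_gap = 1.0, interpolate = TRUE) {
  x <- as.numeric(trace)
  dt <- 1 / sampling_rate
  if (!is.null(band)) {
    x <- zero_phase_bandpass(x, band, fs = sampling_rate * 1000)
  }
  times <- (seq_along(x) - 1) * dt # samples start at the stimulus, t = 0
  d_lat <- first_peak_core(x, times, min_frac, blank_ms, interpolate)
  if (is.na(d_lat)) {
    return(list(d_latency = NA_real_, i1_latency = NA_real_,
                i1_present = FALSE))
  }
  i1_lat <- first_peak_core(x, times, min_frac, d_lat + i1_min_gap,
                            interpolate)
  list(d_latency = d_lat, i1_latency = i1_lat, i1_present = !is.na(i1_lat))
}

#' Summarise D/I1 latencies of a volley sweep by depth
#'
#' Measures [volley_latencies()] on every per-condition average trace and
#' aggregates mean and SEM across intensity blocks per depth.
#'
#' @param sweep a `volley_sweep` from [simulate_volley_sweep()].
#' @param ... passed to [volley_latencies()].
#' @return list with `latencies` (one row per condition) and `by_depth`
#'   (per-depth mean and SEM of D and I1 latencies across intensities).
#' @export
summarise_volley_sweep <- function(sweep, ...) {
  stopifnot(inherits(sweep, "volley_sweep"))
  rows <- lapply(sweep$records, function(r) {
    lat <- volley_latencies(r$average,
                            sampling_rate = sweep$config$sampling_rate, ...)
    data.frame(depth = r$depth, intensity = r$intensity,
               d_latency = lat$d_latency, i1_latency = lat$i1_latency)
  })
  lat <- do.call(rbind, rows)
  sem <- function(v) sd(v) / sqrt(length(v))
  by_depth <- do.call(rbind, lapply(split(lat, lat$depth), function(g) {
    data.frame(depth = g$depth[1],
               d_mean = mean(g$d_latency), d_sem = sem(g$d_latency),
               i1_mean = mean(g$i1_latency), i1_sem = sem(g$i1_latency))
  }))
  rownames(by_depth) <- NULL
  list(latencies = lat, by_depth = by_depth[order(by_depth$depth), ])
}
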