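#' Detect the H-reflex onset from unconditioned traces
#'
#' Automated stand-in for per-subject visual onset determination: the
#' across-trial mean rectified EMG must exceed the pre-stimulus baseline
#' mean by `k` baseline SDs, sustained for `sustain_ms`, inside the reflex
#' search window. One onset is determined per dataset and reused for every
#' trial of that dataset; a manual `override` is returned verbatim.
#'
#' @param traces list of `emg_trace` objects (unconditioned trials, >= 5).
#' @param k threshold in baseline SDs; default 3.
#' @param sustain_ms required supra-threshold duration, ms; default 0.3.
#' @param search_window window searched for the reflex, ms post-stimulus;
#'   default `c(8, 25)` (excludes the M-wave).
#' @param baseline_ms pre-stimulus baseline length, ms; default 50.
#' @param override manual onset in ms post-stimulus; returned as-is.
#' @return onset time in ms post-stimulus.
#' @export
detect_onset <- function(traces, k = 3, sustain_ms = 0.3,
                         search_window = c(8, 25), baseline_ms = 50,
                         override = NULL) {
  if (!is.null(override)) {
    stop_if_not_scalar(override, "override", min = 0)
    return(structure(override, manual = TRUE))
  }
  if (length(traces) < 5) {
    stop("need at least 5 unconditioned traces for onset detection",
         call. = FALSE)
  }
  fs <- traces[[1]]$sampling_rate
  stim <- traces[[1]]$stimulus_marker
  rect <- rowMeans(vapply(traces, function(tr) abs(tr$samples),
                          numeric(length(traces[[1]]$samples))))
  base_idx <- (stim - round(baseline_ms * fs)):(stim - 1L)
  b_mean <- mean(rect[base_idx])
  b_sd <- sd(rect[base_idx])
  thr <- b_mean + k * b_sd
  win <- (stim + round(search_window[1] * fs)):
    (stim + round(search_window[2] * fs))
  need <- max(1L, round(sustain_ms * fs))
  above <- rect[win] > thr
  run <- 0L
  for (i in seq_along(above)) {
    run <- if (above[i]) run + 1L else 0L
    if (run >= need) {
      onset_sample <- win[i - need + 1L]
      return((onset_sample - stim) / fs)
    }
  }
  stop("no sustained threshold crossing in the search window; ",
       "supply a manual onset via `override`", call. = FALSE)
}

#' Quantify one H-reflex by onset-window RMS
#'
#' Computes the root-mean-square of the unrectified EMG over the first
#' 0.5 ms from the H-reflex onset (5 samples at 10 kHz). Baseline offsets
#' are removed by subtracting the value at the onset sample (the onset value
#' is set to zero before squaring). Background EMG is the mean rectified
#' activity over the 50 ms before the stimulus.
#'
#' @param trace an `emg_trace`.
#' @param onset_time onset in ms post-stimulus (from [detect_onset()]).
#' @param rms_window_ms RMS window length from onset, ms; default 0.5.
#' @param background_ms pre-stimulus background window, ms; default 50.
#' @return list of class `hreflex_measurement`: `onset_time` (ms), `rms`
#'   (uV) and `background_emg` (mean rectified uV).
#' @export
quantify_hreflex <- function(trace, onset_time, rms_window_ms = 0.5,
                             background_ms = 50) {
  fs <- trace$sampling_rate
  stim <- trace$stimulus_marker
  s0 <- stim + round(onset_time * fs)
  n <- round(rms_window_ms * fs)
  idx <- s0:(s0 + n - 1L)
  if (max(idx) > length(trace$samples) || s0 < 1) {
    stop("RMS window exceeds the trace", call. = FALSE)
  }
  x <- trace$samples[idx] - trace$samples[s0]
  b0 <- stim - round(background_ms * fs)
  if (b0 < 1) stop("background window exceeds the trace", call. = FALSE)
  structure(
    list(onset_time = onset_time, rms = sqrt(mean(x^2)),
         background_emg = mean(abs(trace$samples[b0:(stim - 1L)]))),
    class = "hreflex_measurement"
  )
}
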