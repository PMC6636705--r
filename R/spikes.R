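#' Configuration for simulating evoked spiking in layer-5 cells
#'
#' Spike generation follows a threshold-crossing rule on the (noiseless)
#' compound EPSP: a cell's first-spike latency to deep stimulation is the
#' time at which its deep-site EPSP crosses the spike threshold, with the
#' threshold jittered per cell. Superficial stimulation evokes the first
#' spike `superficial_extra_delay` ms later (the apical-input timing offset);
#' later response waves recur at `i_wave_period` and overlap in time between
#' the two sites. Per-trial spike-time jitter and per-wave firing
#' probabilities produce realistic PSTHs.
#'
#' @param kinetics named list of [epsp_kinetics()] for `deep` and
#'   `superficial`, as from [default_epsp_kinetics()].
#' @param spike_threshold spike threshold in mV above rest.
#' @param threshold_jitter_sd per-cell threshold jitter SD, mV (>= 0).
#' @param latency_jitter_sd per-trial spike-time jitter SD, ms (>= 0).
#' @param n_trials trials per stimulation site (>= 1).
#' @param superficial_extra_delay extra first-spike latency for superficial
#'   stimulation, ms (>= 0); default 0.6.
#' @param i_wave_period period of the later response waves, ms.
#' @param wave_probs per-wave firing probabilities (first element = first
#'   wave); its length sets the number of waves simulated.
#' @param window analysis window (ms post-stimulus) spikes are kept in.
#' @return object of class `cell_sim_config`.
#' @export
cell_sim_config <- function(kinetics = default_epsp_kinetics(),
                            spike_threshold = 2.5,
                            threshold_jitter_sd = 0.15,
                            latency_jitter_sd = 0.1,
                            n_trials = 100,
                            superficial_extra_delay = 0.6,
                            i_wave_period = 1.7,
                            wave_probs = c(0.9, 0.55, 0.3, 0.12),
                            window = c(0, 10)) {
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  stop_if_not_scalar(threshold_jitter_sd, "threshold_jitter_sd", min = 0)
  stop_if_not_scalar(latency_jitter_sd, "latency_jitter_sd", min = 0)
  stop_if_not_scalar(superficial_extra_delay, "superficial_extra_delay",
                     min = 0)
  stopifnot(all(wave_probs >= 0 & wave_probs <= 1), length(window) == 2)
  structure(
    list(kinetics = kinetics, spike_threshold = spike_threshold,
         threshold_jitter_sd = threshold_jitter_sd,
         latency_jitter_sd = latency_jitter_sd, n_trials = n_trials,
         superficial_extra_delay = superficial_extra_delay,
         i_wave_period = i_wave_period, wave_probs = wave_probs,
         window = window),
    class = "cell_sim_config"
  )
}

# Time at which the deep-site EPSP first crosses `threshold`; NA when the
# EPSP stays subthreshold.
epsp_threshold_crossing <- function(kinetics, threshold) {
  if (threshold >= kinetics$amplitude || threshold <= 0) {
    return(NA_real_)
  }
  s_peak <- epsp_peak_time(kinetics) - kinetics$onset_latency
  f <- function(s) epsp_kernel(kinetics, kinetics$onset_latency + s) - threshold
  kinetics$onset_latency + uniroot(f, c(1e-9, s_peak), tol = 1e-9)$root
}

#' Simulate evoked spike trains for a population of layer-5 cells
#'
#' Each cell is tested with both superficial and deep stimulation over
#' `n_trials` trials per site. Within a trial the wave-retention draws and
#' spike-time jitter are shared between the two sites, so that with
#' `superficial_extra_delay = 0` and zero jitter the two sites produce
#' identical spike trains; the sites differ only by the configured
#' first-wave delay. Cells whose jittered threshold exceeds the EPSP peak
#' fire no spikes and are flagged subthreshold.
#'
#' @param config a [cell_sim_config()].
#' @param n_cells number of cells (>= 2).
#' @param seed integer seed or NULL.
#' @return object of class `spike_train_set`: list with `cells` (per cell, a
#'   list with `deep` and `superficial`, each a list of per-trial spike-time
#'   vectors in ms post-stimulus), `n_trials`, `subthreshold` (logical per
#'   cell), `first_latency` (per-cell deep first-spike latency) and the
#'   generating config.
#' @export
simulate_population_spikes <- function(config = cell_sim_config(),
                                       n_cells = 24, seed = NULL) {
  stopifnot(inherits(config, "cell_sim_config"))
  if (n_cells < 2) stop("`n_cells` must be >= 2", call. = FALSE)
  nw <- length(config$wave_probs)
  P <- config$i_wave_period
  local_seed(seed, {
    subthreshold <- logical(n_cells)
    first_latency <- rep(NA_real_, n_cells)
    cells <- lapply(seq_len(n_cells), function(i) {
      thr <- config$spike_threshold +
        rnorm(1, 0, config$threshold_jitter_sd)
      latency <- epsp_threshold_crossing(config$kinetics$deep, thr)
      if (is.na(latency)) {
        subthreshold[i] <<- TRUE
        empty <- replicate(config$n_trials, numeric(0), simplify = FALSE)
        return(list(deep = empty, superficial = empty))
      }
      first_latency[i] <<- latency
      deep_offsets <- (seq_len(nw) - 1) * P
      sup_offsets <- deep_offsets
      sup_offsets[1] <- config$superficial_extra_delay
      deep <- vector("list", config$n_trials)
      sup <- vector("list", config$n_trials)
      for (tr in seq_len(config$n_trials)) {
        keep <- runif(nw) < config$wave_probs
        jit <- rnorm(nw, 0, config$latency_jitter_sd)
        d <- (latency + deep_offsets + jit)[keep]
        s <- (latency + sup_offsets + jit)[keep]
        deep[[tr]] <- d[d >= config$window[1] & d <= config$window[2]]
        sup[[tr]] <- s[s >= config$window[1] & s <= config$window[2]]
      }
      list(deep = deep, superficial = sup)
    })
    structure(
      list(cells = cells, n_trials = config$n_trials,
           subthreshold = subthreshold, first_latency = first_latency,
           config = config),
      class = "spike_train_set"
    )
  })
}

#' @export
print.spike_train_set <- function(x, ...) {
  cat(sprintf(
    "<spike_train_set> %d cells, %d trials/site (%d subthreshold)\n",
    length(x$cells), x$n_trials, sum(x$subthreshold)
  ))
  invisible(x)
}
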