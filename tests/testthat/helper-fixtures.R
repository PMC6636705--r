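# Hand-built fixtures used across the suite.

# An emg_trace with explicit samples; stimulus at `stimulus_ms` (default
# 100 ms at 10 kHz).
make_emg_trace <- function(samples, stimulus_ms = 100, sampling_rate = 10,
                           tms_marker = NA_integer_) {
  structure(
    list(samples = samples,
         stimulus_marker = round(stimulus_ms * sampling_rate) + 1L,
         tms_marker = tms_marker, sampling_rate = sampling_rate),
    class = "emg_trace"
  )
}

# A spike_train_set from explicit per-cell/per-trial spike times.
# `cells` is a list of lists: cells[[i]]$deep / $superficial are lists of
# numeric vectors (one per trial).
make_spike_set <- function(cells, n_trials) {
  structure(
    list(cells = cells, n_trials = n_trials,
         subthreshold = rep(FALSE, length(cells)),
         first_latency = rep(NA_real_, length(cells)), config = NULL),
    class = "spike_train_set"
  )
}

# Gaussian bump evaluated at 0.1 ms bin centers over 0-10 ms.
gaussian_heights <- function(center, sd = 0.3, n_bins = 100,
                             bin_width = 0.1, amplitude = 1) {
  centers <- (seq_len(n_bins) - 0.5) * bin_width
  amplitude * exp(-(centers - center)^2 / (2 * sd^2))
}

# Synthetic per-delay RMS tables for the EFD search: unconditioned blocks
# are N(10, 1); facilitated delays get `effect` added.
make_efd_tables <- function(delays, facilitated, n_blocks = 15,
                            effect = 5, seed = 1) {
  set.seed(seed)
  uncond <- data.frame(block = seq_len(n_blocks),
                       rms = rnorm(n_blocks, 10, 1))
  cond <- do.call(rbind, lapply(delays, function(d) {
    data.frame(block = seq_len(n_blocks), delay_ms = d,
               rms = rnorm(n_blocks, 10, 1) +
                 if (d %in% facilitated) effect else 0)
  }))
  list(cond = cond, uncond = uncond)
}
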