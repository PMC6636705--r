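#' EPSP kinetics for one stimulation site
#'
#' Describes the compound excitatory postsynaptic potential evoked in a
#' layer-5 pyramidal cell by extracellular stimulation at one site. The
#' waveform model is a difference of exponentials
#' \deqn{v(t) = A \frac{e^{-(t-t_0)/\tau_d} - e^{-(t-t_0)/\tau_r}}{g_{max}}}
#' normalised so that the peak equals `amplitude`. Superficial (layer 1/2)
#' stimulation activates distal apical synapses and therefore has a slower
#' rise and slightly later onset than deep (layer 5, basal) stimulation;
#' dendritic cable filtering is summarised entirely by `rise_tau`.
#'
#' @param amplitude peak amplitude in mV (>= 0).
#' @param rise_tau rise time constant in ms, `0 < rise_tau < decay_tau`.
#' @param decay_tau decay time constant in ms.
#' @param onset_latency synaptic onset latency after the stimulus, ms (>= 0).
#' @param site `"superficial"` or `"deep"`.
#' @return An object of class `epsp_kinetics`.
#' @seealso [default_epsp_kinetics()], [simulate_epsp_trace()],
#'   [epsp_peak_time()]
#' @export
epsp_kinetics <- function(amplitude, rise_tau, decay_tau, onset_latency,
                          site = c("deep", "superficial")) {
  site <- match.arg(site)
  stop_if_not_scalar(amplitude, "amplitude", min = 0)
  stop_if_not_scalar(rise_tau, "rise_tau", min = .Machine$double.eps)
  stop_if_not_scalar(decay_tau, "decay_tau", min = .Machine$double.eps)
  stop_if_not_scalar(onset_latency, "onset_latency", min = 0)
  if (rise_tau >= decay_tau) {
    stop("`rise_tau` must be strictly smaller than `decay_tau`", call. = FALSE)
  }
  structure(
    list(amplitude = amplitude, rise_tau = rise_tau, decay_tau = decay_tau,
         onset_latency = onset_latency, site = site),
    class = "epsp_kinetics"
  )
}

#' Analytic peak time of a difference-of-exponentials EPSP
#'
#' The kernel \eqn{e^{-s/\tau_d} - e^{-s/\tau_r}} peaks at
#' \eqn{s^* = \frac{\tau_r \tau_d}{\tau_d - \tau_r}\log(\tau_d/\tau_r)};
#' in the alpha-kernel limit \eqn{\tau_r \to \tau_d} this tends to
#' \eqn{\tau_r}. The returned time is relative to the stimulus
#' (onset latency included).
#'
#' @param kinetics an [epsp_kinetics()] object.
#' @return peak time in ms after the stimulus.
#' @export
epsp_peak_time <- function(kinetics) {
  tr <- kinetics$rise_tau
  td <- kinetics$decay_tau
  kinetics$onset_latency + tr * td / (td - tr) * log(td / tr)
}

#' Default EPSP kinetics for deep and superficial stimulation
#'
#' Deep (basal-dendrite) input uses a fast rise; the superficial
#' (apical-dendrite) rise time constant is solved numerically so that the
#' analytic peak-time difference between the two sites equals
#' `peak_shift` (default 2.0 ms, the population mean shift between the two
#' stimulation sites that the in vitro calibration targets).
#'
#' @param peak_shift target superficial-minus-deep peak-time difference, ms.
#' @return named list with elements `deep` and `superficial`, each an
#'   [epsp_kinetics()] object.
#' @export
#' @examples
#' k <- default_epsp_kinetics()
#' epsp_peak_time(k$superficial) - epsp_peak_time(k$deep)
default_epsp_kinetics <- function(peak_shift = 2.0) {
  stop_if_not_scalar(peak_shift, "peak_shift", min = 0)
  deep <- epsp_kinetics(amplitude = 4, rise_tau = 1.4, decay_tau = 16,
                        onset_latency = 1.0, site = "deep")
  target <- epsp_peak_time(deep) + peak_shift - 1.3 # peak-from-onset needed
  f <- function(tr) tr * 16 / (16 - tr) * log(16 / tr) - target
  rise <- uniroot(f, c(0.05, 15.9), tol = 1e-10)$root
  superficial <- epsp_kinetics(amplitude = 4, rise_tau = rise, decay_tau = 16,
                               onset_latency = 1.3, site = "superficial")
  list(deep = deep, superficial = superficial)
}

epsp_kernel <- function(kinetics, t) {
  s <- t - kinetics$onset_latency
  s[s < 0] <- 0
  tr <- kinetics$rise_tau
  td <- kinetics$decay_tau
  s_peak <- tr * td / (td - tr) * log(td / tr)
  gmax <- exp(-s_peak / td) - exp(-s_peak / tr)
  kinetics$amplitude * (exp(-s / td) - exp(-s / tr)) / gmax
}

#' Simulate a subthreshold EPSP voltage trace
#'
#' Produces a voltage trace on a regular time grid starting at the stimulus
#' (t = 0) with a 0 mV baseline. With `noise_sd = 0` the trace is the pure
#' kernel and its maximum equals `kinetics$amplitude` up to grid resolution.
#'
#' @param kinetics an [epsp_kinetics()] object.
#' @param duration trace duration in ms; must cover the 70 ms post-stimulus
#'   reference point if the trace is to be measured with [measure_epsp()].
#' @param dt sample interval in ms (default 0.04, i.e. 25 kHz).
#' @param noise_sd additive Gaussian noise SD, mV.
#' @param seed integer seed or NULL.
#' @return object of class `epsp_trace`: list with `time` (ms), `voltage`
#'   (mV), `dt` and the generating kinetics.
#' @export
simulate_epsp_trace <- function(kinetics, duration = 80, dt = 0.04,
                                noise_sd = 0, seed = NULL) {
  stopifnot(inherits(kinetics, "epsp_kinetics"))
  if (!is.numeric(duration) || duration <= 0) {
    stop("`duration` must be positive", call. = FALSE)
  }
  stop_if_not_scalar(noise_sd, "noise_sd", min = 0)
  t <- seq(0, duration, by = dt)
  v <- epsp_kernel(kinetics, t)
  if (noise_sd > 0) {
    v <- v + local_seed(seed, rnorm(length(t), 0, noise_sd))
  }
  structure(list(time = t, voltage = v, dt = dt, kinetics = kinetics),
            class = "epsp_trace")
}

#' Simulate trial-averaged EPSP traces for a cell population
#'
#' For each cell, one trial-averaged subthreshold trace per stimulation site
#' is generated from the site kinetics with per-cell variability: lognormal
#' jitter on amplitude and rise time, Gaussian jitter on onset latency, and
#' residual averaged-trace noise. The same cell shares its amplitude scaling
#' across the two sites (the site contrast under study is in timing, not
#' size).
#'
#' @param n_cells number of cells (>= 2).
#' @param kinetics named list as from [default_epsp_kinetics()].
#' @param amplitude_cv coefficient of variation of per-cell amplitude.
#' @param rise_cv coefficient of variation of per-cell rise time.
#' @param onset_jitter_sd SD of per-cell onset latency jitter, ms.
#' @param noise_sd residual noise SD of the averaged trace, mV.
#' @param duration,dt trace grid, see [simulate_epsp_trace()].
#' @param seed integer seed.
#' @return list of per-cell lists with elements `deep` and `superficial`,
#'   each an `epsp_trace`.
#' @export
simulate_epsp_population <- function(n_cells = 32,
                                     kinetics = default_epsp_kinetics(),
                                     amplitude_cv = 0.2, rise_cv = 0.05,
                                     onset_jitter_sd = 0.1, noise_sd = 0.01,
                                     duration = 80, dt = 0.04, seed = NULL) {
  if (n_cells < 2) stop("`n_cells` must be >= 2", call. = FALSE)
  local_seed(seed, {
    lapply(seq_len(n_cells), function(i) {
      amp_scale <- exp(rnorm(1, 0, amplitude_cv))
      out <- lapply(kinetics, function(k) {
        kc <- epsp_kinetics(
          amplitude = k$amplitude * amp_scale,
          rise_tau = k$rise_tau * exp(rnorm(1, 0, rise_cv)),
          decay_tau = k$decay_tau,
          onset_latency = max(0, k$onset_latency + rnorm(1, 0, onset_jitter_sd)),
          site = k$site
        )
        simulate_epsp_trace(kc, duration = duration, dt = dt,
                            noise_sd = noise_sd)
      })
      out
    })
  })
}

#' Measure amplitude and peak time of an EPSP trace
#'
#' Amplitude is the difference between the peak voltage after the stimulus
#' and the mean voltage near the 70 ms post-stimulus reference point; the
#' peak time is reported relative to the stimulus. The first time-derivative
#' over 2-12 ms post-stimulus is returned alongside, as the rise-rate view of
#' the same waveform.
#'
#' @param trace an `epsp_trace`, or a list with `time` and `voltage`.
#' @param stimulus_time stimulus time on the trace's clock, ms.
#' @param reference_window window (ms post-stimulus) whose mean voltage is
#'   the late reference; default `c(68, 72)` brackets 70 ms.
#' @return list of class `epsp_measurement` with `amplitude` (mV),
#'   `peak_time` (ms post-stimulus, `NA` for a flat trace), `has_peak`,
#'   and `derivative` (data.frame `time`, `dv_dt` for 2-12 ms).
#' @export
measure_epsp <- function(trace, stimulus_time = 0,
                         reference_window = c(68, 72)) {
  t <- trace$time - stimulus_time
  v <- trace$voltage
  if (max(t) < 70) {
    stop("trace must span at least 70 ms post-stimulus", call. = FALSE)
  }
  ref <- mean(v[t >= reference_window[1] & t <= reference_window[2]])
  post <- t >= 0
  vp <- v[post]
  tp <- t[post]
  flat <- diff(range(vp)) < 1e-9
  if (flat) {
    amplitude <- 0
    peak_time <- NA_real_
  } else {
    i <- which.max(vp)
    amplitude <- vp[i] - ref
    peak_time <- tp[i]
  }
  dwin <- tp >= 2 & tp <= 12
  dv <- c(NA, diff(vp)) / c(NA, diff(tp))
  structure(
    list(amplitude = amplitude, peak_time = peak_time, has_peak = !flat,
         reference = ref,
         derivative = data.frame(time = tp[dwin], dv_dt = dv[dwin])),
    class = "epsp_measurement"
  )
}

#' Simulate the voltage response to a hyperpolarizing current step
#'
#' Ideal RC membrane response \eqn{V(t) = -IR(1 - e^{-t/\tau})} for a step of
#' `current` nA starting at t = 0, used to exercise [measure_passive()].
#'
#' @param resistance input resistance, MOhm.
#' @param tau membrane time constant, ms.
#' @param current injected hyperpolarizing current magnitude, nA.
#' @param duration,dt time grid, ms.
#' @param noise_sd additive noise SD, mV.
#' @param seed integer seed or NULL.
#' @return list with `time` (ms) and `voltage` (mV, deflection from rest).
#' @export
simulate_rc_response <- function(resistance, tau, current, duration = 100,
                                 dt = 0.1, noise_sd = 0, seed = NULL) {
  stopifnot(resistance > 0, tau > 0, current > 0)
  t <- seq(0, duration, by = dt)
  v <- -current * resistance * (1 - exp(-t / tau))
  if (noise_sd > 0) v <- v + local_seed(seed, rnorm(length(t), 0, noise_sd))
  list(time = t, voltage = v)
}

#' Passive membrane properties from a current-step response
#'
#' Input resistance is the steady-state voltage deflection divided by the
#' injected current (mV / nA = MOhm). The membrane time constant comes from
#' the gradient of the logarithm of the initial part of the deflection:
#' a straight line is fitted to \eqn{\log(V_\infty - V(t))} over the segment
#' where the deflection lies between 5 % and 80 % of its final value.
#'
#' @param trace list with `time` (ms) and `voltage` (mV deflection, negative
#'   for hyperpolarization), step onset at t = 0.
#' @param injected_current current magnitude, nA (> 0).
#' @return list of class `passive_properties` with `input_resistance` (MOhm)
#'   and `membrane_time_constant` (ms).
#' @details A deflection of 10 mV or more triggers a warning (the measurement
#'   is intended for small, linear-range deflections). A non-monotonic
#'   initial segment (after light smoothing) is a fit-failure error.
#' @export
measure_passive <- function(trace, injected_current) {
  stop_if_not_scalar(injected_current, "injected_current",
                     min = .Machine$double.eps)
  t <- trace$time
  v <- trace$voltage
  n <- length(v)
  v_inf <- mean(v[t >= quantile(t, 0.8)])
  dv <- abs(v_inf)
  if (dv >= 10) {
    warning("voltage deflection >= 10 mV; outside the intended linear range")
  }
  frac <- v / v_inf # deflection progress: 0 at onset -> 1 at steady state
  seg <- which(frac >= 0.05 & frac <= 0.8)
  if (length(seg) < 4) stop("fit failure: too few samples on the initial decay")
  sm <- stats::filter(frac, rep(1 / 5, 5), sides = 2)
  core <- seg[seg > 3 & seg < n - 3]
  if (any(diff(sm[core]) < -0.02, na.rm = TRUE)) {
    stop("fit failure: non-monotonic initial segment")
  }
  y <- log(v[seg] - v_inf) # remaining deflection, = dv * exp(-t / tau)
  ok <- is.finite(y)
  fit <- lm(y[ok] ~ t[seg][ok])
  tau <- -1 / coef(fit)[[2]]
  if (!is.finite(tau) || tau <= 0) stop("fit failure: non-decaying segment")
  structure(
    list(input_resistance = dv / injected_current,
         membrane_time_constant = tau),
    class = "passive_properties"
  )
}
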