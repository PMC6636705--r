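#' Exclude trials with elevated background EMG
#'
#' A trial is excluded when its background EMG (mean rectified activity over
#' the 50 ms before stimulation) exceeds the resting-condition mean by more
#' than 2 resting SDs. The resting baseline comes from the unconditioned
#' trials of the delay-identification session. Excluded trials are retained
#' in the table with `excluded = TRUE` and reason `"background_emg"`; a
#' subject whose every trial is excluded should be dropped from group
#' analysis.
#'
#' @param trials data.frame with a `background_emg` column (uV).
#' @param baseline list with `mean` and `sd` of the resting background EMG.
#' @param n_sd exclusion threshold in resting SDs; default 2.
#' @return `trials` with added `excluded` (logical) and `exclusion_reason`
#'   (character, `NA` for kept trials) columns.
#' @export
exclude_trials <- function(trials, baseline, n_sd = 2) {
  if (!"background_emg" %in% names(trials)) {
    stop("`trials` must carry a `background_emg` column", call. = FALSE)
  }
  if (any(is.na(trials$background_emg))) {
    stop("missing background EMG measurements", call. = FALSE)
  }
  thr <- baseline$mean + n_sd * baseline$sd
  excluded <- trials$background_emg > thr
  trials$excluded <- excluded
  trials$exclusion_reason <- ifelse(excluded, "background_emg",
                                    NA_character_)
  attr(trials, "exclusion_threshold") <- thr
  trials
}

#' Reaction time from rectified EMG
#'
#' The reaction time is the interval between the fixation-point offset and
#' the first rise of the rectified EMG more than `k` SDs above the baseline
#' mean, required to be sustained for `sustain_ms` (guards against
#' single-sample triggers). Baseline statistics come from the
#' `baseline_ms` preceding the fixation offset.
#'
#' @param trace list with `samples`, `fixation_offset_sample`,
#'   `sampling_rate` (kHz), e.g. from [simulate_movement_trace()].
#' @param k threshold in baseline SDs; default 4.
#' @param sustain_ms required supra-threshold duration, ms; default 10.
#' @param baseline_ms baseline window before fixation offset, ms.
#' @return reaction time in ms, or `NA_real_` when no sustained crossing
#'   occurs.
#' @export
reaction_time <- function(trace, k = 4, sustain_ms = 10,
                          baseline_ms = 100) {
  fs <- trace$sampling_rate
  off <- trace$fixation_offset_sample
  if (is.null(off) || is.na(off)) {
    stop("fixation offset marker missing", call. = FALSE)
  }
  rect <- abs(trace$samples)
  base <- rect[max(1, off - round(baseline_ms * fs)):(off - 1)]
  thr <- mean(base) + k * sd(base)
  post <- rect[(off + 1):length(rect)]
  need <- max(1L, round(sustain_ms * fs))
  if (length(post) < need) return(NA_real_)
  # sustained rule: the mean rectified EMG over the following `sustain_ms`
  # must exceed the threshold (guards against single-sample triggers)
  cs <- cumsum(c(0, post))
  win_mean <- (cs[(need + 1):length(cs)] - cs[1:(length(cs) - need)]) / need
  cand <- which(post[seq_along(win_mean)] > thr & win_mean > thr)
  if (!length(cand)) return(NA_real_)
  cand[1] / fs
}

#' H-reflex facilitation percentage
#'
#' Facilitation = conditioned H-reflex / unconditioned test H-reflex x 100 %
#' on the per-subject mean RMS values.
#'
#' @param conditioned,unconditioned numeric vectors of H-reflex RMS (uV).
#' @return facilitation in percent (100 = no change).
#' @export
facilitation <- function(conditioned, unconditioned) {
  if (!length(conditioned) || !length(unconditioned)) {
    stop("both RMS vectors must be non-empty", call. = FALSE)
  }
  mu <- mean(unconditioned)
  if (mu <= 0) stop("unconditioned mean RMS must be > 0", call. = FALSE)
  100 * mean(conditioned) / mu
}

#' Cue-related modulation of H-reflex facilitation
#'
#' Modulation = facilitation(easy) / facilitation(difficult) x 100 %;
#' values above 100 % mean greater facilitation with easy cues.
#'
#' @param facilitation_easy,facilitation_difficult facilitation percentages.
#' @return modulation in percent.
#' @export
cue_modulation <- function(facilitation_easy, facilitation_difficult) {
  if (any(facilitation_difficult <= 0)) {
    stop("difficult-cue facilitation must be > 0", call. = FALSE)
  }
  100 * facilitation_easy / facilitation_difficult
}

#' Paired pre-planned comparisons with Bonferroni adjustment
#'
#' Runs a paired Student's t test per comparison on per-subject values, and
#' flags Bonferroni-adjusted significance at family-wise level `alpha`
#' (raw p < alpha / family size). Raw p values are reported. Normality
#' (Kolmogorov-Smirnov on the standardized paired differences) is reported
#' as a diagnostic only, never as a gate.
#'
#' @param data data.frame with columns `comparison`, `subject`, `value_a`,
#'   `value_b` (paired within subject).
#' @param alpha family-wise significance level; default 0.05.
#' @param family family size for the Bonferroni correction; default the
#'   number of distinct comparisons in `data`.
#' @return data.frame with one row per comparison: `comparison`, `n`,
#'   `mean_a`, `mean_b`, `t`, `p_raw`, `family`, `significant`
#'   (Bonferroni-adjusted), `normality_p`.
#' @export
compare_conditions <- function(data, alpha = 0.05, family = NULL) {
  stopifnot(all(c("comparison", "subject", "value_a", "value_b") %in%
                  names(data)))
  comparisons <- unique(data$comparison)
  if (is.null(family)) family <- length(comparisons)
  rows <- lapply(comparisons, function(cmp) {
    g <- data[data$comparison == cmp, ]
    if (anyDuplicated(g$subject)) {
      stop("multiple rows per subject within a comparison", call. = FALSE)
    }
    if (nrow(g) < 3) stop("need >= 3 subjects per comparison", call. = FALSE)
    if (any(is.na(g$value_a)) || any(is.na(g$value_b))) {
      stop("unpaired or missing values in comparison ", cmp, call. = FALSE)
    }
    d <- g$value_a - g$value_b
    if (sd(d) < .Machine$double.eps) {
      tt <- list(statistic = c(t = 0), p.value = 1)
    } else {
      tt <- t.test(g$value_a, g$value_b, paired = TRUE)
    }
    ks_p <- if (sd(d) < .Machine$double.eps) NA_real_ else {
      suppressWarnings(ks.test(scale(d), "pnorm")$p.value)
    }
    data.frame(comparison = cmp, n = nrow(g),
               mean_a = mean(g$value_a), mean_b = mean(g$value_b),
               t = unname(tt$statistic), p_raw = tt$p.value,
               family = family,
               significant = tt$p.value < alpha / family,
               normality_p = ks_p)
  })
  do.call(rbind, rows)
}

#' Per-subject facilitation table from a probed experiment
#'
#' Runs the measurement pipeline on one subject: onset from the resting
#' session, per-trial H-reflex RMS and background EMG, background-EMG
#' exclusion against the resting baseline, then per-condition facilitation
#' (mean conditioned RMS over mean unconditioned RMS within the same epoch,
#' difficulty and direction cell).
#'
#' @param experiment a `probed_experiment` from [simulate_experiment()].
#' @return list with `trials` (measured + exclusion-flagged trial table)
#'   and `facilitation` (per epoch x delay condition x difficulty x
#'   direction, percent).
#' @export
measure_subject <- function(experiment) {
  stopifnot(inherits(experiment, "probed_experiment"))
  onset <- experiment$resting$onset
  meas <- lapply(experiment$traces, quantify_hreflex, onset_time = onset)
  trials <- experiment$trials
  trials$hreflex_rms <- vapply(meas, `[[`, numeric(1), "rms")
  trials$background_emg <- vapply(meas, `[[`, numeric(1), "background_emg")
  trials <- exclude_trials(trials, list(
    mean = experiment$resting$baseline_mean,
    sd = experiment$resting$baseline_sd
  ))
  kept <- trials[!trials$excluded, ]
  cells <- unique(kept[kept$delay_condition != "unconditioned",
                       c("epoch", "delay_condition", "cue_difficulty",
                         "cue_direction")])
  fac <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    cl <- cells[i, ]
    sel <- kept$epoch == cl$epoch &
      kept$cue_difficulty == cl$cue_difficulty &
      kept$cue_direction == cl$cue_direction
    cond <- kept$hreflex_rms[sel & kept$delay_condition ==
                               cl$delay_condition]
    uncond <- kept$hreflex_rms[sel & kept$delay_condition ==
                                 "unconditioned"]
    cl$facilitation <- facilitation(cond, uncond)
    cl$n_conditioned <- length(cond)
    cl
  }))
  rownames(fac) <- NULL
  fac$subject <- experiment$subject
  list(trials = trials, facilitation = fac)
}

#' Group-level task-epoch analysis of a simulated cohort
#'
#' For every (epoch, delay condition, direction) cell the easy-versus-
#' difficult facilitation difference is tested with a paired t test across
#' subjects; the Bonferroni family is the set of pre-planned comparisons
#' within one direction (epochs x delay conditions), mirroring the
#' per-experiment, per-direction family structure of the protocol.
#' Cue-related modulation (easy/difficult x 100 %) is summarised per cell.
#'
#' @param cohort a `probed_cohort` from [simulate_cohort()] (or a list of
#'   `probed_experiment`s).
#' @param alpha family-wise significance level; default 0.05.
#' @return object of class `facilitation_summary`: `subject_facilitation`
#'   (long per-subject table), `comparisons` (per-cell paired-t table with
#'   Bonferroni flags), `modulation` (per-cell mean cue modulation, %),
#'   `excluded` (per-subject exclusion counts).
#' @export
analyse_task_experiment <- function(cohort, alpha = 0.05) {
  measured <- lapply(cohort, measure_subject)
  fac <- do.call(rbind, lapply(measured, `[[`, "facilitation"))
  excl <- vapply(measured, function(m) sum(m$trials$excluded), integer(1))
  wide_cells <- unique(fac[, c("epoch", "delay_condition",
                               "cue_direction")])
  rows <- lapply(seq_len(nrow(wide_cells)), function(i) {
    cl <- wide_cells[i, ]
    sel <- fac$epoch == cl$epoch &
      fac$delay_condition == cl$delay_condition &
      fac$cue_direction == cl$cue_direction
    easy <- fac[sel & fac$cue_difficulty == "easy", ]
    diff_ <- fac[sel & fac$cue_difficulty == "difficult", ]
    m <- merge(easy[, c("subject", "facilitation")],
               diff_[, c("subject", "facilitation")],
               by = "subject", suffixes = c("_easy", "_difficult"))
    data.frame(
      comparison = sprintf("%s|%s|%s", cl$epoch, cl$delay_condition,
                           cl$cue_direction),
      epoch = cl$epoch, delay_condition = cl$delay_condition,
      cue_direction = cl$cue_direction,
      subject = m$subject, value_a = m$facilitation_easy,
      value_b = m$facilitation_difficult
    )
  })
  long <- do.call(rbind, rows)
  stats <- do.call(rbind, lapply(split(long, long$cue_direction),
                                 function(g) {
    fam <- length(unique(g$comparison))
    compare_conditions(
      g[, c("comparison", "subject", "value_a", "value_b")],
      alpha = alpha, family = fam
    )
  }))
  rownames(stats) <- NULL
  meta <- do.call(rbind, strsplit(stats$comparison, "|", fixed = TRUE))
  stats$epoch <- meta[, 1]
  stats$delay_condition <- meta[, 2]
  stats$cue_direction <- meta[, 3]
  modulation <- do.call(rbind, lapply(split(long, long$comparison),
                                      function(g) {
    data.frame(comparison = g$comparison[1],
               cue_modulation = mean(cue_modulation(g$value_a, g$value_b)))
  }))
  rownames(modulation) <- NULL
  structure(
    list(subject_facilitation = fac, comparisons = stats,
         modulation = modulation, excluded = excl, alpha = alpha),
    class = "facilitation_summary"
  )
}

#' @export
print.facilitation_summary <- function(x, ...) {
  cat("<facilitation_summary>\n")
  sig <- x$comparisons[x$comparisons$significant, "comparison"]
  cat(sprintf("  %d pre-planned comparisons, %d significant after Bonferroni\n",
              nrow(x$comparisons), length(sig)))
  if (length(sig)) cat(paste0("   * ", sig, "\n"), sep = "")
  invisible(x)
}
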