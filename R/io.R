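#' Trial-table schema
#'
#' Column set every persisted trial table must carry. Times are stored in
#' milliseconds (floats); sample indices appear only in trace files, and
#' the `stimulus_sample` column is the explicit bridge between the two
#' clocks.
#'
#' @return character vector of required column names.
#' @export
trial_table_columns <- function() {
  c("trial_id", "epoch", "delay_condition", "delay_ms", "cue_difficulty",
    "cue_direction", "response", "correct", "coherence_pct", "rt_ms",
    "emg_file", "stimulus_sample")
}

#' Write a trial table to CSV
#'
#' @param trials data.frame containing at least [trial_table_columns()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(trials, path) {
  check_trial_table(trials)
  write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Accepts LF or CRLF line endings and quoted fields; errors name any
#' missing schema column.
#'
#' @param path CSV file written by [write_trial_table()].
#' @return data.frame.
#' @export
read_trial_table <- function(path) {
  trials <- read.csv(path, stringsAsFactors = FALSE)
  check_trial_table(trials)
  trials
}

check_trial_table <- function(trials) {
  missing_cols <- setdiff(trial_table_columns(), names(trials))
  if (length(missing_cols)) {
    stop("trial table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  invisible(trials)
}

#' Write EMG traces to a CSV archive
#'
#' Plain-text trace storage: a samples file (one column per trace) plus a
#' metadata file carrying the sampling rate and stimulus/TMS markers (as
#' sample indices).
#'
#' @param traces list of `emg_trace` objects.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_emg_archive <- function(traces, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  samples <- vapply(traces, `[[`, numeric(length(traces[[1]]$samples)),
                    "samples")
  colnames(samples) <- sprintf("trace_%04d", seq_along(traces))
  write.csv(samples, file.path(dir, "samples.csv"), row.names = FALSE)
  meta <- data.frame(
    trace = colnames(samples),
    sampling_rate_khz = vapply(traces, `[[`, numeric(1), "sampling_rate"),
    stimulus_sample = vapply(traces, `[[`, numeric(1), "stimulus_marker"),
    tms_sample = vapply(traces, function(tr) {
      as.numeric(if (is.null(tr$tms_marker)) NA else tr$tms_marker)
    }, numeric(1)),
    units = "uV"
  )
  write.csv(meta, file.path(dir, "metadata.csv"), row.names = FALSE)
  invisible(dir)
}

#' Read an EMG archive written by [write_emg_archive()]
#'
#' @param dir archive directory.
#' @return list of `emg_trace` objects.
#' @export
read_emg_archive <- function(dir) {
  samples <- as.matrix(read.csv(file.path(dir, "samples.csv")))
  meta <- read.csv(file.path(dir, "metadata.csv"), stringsAsFactors = FALSE)
  lapply(seq_len(nrow(meta)), function(i) {
    structure(
      list(samples = unname(samples[, meta$trace[i]]),
           stimulus_marker = meta$stimulus_sample[i],
           tms_marker = if (is.na(meta$tms_sample[i])) NA_integer_ else
             as.integer(meta$tms_sample[i]),
           sampling_rate = meta$sampling_rate_khz[i]),
      class = "emg_trace"
    )
  })
}

#' Run the simulate-and-analyse pipeline
#'
#' Executes the configured stages against freshly simulated data and writes
#' their results plus a run manifest to `out_dir`:
#'
#' * `invitro`: population spike trains, filtered-PSTH first-peak latencies
#'   per site and the Monte Carlo latency test (`invitro_latency.json`).
#' * `invivo`: depth sweep of epidural volleys, D/I1 latency table
#'   (`volley_latencies.csv`) and depth ANOVAs (`invivo_anova.json`).
#' * `efd`: one synthetic subject's two-step search (`efd_result.json`).
#' * `task`: simulated cohort, facilitation summary
#'   (`facilitation_summary.csv`, `task_stats.json`) and the combined
#'   trial table (`trial_table.csv`).
#'
#' The manifest records the root seed, each stage's derived child seed, the
#' package version, the configuration snapshot and MD5 digests of every
#' output file; re-running the same configuration and seed reproduces the
#' outputs bit for bit.
#'
#' @param config named list (or path to a YAML file) with optional elements
#'   `stages` (character subset of invitro/invivo/efd/task), `n_cells`,
#'   `n_shuffles`, `n_subjects`, `trials_per_condition`, `trials_per_delay`,
#'   `volley_trials`.
#' @param seed integer root seed.
#' @param out_dir output directory.
#' @return the manifest, invisibly.
#' @export
run_pipeline <- function(config = list(), seed = 1, out_dir = tempdir()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(stages = c("invitro", "invivo", "efd", "task"),
                   n_cells = 24, n_shuffles = 1000, n_subjects = 5,
                   trials_per_condition = 20, trials_per_delay = 15,
                   volley_trials = 50)
  config <- utils::modifyList(defaults, config)
  bad <- setdiff(config$stages, c("invitro", "invivo", "efd", "task"))
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  stage_seeds <- list()
  emit <- function(object, file) {
    path <- file.path(out_dir, file)
    if (grepl("[.]json$", file)) {
      jsonlite::write_json(object, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, na = "null")
    } else {
      write.csv(object, path, row.names = FALSE)
    }
    outputs <<- c(outputs, path)
    path
  }

  if ("invitro" %in% config$stages) {
    s <- child_seed(seed, "invitro")
    stage_seeds$invitro <- s
    spikes <- simulate_population_spikes(cell_sim_config(),
                                         n_cells = config$n_cells, seed = s)
    lat <- vapply(c("deep", "superficial"), function(site) {
      first_peak_latency(bandpass_psth(compile_population_psth(spikes, site)))
    }, numeric(1))
    mc <- monte_carlo_latency_test(
      psth_by_cell(spikes, "superficial"), psth_by_cell(spikes, "deep"),
      n_shuffles = config$n_shuffles, seed = child_seed(s, "shuffle")
    )
    emit(list(first_peak_latency_ms = as.list(lat),
              superficial_minus_deep_ms = unname(lat["superficial"] -
                                                   lat["deep"]),
              monte_carlo = list(observed_difference = mc$observed_difference,
                                 p_value = mc$p_value,
                                 n_shuffles = mc$n_shuffles)),
         "invitro_latency.json")
  }

  if ("invivo" %in% config$stages) {
    s <- child_seed(seed, "invivo")
    stage_seeds$invivo <- s
    sweep_ <- simulate_volley_sweep(volley_sim_config(),
                                    n_trials = config$volley_trials,
                                    seed = s)
    summ <- summarise_volley_sweep(sweep_)
    emit(summ$latencies, "volley_latencies.csv")
    d_groups <- split(summ$latencies$d_latency, summ$latencies$depth)
    i1_groups <- split(summ$latencies$i1_latency, summ$latencies$depth)
    emit(list(d_wave_anova = one_way_anova(d_groups)[c("F", "p")],
              i1_wave_anova = one_way_anova(i1_groups)[c("F", "p")]),
         "invivo_anova.json")
  }

  if ("efd" %in% config$stages) {
    s <- child_seed(seed, "efd")
    stage_seeds$efd <- s
    pool <- motoneuron_pool(seed = child_seed(s, "pool"))
    res <- simulate_efd_subject(pool, seed = s,
                                trials_per_delay = config$trials_per_delay)
    emit(list(rough_efd_ms = res$rough_efd, fine_efd_ms = res$fine_efd,
              efd_plus_06_ms = res$efd_plus_06,
              edge_warning = res$edge_warning,
              true_coincidence_delay_ms = res$truth),
         "efd_result.json")
    emit(res$fine$per_delay, "efd_fine_per_delay.csv")
  }

  if ("task" %in% config$stages) {
    s <- child_seed(seed, "task")
    stage_seeds$task <- s
    cohort <- simulate_cohort(
      n_subjects = config$n_subjects, seed = s,
      protocol = list(
        epochs = c("cue_onset", "cue_400"),
        delays = c("unconditioned", "efd0", "efd0_p06"),
        difficulties = c("difficult", "easy"),
        directions = c("flexion", "extension"),
        trials_per_condition = config$trials_per_condition
      )
    )
    summary_ <- analyse_task_experiment(cohort)
    trials <- do.call(rbind, lapply(cohort, `[[`, "trials"))
    emit(trials, "trial_table.csv")
    emit(summary_$subject_facilitation, "facilitation_summary.csv")
    emit(list(comparisons = summary_$comparisons,
              modulation = summary_$modulation,
              excluded_trials_per_subject = summary_$excluded),
         "task_stats.json")
  }

  manifest <- list(
    package = "laminaprobe",
    version = as.character(packageVersion("laminaprobe")),
    root_seed = seed, stage_seeds = stage_seeds,
    config = config,
    outputs = lapply(outputs, function(p) {
      list(file = basename(p), md5 = unname(tools::md5sum(p)))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
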