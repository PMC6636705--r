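#' Delay schedule for the rough or fine EFD search stage
#'
#' The rough stage tests TMS-PNS delays from -5 to -2 ms in 0.5 ms steps
#' (7 delays) plus an unconditioned condition, i.e. 8 conditions per block.
#' The fine stage tests 11 delays in 0.1 ms steps spanning 1 ms anchored at
#' the rough-stage result; by default the grid extends towards more negative
#' delays (anchor - 1 ... anchor), with `fine_direction = "positive"`
#' flipping it to (anchor ... anchor + 1).
#'
#' @param stage `"rough"` or `"fine"`.
#' @param anchor rough-stage earliest facilitation, ms (fine stage only).
#' @param trials_per_delay trials (blocks) per delay; default 15.
#' @param fine_direction anchoring direction of the fine grid.
#' @return object of class `delay_schedule`: `stage`, `delays` (ms,
#'   ascending, i.e. most negative first), `trials_per_delay`,
#'   `includes_unconditioned`.
#' @export
delay_schedule <- function(stage = c("rough", "fine"), anchor = NULL,
                           trials_per_delay = 15,
                           fine_direction = c("negative", "positive")) {
  stage <- match.arg(stage)
  fine_direction <- match.arg(fine_direction)
  delays <- if (stage == "rough") {
    seq(-5, -2, by = 0.5)
  } else {
    if (is.null(anchor)) {
      stop("fine schedule needs the rough-stage `anchor`", call. = FALSE)
    }
    if (fine_direction == "negative") {
      seq(anchor - 1, anchor, by = 0.1)
    } else {
      seq(anchor, anchor + 1, by = 0.1)
    }
  }
  structure(
    list(stage = stage, delays = round(delays, 10),
         trials_per_delay = trials_per_delay,
         includes_unconditioned = TRUE),
    class = "delay_schedule"
  )
}

#' Earliest facilitated delay under the consecutive-significance criterion
#'
#' Scans delays from the most negative upwards. A delay qualifies as the
#' earliest facilitation when its conditioned H-reflex RMS is significantly
#' higher than the unconditioned RMS (paired t test by block, p < `alpha`,
#' uncorrected) AND the two subsequent less-negative scheduled delays are
#' also significantly higher. The three-delay rule is the procedure's own
#' multiplicity guard, so individual p values stay uncorrected by design.
#' When a qualifying delay sits so close to the schedule edge that fewer
#' than two successors exist, the remaining successors must all be
#' significant and the result carries `edge_warning = TRUE`.
#'
#' @param cond data.frame of conditioned trials with columns `block`,
#'   `delay_ms`, `rms`.
#' @param uncond data.frame of unconditioned trials with columns `block`,
#'   `rms` (one trial per block; paired design).
#' @param schedule the [delay_schedule()] that generated the data.
#' @param alpha significance level; default 0.05.
#' @return list of class `facilitation_search`: `found`, `delay` (ms or NA),
#'   `edge_warning`, and `per_delay` (delay, mean conditioned and
#'   unconditioned RMS, paired-t p, significant flag).
#' @export
find_earliest_facilitation <- function(cond, uncond, schedule,
                                       alpha = 0.05) {
  stopifnot(inherits(schedule, "delay_schedule"),
            all(c("block", "delay_ms", "rms") %in% names(cond)),
            all(c("block", "rms") %in% names(uncond)))
  delays <- schedule$delays
  u <- uncond$rms[order(uncond$block)]
  if (length(u) < 2) stop("fewer than 2 unconditioned trials", call. = FALSE)
  per_delay <- do.call(rbind, lapply(delays, function(d) {
    g <- cond[abs(cond$delay_ms - d) < 1e-9, ]
    g <- g[order(g$block), ]
    if (nrow(g) < 2) stop("fewer than 2 trials at delay ", d, call. = FALSE)
    if (nrow(g) != length(u)) {
      stop("unpaired design: trial counts differ between conditioned and ",
           "unconditioned conditions", call. = FALSE)
    }
    dif <- g$rms - u
    p <- if (sd(dif) < .Machine$double.eps) {
      if (mean(dif) == 0) 1 else 0
    } else {
      t.test(g$rms, u, paired = TRUE)$p.value
    }
    data.frame(delay_ms = d, mean_conditioned = mean(g$rms),
               mean_unconditioned = mean(u), p = p,
               significant = p < alpha & mean(dif) > 0)
  }))
  found <- FALSE
  hit <- NA_real_
  edge <- FALSE
  nd <- length(delays)
  for (i in seq_len(nd)) {
    if (!per_delay$significant[i]) next
    succ <- seq(i + 1, length.out = min(2, nd - i))
    if (all(per_delay$significant[succ])) {
      found <- TRUE
      hit <- delays[i]
      edge <- length(succ) < 2
      break
    }
  }
  structure(
    list(found = found, delay = hit, edge_warning = edge,
         per_delay = per_delay, alpha = alpha, stage = schedule$stage),
    class = "facilitation_search"
  )
}

#' Two-step (rough then fine) search for the earliest facilitation delay
#'
#' Runs the rough stage, anchors the fine 0.1 ms grid at its earliest
#' facilitation, runs the fine stage with the same criterion, and
#' designates the fine-stage earliest facilitation EFD 0 ms. The delay
#' probing the later volley component is EFD 0 ms + 0.6 ms.
#'
#' @param acquire function taking a [delay_schedule()] and returning the
#'   stage's trial data as a list with `cond` and `uncond` data.frames (see
#'   [find_earliest_facilitation()]), e.g. a wrapper around
#'   [simulate_efd_stage()] or a loader of recorded tables.
#' @param alpha significance level for both stages.
#' @param trials_per_delay blocks per stage; default 15.
#' @param fine_direction fine-grid anchoring direction, see
#'   [delay_schedule()].
#' @return object of class `efd_result`: `rough_efd`, `fine_efd` (EFD 0 ms),
#'   `efd_plus_06`, `edge_warning`, and the per-stage
#'   `facilitation_search` objects under `rough` and `fine`.
#' @export
run_two_step_search <- function(acquire, alpha = 0.05,
                                trials_per_delay = 15,
                                fine_direction = c("negative", "positive")) {
  fine_direction <- match.arg(fine_direction)
  rough_sched <- delay_schedule("rough", trials_per_delay = trials_per_delay)
  rough_data <- acquire(rough_sched)
  rough <- find_earliest_facilitation(rough_data$cond, rough_data$uncond,
                                      rough_sched, alpha)
  if (!rough$found) {
    stop("rough search found no earliest facilitation; cannot anchor the ",
         "fine stage", call. = FALSE)
  }
  fine_sched <- delay_schedule("fine", anchor = rough$delay,
                               trials_per_delay = trials_per_delay,
                               fine_direction = fine_direction)
  fine_data <- acquire(fine_sched)
  fine <- find_earliest_facilitation(fine_data$cond, fine_data$uncond,
                                     fine_sched, alpha)
  fine_efd <- if (fine$found) fine$delay else rough$delay
  structure(
    list(rough_efd = rough$delay, fine_efd = fine_efd,
         efd_plus_06 = fine_efd + 0.6,
         edge_warning = rough$edge_warning || fine$edge_warning ||
           !fine$found,
         fine_found = fine$found, rough = rough, fine = fine),
    class = "efd_result"
  )
}

#' @export
print.efd_result <- function(x, ...) {
  cat(sprintf(
    "<efd_result> rough %.1f ms, EFD 0 ms = %.1f ms (EFD +0.6 ms = %.1f ms)%s\n",
    x$rough_efd, x$fine_efd, x$efd_plus_06,
    if (x$edge_warning) " [edge warning]" else ""
  ))
  invisible(x)
}

#' Simulate one stage of the EFD search protocol
#'
#' Runs `trials_per_delay` randomized blocks; each block tests every
#' scheduled delay plus one unconditioned trial, in random order. H-reflex
#' RMS is quantified with the stage's (or a supplied) onset.
#'
#' @param pool a [motoneuron_pool()].
#' @param schedule a [delay_schedule()].
#' @param seed integer seed.
#' @param gains circuit gains, see [simulate_conditioning_trial()].
#' @param onset onset in ms post-stimulus; `NULL` detects it from this
#'   stage's unconditioned traces.
#' @return list with `cond`, `uncond` (data.frames for
#'   [find_earliest_facilitation()]) and `onset`.
#' @export
simulate_efd_stage <- function(pool, schedule, seed = NULL,
                               gains = c(deep_early = 1,
                                         superficial_late = 1,
                                         later_waves = 1),
                               onset = NULL) {
  stopifnot(inherits(schedule, "delay_schedule"))
  nb <- schedule$trials_per_delay
  delays <- schedule$delays
  local_seed(seed, {
    uncond_traces <- vector("list", nb)
    rows_c <- list()
    rows_u <- list()
    for (b in seq_len(nb)) {
      conditions <- sample(c(delays, NA)) # NA = unconditioned
      for (d in conditions) {
        trial <- simulate_conditioning_trial(
          pool, delay = if (is.na(d)) NULL else d, gains = gains
        )
        if (is.na(d)) {
          uncond_traces[[b]] <- trial$trace
          rows_u[[length(rows_u) + 1L]] <-
            list(block = b, trace = trial$trace)
        } else {
          rows_c[[length(rows_c) + 1L]] <-
            list(block = b, delay_ms = d, trace = trial$trace)
        }
      }
    }
    if (is.null(onset)) onset <- detect_onset(uncond_traces)
    cond <- do.call(rbind, lapply(rows_c, function(r) {
      data.frame(block = r$block, delay_ms = r$delay_ms,
                 rms = quantify_hreflex(r$trace, onset)$rms)
    }))
    uncond <- do.call(rbind, lapply(rows_u, function(r) {
      data.frame(block = r$block,
                 rms = quantify_hreflex(r$trace, onset)$rms)
    }))
    list(cond = cond, uncond = uncond, onset = onset)
  })
}

#' Simulate a full two-step EFD search for one synthetic subject
#'
#' Convenience wrapper: the H-reflex onset is detected once from the rough
#' stage's unconditioned traces and reused for the fine stage, matching the
#' single-onset-per-dataset convention.
#'
#' @param pool a [motoneuron_pool()]; its `coincidence_delay` is the
#'   ground-truth EFD 0 ms.
#' @param seed integer root seed (per-stage child seeds are derived).
#' @param alpha significance level.
#' @param trials_per_delay blocks per stage.
#' @param fine_direction see [delay_schedule()].
#' @return an `efd_result` with an extra `truth` element
#'   (= `pool$coincidence_delay`).
#' @export
simulate_efd_subject <- function(pool, seed = 1, alpha = 0.05,
                                 trials_per_delay = 15,
                                 fine_direction = "negative") {
  onset_env <- new.env()
  acquire <- function(schedule) {
    res <- simulate_efd_stage(
      pool, schedule,
      seed = child_seed(seed, paste0("efd-", schedule$stage)),
      onset = if (schedule$stage == "fine") onset_env$onset else NULL
    )
    if (schedule$stage == "rough") onset_env$onset <- res$onset
    res
  }
  out <- run_two_step_search(acquire, alpha = alpha,
                             trials_per_delay = trials_per_delay,
                             fine_direction = fine_direction)
  out$truth <- pool$coincidence_delay
  out
}
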