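#' Configuration for the adaptive dot-motion task simulation
#'
#' A simulated observer discriminates the net motion direction of a random
#' dot kinematogram. The observer's probability of a correct choice is a
#' lapse-adjusted logistic function of motion coherence,
#' \deqn{P(c) = 0.5 + (0.5 - \lambda)\,\mathrm{logistic}((c - c_{50})/s),}
#' optionally with a slow practice drift that lowers \eqn{c_{50}} over
#' trials (an improving observer). Two independent weighted up/down
#' staircases - one per difficulty - adjust coherence every trial towards
#' the target accuracies: after a correct response coherence decreases by
#' `step * (1 - target)`, after an error it increases by `step * target`,
#' which equilibrates where the observer's accuracy equals the target.
#'
#' @param targets named accuracy targets in (0.5, 1);
#'   default `c(difficult = 0.55, easy = 0.80)`.
#' @param step staircase step scale, coherence percentage points.
#' @param start_coherence starting coherence per difficulty, %.
#' @param observer list with `c50`, `slope` (> 0), `lapse` in `[0, 0.5)`,
#'   and `drift` (c50 decrease per trial, emulating practice).
#' @param n_trials total trials across both difficulties.
#' @param coherence_range clipping range, %; default `c(0, 100)`.
#' @return object of class `task_sim_config`.
#' @export
task_sim_config <- function(targets = c(difficult = 0.55, easy = 0.80),
                            step = 1.5,
                            start_coherence = c(difficult = 15, easy = 50),
                            observer = list(c50 = 25, slope = 8,
                                            lapse = 0.01, drift = 0),
                            n_trials = 4000,
                            coherence_range = c(0, 100)) {
  stopifnot(all(targets > 0.5 & targets < 1),
            all(c("difficult", "easy") %in% names(targets)))
  if (observer$slope <= 0) stop("observer slope must be > 0", call. = FALSE)
  if (n_trials < 1) stop("`n_trials` must be >= 1", call. = FALSE)
  structure(
    list(targets = targets, step = step, start_coherence = start_coherence,
         observer = observer, n_trials = n_trials,
         coherence_range = coherence_range),
    class = "task_sim_config"
  )
}

observer_p_correct <- function(observer, coherence, trial = 1) {
  c50 <- observer$c50 - observer$drift * (trial - 1)
  0.5 + (0.5 - observer$lapse) * plogis((coherence - c50) / observer$slope)
}

#' Simulate an adaptive staircase session of the dot-motion task
#'
#' Difficulties are interleaved at random (50/50); each difficulty's
#' staircase updates after every one of its trials. Long-run accuracy per
#' difficulty converges to the configured targets within Monte Carlo error.
#'
#' @param config a [task_sim_config()].
#' @param seed integer seed or NULL.
#' @return list of class `staircase_session`: `trials` (data.frame with
#'   `trial`, `difficulty`, `coherence_pct`, `direction`, `response`,
#'   `correct`) and `state` (per-trial staircase coherence history per
#'   difficulty).
#' @export
simulate_staircase_session <- function(config = task_sim_config(),
                                       seed = NULL) {
  stopifnot(inherits(config, "task_sim_config"))
  obs <- config$observer
  lo <- config$coherence_range[1]
  hi <- config$coherence_range[2]
  for (d in names(config$targets)) {
    p_hi <- observer_p_correct(obs, hi)
    if (p_hi < config$targets[d]) {
      stop(sprintf(
        "target %.2f unreachable: observer tops out at %.2f within the coherence range",
        config$targets[d], p_hi), call. = FALSE)
    }
  }
  n <- config$n_trials
  local_seed(seed, {
    coh <- config$start_coherence
    difficulty <- sample(c("difficult", "easy"), n, replace = TRUE)
    direction <- sample(c("left", "right"), n, replace = TRUE)
    coherence <- numeric(n)
    correct <- logical(n)
    state <- matrix(NA_real_, nrow = n, ncol = 2,
                    dimnames = list(NULL, c("difficult", "easy")))
    for (i in seq_len(n)) {
      d <- difficulty[i]
      coherence[i] <- coh[d]
      p <- observer_p_correct(obs, coh[d], trial = i)
      correct[i] <- runif(1) < p
      tgt <- config$targets[d]
      coh[d] <- coh[d] +
        if (correct[i]) -config$step * (1 - tgt) else config$step * tgt
      coh[d] <- min(max(coh[d], lo), hi)
      state[i, ] <- coh
    }
    response <- ifelse(correct, direction,
                       ifelse(direction == "left", "right", "left"))
    structure(
      list(trials = data.frame(trial = seq_len(n), difficulty = difficulty,
                               coherence_pct = coherence,
                               direction = direction, response = response,
                               correct = correct),
           state = state, config = config),
      class = "staircase_session"
    )
  })
}

#' Accuracy of a staircase session by difficulty
#'
#' @param session a `staircase_session`.
#' @param last keep only each difficulty's last `last` trials (NULL = all).
#' @return named numeric vector of proportions correct.
#' @export
staircase_accuracy <- function(session, last = NULL) {
  tr <- session$trials
  vapply(split(tr, tr$difficulty), function(g) {
    if (!is.null(last)) g <- tail(g, last)
    mean(g$correct)
  }, numeric(1))
}
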