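test_that("background-EMG exclusion applies the mean + 2 SD threshold exactly", {
  baseline <- list(mean = 10, sd = 2)
  trials <- data.frame(trial_id = 1:5,
                       background_emg = c(10, 10, 10, 15, 10))
  out <- exclude_trials(trials, baseline)
  expect_equal(out$excluded, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$exclusion_reason[4], "background_emg")
  # exactly at the threshold is kept; infinitesimally above is excluded
  edge <- exclude_trials(data.frame(background_emg = c(14, 14 + 1e-9)),
                         baseline)
  expect_equal(edge$excluded, c(FALSE, TRUE))
  # idempotence: re-running on the kept set removes nothing
  kept <- out[!out$excluded, ]
  expect_false(any(exclude_trials(kept, baseline)$excluded))
  expect_error(exclude_trials(data.frame(x = 1), baseline), "background_emg")
  expect_error(exclude_trials(data.frame(background_emg = NA), baseline),
               "missing")
})

test_that("contaminated trials are flagged at roughly the configured rate", {
  pool <- motoneuron_pool(seed = 2)
  exp_ <- simulate_experiment(
    pool,
    protocol = list(epochs = "cue_400",
                    delays = c("unconditioned", "efd0"),
                    difficulties = c("difficult", "easy"),
                    directions = "flexion", trials_per_condition = 15),
    contamination = 0.1, seed = 3
  )
  m <- measure_subject(exp_)
  n <- nrow(m$trials)
  # every contaminated trial must be excluded ...
  expect_true(all(m$trials$excluded[m$trials$contaminated]))
  # ... and the total count stays near the contamination expectation plus
  # the ~2.3 % false-positive rate of a 2 SD threshold
  expect_lt(abs(sum(m$trials$contaminated) - 0.1 * n), 4 * sqrt(0.1 * n))
  expect_lt(sum(m$trials$excluded) - sum(m$trials$contaminated), 0.1 * n)
})

test_that("reaction time implements the sustained 4 SD rule", {
  set.seed(1)
  base <- rnorm(8000, 0, 4)
  tr <- list(samples = base, fixation_offset_sample = 2000,
             sampling_rate = 10)
  step <- tr
  step$samples[4001:8000] <- step$samples[4001:8000] + 40 # +10 SD at +200 ms
  expect_equal(reaction_time(step), 200, tolerance = 1)
  expect_true(is.na(reaction_time(tr)))
  expect_error(reaction_time(list(samples = base,
                                  fixation_offset_sample = NULL,
                                  sampling_rate = 10)), "marker")

  # generator round trip: drawn RTs are recovered and easy < difficult
  rts <- list(easy = rnorm(30, 175, 20), difficult = rnorm(30, 225, 25))
  rec <- lapply(names(rts), function(d) {
    vapply(seq_along(rts[[d]]), function(i) {
      reaction_time(simulate_movement_trace(rts[[d]][i], seed = i))
    }, numeric(1))
  })
  names(rec) <- names(rts)
  expect_equal(mean(rec$easy), mean(rts$easy), tolerance = 0.05)
  expect_lt(mean(rec$easy), mean(rec$difficult))
})

test_that("facilitation and cue modulation follow their ratio definitions", {
  expect_equal(facilitation(c(2, 2, 2), c(2, 2)), 100)
  expect_equal(facilitation(c(3, 3), c(2, 2)), 150)
  expect_error(facilitation(numeric(0), 1), "non-empty")
  expect_error(facilitation(1, c(0, 0)), "> 0")
  # scale invariance
  set.seed(2)
  a <- runif(10, 5, 15); b <- runif(10, 5, 15)
  expect_equal(facilitation(a * 7, b * 7), facilitation(a, b))
  expect_equal(cue_modulation(130, 104), 125)
  expect_equal(cue_modulation(110, 110), 100)
  expect_error(cue_modulation(1, 0), "> 0")
})

test_that("null conditioning keeps group facilitation near 100 %", {
  comp <- data.frame(circuit = "deep_early", arrival_offset = 0, strength = 0)
  fac <- vapply(1:40, function(s) {
    pool <- motoneuron_pool(volley_components = comp, seed = s)
    base <- 100000 * s # disjoint trial-seed blocks per simulated subject
    onset <- detect_onset(lapply(1:6, function(i) {
      simulate_conditioning_trial(pool, seed = base + i)$trace
    }))
    cond <- vapply(1:10, function(i) quantify_hreflex(
      simulate_conditioning_trial(pool, delay = -3,
                                  seed = base + 100 + i)$trace,
      onset)$rms, numeric(1))
    uncond <- vapply(1:10, function(i) quantify_hreflex(
      simulate_conditioning_trial(pool, seed = base + 200 + i)$trace,
      onset)$rms, numeric(1))
    facilitation(cond, uncond)
  }, numeric(1))
  expect_lt(abs(mean(fac) - 100), 2)
})

test_that("paired comparisons match the textbook t formula and Bonferroni", {
  # identical paired vectors: t = 0, p = 1
  d0 <- data.frame(comparison = "a", subject = 1:5,
                   value_a = c(1, 2, 3, 4, 5), value_b = c(1, 2, 3, 4, 5))
  r0 <- compare_conditions(d0)
  expect_equal(r0$t, 0)
  expect_equal(r0$p_raw, 1)

  # brute-force oracle on a 5-pair example
  va <- c(12.1, 9.8, 11.4, 10.9, 13.0)
  vb <- c(10.0, 10.2, 10.8, 9.5, 11.1)
  d <- va - vb
  t_oracle <- mean(d) / (sd(d) / sqrt(5))
  p_oracle <- 2 * stats::pt(-abs(t_oracle), df = 4)
  r <- compare_conditions(data.frame(comparison = "x", subject = 1:5,
                                     value_a = va, value_b = vb))
  expect_equal(r$t, t_oracle, tolerance = 1e-10)
  expect_equal(r$p_raw, p_oracle, tolerance = 1e-10)

  # Bonferroni worked case: raw p ~ 0.026 in a family of 4 is not
  # significant (0.026 > 0.05 / 4)
  z <- scale(seq_len(13))[, 1]
  delta <- uniroot(function(m) {
    t.test(z + m, rep(0, 13), paired = TRUE)$p.value - 0.026
  }, c(0.01, 3), tol = 1e-12)$root
  worked <- compare_conditions(
    data.frame(comparison = "efd0_delay_epoch", subject = 1:13,
               value_a = z + delta, value_b = 0),
    family = 4
  )
  expect_equal(worked$p_raw, 0.026, tolerance = 1e-6)
  expect_false(worked$significant)
  # the same p in a family of 1 would have been significant
  expect_true(compare_conditions(
    data.frame(comparison = "solo", subject = 1:13,
               value_a = z + delta, value_b = 0), family = 1
  )$significant)

  expect_error(compare_conditions(data.frame(
    comparison = "a", subject = 1:2, value_a = 1:2, value_b = 2:3
  )), ">= 3 subjects")
})
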