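test_that("rough and fine schedules have the protocol cardinalities", {
  rough <- delay_schedule("rough")
  expect_equal(rough$delays, seq(-5, -2, by = 0.5))
  expect_length(rough$delays, 7)
  expect_true(rough$includes_unconditioned)
  # a block therefore tests 7 delays + 1 unconditioned = 8 conditions
  expect_equal(length(rough$delays) + 1, 8)

  fine <- delay_schedule("fine", anchor = -3.5)
  expect_equal(fine$delays, seq(-4.5, -3.5, by = 0.1))
  expect_length(fine$delays, 11)
  fine_pos <- delay_schedule("fine", anchor = -3.5,
                             fine_direction = "positive")
  expect_equal(fine_pos$delays, seq(-3.5, -2.5, by = 0.1))
  expect_error(delay_schedule("fine"), "anchor")
})

test_that("H-reflex RMS follows the onset-zeroed 0.5 ms window arithmetic", {
  samples <- rep(0, 2000)
  s0 <- 1001 + 165 # stimulus at sample 1001, onset at 16.5 ms
  samples[s0:(s0 + 4)] <- c(0, 3, -4, 0, 0)
  tr <- make_emg_trace(samples)
  m <- quantify_hreflex(tr, 16.5)
  expect_equal(m$rms, sqrt(5))
  expect_equal(m$background_emg, 0)

  # constant trace: zeroing at onset removes the offset entirely
  trc <- make_emg_trace(rep(7, 2000))
  expect_equal(quantify_hreflex(trc, 16.5)$rms, 0)
  expect_equal(quantify_hreflex(trc, 16.5)$background_emg, 7)

  expect_error(quantify_hreflex(make_emg_trace(rep(0, 1100)), 16.5),
               "exceeds the trace")
})

test_that("onset detection finds the reflex start and honours overrides", {
  pool <- motoneuron_pool(conduction_sd = 0, seed = 1)
  traces <- lapply(1:10, function(i) {
    simulate_conditioning_trial(pool, seed = i)$trace
  })
  onset <- detect_onset(traces)
  expect_lt(abs(onset - pool$conduction_mean), 0.2)

  flat <- lapply(1:6, function(i) {
    make_emg_trace(rnorm(2000, 0, 3))
  })
  expect_error(detect_onset(flat), "manual onset")
  expect_equal(as.numeric(detect_onset(flat, override = 16.3)), 16.3)
  expect_error(detect_onset(traces[1:3]), "at least 5")
})

test_that("the earliest facilitation needs two significant successors", {
  sched <- delay_schedule("rough")
  # facilitation from -3.5 onward -> earliest = -3.5
  tabs <- make_efd_tables(sched$delays, facilitated = c(-3.5, -3, -2.5, -2),
                          seed = 1)
  res <- find_earliest_facilitation(tabs$cond, tabs$uncond, sched)
  expect_true(res$found)
  expect_equal(res$delay, -3.5)
  expect_false(res$edge_warning)

  # a single significant delay with non-significant successors -> none
  tabs2 <- make_efd_tables(sched$delays, facilitated = -4, seed = 2)
  res2 <- find_earliest_facilitation(tabs2$cond, tabs2$uncond, sched)
  expect_false(res2$found)
  expect_true(is.na(res2$delay))

  # facilitation only from the edge delay -2.5: one successor available,
  # accepted with an edge warning
  tabs3 <- make_efd_tables(sched$delays, facilitated = c(-2.5, -2), seed = 3)
  res3 <- find_earliest_facilitation(tabs3$cond, tabs3$uncond, sched)
  expect_true(res3$found)
  expect_equal(res3$delay, -2.5)
  expect_true(res3$edge_warning)

  # suppression (conditioned < unconditioned) never counts as facilitation
  tabs4 <- make_efd_tables(sched$delays, facilitated = NULL, effect = 0,
                           seed = 4)
  tabs4$cond$rms <- tabs4$cond$rms - 5
  res4 <- find_earliest_facilitation(tabs4$cond, tabs4$uncond, sched)
  expect_false(res4$found)
})

test_that("null data rarely produce a spurious earliest facilitation", {
  sched <- delay_schedule("rough")
  hits <- vapply(1:60, function(s) {
    tabs <- make_efd_tables(sched$delays, facilitated = NULL, effect = 0,
                            seed = 100 + s)
    find_earliest_facilitation(tabs$cond, tabs$uncond, sched)$found
  }, logical(1))
  expect_lt(mean(hits), 0.05)
})

test_that("two-step search recovers the true coincidence onset to 0.1 ms", {
  pool <- motoneuron_pool(coincidence_delay = -3.73, seed = 3)
  res <- simulate_efd_subject(pool, seed = 11)
  expect_equal(res$rough_efd, -3.5)
  expect_equal(res$fine_efd, -3.7)
  expect_equal(res$efd_plus_06, -3.1)
  expect_gte(res$fine_efd, res$rough_efd - 1)
  expect_lte(res$fine_efd, res$rough_efd)

  # determinism across identical runs
  res2 <- simulate_efd_subject(pool, seed = 11)
  expect_identical(res$fine_efd, res2$fine_efd)

  # a pool with no descending effect aborts at the rough stage
  comp <- data.frame(circuit = "deep_early", arrival_offset = 0,
                     strength = 0)
  null_pool <- motoneuron_pool(volley_components = comp, seed = 5)
  expect_error(simulate_efd_subject(null_pool, seed = 1),
               "no earliest facilitation")
})
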