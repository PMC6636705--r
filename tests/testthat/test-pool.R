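noiseless_pool <- function(...) {
  motoneuron_pool(drive_noise_sd = 0, unit_jitter_sd = 0, emg_noise_sd = 0,
                  ...)
}

test_that("unconditioned recruitment sits in the 15-25 % H/Mmax band", {
  for (s in 1:5) {
    pool <- motoneuron_pool(seed = s)
    expect_gte(h_over_mmax(pool), 0.15)
    expect_lte(h_over_mmax(pool), 0.25)
  }
})

test_that("null conditioning is indistinguishable from unconditioned trials", {
  comp <- data.frame(circuit = c("deep_early", "superficial_late"),
                     arrival_offset = c(0, 0.6), strength = c(0, 0))
  pool <- motoneuron_pool(volley_components = comp, seed = 1)
  cond <- simulate_conditioning_trial(pool, delay = -3.0, seed = 7)
  uncond <- simulate_conditioning_trial(pool, seed = 7)
  expect_identical(cond$trace$samples, uncond$trace$samples)
  expect_identical(cond$record$recruited, uncond$record$recruited)
})

test_that("a delay before the earliest coincidence leaves the H-reflex untouched", {
  pool <- noiseless_pool(coincidence_delay = -3.5, seed = 1)
  early <- simulate_conditioning_trial(pool, delay = -4.0, seed = 1)
  uncond <- simulate_conditioning_trial(pool, seed = 1)
  expect_identical(early$record$recruited, uncond$record$recruited)
  at0 <- simulate_conditioning_trial(pool, delay = -3.5, seed = 1)
  expect_gt(at0$record$recruited, uncond$record$recruited)
})

test_that("recruitment grows monotonically as the delay becomes less negative", {
  pool <- noiseless_pool(coincidence_delay = -3.5, seed = 2)
  rec <- vapply(seq(-5, -0.5, by = 0.1), function(d) {
    simulate_conditioning_trial(pool, delay = d, seed = 1)$record$recruited
  }, numeric(1))
  expect_true(all(diff(rec) >= 0))
  expect_lte(max(rec), pool$n_units)
})

test_that("recruitment is monotone in afferent and circuit strengths", {
  recs <- vapply(seq(0.5, 1.1, by = 0.1), function(a) {
    p <- noiseless_pool(afferent_strength = a, seed = 3)
    simulate_conditioning_trial(p, seed = 1)$record$recruited
  }, numeric(1))
  expect_true(all(diff(recs) >= 0))

  # doubling the superficial-late gain recruits more units at EFD +0.6,
  # but cannot act at EFD 0 where that component has not yet arrived
  pool <- noiseless_pool(coincidence_delay = -3.5, seed = 1)
  g1 <- c(deep_early = 1, superficial_late = 1, later_waves = 1)
  g2 <- c(deep_early = 1, superficial_late = 2, later_waves = 1)
  at_p06 <- function(g) simulate_conditioning_trial(
    pool, delay = -2.9, gains = g, seed = 1)$record$recruited
  at_0 <- function(g) simulate_conditioning_trial(
    pool, delay = -3.5, gains = g, seed = 1)$record$recruited
  expect_gt(at_p06(g2), at_p06(g1))
  expect_identical(at_0(g2), at_0(g1))
})

test_that("trial simulation is seed-deterministic and validates input", {
  pool <- motoneuron_pool(seed = 1)
  a <- simulate_conditioning_trial(pool, delay = -3, seed = 5)
  b <- simulate_conditioning_trial(pool, delay = -3, seed = 5)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_error(simulate_conditioning_trial(pool, gains = c(deep_early = 0)),
               "gains")
  expect_error(motoneuron_pool(n_units = 10), "n_units")
})

test_that("EMG amplitude scales linearly with recruited count when MUAPs align", {
  # with zero conduction spread all MUAPs superimpose exactly, so the
  # H-reflex peak is (recruited count) x (kernel peak)
  peaks <- vapply(c(0.7, 0.9, 1.1), function(a) {
    p <- noiseless_pool(afferent_strength = a, conduction_sd = 0, seed = 4)
    trial <- simulate_conditioning_trial(p, seed = 1)
    h_window <- trial$trace$samples[(trial$trace$stimulus_marker + 120):
                                      (trial$trace$stimulus_marker + 250)]
    c(max(h_window), trial$record$recruited)
  }, numeric(2))
  per_unit <- peaks[1, ] / peaks[2, ]
  expect_lt(diff(range(per_unit)) / mean(per_unit), 1e-9)
})

test_that("H-reflex RMS increases with the number of recruited units", {
  # one onset per dataset, as in the protocol: detect it on the reference
  # condition and reuse it across the strength grid
  grid <- seq(0.6, 1.1, by = 0.1)
  ref <- simulate_conditioning_trial(
    noiseless_pool(afferent_strength = grid[1], seed = 4), seed = 1)$trace
  onset <- detect_onset(replicate(5, ref, simplify = FALSE))
  res <- vapply(grid, function(a) {
    p <- noiseless_pool(afferent_strength = a, seed = 4)
    trial <- simulate_conditioning_trial(p, seed = 1)
    c(rms = quantify_hreflex(trial$trace, onset)$rms,
      recruited = trial$record$recruited)
  }, numeric(2))
  expect_true(all(diff(res["recruited", ]) > 0))
  expect_true(all(diff(res["rms", ]) > 0))
})
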