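test_that("EPSP kernel respects amplitude, zero case and validation", {
  k <- epsp_kinetics(amplitude = 4, rise_tau = 1.4, decay_tau = 16,
                     onset_latency = 1)
  tr <- simulate_epsp_trace(k, noise_sd = 0)
  expect_equal(tr$voltage[1], 0)
  expect_lt(abs(max(tr$voltage) - 4) / 4, 0.01)

  k0 <- epsp_kinetics(amplitude = 0, rise_tau = 1.4, decay_tau = 16,
                      onset_latency = 1)
  expect_true(all(simulate_epsp_trace(k0)$voltage == 0))

  expect_error(epsp_kinetics(4, rise_tau = 5, decay_tau = 5, 1),
               "strictly smaller")
  expect_error(simulate_epsp_trace(k, duration = -1), "positive")
})

test_that("alpha-kernel limit: peak time tends to onset + rise_tau", {
  # closed form: t * exp(1 - t/tau) peaks at t = tau; the difference of
  # exponentials approaches the alpha kernel as decay -> rise
  errs <- vapply(c(0.1, 0.01, 0.001), function(eps) {
    k <- epsp_kinetics(amplitude = 1, rise_tau = 2, decay_tau = 2 + eps,
                       onset_latency = 1)
    tr <- simulate_epsp_trace(k, duration = 30, dt = 0.001)
    peak_num <- tr$time[which.max(tr$voltage)]
    abs(peak_num - (1 + 2))
  }, numeric(1))
  expect_lt(errs[3], 0.01)
  expect_true(all(diff(errs) < 0))
  # and the analytic formula agrees with the numeric argmax
  k <- epsp_kinetics(1, 1.4, 16, 1)
  tr <- simulate_epsp_trace(k, duration = 40, dt = 0.001)
  expect_equal(tr$time[which.max(tr$voltage)], epsp_peak_time(k),
               tolerance = 1e-3)
})

test_that("measure_epsp reports amplitude, peak time and the 2-12 ms derivative", {
  k <- default_epsp_kinetics()$deep
  m <- measure_epsp(simulate_epsp_trace(k))
  expect_true(m$has_peak)
  expect_equal(m$peak_time, epsp_peak_time(k), tolerance = 0.05)
  expect_equal(m$amplitude, k$amplitude, tolerance = 0.1)
  expect_equal(range(m$derivative$time), c(2, 12), tolerance = 0.05)

  flat <- list(time = seq(0, 80, 0.1), voltage = rep(2, 801))
  mf <- measure_epsp(flat)
  expect_identical(mf$amplitude, 0)
  expect_true(is.na(mf$peak_time))
  expect_false(mf$has_peak)

  short <- list(time = seq(0, 50, 0.1), voltage = rep(0, 501))
  expect_error(measure_epsp(short), "70 ms")
})

test_that("default calibration yields a 2.0 ms analytic peak-time split", {
  k <- default_epsp_kinetics()
  expect_equal(epsp_peak_time(k$superficial) - epsp_peak_time(k$deep), 2.0,
               tolerance = 1e-8)
  expect_gt(k$superficial$rise_tau, k$deep$rise_tau)
})

test_that("passive properties are recovered from current-step responses", {
  rc <- simulate_rc_response(100, 15, 0.1)
  p <- measure_passive(rc, 0.1)
  expect_equal(p$input_resistance, 100, tolerance = 0.01)
  expect_equal(p$membrane_time_constant, 15, tolerance = 0.02)

  # doubling the current doubles the deflection but not the resistance
  rc2 <- simulate_rc_response(100, 15, 0.05)
  p2 <- measure_passive(rc2, 0.05)
  expect_equal(p2$input_resistance, p$input_resistance, tolerance = 0.01)

  # simulation oracle: median recovered tau over noisy repeats within 5 %
  taus <- vapply(seq_len(50), function(s) {
    rcn <- simulate_rc_response(100, 15, 0.1, noise_sd = 0.1, seed = s)
    measure_passive(rcn, 0.1)$membrane_time_constant
  }, numeric(1))
  expect_lt(abs(median(taus) - 15) / 15, 0.05)

  # large deflections are outside the intended linear range
  expect_warning(measure_passive(simulate_rc_response(200, 15, 0.1), 0.1),
                 "10 mV")
})
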