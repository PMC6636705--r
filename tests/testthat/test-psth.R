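test_that("PSTH compilation normalizes by trials and averages cells equally", {
  one <- make_spike_set(list(list(deep = list(2.05), superficial = list())),
                        n_trials = 1)
  p <- compile_population_psth(one, "deep")
  expect_equal(p$bin_width, 0.1)
  expect_equal(sum(p$heights), 1)
  expect_equal(p$heights[21], 1) # bin [2.0, 2.1)
  expect_true(all(p$heights[-21] == 0))

  # cell with heights h plus a silent cell -> h/2 everywhere
  two <- make_spike_set(list(
    list(deep = list(c(2.05, 5.55)), superficial = list()),
    list(deep = list(numeric(0)), superficial = list())
  ), n_trials = 1)
  p2 <- compile_population_psth(two, "deep")
  expect_equal(p2$heights, compile_population_psth(
    make_spike_set(list(list(deep = list(c(2.05, 5.55)),
                             superficial = list())), 1), "deep"
  )$heights / 2)

  # k identical cells equal the single-cell PSTH
  cellrec <- list(deep = list(c(1.23, 3.75), c(2.05)), superficial = list())
  k5 <- make_spike_set(rep(list(cellrec), 5), n_trials = 2)
  k1 <- make_spike_set(list(cellrec), n_trials = 2)
  expect_equal(compile_population_psth(k5, "deep")$heights,
               compile_population_psth(k1, "deep")$heights)

  # spikes outside 0-10 ms are discarded
  out <- make_spike_set(list(list(deep = list(c(2.05, 12.3, -1)),
                                  superficial = list())), 1)
  expect_equal(sum(compile_population_psth(out, "deep")$heights), 1)
})

test_that("band-pass keeps the passband, rejects DC and preserves phase", {
  centers <- (1:100 - 0.5) * 0.1
  sine <- sin(2 * pi * 1 * centers) # 1 kHz at a 10 kHz bin rate
  f <- bandpass_psth(sine)
  mid <- 20:80 # away from edges
  expect_equal(sd(f$heights[mid]) / sd(sine[mid]), 1, tolerance = 0.05)

  const <- bandpass_psth(rep(3, 100))
  expect_lt(max(abs(const$heights)) / 3, 0.01)

  # symmetric bump: filtered first peak stays put (zero-phase)
  bump <- gaussian_heights(4.05, sd = 0.4)
  raw_peak <- first_peak_latency(bump)
  filt_peak <- first_peak_latency(bandpass_psth(bump))
  expect_lt(abs(filt_peak - raw_peak), 0.05)

  expect_error(bandpass_psth(bump, band = c(400, 6000)), "Nyquist|band")
})

test_that("first-peak latency follows the first qualifying local maximum", {
  expect_equal(first_peak_latency(gaussian_heights(3.0, sd = 0.3)), 3.0,
               tolerance = 1e-6)
  # two equal bumps: first wins, not the largest/latest
  two <- gaussian_heights(3.0, sd = 0.25) + gaussian_heights(4.5, sd = 0.25)
  expect_equal(first_peak_latency(two), 3.0, tolerance = 0.01)
  # small early bump below the qualification fraction is skipped
  small <- 0.1 * gaussian_heights(2.0, sd = 0.2) + gaussian_heights(5, 0.3)
  expect_equal(first_peak_latency(small), 5.0, tolerance = 0.01)
  # degenerate trace -> explicit no-peak result
  expect_true(is.na(first_peak_latency(rep(0, 100))))
  # blanking hides peaks before 0.5 ms
  early <- gaussian_heights(0.2, sd = 0.1) + 0.5 * gaussian_heights(6, 0.3)
  expect_equal(first_peak_latency(early), 6.0, tolerance = 0.05)
})

test_that("identical groups give a null Monte Carlo result", {
  set.seed(1)
  cells <- lapply(1:6, function(i) {
    h <- gaussian_heights(2 + 0.1 * i, sd = 0.3) + rnorm(100, 0, 0.02)
    structure(list(bin_edges = seq(0, 10, 0.1), heights = h,
                   bin_width = 0.1, site = "deep", n_cells = 1L),
              class = "psth")
  })
  res <- monte_carlo_latency_test(cells, cells, n_shuffles = 200, seed = 2)
  expect_equal(res$observed_difference, 0)
  expect_equal(res$p_value, 1)
  expect_length(res$null_differences, 200)
})

test_that("imposed latency shifts of 0.3/0.6/0.9 ms are recovered within one bin", {
  for (shift in c(0.3, 0.6, 0.9)) {
    cfg <- cell_sim_config(superficial_extra_delay = shift)
    sp <- simulate_population_spikes(cfg, n_cells = 24,
                                     seed = round(1000 * shift))
    a <- psth_by_cell(sp, "superficial")
    b <- psth_by_cell(sp, "deep")
    res <- monte_carlo_latency_test(a, b, n_shuffles = 200,
                                    seed = round(100 * shift))
    expect_lt(abs(res$observed_difference - shift), 0.1)
    expect_lt(res$p_value, 0.05)
  }
})

test_that("degenerate shuffle traces abort with a diagnostic", {
  flat <- lapply(1:4, function(i) {
    structure(list(heights = rep(0, 100), bin_width = 0.1,
                   bin_edges = seq(0, 10, 0.1), site = "deep",
                   n_cells = 1L), class = "psth")
  })
  expect_error(monte_carlo_latency_test(flat, flat, n_shuffles = 50, seed = 1),
               "degenerate")
  expect_error(monte_carlo_latency_test(flat[1], flat, n_shuffles = 10),
               "at least 2")
})

test_that("one-way ANOVA matches the brute-force sums of squares", {
  # identical groups: no between-group variance at all
  g <- list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3))
  res <- one_way_anova(g)
  expect_equal(res$F, 0)
  expect_equal(res$p, 1)

  # brute-force oracle on arbitrary unbalanced groups
  set.seed(7)
  groups <- list(rnorm(5, 0), rnorm(7, 0.5), rnorm(6, -0.2))
  v <- unlist(groups)
  grand <- mean(v)
  ssb <- sum(vapply(groups, function(x) length(x) * (mean(x) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(v) - length(groups)
  f_oracle <- (ssb / dfb) / (ssw / dfw)
  res2 <- one_way_anova(groups)
  expect_equal(res2$F, f_oracle, tolerance = 1e-10)
  expect_equal(res2$p, stats::pf(f_oracle, dfb, dfw, lower.tail = FALSE),
               tolerance = 1e-10)

  # one clearly shifted mean is detected
  set.seed(8)
  shifted <- list(rnorm(30), rnorm(30), rnorm(30, 1.5))
  expect_lt(one_way_anova(shifted)$p, 0.01)

  # all-constant input is flagged degenerate
  expect_true(one_way_anova(list(c(1, 1), c(1, 1)))$degenerate)
  expect_error(one_way_anova(list(c(1, 2))), "2 groups")
  expect_error(one_way_anova(list(c(1, 2), 3)), "2 values")
})
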