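test_that("a flat noiseless trace yields an empty table", {
  tr <- resonance_trace(seq(0, 50, by = 0.02), rep(0, 2501))
  tab <- detect_events(tr)
  expect_identical(nrow(tab), 0L)
})

test_that("short or irregular traces are refused", {
  expect_error(detect_events(resonance_trace(seq(0, 5, by = 0.02),
                                             rep(0, 251))),
               "10 s")
  expect_error(detect_events(resonance_trace(seq(0, 1, by = 0.02),
                                             rep(0, 51))),
               "100 frames")
  expect_error(resonance_trace(c(0, 0.02, 0.05), c(0, 0, 0)), "uniform")
})

test_that("a single injected step is recovered with accurate onset and amplitude", {
  for (s in 1:3) {
    gt <- manual_truth("step", 50, 20, duration = 100)
    tr <- render_trace(gt, noise_params(sigma_white = 2), seed = s)
    tab <- detect_events(tr)
    steps <- tab[tab$type == "step", ]
    expect_identical(nrow(steps), 1L)
    expect_lt(abs(steps$onset_s - 50), 0.1)
    expect_lt(abs(steps$amplitude_fm - 20), 2)
  }
})

test_that("detected amplitudes scale with the trace and onsets with its origin", {
  gt <- manual_truth(c("step", "spike", "step"), c(20, 45.37, 70),
                     c(25, 40, 18), dwell = c(NA, 0.11, NA), duration = 100)
  tr <- render_trace(gt, noise_params(sigma_white = 0))
  tab <- detect_events(tr)
  expect_identical(nrow(tab), 3L)

  # amplitude-scale equivariance
  tr2 <- resonance_trace(tr$time_s, tr$dlambda_fm * 2.5)
  tab2 <- detect_events(tr2)
  expect_identical(tab2$type, tab$type)
  expect_equal(tab2$onset_s, tab$onset_s)
  expect_equal(tab2$amplitude_fm, tab$amplitude_fm * 2.5, tolerance = 1e-9)
  expect_equal(tab2$tau_s, tab$tau_s)

  # time-shift equivariance
  tr3 <- resonance_trace(tr$time_s + 7, tr$dlambda_fm)
  tab3 <- detect_events(tr3)
  expect_equal(tab3$onset_s, tab$onset_s + 7)
})

test_that("spike recall and false-positive rate meet the benchmark at SNR 20", {
  gt <- census_truth(0, 50, duration = 600, amp_mean = 40, amp_sd = 0,
                     k_off = 16.1, seed = 3)
  tr <- render_trace(gt, noise_params(sigma_white = 2), seed = 4)
  tab <- detect_events(tr)
  m <- match_events(gt, tab, "spike")
  expect_gte(m$recall, 0.9)
  expect_lte(m$false_positives / 600, 0.02)
})

test_that("recall does not degrade when the SNR improves", {
  gt <- census_truth(0, 60, duration = 600, amp_mean = 40, amp_sd = 0,
                     k_off = 10, seed = 6)
  recs <- vapply(c(8, 4, 2), function(sig) {
    tr <- render_trace(gt, noise_params(sigma_white = sig), seed = 7)
    match_events(gt, detect_events(tr), "spike")$recall
  }, numeric(1))
  expect_true(recs[3] >= recs[1])
})

test_that("recorded dwells respect the frame dead time and its censoring bound", {
  gt <- census_truth(0, 200, duration = 2000, amp_mean = 40, amp_sd = 0,
                     k_off = 16.1, seed = 8)
  tr <- render_trace(gt, noise_params(sigma_white = 2), seed = 9)
  tab <- detect_events(tr)
  taus <- tab$tau_s[tab$type == "spike"]
  expect_true(all(taus >= 0.02 - 1e-12))
  d <- dead_time_diagnostic(gt, tab)
  # geometric bound: 1 - exp(-k_off * dt); area-weighted rendering recovers
  # part of the sub-frame population, so the observed loss sits below it
  expect_equal(d$predicted_missed, 1 - exp(-16.1 * 0.02), tolerance = 1e-12)
  expect_gt(d$observed_missed, 0)
  expect_lte(d$observed_missed, d$predicted_missed + 0.03)
})

test_that("amplitude population fits recover Gaussian parameters", {
  set.seed(15)
  tab <- structure(data.frame(type = "spike",
                              onset_s = seq_len(500),
                              amplitude_fm = rnorm(500, 50, 8),
                              tau_s = 0.1, snr = 10),
                   class = c("event_table", "data.frame"))
  f <- amplitude_histogram(tab)
  expect_lt(abs(f$mu - 50), 1)
  expect_lt(abs(f$sigma - 8), 1)
  expect_false(f$degenerate)
  expect_false(f$poor_fit)

  # identical amplitudes: degenerate, sigma 0
  tab2 <- tab
  tab2$amplitude_fm <- rep(40, 500)
  f2 <- amplitude_histogram(tab2)
  expect_identical(f2$sigma, 0)
  expect_true(f2$degenerate)

  # two well-separated populations: flagged by the goodness-of-fit test
  tab3 <- tab
  tab3$amplitude_fm <- c(rnorm(250, 30, 2), rnorm(250, 80, 2))
  expect_true(amplitude_histogram(tab3)$poor_fit)

  expect_error(amplitude_histogram(tab[1:5, ]), "10 events")
})

test_that("step/spike counts and their ratio handle edge cases", {
  tbl <- data.frame(type = c(rep("step", 30), rep("spike", 27)),
                    onset_s = seq_len(57))
  cc <- step_spike_counts(tbl)
  expect_identical(cc$n_step, 30L)
  expect_identical(cc$n_spike, 27L)
  expect_equal(cc$ratio, 30 / 27)

  empty <- data.frame(type = character(0), onset_s = numeric(0))
  c0 <- step_spike_counts(empty)
  expect_identical(c0$n_step, 0L)
  expect_false(c0$ratio_defined)

  only_steps <- data.frame(type = rep("step", 35), onset_s = seq_len(35))
  c1 <- step_spike_counts(only_steps)
  expect_identical(c1$n_step, 35L)
  expect_false(c1$ratio_defined)
  expect_true(is.na(c1$ratio))
})

test_that("inter-event intervals are computed per type from sorted onsets", {
  tbl <- data.frame(type = c("spike", "step", "spike", "spike"),
                    onset_s = c(3, 4, 1, 6))
  expect_equal(interevent_intervals(tbl, "spike"), c(2, 3))
  expect_identical(length(interevent_intervals(tbl, "step")), 0L)
})
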