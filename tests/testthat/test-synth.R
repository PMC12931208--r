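test_that("identical seed and parameters give byte-identical output", {
  p <- event_gen_params(k_on1 = 0.47, k_on2 = 0.03, w1 = 0.5, k_off = 27,
                        amp_mean = 50, amp_sd = 8, step_fraction = 0.3,
                        duration = 300)
  expect_identical(simulate_events(p, seed = 5), simulate_events(p, seed = 5))
  gt <- simulate_events(p, seed = 5)
  expect_identical(render_trace(gt, noise_params(), seed = 9),
                   render_trace(gt, noise_params(), seed = 9))
  lp <- langmuir_gen_params()
  expect_identical(simulate_pressure_trace(lp, seed = 3),
                   simulate_pressure_trace(lp, seed = 3))
  expect_identical(
    simulate_temperature_series(25e3, 20, rel_noise = 0.1, seed = 2),
    simulate_temperature_series(25e3, 20, rel_noise = 0.1, seed = 2))
})

test_that("seeded generators leave the caller's RNG stream untouched", {
  set.seed(123)
  before <- .Random.seed
  invisible(rexp_mixture(100, 1, seed = 7))
  expect_identical(.Random.seed, before)
})

test_that("single-component arrivals have the expected mean interval", {
  # fast-arrival regime: mean inter-arrival 1/16.1 = 0.0621 s
  p <- event_gen_params(k_on1 = 16.1, k_off = 27, amp_mean = 50, amp_sd = 8,
                        step_fraction = 0, duration = 100)
  gt <- simulate_events(p, seed = 11)
  gaps <- diff(gt$events$onset)
  se <- (1 / 16.1) / sqrt(length(gaps))
  expect_lt(abs(mean(gaps) - 1 / 16.1), 4 * se)
})

test_that("degenerate step_fraction = 1 yields only persistent steps", {
  p <- event_gen_params(k_on1 = 1, k_off = 10, amp_mean = 40, amp_sd = 0,
                        step_fraction = 1, duration = 60)
  gt <- simulate_events(p, seed = 2)
  expect_true(all(gt$events$type == "step"))
  expect_true(all(is.na(gt$events$dwell)))
})

test_that("mixture draws match the closed-form mixture survivor pointwise", {
  n <- 10000
  x <- rexp_mixture(n, 0.47, 0.03, w1 = 0.5, seed = 21)
  grid <- c(0.5, 1, 2, 5, 10, 20, 50)
  for (t in grid) {
    s_hat <- mean(x > t)
    s_true <- 0.5 * exp(-0.47 * t) + 0.5 * exp(-0.03 * t)
    expect_lt(abs(s_hat - s_true),
              4 * sqrt(s_true * (1 - s_true) / n) + 1e-12)
  }
})

test_that("w1 = 1 reduces the mixture to the single-exponential process", {
  x <- rexp_mixture(10000, 16.1, k2 = 0.5, w1 = 1, seed = 31)
  set.seed(32)
  y <- stats::rexp(10000, 16.1)
  ks <- suppressWarnings(stats::ks.test(x, y))
  expect_gt(ks$p.value, 0.01)
})

test_that("exponential dwell draws have mean 1/k within sampling error", {
  n <- 1e5
  p <- event_gen_params(k_on1 = 50, k_off = 16.1, amp_mean = 40, amp_sd = 0,
                        step_fraction = 0, duration = n / 50 + 100)
  gt <- simulate_events(p, seed = 4)
  d <- gt$events$dwell
  expect_gt(length(d), 1e4)
  expect_lt(abs(mean(d) - 1 / 16.1), 3 * (1 / 16.1) / sqrt(length(d)))
})

test_that("rendering is exact for noiseless boxcars", {
  # no events, no noise: identically zero
  empty <- manual_truth(character(0), numeric(0), numeric(0), duration = 20)
  tr0 <- render_trace(empty, noise_params(sigma_white = 0))
  expect_true(all(tr0$dlambda_fm == 0))

  # single 20 fm step at t = 10: 0 before, 20 after, exactly
  gt <- manual_truth("step", 10, 20, duration = 20)
  tr <- render_trace(gt, noise_params(sigma_white = 0))
  expect_equal(tr$dlambda_fm[tr$time_s < 10 - 0.021], rep(0, 499))
  expect_equal(tr$dlambda_fm[tr$time_s >= 10],
               rep(20, sum(tr$time_s >= 10)))

  # half-frame spike, frame-aligned: one frame elevated by the area-weighted
  # half amplitude
  gt2 <- manual_truth("spike", 10, 40, dwell = 0.01, duration = 20)
  tr2 <- render_trace(gt2, noise_params(sigma_white = 0))
  nz <- which(tr2$dlambda_fm != 0)
  expect_length(nz, 1L)
  expect_equal(tr2$dlambda_fm[nz], 20)
})

test_that("level change equals the sum of active step amplitudes frame by frame", {
  gt <- manual_truth(rep("step", 3), c(5, 12.004, 17.5), c(10, 25, 7),
                     duration = 30)
  tr <- render_trace(gt, noise_params(sigma_white = 0))
  expected <- vapply(tr$time_s, function(t) {
    # a frame [t, t+dt) fully past an onset carries the full amplitude
    sum(gt$events$amplitude[gt$events$onset <= t])
  }, numeric(1))
  inside <- vapply(tr$time_s, function(t)
    all(abs(gt$events$onset - t) > 0.021 |
          gt$events$onset <= t), logical(1))
  expect_equal(tr$dlambda_fm[inside], expected[inside])
})

test_that("TM/TE pairing scales amplitudes by the anisotropy ratio", {
  gt <- manual_truth("step", 10, 20, duration = 30)
  pair1 <- simulate_tm_te(gt, 1, noise_params(sigma_white = 0), seed = 1)
  expect_equal(pair1$tm$dlambda_fm, pair1$te$dlambda_fm)
  pair <- simulate_tm_te(gt, 1.5, noise_params(sigma_white = 0), seed = 1)
  after <- pair$te$time_s >= 10
  expect_equal(pair$tm$dlambda_fm[after] / pair$te$dlambda_fm[after],
               rep(1.5, sum(after)))
})

test_that("temperature series reproduces the transmission-coefficient limit", {
  # oracle: direct arithmetic with CODATA constants
  k_expected <- 1.380649e-23 * 298.15 / 6.62607015e-34
  tab <- simulate_temperature_series(0, 0, temperatures = 298.15,
                                     rel_noise = 0)
  expect_equal(tab$k_per_s, k_expected, tolerance = 1e-12)
  expect_equal(tab$k_per_s, 6.212e12, tolerance = 1e-4)
})

test_that("pressure generator hits its asymptotes", {
  # control: no adsorption, trace returns to the baseline
  lp0 <- langmuir_gen_params(delta_pi_inf = 0, sigma = 0, duration = 2000,
                             injection_time = 100)
  tr0 <- simulate_pressure_trace(lp0)
  tail_mean <- mean(tr0$pressure_mN_per_m[tr0$time_s > 1500])
  expect_lt(abs(tail_mean - 30), 1e-4)

  # sustained rise converges to delta_pi_inf
  lp1 <- langmuir_gen_params(delta_pi_inf = 1.07, sigma = 0, duration = 2000,
                             injection_time = 100)
  tr1 <- simulate_pressure_trace(lp1)
  expect_equal(tr1$pressure_mN_per_m[nrow(tr1)] - 30, 1.07,
               tolerance = 1e-4)
})

test_that("parameter validation rejects invalid generator inputs", {
  expect_error(event_gen_params(k_on1 = -1, k_off = 1, amp_mean = 10,
                                amp_sd = 1, step_fraction = 0, duration = 10),
               "k_on1")
  expect_error(event_gen_params(k_on1 = 1, k_on2 = NULL, w1 = 0.5, k_off = 1,
                                amp_mean = 10, amp_sd = 1, step_fraction = 0,
                                duration = 10),
               "w1")
  expect_error(simulate_tm_te(manual_truth("step", 1, 10), -2), "anisotropy")
  expect_error(langmuir_gen_params(artifact_recovery_tau = -5), "tau")
  expect_error(simulate_temperature_series(0, 0, temperatures = numeric(0)),
               "non-empty")
})

test_that("a duration below one expected interval flags empty ground truth", {
  p <- event_gen_params(k_on1 = 0.01, k_off = 1, amp_mean = 10, amp_sd = 0,
                        step_fraction = 0, duration = 1)
  expect_warning(gt <- simulate_events(p, seed = 1), "shorter")
  expect_identical(nrow(gt$events), 0L)
  expect_true(gt$short_duration)
})
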