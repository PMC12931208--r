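test_that("the empirical survivor function counts exceedances exactly", {
  s <- survivor(c(1, 2, 3))
  expect_equal(s$time, c(1, 2, 3))
  expect_equal(s$surv, c(2 / 3, 1 / 3, 0))

  # ties merge into a single point
  s2 <- survivor(c(2, 2))
  expect_identical(nrow(s2), 1L)
  expect_equal(s2$surv, 0)

  expect_error(survivor(numeric(0)), "non-empty")
  expect_error(survivor(c(1, -2)), "positive")
})

test_that("-log S is linear in t with slope k for exponential samples", {
  x <- rexp_mixture(3000, 2, seed = 41)
  s <- survivor(x)
  keep <- s$surv > 0.01
  fit <- lm(I(-log(surv)) ~ time, data = s[keep, ])
  expect_lt(abs(coef(fit)[[2]] - 2), 0.1)
})

test_that("single-exponential fit inverts exact curve points", {
  t <- seq(0.05, 3, by = 0.05)
  f <- fit_single_exponential(exact_curve(t, exp(-2 * t)))
  expect_equal(unname(f$rates["k"]), 2, tolerance = 1e-6)
  expect_equal(unname(f$amplitudes["A"]), 1, tolerance = 1e-6)
  expect_equal(unname(f$mean_times), 0.5, tolerance = 1e-6)
})

test_that("off-rates and mean interaction times are recovered from dwell samples", {
  # amino-acid-like off-rate / mean-time pairs
  cases <- list(c(27.0, 0.037), c(44.5, 0.0225), c(16.1, 0.0622))
  for (i in seq_along(cases)) {
    k_true <- cases[[i]][1]
    f <- fit_single_exponential(
      survivor(rexp_mixture(5000, k_true, seed = 50 + i)))
    expect_lt(abs(f$rates[["k"]] - k_true) / k_true, 0.05)
    expect_lt(abs(f$mean_times[[1]] - cases[[i]][2]) / cases[[i]][2], 0.06)
  }
})

test_that("bi-exponential fit inverts exact mixture points and ordering holds", {
  t <- seq(0.2, 60, by = 0.2)
  f <- fit_biexponential(
    exact_curve(t, 0.5 * exp(-0.47 * t) + 0.5 * exp(-0.03 * t)))
  expect_equal(unname(f$rates["k1"]), 0.47, tolerance = 1e-4)
  expect_equal(unname(f$rates["k2"]), 0.03, tolerance = 1e-4)
  expect_gte(f$rates[["k1"]], f$rates[["k2"]])
})

test_that("two-component rates are recovered from sampled mixtures", {
  # glycine-like fast/slow pair at 10 nM
  x <- rexp_mixture(10000, 4.14, 0.04, w1 = 0.5, seed = 61)
  f <- fit_biexponential(survivor(x))
  expect_lt(abs(f$rates[["k1"]] - 4.14) / 4.14, 0.10)
  expect_lt(abs(f$rates[["k2"]] - 0.04) / 0.04, 0.25)
})

test_that("single-exponential truth is not over-fitted by the mixture model", {
  x <- rexp_mixture(2000, 1, seed = 71)
  cv <- survivor(x)
  f1 <- fit_single_exponential(cv)
  f2 <- fit_biexponential(cv)
  sel <- select_model(f1, f2)
  expect_identical(sel$choice, 1L)
  # and the mixture either collapses its rates or kills one amplitude
  collapse <- f2$rates[["k1"]] / f2$rates[["k2"]] < 3 ||
    min(f2$amplitudes) < 0.05 * max(f2$amplitudes)
  expect_true(collapse || f2$identifiability_warning)
})

test_that("identical fits default to one component by parsimony", {
  t <- seq(0.1, 5, by = 0.1)
  cv <- exact_curve(t, exp(-t))
  sel <- select_model(fit_single_exponential(cv), fit_biexponential(cv))
  expect_identical(sel$choice, 1L)
})

test_that("NLS survivor fit agrees with the ML rate estimator", {
  x <- rexp_mixture(2000, 16.1, seed = 81)
  f <- fit_single_exponential(survivor(x))
  m <- mle_rate(x)
  combined_se <- 2 * (f$se[["k"]] + m[["se"]])
  expect_lt(abs(f$rates[["k"]] - m[["k"]]), combined_se)
})

test_that("rates and mean times transform correctly under time rescaling", {
  x <- rexp_mixture(3000, 5, seed = 91)
  f1 <- fit_single_exponential(survivor(x))
  f2 <- fit_single_exponential(survivor(x * 10))
  expect_equal(f2$rates[["k"]], f1$rates[["k"]] / 10, tolerance = 1e-6)
  expect_equal(f2$mean_times[[1]], f1$mean_times[[1]] * 10, tolerance = 1e-6)
})

test_that("the 95% interval for k has near-nominal coverage", {
  set.seed(101)
  n_sim <- 200
  cover <- 0
  for (i in seq_len(n_sim)) {
    f <- fit_single_exponential(survivor(rexp(5000, 16.1)))
    lo <- f$rates[["k"]] - 1.96 * f$se[["k"]]
    hi <- f$rates[["k"]] + 1.96 * f$se[["k"]]
    if (lo <= 16.1 && 16.1 <= hi) cover <- cover + 1
  }
  expect_gte(cover / n_sim, 0.90)
  expect_lte(cover / n_sim, 0.98)
})

test_that("rate_table produces the grouped on/off-rate layout", {
  set.seed(111)
  mk_group <- function(analyte, conc, n = 150, kon = 0.5, koff = 20) {
    onsets <- cumsum(rexp(n, kon))
    data.frame(analyte = analyte, concentration = conc, type = "spike",
               onset_s = onsets, tau_s = rexp(n, koff))
  }
  ev <- rbind(mk_group("GABA", "10 nM"), mk_group("GABA", "1 uM"),
              mk_group("GABA", "100 uM"))
  tab <- rate_table(ev)
  expect_identical(nrow(tab), 6L)   # 3 concentrations x (spike_on, spike_off)
  expect_setequal(unique(tab$signal), c("spike_on", "spike_off"))
  # mean time is definitionally 1/k1
  expect_equal(tab$mean_time_s, 1 / tab$k1)
  # two-component columns are empty for single-component truth
  expect_true(all(is.na(tab$k2[tab$model == 1])))

  # underpopulated groups are skipped with a message
  small <- mk_group("X", "1 nM", n = 5)
  expect_message(tab2 <- rate_table(rbind(ev, small)), "skipping")
  expect_false("X" %in% tab2$analyte)
})

test_that("kinetic_fit methods expose coefficients and predictions", {
  x <- rexp_mixture(1000, 3, seed = 121)
  f <- fit_single_exponential(survivor(x))
  cf <- coef(f)
  expect_named(cf, c("A", "k"))
  expect_equal(predict(f, 0), unname(cf["A"]), tolerance = 1e-12)
  s <- summary(f)
  expect_s3_class(s, "summary.kinetic_fit")
  expect_output(print(f), "1-component")
})
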