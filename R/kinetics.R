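#' Empirical survivor function
#'
#' Builds the empirical survivor curve `S(t) = P(T > t)` of a sample of
#' positive times: at each distinct sample time `t_i`, `S(t_i)` is the
#' fraction of samples strictly greater than `t_i`. Ties are merged, `S` is 1
#' before the first sample and 0 at (and after) the largest.
#'
#' @param samples Positive times (s): dwell times or inter-event intervals.
#' @return An object of class `survivor_curve`: a data frame with columns
#'   `time` and `surv`, and attribute `n` (sample size).
#' @export
#' @examples
#' survivor(c(1, 2, 3))   # S = 2/3, 1/3, 0
survivor <- function(samples) {
  if (length(samples) == 0L) stop_param("`samples` must be non-empty")
  if (any(!is.finite(samples)) || any(samples <= 0))
    stop_param("`samples` must be positive and finite")
  n <- length(samples)
  t_sorted <- sort(unique(samples))
  surv <- vapply(t_sorted, function(t) sum(samples > t), numeric(1)) / n
  structure(data.frame(time = t_sorted, surv = surv),
            n = n, samples = as.numeric(samples),
            class = c("survivor_curve", "data.frame"))
}

# Log-linear initializer: regress log S on t over the strictly positive part.
init_single_exp <- function(curve) {
  keep <- curve$surv > 0
  if (sum(keep) >= 2L) {
    cf <- coef(lm(log(surv) ~ time, data = curve[keep, ]))
    k0 <- max(-cf[[2L]], 1e-8)
    A0 <- min(max(exp(cf[[1L]]), 1e-8), 2)
  } else {
    k0 <- 1 / mean(curve$time)
    A0 <- 1
  }
  c(A = A0, k = k0)
}

# Sample-likelihood standard errors for the fitted rates. The survivor
# points are strongly autocorrelated, so the NLS covariance (which treats
# them as independent) understates rate uncertainty by orders of magnitude;
# the Fisher information of the exponential (mixture) density on the raw
# samples gives errors on the correct sampling scale.
rate_se_single <- function(samples, k) {
  if (is.null(samples) || !length(samples)) return(NA_real_)
  k / sqrt(length(samples))
}

rate_se_biexp <- function(samples, k1, k2, w) {
  if (is.null(samples) || !length(samples)) return(c(NA_real_, NA_real_))
  nll <- function(par) {
    a1 <- exp(par[1L]); a2 <- exp(par[2L]); pw <- stats::plogis(par[3L])
    d <- pw * a1 * exp(-a1 * samples) + (1 - pw) * a2 * exp(-a2 * samples)
    -sum(log(pmax(d, .Machine$double.xmin)))
  }
  out <- tryCatch({
    par <- c(log(k1), log(k2), stats::qlogis(min(max(w, 1e-6), 1 - 1e-6)))
    H <- stats::optimHess(par, nll)
    V <- solve(H)
    # delta method back from the log-rate scale
    c(k1 * sqrt(max(V[1L, 1L], 0)), k2 * sqrt(max(V[2L, 2L], 0)))
  }, error = function(e) c(NA_real_, NA_real_))
  out
}

# AIC of the fitted exponential (mixture) density evaluated on the raw
# samples behind the survivor curve. The survivor points themselves are
# strongly autocorrelated, so an AIC computed from the point-wise NLS
# residuals vastly overstates the information in the curve; the sample
# likelihood is the exchange rate that makes one- vs two-component
# comparisons honest. Parameters counted: k (1) vs k1, k2, weight (3).
sample_aic <- function(samples, rates, amplitudes) {
  if (is.null(samples) || !length(samples)) return(NA_real_)
  if (length(rates) == 1L) {
    ll <- sum(stats::dexp(samples, rates[1L], log = TRUE))
    return(-2 * ll + 2 * 1)
  }
  tot <- sum(amplitudes)
  w <- if (tot > 0) max(0, min(1, amplitudes[1L] / tot)) else 0.5
  dens <- w * rates[1L] * exp(-rates[1L] * samples) +
    (1 - w) * rates[2L] * exp(-rates[2L] * samples)
  -2 * sum(log(pmax(dens, .Machine$double.xmin))) + 2 * 3
}

new_kinetic_fit <- function(n_components, rates, amplitudes, se, rss, aic,
                            n_points, n_samples, converged,
                            identifiability_warning = FALSE, fit = NULL) {
  structure(list(n_components = n_components, rates = rates,
                 amplitudes = amplitudes, se = se, rss = rss, aic = aic,
                 mean_times = 1 / rates, n_points = n_points,
                 n_samples = n_samples, converged = converged,
                 identifiability_warning = identifiability_warning,
                 fit = fit),
            class = "kinetic_fit")
}

#' Single-exponential survivor fit
#'
#' Nonlinear least squares of `A * exp(-k * t)` to the points of an empirical
#' survivor curve, with the amplitude `A` left free (matching how plotted
#' survivor fits are usually drawn) and initialization by log-linear
#' regression. The mean time `1/k` is reported alongside the rate.
#'
#' Because neighbouring survivor points share almost all of their samples,
#' the point-wise NLS covariance drastically understates rate uncertainty;
#' the reported rate standard error therefore comes from the Fisher
#' information of the exponential likelihood of the underlying samples
#' (`k/sqrt(n)`), and amplitude errors from the NLS.
#'
#' @param curve A [survivor()] curve with at least 5 distinct points.
#' @return A `kinetic_fit` with `n_components = 1`, elements `rates` (named
#'   `k`), `amplitudes` (`A`), `se`, `rss`, `aic`, `mean_times` and
#'   `converged`. When the optimizer fails, the log-linear initializer values
#'   are returned with `converged = FALSE`.
#' @export
#' @examples
#' s <- survivor(rexp_mixture(2000, k1 = 16.1, seed = 1))
#' coef(fit_single_exponential(s))
fit_single_exponential <- function(curve) {
  if (!inherits(curve, "survivor_curve"))
    stop_param("`curve` must be a `survivor_curve`")
  if (nrow(curve) < 5L) stop_param("need at least 5 distinct survivor points")
  st <- init_single_exp(curve)
  fit <- tryCatch(
    minpack.lm::nlsLM(surv ~ A * exp(-k * time), data = curve,
                      start = list(A = st[["A"]], k = st[["k"]]),
                      lower = c(A = 0, k = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(new_kinetic_fit(1L, c(k = st[["k"]]), c(A = st[["A"]]),
                           se = c(A = NA_real_, k = NA_real_),
                           rss = NA_real_, aic = NA_real_,
                           n_points = nrow(curve), n_samples = attr(curve, "n"),
                           converged = FALSE))
  }
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  samples <- attr(curve, "samples")
  k_se <- rate_se_single(samples, unname(cf["k"]))
  if (!is.finite(k_se)) k_se <- unname(se["k"])
  new_kinetic_fit(1L, c(k = unname(cf["k"])), c(A = unname(cf["A"])),
                  se = c(A = unname(se["A"]), k = k_se),
                  rss = sum(residuals(fit)^2),
                  aic = sample_aic(attr(curve, "samples"),
                                   unname(cf["k"]), unname(cf["A"])),
                  n_points = nrow(curve), n_samples = attr(curve, "n"),
                  converged = TRUE, fit = fit)
}

#' Bi-exponential survivor fit
#'
#' Least-squares fit of `A * exp(-k1 * t) + B * exp(-k2 * t)` to an empirical
#' survivor curve under the constraints `k1 >= k2 > 0` and `A, B >= 0`, the
#' two-component on-rate model for arrival processes that mix a fast and a
#' slow association pathway. Initialization is a multi-start search over a
#' log-spaced 5 x 5 grid of rate pairs spanning the observed time range; the
#' best residual sum of squares is kept and label switching is resolved by
#' ordering `k1 >= k2`. A fitted rate ratio `k1/k2 < 3` sets
#' `identifiability_warning`. As in [fit_single_exponential()], rate standard
#' errors are computed from the observed information of the mixture
#' likelihood on the raw samples rather than from the autocorrelated curve
#' points.
#'
#' @param curve A [survivor()] curve with at least 8 distinct points.
#' @param n_grid Grid size per rate axis for the multi-start (default 5).
#' @return A `kinetic_fit` with `n_components = 2`, `rates` named `k1`, `k2`
#'   and `amplitudes` named `A`, `B`.
#' @export
#' @examples
#' s <- survivor(rexp_mixture(5000, 0.47, 0.03, w1 = 0.5, seed = 1))
#' coef(fit_biexponential(s))
fit_biexponential <- function(curve, n_grid = 5) {
  if (!inherits(curve, "survivor_curve"))
    stop_param("`curve` must be a `survivor_curve`")
  if (nrow(curve) < 8L) stop_param("need at least 8 distinct survivor points")
  t_min <- min(curve$time)
  t_max <- max(curve$time)
  k_grid <- exp(seq(log(0.5 / t_max), log(2 / t_min), length.out = n_grid))
  A0 <- max(curve$surv) / 2
  best <- NULL
  best_rss <- Inf
  for (k1s in k_grid) for (k2s in k_grid) {
    if (k1s < k2s) next
    fit <- tryCatch(
      minpack.lm::nlsLM(surv ~ A * exp(-k1 * time) + B * exp(-k2 * time),
                        data = curve,
                        start = list(A = A0, B = A0, k1 = k1s, k2 = k2s),
                        lower = c(A = 0, B = 0, k1 = 1e-12, k2 = 1e-12),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(residuals(fit)^2)
    if (rss < best_rss) {
      best <- fit
      best_rss <- rss
    }
  }
  if (is.null(best)) {
    st <- init_single_exp(curve)
    return(new_kinetic_fit(2L, c(k1 = st[["k"]], k2 = st[["k"]] / 10),
                           c(A = st[["A"]] / 2, B = st[["A"]] / 2),
                           se = c(A = NA_real_, B = NA_real_,
                                  k1 = NA_real_, k2 = NA_real_),
                           rss = NA_real_, aic = NA_real_,
                           n_points = nrow(curve), n_samples = attr(curve, "n"),
                           converged = FALSE))
  }
  cf <- coef(best)
  se <- sqrt(diag(vcov(best)))
  rates <- c(k1 = unname(cf["k1"]), k2 = unname(cf["k2"]))
  amps <- c(A = unname(cf["A"]), B = unname(cf["B"]))
  ses <- c(A = unname(se["A"]), B = unname(se["B"]),
           k1 = unname(se["k1"]), k2 = unname(se["k2"]))
  if (rates["k1"] < rates["k2"]) {   # resolve label switching
    rates <- c(k1 = unname(rates["k2"]), k2 = unname(rates["k1"]))
    amps <- c(A = unname(amps["B"]), B = unname(amps["A"]))
    ses <- c(A = unname(ses["B"]), B = unname(ses["A"]),
             k1 = unname(ses["k2"]), k2 = unname(ses["k1"]))
  }
  samples <- attr(curve, "samples")
  tot <- sum(amps)
  w_hat <- if (tot > 0) amps[["A"]] / tot else 0.5
  k_ses <- rate_se_biexp(samples, rates[["k1"]], rates[["k2"]], w_hat)
  if (is.finite(k_ses[1L])) ses["k1"] <- k_ses[1L]
  if (is.finite(k_ses[2L])) ses["k2"] <- k_ses[2L]
  ident_warn <- is.finite(rates["k2"]) && rates["k2"] > 0 &&
    rates["k1"] / rates["k2"] < 3
  new_kinetic_fit(2L, rates, amps, ses, rss = best_rss,
                  aic = sample_aic(attr(curve, "samples"), rates, amps),
                  n_points = nrow(curve), n_samples = attr(curve, "n"),
                  converged = TRUE,
                  identifiability_warning = isTRUE(ident_warn), fit = best)
}

#' Choose between one- and two-component survivor fits
#'
#' Model selection by AIC with a parsimony margin: the bi-exponential model
#' is preferred only when its AIC improves on the single-exponential AIC by
#' more than `delta_aic`. An extra-sum-of-squares F-test on the residuals is
#' reported as secondary evidence.
#'
#' @param fit1 A one-component `kinetic_fit`.
#' @param fit2 A two-component `kinetic_fit` on the same curve.
#' @param delta_aic Required AIC improvement (default 2).
#' @return A list with `choice` (1 or 2), `delta_aic` (AIC1 - AIC2, positive
#'   when the two-component model fits better), `f_statistic` and `f_p`.
#' @export
select_model <- function(fit1, fit2, delta_aic = 2) {
  stopifnot(inherits(fit1, "kinetic_fit"), inherits(fit2, "kinetic_fit"))
  if (fit1$n_components != 1L || fit2$n_components != 2L)
    stop_param("`fit1` must have 1 component and `fit2` 2 components")
  d_aic <- fit1$aic - fit2$aic
  n <- fit1$n_points
  f_stat <- f_p <- NA_real_
  if (is.finite(fit1$rss) && is.finite(fit2$rss) && fit2$rss > 0 && n > 4) {
    f_stat <- ((fit1$rss - fit2$rss) / 2) / (fit2$rss / (n - 4))
    f_p <- pf(f_stat, 2, n - 4, lower.tail = FALSE)
  }
  choice <- if (is.finite(d_aic) && d_aic > delta_aic) 2L else 1L
  list(choice = choice, delta_aic = d_aic,
       f_statistic = f_stat, f_p = f_p)
}

#' Rate table for grouped event data
#'
#' For each analyte-by-concentration group: fits the spike inter-event
#' intervals with one- or two-component exponentials (chosen by
#' [select_model()]) to obtain on-rates, the spike dwell times with a single
#' exponential to obtain the off-rate, and, when present, the step
#' inter-event intervals for the step-associated on-rate.
#'
#' @param events Data frame with columns `analyte`, `concentration`, `type`,
#'   `onset_s` and `tau_s` (e.g. row-bound `event_table`s with metadata
#'   columns added).
#' @param min_events Minimum events per group; smaller groups are skipped
#'   with a message.
#' @return Data frame with one row per (group, quantity): columns `analyte`,
#'   `concentration`, `signal` (`spike_on`, `spike_off`, `step_on`), `model`
#'   (1 or 2 components), `k1`, `k1_se`, `k2`, `k2_se`, `mean_time_s`
#'   (`1/k1`) and `n`.
#' @export
rate_table <- function(events, min_events = 20) {
  need <- c("analyte", "concentration", "type", "onset_s", "tau_s")
  if (!all(need %in% names(events)))
    stop_param("`events` must have columns ",
               paste(need, collapse = ", "))
  groups <- unique(events[c("analyte", "concentration")])
  rows <- list()
  add_row <- function(analyte, conc, signal, samples, biexp = FALSE) {
    n <- length(samples)
    if (n < min_events) {
      message(sprintf("skipping %s / %s %s: only %d events",
                      analyte, conc, signal, n))
      return(invisible(NULL))
    }
    curve <- survivor(samples)
    f1 <- fit_single_exponential(curve)
    model <- 1L
    fit <- f1
    if (biexp && nrow(curve) >= 8L) {
      f2 <- fit_biexponential(curve)
      if (f2$converged && select_model(f1, f2)$choice == 2L) {
        fit <- f2
        model <- 2L
      }
    }
    rows[[length(rows) + 1L]] <<- data.frame(
      analyte = analyte, concentration = conc, signal = signal,
      model = model,
      k1 = unname(fit$rates[1L]), k1_se = unname(fit$se[if (model == 2L) "k1" else "k"]),
      k2 = if (model == 2L) unname(fit$rates["k2"]) else NA_real_,
      k2_se = if (model == 2L) unname(fit$se["k2"]) else NA_real_,
      mean_time_s = 1 / unname(fit$rates[1L]), n = n)
  }
  for (g in seq_len(nrow(groups))) {
    an <- groups$analyte[g]
    co <- groups$concentration[g]
    sub <- events[events$analyte == an & events$concentration == co, ]
    spikes <- sub[sub$type == "spike", ]
    steps <- sub[sub$type == "step", ]
    add_row(an, co, "spike_on", interevent_intervals(spikes, "spike"),
            biexp = TRUE)
    add_row(an, co, "spike_off", spikes$tau_s[is.finite(spikes$tau_s) &
                                                spikes$tau_s > 0])
    if (nrow(steps) >= 2L)
      add_row(an, co, "step_on", interevent_intervals(steps, "step"),
              biexp = TRUE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(analyte = character(0), concentration = character(0),
               signal = character(0), model = integer(0), k1 = numeric(0),
               k1_se = numeric(0), k2 = numeric(0), k2_se = numeric(0),
               mean_time_s = numeric(0), n = integer(0))
  rownames(out) <- NULL
  out
}

#' Maximum-likelihood rate estimate for exponential samples
#'
#' The ML estimator `k = 1/mean(x)` with its asymptotic standard error
#' `k/sqrt(n)`; the independent cross-check for the NLS survivor fit.
#'
#' @param samples Positive times.
#' @return Named vector `c(k, se)`.
#' @export
mle_rate <- function(samples) {
  if (any(samples <= 0)) stop_param("`samples` must be positive")
  k <- 1 / mean(samples)
  c(k = k, se = k / sqrt(length(samples)))
}

## ---- S3 methods -----------------------------------------------------------

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%d-component exponential survivor fit (%s)\n",
              x$n_components,
              if (x$converged) "converged" else "NOT converged"))
  for (i in seq_along(x$rates)) {
    nm <- names(x$rates)[i]
    cat(sprintf("  %s = %.4g s^-1 (mean time %.4g s)\n",
                nm, x$rates[i], x$mean_times[i]))
  }
  cat(sprintf("  RSS = %.4g, AIC = %.4g, n = %d points / %d samples\n",
              x$rss, x$aic, x$n_points, x$n_samples))
  if (isTRUE(x$identifiability_warning))
    cat("  warning: k1/k2 < 3, components weakly identified\n")
  invisible(x)
}

#' @export
coef.kinetic_fit <- function(object, ...) {
  c(object$amplitudes, object$rates)
}

#' @export
summary.kinetic_fit <- function(object, ...) {
  est <- coef(object)
  se <- object$se[names(est)]
  tab <- data.frame(estimate = est, se = se,
                    row.names = names(est))
  structure(list(coefficients = tab, n_components = object$n_components,
                 rss = object$rss, aic = object$aic,
                 mean_times = object$mean_times,
                 converged = object$converged),
            class = "summary.kinetic_fit")
}

#' @export
print.summary.kinetic_fit <- function(x, ...) {
  cat(sprintf("%d-component exponential survivor fit\n", x$n_components))
  print(x$coefficients)
  cat(sprintf("RSS %.4g, AIC %.4g\n", x$rss, x$aic))
  invisible(x)
}

#' @export
predict.kinetic_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) NULL else
    if (is.data.frame(newdata)) newdata$time else newdata
  if (is.null(t)) stop_param("supply times to predict at")
  s <- numeric(length(t))
  for (i in seq_along(object$rates))
    s <- s + object$amplitudes[i] * exp(-object$rates[i] * t)
  unname(s)
}

#' @export
print.survivor_curve <- function(x, ...) {
  cat(sprintf("Empirical survivor curve: %d samples, %d distinct times\n",
              attr(x, "n"), nrow(x)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

#' @export
plot.survivor_curve <- function(x, log_y = TRUE, ...) {
  graphics::plot(x$time, x$surv, log = if (log_y) "y" else "",
                 xlab = "time (s)", ylab = "S(t)", ...)
  invisible(x)
}
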