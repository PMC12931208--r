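#' Detect the injection artifact in a surface-pressure trace
#'
#' Subphase injection produces a sharp, reproducible pressure drop followed
#' by an exponential recovery. The artifact window starts at the first sample
#' more than `depth_sigmas` baseline-noise standard deviations below the
#' pre-injection baseline and ends when the fitted artifact decay has relaxed
#' (three recovery time constants after onset, by which point the residual
#' artifact is about 5% of its depth, comparable to the noise floor).
#'
#' @param trace A `pressure_trace` (data frame with `time_s` and
#'   `pressure_mN_per_m`). At least `baseline_span` seconds of baseline must
#'   precede the injection.
#' @param baseline_span Length (s) of the initial segment used to estimate
#'   the baseline level and noise.
#' @param depth_sigmas Onset threshold in baseline-noise units.
#' @param search_span How far past onset (s) to search for the artifact
#'   minimum.
#' @return A list of class `injection_window`: `t_start`, `t_end`, `depth`,
#'   `tau` (estimated recovery constant, s), `baseline_mean`,
#'   `baseline_noise` and `empty` (TRUE when no artifact is found, in which
#'   case the window times are `NA`).
#' @export
#' @examples
#' tr <- simulate_pressure_trace(langmuir_gen_params(), seed = 1)
#' detect_injection(tr)
detect_injection <- function(trace, baseline_span = 60, depth_sigmas = 5,
                             search_span = 60) {
  t <- trace$time_s
  p <- trace$pressure_mN_per_m
  if (t[length(t)] - t[1L] < baseline_span)
    stop_param("trace shorter than the baseline span")
  base_sel <- t <= t[1L] + baseline_span
  mu0 <- median(p[base_sel])
  sigma0 <- mad(diff(p[base_sel])) / sqrt(2)
  sigma0 <- max(sigma0, .Machine$double.eps)
  below <- which(p < mu0 - depth_sigmas * sigma0 & !base_sel)
  if (!length(below)) {
    return(structure(list(t_start = NA_real_, t_end = NA_real_,
                          depth = NA_real_, tau = NA_real_,
                          baseline_mean = mu0, baseline_noise = sigma0,
                          empty = TRUE),
                     class = "injection_window"))
  }
  i_start <- below[1L]
  t_start <- t[i_start]
  horizon <- which(t >= t_start & t <= t_start + search_span)
  i_min <- horizon[which.min(p[horizon])]
  depth <- mu0 - p[i_min]
  # recovery time constant from the half-recovery time after the minimum
  half_level <- mu0 - depth / 2
  after <- which(t > t[i_min] & p >= half_level)
  tau <- if (length(after)) (t[after[1L]] - t[i_min]) / log(2)
         else (t[length(t)] - t[i_min]) / log(2)
  tau <- max(tau, t[2L] - t[1L])
  t_end <- min(t_start + 3 * tau, t[length(t)])
  structure(list(t_start = t_start, t_end = t_end, depth = depth,
                 tau = tau, baseline_mean = mu0, baseline_noise = sigma0,
                 empty = FALSE),
            class = "injection_window")
}

#' @export
print.injection_window <- function(x, ...) {
  if (x$empty) {
    cat("No injection artifact detected\n")
  } else {
    cat(sprintf("Injection artifact: onset %.1f s, window end %.1f s, depth %.3g mN/m (tau %.3g s)\n",
                x$t_start, x$t_end, x$depth, x$tau))
  }
  invisible(x)
}

#' Injection-artifact-corrected surface-pressure change
#'
#' Estimates the sustained pressure change after analyte injection as the
#' mean over the last `analysis_span` seconds of the trace minus the mean
#' over the pre-injection baseline, excluding the injection-artifact window.
#' The standard error combines the two segment variances; a linear drift rate
#' fitted to the baseline segment is reported as a diagnostic, since for
#' near-zero responses baseline drift and genuine adsorption are not
#' distinguishable from the trace alone.
#'
#' @param trace A `pressure_trace`.
#' @param window An [detect_injection()] window, or `NULL` to detect it from
#'   the trace. When the window is empty, the annotated `injection_time`
#'   attribute of the trace separates baseline from response.
#' @param analysis_span Length (s) of tail data averaged for the final level.
#' @return A list of class `pressure_change`: `delta_pi` (mN m^-1), `se`,
#'   `baseline_mean`, `tail_mean`, `drift_mN_per_m_per_s`, `window` and the
#'   segment sizes `n_baseline`, `n_tail`.
#' @export
#' @examples
#' tr <- simulate_pressure_trace(langmuir_gen_params(delta_pi_inf = 1.07),
#'                               seed = 1)
#' corrected_pressure_change(tr)
corrected_pressure_change <- function(trace, window = NULL,
                                      analysis_span = 300) {
  t <- trace$time_s
  p <- trace$pressure_mN_per_m
  check_positive(analysis_span, "analysis_span")
  if (is.null(window)) window <- detect_injection(trace)
  if (window$empty) {
    t0 <- attr(trace, "injection_time")
    if (is.null(t0))
      stop_param("no artifact found and no annotated injection time")
    t_end <- t0
  } else {
    t0 <- window$t_start
    t_end <- window$t_end
  }
  base_sel <- t < t0
  if (sum(base_sel) < 2L) stop_param("no pre-injection baseline")
  tail_start <- t[length(t)] - analysis_span
  if (tail_start < t_end)
    stop_param("insufficient post-window data for the analysis span")
  tail_sel <- t >= tail_start
  delta <- mean(p[tail_sel]) - mean(p[base_sel])
  se <- sqrt(var(p[base_sel]) / sum(base_sel) +
               var(p[tail_sel]) / sum(tail_sel))
  drift <- unname(coef(lm(p[base_sel] ~ t[base_sel]))[2L])
  structure(list(delta_pi = delta, se = se,
                 baseline_mean = mean(p[base_sel]),
                 tail_mean = mean(p[tail_sel]),
                 drift_mN_per_m_per_s = drift,
                 window = window,
                 n_baseline = sum(base_sel), n_tail = sum(tail_sel)),
            class = "pressure_change")
}

#' @export
print.pressure_change <- function(x, ...) {
  cat(sprintf("Corrected surface-pressure change: %.3f +/- %.3f mN/m\n",
              x$delta_pi, x$se))
  cat(sprintf("  baseline %.3f, tail %.3f mN/m; baseline drift %.2g mN/m/s\n",
              x$baseline_mean, x$tail_mean, x$drift_mN_per_m_per_s))
  invisible(x)
}
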