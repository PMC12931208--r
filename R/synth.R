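#' Event-generator parameters
#'
#' Parameters of the renewal process that drives simulated single-molecule
#' binding events. Inter-arrival times are drawn from the exponential mixture
#' `w1 * Exp(k_on1) + (1 - w1) * Exp(k_on2)`; spike dwell times from
#' `Exp(k_off)`; event amplitudes from a Normal truncated at zero; each event
#' is a persistent step with probability `step_fraction`, otherwise a
#' transient spike.
#'
#' @param k_on1 Fast arrival rate (s^-1).
#' @param k_on2 Slow arrival rate (s^-1), or `NULL` for a single-component
#'   arrival process.
#' @param w1 Probability that an interval is drawn from the fast component.
#'   Must be 1 when `k_on2` is `NULL`.
#' @param k_off Spike dwell rate (s^-1).
#' @param amp_mean Mean event amplitude (fm).
#' @param amp_sd Amplitude standard deviation (fm); 0 gives fixed amplitudes.
#' @param step_fraction Probability an event is a persistent step.
#' @param duration Total simulated time (s).
#' @param release_rate Optional release rate (s^-1) for steps; by default
#'   steps persist to the end of the trace.
#' @return An object of class `event_gen_params`.
#' @export
#' @examples
#' event_gen_params(k_on1 = 0.47, k_on2 = 0.03, w1 = 0.5, k_off = 27,
#'                  amp_mean = 50, amp_sd = 8, step_fraction = 0,
#'                  duration = 600)
event_gen_params <- function(k_on1, k_on2 = NULL, w1 = 1, k_off,
                             amp_mean, amp_sd, step_fraction,
                             duration, release_rate = NULL) {
  check_positive(k_on1, "k_on1")
  if (!is.null(k_on2)) check_positive(k_on2, "k_on2")
  check_fraction(w1, "w1")
  if (is.null(k_on2) && w1 != 1)
    stop_param("`w1` must be 1 when `k_on2` is absent")
  check_positive(k_off, "k_off")
  check_positive(amp_mean, "amp_mean")
  check_nonneg(amp_sd, "amp_sd")
  check_fraction(step_fraction, "step_fraction")
  check_positive(duration, "duration")
  if (!is.null(release_rate)) check_positive(release_rate, "release_rate")
  structure(list(k_on1 = k_on1, k_on2 = k_on2, w1 = w1, k_off = k_off,
                 amp_mean = amp_mean, amp_sd = amp_sd,
                 step_fraction = step_fraction, duration = duration,
                 release_rate = release_rate),
            class = "event_gen_params")
}

#' Trace noise parameters
#'
#' @param sigma_white Per-frame white-noise standard deviation (fm). The
#'   default 2 fm puts typical 20-90 fm single-molecule events at a
#'   signal-to-noise ratio of roughly 10-45.
#' @param drift_rate Linear drift (fm s^-1).
#' @param frame_interval Sampling period (s); 0.02 s matches swept-laser
#'   acquisition at one spectrum every 20 ms.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(sigma_white = 2, drift_rate = 0,
                         frame_interval = 0.02) {
  check_nonneg(sigma_white, "sigma_white")
  if (!is.numeric(drift_rate) || length(drift_rate) != 1L || !is.finite(drift_rate))
    stop_param("`drift_rate` must be a single finite number")
  check_positive(frame_interval, "frame_interval")
  structure(list(sigma_white = sigma_white, drift_rate = drift_rate,
                 frame_interval = frame_interval),
            class = "noise_params")
}

#' Draw inter-arrival times from a one- or two-component exponential mixture
#'
#' @param n Number of draws.
#' @param k1 Fast rate (s^-1).
#' @param k2 Slow rate (s^-1) or `NULL` for a single component.
#' @param w1 Mixture weight of the fast component.
#' @param seed Optional integer seed; the caller's RNG state is preserved.
#' @return Numeric vector of `n` intervals (s).
#' @export
#' @examples
#' x <- rexp_mixture(1000, k1 = 0.47, k2 = 0.03, w1 = 0.5, seed = 1)
rexp_mixture <- function(n, k1, k2 = NULL, w1 = 1, seed = NULL) {
  check_positive(k1, "k1")
  if (!is.null(k2)) check_positive(k2, "k2")
  check_fraction(w1, "w1")
  if (is.null(k2) && w1 != 1)
    stop_param("`w1` must be 1 when `k2` is absent")
  with_seed(seed, {
    if (is.null(k2)) {
      rexp(n, rate = k1)
    } else {
      fast <- runif(n) < w1
      x <- numeric(n)
      x[fast] <- rexp(sum(fast), rate = k1)
      x[!fast] <- rexp(sum(!fast), rate = k2)
      x
    }
  })
}

# Normal(amp_mean, amp_sd) truncated at 0 by rejection; amp_sd = 0 returns
# the constant mean.
ramp_truncated <- function(n, amp_mean, amp_sd) {
  if (n == 0L) return(numeric(0))
  if (amp_sd == 0) return(rep(amp_mean, n))
  out <- rnorm(n, amp_mean, amp_sd)
  bad <- which(out <= 0)
  while (length(bad)) {
    out[bad] <- rnorm(length(bad), amp_mean, amp_sd)
    bad <- bad[out[bad] <= 0]
  }
  out
}

#' Simulate a ground-truth event list
#'
#' Generates event onsets from the renewal process defined by
#' [event_gen_params()], assigns step/spike types, truncated-Gaussian
#' amplitudes and exponential spike dwell times, and returns the list together
#' with the generating parameters as attached ground truth.
#'
#' @param params An [event_gen_params()] object.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `ground_truth`: a list with elements `events`
#'   (data frame with columns `type`, `onset`, `amplitude`, `dwell`),
#'   `params`, `seed` and logical `short_duration`, which flags a duration
#'   below one expected inter-arrival time (in which case the event list is
#'   empty).
#' @export
#' @examples
#' p <- event_gen_params(k_on1 = 16.1, k_off = 27, amp_mean = 50, amp_sd = 8,
#'                       step_fraction = 0, duration = 100)
#' gt <- simulate_events(p, seed = 42)
#' nrow(gt$events)
simulate_events <- function(params, seed = NULL) {
  if (!inherits(params, "event_gen_params"))
    stop_param("`params` must be an `event_gen_params` object")
  p <- params
  mean_interval <- p$w1 / p$k_on1 +
    if (is.null(p$k_on2)) 0 else (1 - p$w1) / p$k_on2
  if (p$duration < mean_interval) {
    warning("duration is shorter than one expected inter-arrival time; ",
            "returning empty ground truth")
    ev <- data.frame(type = character(0), onset = numeric(0),
                     amplitude = numeric(0), dwell = numeric(0))
    return(structure(list(events = ev, params = p, seed = seed,
                          short_duration = TRUE),
                     class = "ground_truth"))
  }
  with_seed(seed, {
    # draw arrivals in chunks until past the end of the trace
    chunk <- max(16L, ceiling(2 * p$duration / mean_interval))
    onsets <- numeric(0)
    t_last <- 0
    while (t_last <= p$duration) {
      gaps <- rexp_mixture(chunk, p$k_on1, p$k_on2, p$w1)
      onsets <- c(onsets, t_last + cumsum(gaps))
      t_last <- onsets[length(onsets)]
    }
    onsets <- onsets[onsets < p$duration]
    n <- length(onsets)
    type <- ifelse(runif(n) < p$step_fraction, "step", "spike")
    dwell <- rep(NA_real_, n)
    dwell[type == "spike"] <- rexp(sum(type == "spike"), rate = p$k_off)
    if (!is.null(p$release_rate))
      dwell[type == "step"] <- rexp(sum(type == "step"), rate = p$release_rate)
    amplitude <- ramp_truncated(n, p$amp_mean, p$amp_sd)
    ev <- data.frame(type = type, onset = onsets, amplitude = amplitude,
                     dwell = dwell)
    structure(list(events = ev, params = p, seed = seed,
                   short_duration = FALSE),
              class = "ground_truth")
  })
}

#' Build a ground truth with a fixed census of steps and spikes
#'
#' Places exactly `n_steps` persistent steps and `n_spikes` transient spikes
#' at uniformly random onsets over the trace, with truncated-Gaussian
#' amplitudes and exponential spike dwells. Useful for detector benchmarks
#' where the event counts, not the arrival process, are the ground truth.
#'
#' @param n_steps,n_spikes Event counts.
#' @param duration Trace length (s).
#' @param amp_mean,amp_sd Amplitude distribution (fm); `amp_sd = 0` gives
#'   fixed amplitudes.
#' @param k_off Spike dwell rate (s^-1).
#' @param margin Onsets are confined to `[margin, duration - margin]` (s).
#' @param seed Optional integer seed.
#' @return A `ground_truth` object (see [simulate_events()]).
#' @export
#' @examples
#' gt <- census_truth(n_steps = 30, n_spikes = 27, duration = 900,
#'                    amp_mean = 40, amp_sd = 0, seed = 7)
#' table(gt$events$type)
census_truth <- function(n_steps, n_spikes, duration = 900,
                         amp_mean = 40, amp_sd = 0, k_off = 5.4,
                         margin = 5, seed = NULL) {
  stopifnot(n_steps >= 0, n_spikes >= 0)
  check_positive(duration, "duration")
  check_positive(k_off, "k_off")
  with_seed(seed, {
    n <- n_steps + n_spikes
    onsets <- sort(runif(n, margin, duration - margin))
    type <- sample(c(rep("step", n_steps), rep("spike", n_spikes)))
    dwell <- rep(NA_real_, n)
    dwell[type == "spike"] <- rexp(n_spikes, rate = k_off)
    amplitude <- ramp_truncated(n, amp_mean, amp_sd)
    params <- event_gen_params(
      k_on1 = max(n, 1) / duration, k_off = k_off, amp_mean = amp_mean,
      amp_sd = amp_sd, step_fraction = if (n > 0) n_steps / n else 0,
      duration = duration)
    structure(list(events = data.frame(type = type, onset = onsets,
                                       amplitude = amplitude, dwell = dwell),
                   params = params, seed = seed, short_duration = FALSE),
              class = "ground_truth")
  })
}

#' Construct a resonance-shift trace
#'
#' @param time_s Uniform time grid (s).
#' @param dlambda_fm Resonance shift relative to trace start (fm).
#' @param fwhm_fm Optional linewidth series (fm).
#' @param channel One of `"TE"`, `"TM"`, `"unpolarized"`.
#' @return A data frame of class `resonance_trace` with attributes
#'   `frame_interval` and `channel`.
#' @export
resonance_trace <- function(time_s, dlambda_fm, fwhm_fm = NULL,
                            channel = c("unpolarized", "TE", "TM")) {
  channel <- match.arg(channel)
  stopifnot(length(time_s) == length(dlambda_fm))
  if (length(time_s) >= 2L) {
    dts <- diff(time_s)
    if (max(dts) - min(dts) > 1e-9 * max(abs(dts)))
      stop_param("`time_s` must be uniformly sampled")
    dt <- dts[1L]
  } else dt <- NA_real_
  out <- data.frame(time_s = time_s, dlambda_fm = dlambda_fm)
  if (!is.null(fwhm_fm)) out$fwhm_fm <- fwhm_fm
  structure(out, frame_interval = dt, channel = channel,
            class = c("resonance_trace", "data.frame"))
}

#' Render a ground truth into a sampled resonance trace
#'
#' Events contribute boxcars: a spike adds its amplitude over
#' `[onset, onset + dwell)`, a step from its onset to the end of the trace.
#' Frames partially covered by an event receive the area-weighted fraction of
#' the amplitude, so sub-frame events still contribute to the frame that
#' overlaps them. Linear drift and white noise are added on top.
#'
#' @param truth A `ground_truth` object.
#' @param noise A [noise_params()] object.
#' @param seed Optional integer seed for the noise draw.
#' @param channel Channel label for the output trace.
#' @param amplitude_scale Multiplier applied to all event amplitudes (used for
#'   TE/TM anisotropy rendering).
#' @return A [resonance_trace()].
#' @export
#' @examples
#' p <- event_gen_params(k_on1 = 0.5, k_off = 16, amp_mean = 40, amp_sd = 5,
#'                       step_fraction = 0.5, duration = 60)
#' tr <- render_trace(simulate_events(p, seed = 1), noise_params(), seed = 2)
render_trace <- function(truth, noise = noise_params(), seed = NULL,
                         channel = "unpolarized", amplitude_scale = 1) {
  if (!inherits(truth, "ground_truth"))
    stop_param("`truth` must be a `ground_truth` object")
  if (!inherits(noise, "noise_params"))
    stop_param("`noise` must be a `noise_params` object")
  duration <- truth$params$duration
  if (!is.finite(duration) || duration <= 0)
    stop_param("ground truth has non-positive duration")
  dt <- noise$frame_interval
  n <- floor(duration / dt + 1e-9)
  time <- (seq_len(n) - 1L) * dt
  signal <- numeric(n)
  ev <- truth$events
  if (nrow(ev)) {
    for (i in seq_len(nrow(ev))) {
      a <- ev$onset[i]
      b <- if (ev$type[i] == "spike" || !is.na(ev$dwell[i]))
        a + ev$dwell[i] else duration
      b <- min(b, duration)
      if (b <= a) next
      i0 <- max(1L, floor(a / dt) + 1L)
      i1 <- min(n, ceiling(b / dt))
      idx <- i0:i1
      overlap <- pmin(b, idx * dt) - pmax(a, (idx - 1L) * dt)
      signal[idx] <- signal[idx] +
        ev$amplitude[i] * amplitude_scale * overlap / dt
    }
  }
  with_seed(seed, {
    x <- signal + noise$drift_rate * time +
      if (noise$sigma_white > 0) rnorm(n, 0, noise$sigma_white) else 0
    resonance_trace(time, x, channel = channel)
  })
}

#' Simulate a paired TE/TM channel from one ground truth
#'
#' The TM channel carries the same events as the TE channel with all
#' amplitudes multiplied by `anisotropy_ratio`; noise is drawn independently
#' per channel.
#'
#' @param truth A `ground_truth` object.
#' @param anisotropy_ratio TM/TE amplitude ratio (> 0).
#' @param noise A [noise_params()] object applied to both channels.
#' @param seed Optional integer seed.
#' @return A list with elements `te` and `tm`, each a [resonance_trace()].
#' @export
simulate_tm_te <- function(truth, anisotropy_ratio, noise = noise_params(),
                           seed = NULL) {
  check_positive(anisotropy_ratio, "anisotropy_ratio")
  with_seed(seed, {
    te <- render_trace(truth, noise, seed = NULL, channel = "TE")
    tm <- render_trace(truth, noise, seed = NULL, channel = "TM",
                       amplitude_scale = anisotropy_ratio)
    list(te = te, tm = tm)
  })
}

#' Simulate a temperature series of Eyring-governed rate constants
#'
#' @param dH Activation enthalpy (J mol^-1).
#' @param dS Activation entropy (J mol^-1 K^-1).
#' @param temperatures Temperatures (K); default grid spans 288-310 K.
#' @param rel_noise Relative standard deviation of multiplicative lognormal
#'   noise on the rates (0 for noiseless).
#' @param seed Optional integer seed.
#' @return Data frame with columns `T_K` and `k_per_s`.
#' @export
#' @examples
#' simulate_temperature_series(25e3, 20, rel_noise = 0)
simulate_temperature_series <- function(dH, dS,
                                        temperatures = seq(288, 310, by = 5.5),
                                        rel_noise = 0, seed = NULL) {
  if (length(temperatures) == 0L)
    stop_param("`temperatures` must be non-empty")
  if (any(!is.finite(temperatures)) || any(temperatures <= 0))
    stop_param("`temperatures` must be positive and finite")
  check_nonneg(rel_noise, "rel_noise")
  k <- eyring_rate(dH, dS, temperatures)
  with_seed(seed, {
    if (rel_noise > 0) {
      sdlog <- sqrt(log1p(rel_noise^2))
      # mean-one multiplicative noise with relative s.d. = rel_noise
      k <- k * exp(rnorm(length(k), -sdlog^2 / 2, sdlog))
    }
    data.frame(T_K = temperatures, k_per_s = k)
  })
}

#' Langmuir trace generator parameters
#'
#' The generated pressure trace is flat at `pi0` before the injection, then
#' follows `pi0 - artifact_depth * exp(-(t - t0)/artifact_recovery_tau) +
#' delta_pi_inf * (1 - exp(-(t - t0)/adsorption_tau))` plus white noise.
#'
#' @param pi0 Baseline surface pressure (mN m^-1); monolayers are compressed
#'   to 30 mN m^-1 before injection.
#' @param artifact_depth Depth of the sharp injection artifact (mN m^-1).
#' @param artifact_recovery_tau Artifact recovery time constant (s).
#' @param delta_pi_inf Sustained adsorption rise (mN m^-1).
#' @param adsorption_tau Adsorption time constant (s).
#' @param sigma Noise standard deviation (mN m^-1).
#' @param injection_time Injection time (s); must lie within the trace.
#' @param duration Trace length (s).
#' @param dt Sampling period (s).
#' @return An object of class `langmuir_gen_params`.
#' @export
langmuir_gen_params <- function(pi0 = 30, artifact_depth = 0.5,
                                artifact_recovery_tau = 30,
                                delta_pi_inf = 1.07, adsorption_tau = 30,
                                sigma = 0.02, injection_time = 120,
                                duration = 1200, dt = 1) {
  check_positive(pi0, "pi0")
  check_nonneg(artifact_depth, "artifact_depth")
  check_positive(artifact_recovery_tau, "artifact_recovery_tau")
  check_nonneg(delta_pi_inf, "delta_pi_inf")
  check_positive(adsorption_tau, "adsorption_tau")
  check_nonneg(sigma, "sigma")
  check_positive(duration, "duration")
  check_positive(dt, "dt")
  if (injection_time <= 0 || injection_time >= duration)
    stop_param("`injection_time` must lie within the trace")
  structure(list(pi0 = pi0, artifact_depth = artifact_depth,
                 artifact_recovery_tau = artifact_recovery_tau,
                 delta_pi_inf = delta_pi_inf, adsorption_tau = adsorption_tau,
                 sigma = sigma, injection_time = injection_time,
                 duration = duration, dt = dt),
            class = "langmuir_gen_params")
}

#' Simulate a Langmuir surface-pressure trace
#'
#' @param params A [langmuir_gen_params()] object.
#' @param seed Optional integer seed.
#' @return A data frame of class `pressure_trace` with columns `time_s` and
#'   `pressure_mN_per_m` and an `injection_time` attribute.
#' @export
#' @examples
#' tr <- simulate_pressure_trace(langmuir_gen_params(), seed = 1)
simulate_pressure_trace <- function(params, seed = NULL) {
  if (!inherits(params, "langmuir_gen_params"))
    stop_param("`params` must be a `langmuir_gen_params` object")
  p <- params
  n <- floor(p$duration / p$dt + 1e-9)
  time <- (seq_len(n) - 1L) * p$dt
  u <- pmax(0, time - p$injection_time)
  pressure <- rep(p$pi0, n)
  post <- time >= p$injection_time
  pressure[post] <- p$pi0 -
    p$artifact_depth * exp(-u[post] / p$artifact_recovery_tau) +
    p$delta_pi_inf * (1 - exp(-u[post] / p$adsorption_tau))
  with_seed(seed, {
    if (p$sigma > 0) pressure <- pressure + rnorm(n, 0, p$sigma)
    structure(data.frame(time_s = time, pressure_mN_per_m = pressure),
              injection_time = p$injection_time,
              class = c("pressure_trace", "data.frame"))
  })
}
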