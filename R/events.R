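#' Detect step and spike events in a resonance-shift trace
#'
#' Two-stage detector for the event taxonomy of single-molecule WGM traces:
#' persistent level changes (steps, sustained membrane association) and
#' transient excursions (spikes, brief visits to the plasmonic near field).
#'
#' The noise scale is estimated robustly as the scaled median absolute
#' deviation of successive differences, which is insensitive to both events
#' and slow drift. Steps are located by a two-sided running-median jump
#' statistic (windows of `jump_window` seconds on either side of each frame);
#' a candidate jump is accepted as a step when the level change persists for
#' at least `step_min_duration` seconds, and its amplitude is the difference
#' of the post- and pre-onset median levels. The fitted step staircase and a
#' running-median drift baseline (window `baseline_window` seconds) are then
#' subtracted, and spikes are excursions of the residual above
#' `threshold_sigmas` times the noise scale; to control the per-frame false
#' alarm rate, a single-frame excursion must additionally exceed
#' `threshold_sigmas + 1` noise standard deviations. Spike amplitude is the
#' peak residual; the dwell time is the time spent above half amplitude, so
#' recorded dwells are never shorter than one frame.
#'
#' @param trace A [resonance_trace()] of at least 10 s and 100 frames.
#' @param threshold_sigmas Detection threshold in units of the noise scale.
#' @param step_min_duration Minimum persistence (s) for a level change to be
#'   a step rather than a spike.
#' @param baseline_window Running-median window (s) for drift removal.
#' @param jump_window Half-window (s) of the step jump statistic; also the
#'   detector's resolution for closely spaced steps.
#' @param metadata Optional named list (analyte, concentration, temperature,
#'   ...) carried on the result.
#' @return An `event_table`: a data frame with columns `type`, `onset_s`,
#'   `amplitude_fm`, `tau_s` (NA for steps) and `snr`, with attributes
#'   `sigma` (estimated noise, fm), `frame_interval` and `metadata`.
#' @export
#' @examples
#' p <- event_gen_params(k_on1 = 0.2, k_off = 16, amp_mean = 40, amp_sd = 0,
#'                       step_fraction = 1, duration = 120)
#' tr <- render_trace(simulate_events(p, seed = 1), noise_params(4), seed = 2)
#' detect_events(tr)
detect_events <- function(trace, threshold_sigmas = 3,
                          step_min_duration = 1.0, baseline_window = 5,
                          jump_window = 0.25, metadata = list()) {
  if (!inherits(trace, "resonance_trace"))
    stop_param("`trace` must be a `resonance_trace`")
  check_positive(threshold_sigmas, "threshold_sigmas")
  x <- trace$dlambda_fm
  time <- trace$time_s
  n <- length(x)
  if (n < 100L) stop_param("trace has fewer than 100 frames")
  dt <- attr(trace, "frame_interval")
  if (!is.finite(dt)) stop_param("trace sampling interval is undefined")
  if (time[n] - time[1L] < 10) stop_param("trace must span at least 10 s")

  sigma <- mad(diff(x)) / sqrt(2)
  # floor the scale against floating-point residue on noiseless fixtures
  sigma_eff <- max(sigma, 1e-8 * diff(range(x)), .Machine$double.eps)

  ## ---- stage 1: steps via a two-sided running-median jump statistic ----
  w <- max(3L, round(jump_window / dt))
  if (w %% 2L == 0L) w <- w + 1L
  h <- (w - 1L) %/% 2L
  rm_ <- runmed(x, w, endrule = "median")
  J <- rep(0, n)
  jr <- (h + 2L):(n - h)
  J[jr] <- rm_[jr + h] - rm_[jr - 1L - h]
  sigma_J <- sigma_eff * sqrt(pi / w)

  cand <- which(J > threshold_sigmas * sigma_J)
  clusters <- split_clusters(cand, gap = w)
  peaks <- vapply(clusters, function(cl) cl[which.max(J[cl])], integer(1))

  wlev <- round(min(step_min_duration, 2) / dt)   # level-estimation window
  wper <- round(step_min_duration / dt)           # persistence lag
  steps <- list()
  for (i in seq_along(peaks)) {
    jpk <- peaks[i]
    lo_bound <- if (i > 1L) peaks[i - 1L] + 2L else 1L
    hi_bound <- if (i < length(peaks)) peaks[i + 1L] - 2L else n
    pre_idx <- max(lo_bound, jpk - w - wlev + 1L):max(lo_bound, jpk - w)
    post_idx <- min(hi_bound, jpk + w):min(hi_bound, jpk + w + wlev - 1L)
    if (length(pre_idx) < 3L || length(post_idx) < 3L) next
    pre <- median(x[pre_idx])
    post <- median(x[post_idx])
    amp <- post - pre
    sd_diff <- sigma_eff *
      sqrt(pi / 2 * (1 / length(pre_idx) + 1 / length(post_idx)))
    if (amp <= threshold_sigmas * sd_diff) next
    # persistence: the elevated level must still hold step_min_duration later
    # (unless the trace or the next jump arrives first)
    per_idx <- min(hi_bound, jpk + wper):min(hi_bound, jpk + wper + w)
    persistent <- if (max(per_idx) <= jpk + w) TRUE
      else median(x[per_idx]) - pre >= amp / 2
    if (!persistent) next
    # refine onset: first half-amplitude crossing of the smoothed trace
    seg <- max(1L, jpk - w):min(n, jpk + w)
    xs <- runmed(x[seg], 3L, endrule = "median")
    crossed <- which(xs >= (pre + post) / 2)
    onset_idx <- if (length(crossed)) seg[crossed[1L]] else jpk
    steps[[length(steps) + 1L]] <-
      data.frame(type = "step", onset_s = time[onset_idx],
                 amplitude_fm = amp, tau_s = NA_real_,
                 snr = amp / sigma_eff)
  }
  steps <- if (length(steps)) do.call(rbind, steps) else NULL

  ## ---- stage 2: spikes in the staircase- and drift-corrected residual ----
  stair <- numeric(n)
  if (!is.null(steps)) {
    for (i in seq_len(nrow(steps))) {
      a <- steps$onset_s[i] - time[1L]
      i0 <- max(1L, floor(a / dt) + 1L)
      idx <- i0:n
      overlap <- pmin(1, (idx * dt - a) / dt)
      stair[idx] <- stair[idx] + steps$amplitude_fm[i] * pmax(0, overlap)
    }
  }
  kb <- round(baseline_window / dt)
  if (kb %% 2L == 0L) kb <- kb + 1L
  kb <- min(kb, if (n %% 2L == 0L) n - 1L else n)
  b <- runmed(x - stair, kb, endrule = "median")
  r <- x - stair - b

  above <- r > threshold_sigmas * sigma_eff
  if (!is.null(steps)) {          # mask the step transition frames
    for (a in steps$onset_s) {
      i0 <- max(1L, floor((a - time[1L]) / dt) + 1L - w)
      above[i0:min(n, i0 + 2L * w)] <- FALSE
    }
  }
  spike_clusters <- split_clusters(which(above), gap = 1L)
  ranges <- list()
  for (cl in spike_clusters) {
    peak <- max(r[cl])
    if (length(cl) < 2L && peak < (threshold_sigmas + 1) * sigma_eff) next
    half <- peak / 2
    lo <- cl[1L]; hi <- cl[length(cl)]
    while (lo > 1L && r[lo - 1L] > half) lo <- lo - 1L
    while (hi < n && r[hi + 1L] > half) hi <- hi + 1L
    ranges[[length(ranges) + 1L]] <- c(lo, hi)
  }
  ranges <- merge_ranges(ranges)
  spikes <- list()
  for (rg in ranges) {
    idx <- rg[1L]:rg[2L]
    peak <- max(r[idx])
    tau <- length(idx) * dt
    if (tau >= step_min_duration) {
      # residual excursion persisting beyond the step scale: record as a step
      spikes[[length(spikes) + 1L]] <-
        data.frame(type = "step", onset_s = time[rg[1L]],
                   amplitude_fm = median(r[idx]), tau_s = NA_real_,
                   snr = median(r[idx]) / sigma_eff)
    } else {
      spikes[[length(spikes) + 1L]] <-
        data.frame(type = "spike", onset_s = time[rg[1L]],
                   amplitude_fm = peak, tau_s = tau,
                   snr = peak / sigma_eff)
    }
  }
  spikes <- if (length(spikes)) do.call(rbind, spikes) else NULL

  out <- rbind(steps, spikes)
  if (is.null(out))
    out <- data.frame(type = character(0), onset_s = numeric(0),
                      amplitude_fm = numeric(0), tau_s = numeric(0),
                      snr = numeric(0))
  out <- out[order(out$onset_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, sigma = sigma, frame_interval = dt,
            metadata = c(metadata, list(channel = attr(trace, "channel"))),
            class = c("event_table", "data.frame"))
}

# Split sorted indices into clusters separated by more than `gap`.
split_clusters <- function(idx, gap) {
  if (!length(idx)) return(list())
  brk <- c(0L, which(diff(idx) > gap), length(idx))
  lapply(seq_len(length(brk) - 1L),
         function(i) idx[(brk[i] + 1L):brk[i + 1L]])
}

# Merge overlapping [lo, hi] index ranges.
merge_ranges <- function(ranges) {
  if (length(ranges) < 2L) return(ranges)
  ranges <- ranges[order(vapply(ranges, `[`, numeric(1), 1L))]
  out <- list(ranges[[1L]])
  for (rg in ranges[-1L]) {
    last <- out[[length(out)]]
    if (rg[1L] <= last[2L] + 1L)
      out[[length(out)]] <- c(last[1L], max(last[2L], rg[2L]))
    else out[[length(out) + 1L]] <- rg
  }
  out
}

#' Inter-event intervals for one event type
#'
#' Time differences between successive onsets of the given type; the
#' distribution of these intervals encodes the association (on) rate.
#'
#' @param table An `event_table` from [detect_events()], or any data frame
#'   with `type` and `onset_s` columns.
#' @param type `"spike"` or `"step"`.
#' @return Numeric vector of intervals (s); length is one less than the
#'   number of events of that type.
#' @export
interevent_intervals <- function(table, type = c("spike", "step")) {
  type <- match.arg(type)
  on <- sort(table$onset_s[table$type == type])
  if (length(on) < 2L) return(numeric(0))
  diff(on)
}

#' Gaussian fit to the event-amplitude distribution
#'
#' Fits a normal distribution to detected event amplitudes (maximum
#' likelihood: sample mean and standard deviation, with their standard
#' errors) and flags misspecification by a Shapiro-Wilk normality test.
#'
#' @param table An `event_table` with at least 10 events.
#' @param bins Number of histogram bins computed alongside the fit.
#' @return A list of class `amplitude_fit`: `mu`, `sigma` (fm), `se_mu`,
#'   `se_sigma`, `n`, `degenerate` (TRUE when all amplitudes are identical),
#'   `gof_p` (Shapiro-Wilk p-value, NA when degenerate), `poor_fit`
#'   (TRUE when `gof_p < 0.01`) and `histogram`.
#' @export
amplitude_histogram <- function(table, bins = 20) {
  amps <- table$amplitude_fm
  n <- length(amps)
  if (n < 10L) stop_param("at least 10 events are required")
  mu <- mean(amps)
  s <- sd(amps) * sqrt((n - 1) / n)   # ML estimate
  degenerate <- s == 0
  gof_p <- if (degenerate) NA_real_ else
    tryCatch(stats::shapiro.test(amps)$p.value, error = function(e) NA_real_)
  h <- graphics::hist(amps, breaks = bins, plot = FALSE)
  structure(list(mu = mu, sigma = s, se_mu = s / sqrt(n),
                 se_sigma = s / sqrt(2 * n), n = n,
                 degenerate = degenerate, gof_p = gof_p,
                 poor_fit = isTRUE(gof_p < 0.01), histogram = h),
            class = "amplitude_fit")
}

#' Step and spike counts and their ratio
#'
#' @param table An `event_table`.
#' @return A list with `n_step`, `n_spike`, `ratio` (`NA` when there are no
#'   spikes) and `ratio_defined`.
#' @export
#' @examples
#' tbl <- data.frame(type = c(rep("step", 30), rep("spike", 27)),
#'                   onset_s = seq_len(57))
#' step_spike_counts(tbl)
step_spike_counts <- function(table) {
  n_step <- sum(table$type == "step")
  n_spike <- sum(table$type == "spike")
  list(n_step = n_step, n_spike = n_spike,
       ratio = if (n_spike > 0) n_step / n_spike else NA_real_,
       ratio_defined = n_spike > 0)
}

#' Match detected events to ground truth by onset time
#'
#' Greedy one-to-one matching of detected to true events of the same type
#' within an onset tolerance; used for recall/false-positive benchmarks and
#' the dead-time diagnostic.
#'
#' @param truth A `ground_truth` object.
#' @param table An `event_table`.
#' @param type Event type to match.
#' @param tol Onset tolerance (s).
#' @return A list with `n_truth`, `n_detected`, `n_matched`, `recall` and
#'   `false_positives` (detections of that type with no true counterpart).
#' @export
match_events <- function(truth, table, type = c("spike", "step"), tol = 0.15) {
  type <- match.arg(type)
  t_true <- truth$events$onset[truth$events$type == type]
  t_det <- table$onset_s[table$type == type]
  used <- rep(FALSE, length(t_det))
  matched <- 0L
  for (a in t_true) {
    d <- abs(t_det - a)
    d[used] <- Inf
    if (length(d) && min(d) <= tol) {
      used[which.min(d)] <- TRUE
      matched <- matched + 1L
    }
  }
  list(n_truth = length(t_true), n_detected = length(t_det),
       n_matched = matched,
       recall = if (length(t_true)) matched / length(t_true) else NA_real_,
       false_positives = length(t_det) - matched)
}

#' Dead-time diagnostic for spike detection
#'
#' Spikes shorter than the frame interval cannot have their dwell resolved;
#' under exponential dwells at rate `k_off` the geometric censoring bound on
#' the missed fraction is `1 - exp(-k_off * frame_interval)`. Area-weighted
#' rendering lets bright sub-frame events survive detection, so the observed
#' missed fraction is at most this bound.
#'
#' @param truth A `ground_truth` object whose parameters carry `k_off`.
#' @param table An `event_table` for the rendered trace.
#' @param frame_interval Sampling period (s).
#' @param tol Matching tolerance (s), see [match_events()].
#' @return A list with `predicted_missed` (the censoring bound), the
#'   `observed_missed` fraction, and the matching counts.
#' @export
dead_time_diagnostic <- function(truth, table, frame_interval = 0.02,
                                 tol = 0.15) {
  m <- match_events(truth, table, "spike", tol = tol)
  predicted <- 1 - exp(-truth$params$k_off * frame_interval)
  c(list(predicted_missed = predicted,
         observed_missed = 1 - m$recall), m)
}
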