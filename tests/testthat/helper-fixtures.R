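# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# Ground truth with hand-placed events (bypasses the renewal process).
manual_truth <- function(type, onset, amplitude, dwell = NA_real_,
                         duration = 100, k_off = 16) {
  params <- event_gen_params(k_on1 = max(length(onset), 1) / duration,
                             k_off = k_off,
                             amp_mean = if (length(amplitude))
                               mean(amplitude) else 1,
                             amp_sd = 0,
                             step_fraction = if (length(type))
                               mean(type == "step") else 0,
                             duration = duration)
  structure(list(events = data.frame(type = type, onset = onset,
                                     amplitude = amplitude,
                                     dwell = rep_len(dwell, length(onset))),
                 params = params, seed = NULL, short_duration = FALSE),
            class = "ground_truth")
}

# Survivor curve evaluated on exact model values (no sampling noise); used
# for noiseless-inversion checks. Carries no raw samples.
exact_curve <- function(times, surv_values) {
  structure(data.frame(time = times, surv = surv_values),
            n = length(times),
            class = c("survivor_curve", "data.frame"))
}

# Lorentzian test grid: 4 pm span around 780 nm, fine enough to resolve a
# 400 fm linewidth.
lorentz_grid <- function(n = 201, span_nm = 4e-3, center = 780) {
  seq(center - span_nm / 2, center + span_nm / 2, length.out = n)
}
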