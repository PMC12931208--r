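# wgmkinetics

Single-molecule kinetics from whispering-gallery-mode (WGM) sensor traces.

Optoplasmonic WGM sensors resolve individual small molecules — here,
neurotransmitters interacting with supported lipid bilayers — as
femtometre-scale shifts of an optical resonance sampled every 20 ms.
Transient visits appear as **spikes**, sustained membrane association as
persistent **steps**. This package is for experimentalists and analysts who
need to turn such traces (or raw sweep spectra) into kinetic and
thermodynamic parameters, and to validate every step of that chain against
simulated ground truth, since raw single-molecule recordings are rarely
deposited.

## What it computes

* **Survivor-function kinetics.** The empirical survivor function
  S(t) = P(T > t) of spike dwell times τ or inter-event intervals Δt is
  fitted with `y = A·exp(−k·t)` or the two-component mixture
  `y = A·exp(−k₁t) + B·exp(−k₂t)` (k₁ ≥ k₂, multi-start
  Levenberg–Marquardt). Dwell fits give the off-rate k_off and mean
  interaction time 1/k_off; interval fits give association rates. Model
  choice is by AIC on the sample likelihood (ΔAIC > 2) with an F-test as
  secondary evidence.
* **Event detection.** Robust two-stage detector: running-median jump
  statistic for steps (with a persistence criterion), staircase- and
  drift-corrected residual thresholding for spikes; amplitudes, dwell
  times, SNR, and step/spike censuses.
* **Resonance tracking.** Centroid or Lorentzian per-frame fits of sweep
  spectra into Δλ(t) and linewidth κ(t) traces.
* **Eyring analysis.** OLS of ln(k/T) on 1/T yields ΔH‡, ΔS‡ and
  ΔG‡ = ΔH‡ − T·ΔS‡ with propagated errors,
  k = (k_B·T/h)·exp(ΔS‡/R − ΔH‡/RT).
* **TE/TM anisotropy.** ΔΔλ(t) = Δλ_TM − Δλ_TE, the ratio
  R(t) = Δλ_TM/Δλ_TE with a floor guard, deviation scores against an
  isotropic baseline, and the first-order layer-thickness conversion
  t = a·Δλ/λ.
* **Langmuir monolayer analysis.** Injection-artifact detection and
  artifact-corrected sustained surface-pressure changes ΔΠ.
* **Seeded generators** for every input — event streams, traces, paired
  TE/TM channels, sweep spectra, temperature series, pressure traces —
  with ground truth attached for recovery testing.

## Worked example

Simulate a membrane-inert analyte — spike-only traffic with a
two-component association (k₁ = 0.47, k₂ = 0.03 s⁻¹, equal weights) and
fast dissociation (k_off = 27 s⁻¹) — then recover everything from the
rendered trace:

```r
library(wgmkinetics)

params <- event_gen_params(k_on1 = 0.47, k_on2 = 0.03, w1 = 0.5, k_off = 27,
                           amp_mean = 50, amp_sd = 8, step_fraction = 0,
                           duration = 1800)
truth  <- simulate_events(params, seed = 42)
trace  <- render_trace(truth, noise_params(sigma_white = 2), seed = 43)
events <- detect_events(trace)

dwells  <- events$tau_s[events$type == "spike"]
fit_off <- fit_single_exponential(survivor(dwells))
fit_off
#> 1-component exponential survivor fit (converged)
#>   k = 26.31 s^-1 (mean time 0.03801 s)
#>   RSS = 0.003517, AIC = -290.7, n = 8 points / 80 samples

dt <- interevent_intervals(events, "spike")
f1 <- fit_single_exponential(survivor(dt))
f2 <- fit_biexponential(survivor(dt))
select_model(f1, f2)$choice
#> [1] 2
f2
#> 2-component exponential survivor fit (converged)
#>   k1 = 0.3803 s^-1 (mean time 2.63 s)
#>   k2 = 0.02509 s^-1 (mean time 39.86 s)
#>   RSS = 0.0148, AIC = 605.7, n = 75 points / 79 samples
```

The detected off-rate (26.3 s⁻¹, mean dwell 38 ms) recovers the generating
27 s⁻¹ through the full detect-and-fit chain; the interval analysis
correctly prefers two association components and returns rate estimates
whose scatter reflects the modest event count (79 intervals), with rate
standard errors computed on the sample-likelihood scale. Whole runs
(simulate → detect → rate tables → Eyring/anisotropy/Langmuir stages, with
CSV/TSV/JSON outputs) are driven by `run_pipeline()` from a list or YAML
configuration; see `?run_pipeline` and the methods vignette in
`vignettes/`.

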