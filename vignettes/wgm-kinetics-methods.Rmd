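---
title: "Models and methods behind wgmkinetics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind wgmkinetics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wgmkinetics)
```

# The measurement this package models

An optoplasmonic whispering-gallery-mode (WGM) sensor tracks the resonance
wavelength of a glass microsphere, sampled here once per 20 ms frame. When a
single molecule enters the plasmonic near field the resonance shifts by tens
of femtometres. Two signal classes carry the biology:

* **spikes** — transient excursions: the molecule visits the sensing volume
  and leaves. Their dwell times $\tau$ are exponential with the dissociation
  rate $k_\mathrm{off}$, and the intervals $\Delta t$ between successive
  events carry the association rate.
* **steps** — persistent level changes: sustained association (membrane
  partitioning). Their dissociation is too slow to resolve, so only the
  step-interval statistics (and the step/spike census) are informative.

Around this core the package provides resonance tracking from raw sweep
spectra, survivor-function kinetics, Eyring activation thermodynamics,
TE/TM polarization anisotropy metrics, and Langmuir trough surface-pressure
analysis — together with seeded generators for every input, so each analysis
stage can be validated against attached ground truth.

# Kinetic model

Dwell times and inter-event intervals are modelled as exponential, or as a
two-component exponential mixture when association proceeds through two
kinetically distinct pathways (e.g. direct 3D arrival versus a surface-
mediated 2D pathway). The empirical survivor function

$$S(t) = \Pr(T > t)$$

is fitted by nonlinear least squares with a *free* amplitude,
$y = A e^{-kt}$ or $y = A e^{-k_1 t} + B e^{-k_2 t}$, mirroring how survivor
fits are conventionally drawn; the amplitudes are not constrained to
$A + B = 1$. Label switching is resolved by the convention $k_1 \ge k_2$,
and a fitted ratio $k_1/k_2 < 3$ raises an identifiability flag: below about
a factor of three the two components trade off against each other and the
split is not trustworthy. The mixture fit uses multi-start
Levenberg–Marquardt over a $5 \times 5$ log-spaced grid of rate pairs
spanning the observed time range, keeping the best residual.

## Uncertainties and model choice on the right scale

Adjacent survivor points share almost all of their underlying samples, so
any statistic that treats the curve points as independent observations —
the NLS covariance matrix, or an AIC built from the point-wise residuals —
overstates the information in the curve by orders of magnitude. The package
therefore reports rate standard errors from the Fisher information of the
exponential (or mixture) likelihood evaluated on the raw samples
($\mathrm{se}(\hat k) = \hat k/\sqrt{n}$ in the single-component case), and
computes the AIC used by `select_model()` from that same sample likelihood
(1 parameter for the single model; rates plus a weight, 3, for the mixture).
The interface is unchanged — the two-component model is preferred only when
it improves AIC by more than 2 — and an extra-sum-of-squares F-test on the
curve residuals is reported as secondary evidence. With this accounting the
nominal 95% interval for $k$ covers the truth at close to its nominal rate,
and model selection attains the intended specificity, which the test suite
checks by simulation.

`mle_rate()` ($\hat k = 1/\bar x$) is kept as an independent oracle: for
single-exponential data the NLS-on-survivor estimate must agree with it
within combined standard errors, and a test enforces this.

# Event detection

`detect_events()` works in two stages on a uniformly sampled trace:

1. **Noise scale.** $\hat\sigma$ is the median absolute deviation (scaled by
   1.4826) of successive differences divided by $\sqrt 2$ — robust to both
   events and slow drift. A floor of $10^{-8}$ of the trace range guards
   noiseless fixtures against floating-point residue.
2. **Steps.** A two-sided running-median jump statistic with 0.25 s windows
   flags candidate level changes; a candidate becomes a step when the level
   change exceeds the threshold *and* still holds one `step_min_duration`
   (default 1 s) after onset. The amplitude is the difference of post- and
   pre-onset medians over windows bounded by neighbouring candidates, and
   the onset is refined to the half-amplitude crossing. The 1 s persistence
   default separates the observed dwell scale (tens of milliseconds) from
   steps that persist for minutes; 0.25 s is the resolution limit for
   closely spaced steps, below which two true steps merge into one
   detection.
3. **Spikes.** The fitted step staircase and a 5 s running-median drift
   baseline are subtracted; excursions of the residual above
   `threshold_sigmas` $\times\,\hat\sigma$ (default 3) become spikes, with
   amplitude at the residual peak and dwell measured as time above half
   amplitude (stable under noise, and never shorter than one frame). A
   single-frame excursion must additionally clear
   $(\mathrm{threshold}+1)\,\hat\sigma$: at 50 frames per second a plain
   $3\sigma$ rule alone would produce several noise crossings per minute,
   and the extra sigma keeps the false-positive rate far below the
   0.02 events/s benchmark while leaving genuine events (which reach
   $\ge 10\sigma$ at the simulated amplitudes) untouched.

## Dead time and censoring

The frame interval imposes a dead time: a spike shorter than 20 ms cannot
have its dwell resolved. Under exponential dwells the geometric bound on the
missed fraction is $1 - e^{-k_\mathrm{off}\,\Delta}$ with $\Delta$ the frame
interval. Because the renderer distributes sub-frame events into their frame
area-weighted, bright sub-frame events still clear the threshold, so the
observed loss sits *below* this bound; `dead_time_diagnostic()` reports
both numbers. Recorded dwells are quantized to whole frames, which inflates
short-dwell estimates — visible when $1/k_\mathrm{off}$ approaches the frame
interval.

# What the generators emulate — and what they do not

`simulate_events()` draws a renewal process whose inter-arrival times come
from $w_1\,\mathrm{Exp}(k_{on,1}) + (1-w_1)\,\mathrm{Exp}(k_{on,2})$, marks
each event as a step with probability `step_fraction`, draws spike dwells
from $\mathrm{Exp}(k_\mathrm{off})$ and amplitudes from a Normal truncated
at zero (binding shifts are single-signed). Defaults that the data do not
pin down, chosen once:

* **White noise 2 fm per frame** — puts typical 20–90 fm events at SNR
  10–45, the regime in which single-molecule steps are clearly resolvable
  by eye, as published traces are.
* **Mixture weight $w_1 = 0.5$** — the published two-component amplitudes
  are unnormalized fit constants, so the generator exposes the weight
  explicitly and defaults to an equal split.
* **Steps persist to the end of the trace** — step dissociation is not
  resolved experimentally; an optional `release_rate` exists for stress
  tests.
* **Census dwell scale 5.4 s⁻¹** — for fixed-census fixtures
  (`census_truth()`), the spike dwell rate defaults to the published
  off-rate of the aromatic neurotransmitter most similar to histamine
  (dopamine, which shares its association frequency).

The generator keeps continuous-time truth and renders area-weighted frames,
so discretization bias is measurable rather than hidden. It does **not**
emulate instrument drift nonlinearity, baseline wander beyond a linear
term, photothermal transients, correlated noise, multi-molecule pile-up, or
optical mode structure: passing recovery tests shows the analysis chain is
correct for the stated stochastic model, not that real instrument artifacts
are handled.

# Resonance tracking

`lorentzian_model()` renders the transmission dip
$T(\lambda) = 1 - d\,\frac{(\kappa/2)^2}{(\lambda-\lambda_0)^2 + (\kappa/2)^2}$.
Per frame, the position is either the intensity-weighted centroid of
$1 - T$ over points above half the maximum dip (threshold 0.5 by default —
tighter thresholds discard noisy tail points and reduce jitter, which a
Monte-Carlo test verifies), or a Lorentzian fit initialized from the
centroid and the numerical half width, which also yields the linewidth
$\kappa$. Traces are reported as shifts relative to the first frame, in fm.
Frames without a discernible dip (depth < 0.05) are gaps; up to two
consecutive gaps are linearly interpolated, more is an error. The gap policy
is a package invention — acquisition losses are not characterized in the
source data.

# Eyring analysis

`eyring_fit()` runs ordinary least squares of $\ln(k/T)$ on $1/T$: the
slope is $-\Delta H^\ddagger/R$, the intercept $\ln(k_B/h) +
\Delta S^\ddagger/R$, and $\Delta G^\ddagger = \Delta H^\ddagger -
T_\mathrm{ref}\,\Delta S^\ddagger$ (with its error propagated from the full
regression covariance). The linearized form is standard Eyring practice; a
direct nonlinear refit on the rate scale is available as a cross-check.
Constants are pinned to CODATA values and guarded by a regression test.
Simulated temperature series default to a 288–310 K grid — a realistic
span for supported-bilayer experiments bounded by lipid phase behaviour and
evaporation. Over such a modest span the entropy (intercept) extrapolates
across $1/T \to 0$ and its standard error is intrinsically large; the
Monte-Carlo tests assert honest interval coverage rather than small errors.

# Anisotropy metrics

For paired channels, $\Delta\Delta\lambda(t) = \Delta\lambda_{TM} -
\Delta\lambda_{TE}$ and $R(t) = \Delta\lambda_{TM}/\Delta\lambda_{TE}$,
the latter only where $|\Delta\lambda_{TE}|$ exceeds a floor (default 5 fm,
2.5 noise standard deviations at the default noise) to avoid ratio blow-up
near zero shift. `isotropic_deviation()` scores the median ratio against a
user-supplied isotropic mode-set baseline in robust (IQR/1.349) units; the
baseline ratio is instrument-specific and therefore a configuration input,
not a constant. `layer_thickness()` applies the first-order size
perturbation $t = a\,\Delta\lambda/\lambda$; note this is a *radius*
increase — descriptions of the same number as a diameter increase conflate
the two, and the function documents the radius reading.

# Langmuir surface-pressure correction

Subphase injection produces a sharp artifact (depth ~0.5 mN/m) that decays
with a ~30 s constant, superimposed on any genuine adsorption rise.
`detect_injection()` finds the onset (first sample more than 5 baseline
noise SDs below the pre-injection level) and closes the window three
estimated recovery constants later, by which point the residual artifact is
~5% of its depth — comparable to the noise floor. The recovery constant is
estimated from the half-recovery time, which is biased short when the
adsorption rise overlaps the artifact; this only shrinks the excluded
window, and the estimate itself is insensitive to it because
`corrected_pressure_change()` averages the *last* `analysis_span` seconds
(default 300 s, long enough to average noise, late enough that both
transients have settled) against the pre-injection baseline. A baseline
drift rate is reported as a diagnostic: for responses of a few hundredths
of mN/m, drift and genuine adsorption cannot be separated from the trace
alone, so the package reports $\Delta\Pi$ with its error and no verdict.
With a slow adsorption constant (300 s) a 1200 s trace is ~95% saturated in
the analysis window, so recovered values sit a few percent below the
asymptote; the tolerance bands account for this.

# Orchestration and reproducibility

`run_pipeline()` validates its configuration (unknown keys are rejected
before any stage runs), then derives every stage's seed from the single
configuration seed by fixed offsets. A rerun with the same configuration
reproduces `report.json` byte for byte; timestamps live only in the log.

# Problem sizes and test design

Recovery tests use the sample sizes of the analyses they mirror: 5,000
dwell times per off-rate, 10,000 intervals per mixture, 2,000 events for
the sparse aromatic kinetics, a 900 s census trace, and 200–300 Monte-Carlo
replicates for coverage and model-selection operating characteristics —
large enough that the assertions' tolerances are dominated by the
estimators, not by Monte-Carlo error, and small enough that the full suite
runs in about a minute.

# Known limitations

* Steps closer than ~0.3 s merge into one detection; the census benchmark
  accepts the resulting occasional undercount.
* Spikes occurring within ~0.5 s of a step onset are masked out to avoid
  double-counting the transition and can be lost.
* Dwell quantization biases $\hat k_\mathrm{off}$ when $1/k_\mathrm{off}
  \lesssim 3$ frames; the dead-time diagnostic quantifies, but does not
  correct, this.
* The two-component mixture is the most complex arrival model fitted; more
  components, gamma-distributed dwells, or concentration–rate binding
  models are out of scope.
* No real-data ingestion quirks (sag, missing frames beyond two, spectral
  asymmetry) are modelled.
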