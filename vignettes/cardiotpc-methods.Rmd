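---
title: "Cardiac thermal performance curves: models, traits and comparative tests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac thermal performance curves: models, traits and comparative tests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardioTPC)
```

## The problem

Intertidal ectotherms such as neritid snails experience body temperatures
during emersion that range from seawater temperature to over 50 °C on
sun-exposed rock. Their cardiac activity, recorded with an infrared
reflectance sensor glued to the shell while the animal is warmed at a
controlled rate, traces out a *cardiac thermal performance curve* (cTPC):
heart rate rises roughly exponentially with temperature, peaks, then
collapses, and finally flatlines at the upper lethal temperature.
`cardioTPC` turns such raw sensor traces into five per-individual thermal
traits and runs the comparative analyses used to ask whether those traits
track habitat:

* **slope gradient** — the activation energy $E$ (eV) of the fitted rate
  model, describing the steepness of the upslope;
* **slope curvature** — $2 c_2$ from the quadratic
  $HR = c_0 + c_1 T + c_2 T^2$ fitted to the upslope
  (temperatures below $T_{opt}$), in bpm·°C$^{-2}$;
* **HRmax** — the fitted maximum heart rate (bpm);
* **Topt** — the temperature maximizing the fitted curve (°C);
* **ULT** — the upper lethal temperature, called from heartbeat
  flatlining (°C).

## The rate model

Heart rate as a function of body temperature is modelled with the
Sharpe–Schoolfield formulation in its high-temperature-inactivation form,

$$ r(T) \;=\; \frac{r_{tref}\,
   \exp\!\left[-\tfrac{E}{k}\!\left(\tfrac1T - \tfrac1{T_{ref}}\right)\right]}
  {1 + \exp\!\left[\tfrac{E_h}{k}\!\left(\tfrac1{T_h} - \tfrac1T\right)\right]} ,$$

with $T$ in Kelvin, $k = 8.617333\times10^{-5}$ eV K$^{-1}$, activation
energy $E$, deactivation energy $E_h > E$, and $T_h$ the temperature at
which the inactivation term halves the rate. $T_{ref}$ is fixed at 30 °C,
the start of the heating ramp, for identifiability. With $E_h > E > 0$ the
curve is positive and unimodal, and the optimum has the closed form

$$ T_{opt} = \frac{E_h T_h}{E_h + k T_h \ln(E_h/E - 1)} , $$

which the package uses as an internal oracle: the reported `t_opt_C` is the
argmax of the fitted curve on a 0.01 °C grid restricted to the observed
temperature range (we deliberately do not search outside the data), and the
two agree to well under the grid step.

Fitting is multi-start nonlinear least squares (Levenberg–Marquardt via
`minpack.lm`). Sharpe–Schoolfield fits are initialization-sensitive, so
`fit_ss()` uses one deterministic data-driven start plus `n_starts - 1 = 19`
draws from wide uniform boxes ($E \in [0.1, 2]$ eV, $E_h \in [1, 10]$ eV,
$T_h$ across the observed Kelvin range), keeping the converged start with
the lowest residual sum of squares. Windows at or after the flatline onset
are excluded before fitting: a stopped heart is a different regime (death),
not low performance. Fits whose best solution is rate-flat (relative span
< 1% over the observed range, or $E < 0.01$ eV, or $E_h \le E$) are
flagged degenerate.

## From trace to heart-rate series

The measurement chain is:

1. **Optional Bartlett smoothing** (`bartlett_smooth()`): convolution with
   a unit-sum triangular kernel; edge windows renormalized. Analyses can
   run on raw or smoothed traces; the per-trace pipeline defaults to a
   0.1 s kernel, which suppresses sensor noise at the 40 Hz sampling rate
   without flattening the ~0.15 s pulses.
2. **Beat detection** (`detect_beats()`): local maxima of the
   baseline-detrended signal with at least `min_prominence` height, thinned
   so no two beats are closer than the 0.25 s refractory period (taller
   peaks win; this tallest-first rule makes the beat count monotone in the
   threshold). The baseline is a 2 s *running median* rather than a moving
   average, and the default threshold is 4 × a robust noise scale estimated
   from the lower tail of the detrended signal (median minus the 15.87%
   quantile). Both choices matter near HRmax: pulses there occupy a large
   duty cycle, so a mean baseline and a MAD computed over the whole signal
   are both inflated by the pulses themselves, which in testing cost up to
   half the beats near the curve's peak; the median baseline and the
   one-sided scale are blind to the positive pulses and recover > 99% of
   beats at a noise SD of 20% of pulse height.
3. **Windowed rates** (`hr_series()`): sliding 60 s windows stepped by
   30 s; each reports $hr = 60\,n_{beats}/window$ and the arithmetic mean
   of its sample temperatures (robust to slight ramp nonlinearity). At the
   0.25 °C/min protocol rate a window spans 0.25 °C, which bounds the
   temperature resolution of everything downstream.
4. **Flatline call** (`detect_flatline()`): on a heating ramp, the ULT is
   the mean temperature of the first window of a terminal run of windows
   below 5 bpm lasting at least 120 s and persisting to the end of the
   trace. A sub-floor episode followed by recovery is *not* a ULT — this
   distinguishes death from transient metabolic depression. Because the
   run must begin at a window boundary, the call carries a small positive
   bias of at most about one window's temperature span.

All thresholds are arguments with the defaults above; none are hard-coded.

## Comparative analyses

Species means (arithmetic, in measured units) are regressed on habitat by
generalized least squares with residual covariance
$\sigma^2 C(\lambda)$, where $C_{ij}$ is the shared root-to-MRCA path
length and $\lambda$ scales the off-diagonals (Pagel's λ). Three models are
compared: **star** ($\lambda = 0$, phylogeny ignored), **Brownian**
($\lambda = 1$) and **Pagel** ($\lambda$ maximized over $[0,1]$ by bounded
1-D search with tolerance $10^{-6}$, endpoints included and reported
exactly as 0 or 1 on boundary solutions). The likelihood is ML rather than
REML so that AICc values are comparable between fixed-λ and estimated-λ
models; the parameter count includes $\sigma^2$, and λ for the Pagel
model. Model support uses small-sample Akaike weights
$w_i = e^{-\Delta_i/2} / \sum_j e^{-\Delta_j/2}$. t statistics use the
conventional residual degrees of freedom $n - \mathrm{rank}(X)$, reported
transparently (with six species and a two-column design this is 4). The
implementation is validated in the test suite against `nlme::gls` with
`ape::corPagel` as an independent route.

Within-habitat species contrasts use Gaussian linear models (identical to
Gaussian-error GLMs), likelihood-ratio tests on ML log-likelihoods
(χ² asymptotics with the residual variance estimated), and Tukey–Kramer
HSD with p-values from the studentized-range distribution; compact letter
displays are built by insert-and-absorb (split every letter group
containing a significantly different pair, absorb subsets). Trait
variability is summarized as $CV\% = 100\,\sigma/|\mu|$ per species, with
`t_opt_C` and `ult_C` shifted to Kelvin first so that relative variability
of temperatures is measured on an absolute scale (the shift strictly
reduces the CV of any positive Celsius trait; the absolute value keeps the
statistic non-negative for the sign-varying curvature).

## What the synthetic-data module emulates

`simulate_environment()` produces diurnal shore temperature series: a
sinusoid peaking in early afternoon plus half-day midday heat pulses with
lognormal day-to-day amplitudes (optionally tidally modulated), affinely
rescaled so the empirical mean and maximum hit the preset exactly. The
built-in presets are a sun-exposed rocky shore (mean 31.8, max 51.3 °C)
and a shaded mangrove trunk (mean 27.7, max 33.2 °C), logged every 10 min
for 30 days. The generator reproduces summary statistics, not any
particular waveform.

`simulate_trace()` inverts the measurement chain: beats form an
inhomogeneous renewal process (quasi-regular, 5% multiplicative interval
jitter — real heartbeats are not Poisson) whose rate follows a generating
Sharpe–Schoolfield curve, optionally capped below an onset temperature by
a metabolic-depression plateau, and zero above the true ULT. Each beat is
a stereotyped Gaussian voltage bump (~0.15 s wide, 1 mV) in Gaussian
sensor noise; the default noise SD of 0.2 mV is 20% of pulse height. The
temperature channel follows the 0.25 °C/min, 30–65 °C, 40 Hz protocol
exactly.

`simulate_tree_and_traits()` grows pure-birth ultrametric trees and draws
species traits as a habitat effect plus multivariate-normal noise with
λ-scaled Brownian covariance, returning the generating parameters for
recovery tests.

The default cohort (`run_config()`) is 6 species × 9 individuals, three
species per habitat, species-mean HRmax between 108 and 151 bpm, Topt
42–45 °C, ULT 51–52.5 °C, and a habitat effect on the slope gradient
(rocky 0.85–0.95 eV vs mangrove 0.60–0.70 eV). Individual-level
dispersions are set to the per-species coefficients of variation
characteristic of these traits in neritids — ULT 0.955% and Topt 2.19% on
the Kelvin scale, HRmax 12.6%, activation energy 19.2% — and the
depression-plateau probability per individual (1/9 to 4/9 depending on
species, zero in two species) mirrors how often resting depression is seen
in such cohorts. Curvature dispersion is deliberately *emergent*: the
depression mixture drives per-species curvature means toward zero and
makes curvature by far the most variable trait, reproducing the
characteristic variability hierarchy ULT < Topt < HRmax < slope gradient
< slope curvature.

Two generator details are compromises worth knowing about. First, Topt
and ULT pairs are drawn jointly with rejection (ULT ≥ Topt + 1.5 °C,
Topt ∈ [34, 51] °C, ULT ∈ [46, 60] °C): the ordering constraint
necessarily truncates the temperature dispersions, so realized Topt CVs
sit below the 2.19% target while remaining clearly above ULT CVs. Second,
the generator makes no attempt to emulate hardware artefacts (sensor
drift, movement artefacts, signal dropouts) or inter-beat waveform
variation; passing recovery tests therefore demonstrates correctness of
the estimation chain under the stated noise model, not robustness to every
failure mode of real recordings — which is why detection thresholds remain
per-trace configurable.

## Numerical choices and degenerate inputs

* Temperatures are converted to Kelvin only where physics requires it
  (the rate model, CV% of temperature traits); data tables stay in °C.
* `hr_series()` windows are indexed by start time; empty windows yield
  0 bpm, not `NA`.
* A flat or empty trace yields an empty beat list, not an error; a series
  that never drops below the floor yields *no* flatline call, and an
  all-flat series calls the first window.
* NJ trees from non-additive matrices can have negative branch lengths;
  they are clamped to zero with a warning. Additive matrices round-trip
  exactly.
* `compare_models()` refuses fits of different responses; AICc is flagged
  undefined when $n - p - 1 \le 0$.
* All simulators take explicit seeds and restore the caller's RNG state;
  `run_traits()` derives a stable per-trace seed from the cohort seed so
  reruns are bit-identical.

## Problem sizes used in the shipped checks

The package's own test suite exercises the full 40 Hz, 0.25 °C/min
protocol where the property under test concerns it (trait recovery from
20 replicate noisy traces; 20 replicate 6 × 9 cohort runs for the CV
hierarchy) and reduced ramps (0.5 °C/min) elsewhere, a balance chosen to
keep the default check fast while still covering the protocol end to end.
Calibration checks use 1000-replicate null simulations (type-I error of
the star-model habitat test and of the Gaussian LRT), 50-replicate λ
recovery on 64-tip trees, and a 10⁶-draw Monte-Carlo studentized-range
oracle for the Tukey p-values.

## Known limitations

* The ULT call inherits the windowing resolution; sub-window precision
  would require beat-level changepoint detection, which is out of scope.
* The Pagel λ search assumes a unimodal profile likelihood on $[0,1]$;
  with very small species counts the profile can be flat, in which case
  boundary ties are resolved toward the endpoint values.
* Gaussian-error linear models are the only family offered for the
  within-habitat contrasts; residuals are exported for external diagnostic
  plotting rather than formally tested.
* The slope-gradient trait is reported as the activation energy in eV; a
  log₂-transformed linear slope can be computed from the exported series
  but is not a packaged trait, since the two summarize the same upslope.
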