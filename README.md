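# cardioTPC

Cardiac thermal performance curves (cTPCs) for intertidal ectotherms:
from raw heartbeat sensor traces recorded during controlled heating ramps
to per-individual thermal traits, and on to phylogenetically informed
habitat comparisons.

Marine snails warmed at a field-realistic 0.25 °C/min show a
characteristic heart-rate response: a roughly Arrhenius rise, a peak, a
collapse, and a permanent flatline at the upper lethal temperature. The
package models the rising and falling portion with the Sharpe–Schoolfield
equation (high-temperature inactivation form),

    r(T) = r_tref * exp(-E/k (1/T - 1/Tref)) / (1 + exp(Eh/k (1/Th - 1/T)))

with T in Kelvin and k the Boltzmann constant in eV/K, and extracts five
traits per individual:

| trait | meaning | units |
|---|---|---|
| slope gradient | activation energy E of the fit | eV |
| slope curvature | 2·c₂ of a quadratic fit to the upslope (T < Topt) | bpm·°C⁻² |
| HRmax | fitted maximum heart rate | bpm |
| Topt | temperature maximizing the fitted curve | °C |
| ULT | upper lethal temperature, from heartbeat flatlining | °C |

Species-mean traits are then regressed on habitat by phylogenetic
generalized least squares under star (λ = 0), Brownian (λ = 1) and Pagel
(λ estimated by ML) covariance models ranked by AICc weights; species are
compared within habitats by Gaussian linear models with likelihood-ratio
tests and Tukey HSD letters; and trait variability is summarized as CV%
computed on the Kelvin scale for the temperature traits. A synthetic-data
module generates shore temperature regimes, ramped heartbeat traces and
phylogenies with known ground truth, so the whole chain is testable
without any field data. It is aimed at comparative physiologists working
with heartbeat (or similar pulse-train) recordings of ectotherms.

## Worked example

Simulate one individual under the full protocol (30→65 °C at 0.25 °C/min,
40 Hz, sensor noise 20% of pulse height) and run it through the pipeline:

```r
library(cardioTPC)

truth <- true_traits(r_tref = 40, e_act = 0.8, e_deact = 4,
                     topt_C = 45, ult_C = 52)
trace <- simulate_trace(truth, ramp = ramp_protocol(30, 65, 0.25, 40),
                        noise_sd = 0.2, seed = 7)
trace
#> cardiac_trace: 336001 samples at 40 Hz, 8400.0 s, temp 30.0-65.0 degC

traits <- trace_to_traits(trace, seed = 1)
traits
#> cardiac traits: slope gradient 0.779 eV, curvature 0.191 bpm/degC^2,
#>   HRmax 134.1 bpm, Topt 45.05 degC, ULT 52.12 degC (fit_ok=TRUE)

attr(traits, "diagnostics")$flatline
#> flatline call: ULT = 52.12 degC at t = 5280 s [hr < 5 bpm sustained >= 120 s to trace end (window 60 s)]
```

The generating optimum is 45 °C and the generating activation energy
0.8 eV: the fitted trace recovers Topt within 0.05 °C, E within 3%, and
calls the flatline 0.12 °C above the true 52 °C ULT (the call is biased
upward by at most about one 60 s window, i.e. 0.25 °C at this ramp rate).

A whole study runs in three calls:

```r
cfg <- run_config()                      # 6 species x 9 individuals
cohort <- run_simulate(cfg, seed = 11)   # traces + truth manifest + tree
traits <- run_traits(cohort)             # one row per individual
cmp    <- run_compare(traits, cohort$tree, cfg)
cmp$pgls                                 # trait x model table with wAICc
```

`cmp$pgls` is a 15-row table (5 traits × 3 covariance models) whose AICc
weights sum to 1 within each trait; `cmp$habitat_stats` holds the
per-habitat LRTs and Tukey letters, and `cmp$cv` the Kelvin-based CV%
summaries. A thin command-line wrapper over the same functions is
installed at `inst/scripts/ctpc-pipeline.R`
(`simulate` / `traits` / `compare` / `all` subcommands).

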