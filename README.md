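# limnocw

Cold/warm (CW) coding of climate-sensitive phases in dimictic aquatic
systems: an R package for limnologists and climate ecologists who want to
compare warming patterns between lakes (and coastal seas) across latitude
using long-term depth-resolved temperature monitoring.

## What it does

Every year of a dimictic system passes through four phenomenological
phases: inverse winter stratification (ends at ice-off or T(3 m) > 3 °C),
spring overturn (first day of 4 °C homothermy over 0–10 m), early thermal
stratification (T(3 m) > 10 °C) and summer stagnation (July). The package

1. interpolates irregular depth profiles to daily series and detects the
   phase timings;
2. averages each phase over a fixed calendar window, shifted per site by
   the latitudinal offset Δ obtained from cumulative clear-sky radiation —
   the day *t₂* at latitude lat₂ matching day *t₁* at lat₁ satisfies

   G<sub>max,lat₂,t₂</sub> = G<sub>max,lat₁,t₁</sub>,  where
   G<sub>max,lat,t</sub> = Σ<sub>d=1..t</sub> G<sub>max,lat,d</sub>

   and G<sub>max,lat,d</sub> is the daily cloudless global radiation sum
   (kJ cm⁻²) from an astronomical model with Linke turbidity T_L = 2
   (about 2 days per degree latitude over 45–60 °N);
3. classifies each phase-year against per-phase thresholds (lake profile
   3/4/14/20 °C; means ≥ threshold are Warm) into a yearly four-letter CW
   code;
4. quantifies cross-system coherence of two code grids by the similarity
   percentage 100 (N₍cc₎+N₍ww₎)/N, the Phi coefficient, the odds ratio
   (cross-product formula and conditional MLE) and Fisher's exact test;
5. fits warm-occurrence trends P(W|year) = logit⁻¹(a + b·year) by binomial
   GLM with quasi-separation flagging, tests warm-count trends by
   Mann–Kendall, and relates yearly responses (e.g. Brunt–Väisälä
   stability N = √((g/ρ) dρ/dz)) to the codes via Levene and Mann–Whitney
   tests;
6. generates synthetic dimictic lakes with known ground truth (radiation-
   driven epilimnion, full dimictic depth cycle, per-year warm/cold
   offsets, observation noise) so the entire pipeline is testable without
   external data.

See `vignettes/cw-coding.Rmd` for the model details and design choices.

## Worked example

```r
library(limnocw)

# latitudinal shift from the 50.73 N reference to 59.52 N (Lake Erken)
shift <- latitudinal_shift_days(50.733, 59.517)
round(shift$per_day_shifts, 1)
#>   91  121
#> 18.5 16.9
round(shift$mean_shift_days, 1)
#> [1] 17.7

# a 10-year synthetic lake with alternating +-1.5 degC years,
# weekly sampling, 0.3 degC noise
sc  <- lake_scenario(years = 10, year_offsets_c = rep(c(1.5, -1.5), 5),
                     observation_noise_sd_c = 0.3,
                     sampling_interval_days = 7, seed = 1)
sim <- generate_lake(sc)

tab  <- phase_table(interpolate_daily(sim$profiles))
grid <- classify_grid(tab, threshold_profile("lake"), site_id = "demo")
grid
#> CW grid for demo: 10 years
#>    year phase1 phase2 phase3 phase4
#> 1  1990      C      W      W      W
#> 2  1991      C      C      C      C
#> ...

# agreement with the generator's imposed ground truth
s <- coherence_summary(sim$truth$codes, grid)
sprintf("similarity %.1f%%  phi %.2f  fisher p %.2g",
        s$similarity_pct, s$phi, s$fisher_p)
#> [1] "similarity 100.0%  phi 1.00  fisher p 2.5e-11"
```

The warm years (+1.5 °C) code WWW in phases 2–4 while phase 1 stays cold —
the winter mean (≈ 2.8 °C) remains below the 3 °C threshold even in warm
years — and every imposed code is recovered from the noisy weekly
observations.

Published trend coefficients can be evaluated directly:

```r
round(100 * predict_warm_probability(-304.15, 0.15148, c(2010, 2030)))
#> [1] 58 97
```

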