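---
title: "Cold/warm coding of climate-sensitive phases in dimictic aquatic systems"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cold/warm coding of climate-sensitive phases in dimictic aquatic systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(limnocw)
```

## The method

Dimictic water bodies — lakes and coastal seas that mix fully twice a year —
pass through four phenomenologically defined, climate-sensitive phases every
year:

1. **Inverse winter stratification**, ending at ice-off or when the 3 m
   temperature first exceeds 3 °C;
2. **Spring overturn**, starting on the first day of 4 °C homothermy over
   the 0–10 m (or 0–15 m) column;
3. **Early thermal stratification**, starting when the 3 m temperature first
   exceeds 10 °C;
4. **Summer stagnation**, fixed to July (no temperature criterion).

Because the comparison targets inter-annual variability rather than absolute
timing, each phase is *averaged over a fixed calendar window* anchored at
the reference system (50.73 °N): days 1–74 for phase 1, the single day 91
for phase 2 (read at 10 m), days 121–151 for phase 3 and days 182–212 for
phase 4. For a site at another latitude the windows of phases 2–4 (and the
end of the phase-1 window) are moved by a per-site shift Δ derived from
cumulative clear-sky radiation (below). Yearly phase means are compared to
per-phase thresholds; a phase-year is coded **W** (warm) when its mean
equals or exceeds the threshold and **C** (cold) otherwise, giving one
four-letter CW code per year. Everything downstream — cross-system
coherence, occurrence trends, phase-conditioned responses — operates on
these binary grids.

## The clear-sky radiation model and the latitudinal date transfer

The latitudinal transfer rests on the cumulative clear-sky (cloudless)
global radiation since 1 January,

$$G_{\max,\mathrm{lat},t} = \sum_{d=1}^{t} G_{\max,\mathrm{lat},d},$$

and moves a day-of-year $t_1$ from latitude $\mathrm{lat}_1$ to
$\mathrm{lat}_2$ by finding the day $t_2$ with the same cumulative sum. The
daily sums $G_{\max,\mathrm{lat},d}$ (kJ cm⁻² day⁻¹) are computed from a
documented astronomical model:

* solar constant 1367 W m⁻² with the standard eccentricity correction;
* solar declination from the seven-term Fourier series (Spencer);
* hour-angle quadrature of the instantaneous irradiance at 5-minute steps
  (a 1-minute independent integration agrees to well under 0.5 %);
* beam transmission $\exp(-0.8662\,T_L\,m\,\delta_R(m))$ with the Linke
  turbidity factor $T_L$ (default 2, a very clear atmosphere), the
  Kasten–Young relative optical air mass $m$ and the Kasten Rayleigh
  optical thickness $\delta_R$;
* a Liu–Jordan clear-sky diffuse fraction,
  $D/G_0 = 0.2710 - 0.2939\,\tau_b$, clipped at zero.

Only the *relative shape* of the cumulative curves across latitude matters
for the transfer; the verification surface is therefore the regression of
transferred days on latitude over the six reference lakes (47–60 °N), whose
slopes must sit in the published bands (2.125 ± 0.15 days per degree for the
day-91 anchor, 1.97 ± 0.15 for day 121). The model above lands at 2.08 and
1.92 without any latitude-dependent tuning. Altitude, continentality and
cloud climatology are deliberately outside the model.

`transfer_date()` returns, by convention, the first day whose cumulative sum
meets or exceeds the reference value (an integer ceiling); the fractional
alternative interpolates linearly within that day and is the default inside
`latitudinal_shift_days()`, which averages the shifts of the day-91 and
day-121 anchors into the single per-site Δ applied to the windows. For
windowing, Δ is rounded half-up to whole days; the fractional value is kept
for reporting. Cumulative curves of two latitudes in the 45–60 °N band never
cross between days 32 and 182, so the spring transfer is well defined.

## Thresholds and classification conventions

Thresholds are per-phase means of the yearly phase means over a reference
period (default 1990–2009, at least five usable years per phase), rounded
**half-up to the integer** for lakes and kept at one decimal for marine
stations. The shipped constant lake profile is (3, 4, 14, 20) °C; the
Baltic and North Sea profiles are (3.0, 4.0, 11.5, 18.3) and
(5.5, 5.8, 10.8, 17.0) °C. Classification treats equality as warm. Missing
phase means stay missing — they are never imputed and are skipped when
contingency tables are pooled.

Detection uses strict `>` comparisons (3 °C, 10 °C) with a first-crossing
convention: later dips below the threshold do not move a detected start.
Homothermy is operationalised as the *minimum* temperature over the
0–10 m column reaching 4.0 °C, which reproduces the intended overturn onset
from below (cold surface over ~4 °C deep water) without an equality
tolerance.

Interpolation to daily resolution is linear per depth, exact on observation
days, and refuses to bridge gaps longer than 21 days (a limit chosen so
that fortnightly monitoring with occasional missed campaigns still yields
complete series, while season-long holes stay missing). Window means
require 80 % day coverage. When the single phase-2 evaluation day is
missing, the nearest available day within ±3 days is substituted and
flagged.

## Coherence statistics

Agreement between the reference grid and another system's grid is pooled
into a 2×2 table of counts $N_{cc}, N_{ww}, N_{cw}, N_{wc}$ and summarised
by

* the **similarity** $100\,(N_{cc}+N_{ww})/N$;
* the **Phi coefficient**
  $\phi = (N_{cc}N_{ww} - N_{cw}N_{wc}) / \sqrt{\prod \text{margins}}$,
  the Pearson correlation of the two binary series;
* the **odds ratio**, in two estimators: the cross-product formula
  $(N_{cc}N_{ww})/(N_{cw}N_{wc})$ (default; ∞ when only the mismatch
  product vanishes) and the conditional maximum-likelihood estimate under
  the noncentral hypergeometric model. Both are exposed because the two
  differ noticeably in small samples (e.g. 107.7 vs 86.2 for the table
  19/17/3/1); reports should label which is used;
* the two-sided **Fisher exact test** with the probability-ordering
  definition of "as extreme".

Per-phase tables and phase-pooled tables are both available. A "mean
similarity over all phases/sites" can be read two ways — averaging per-site
percentages or pooling counts; the per-site average is what the shipped
reference comparisons summarise to (84 % across the five non-reference
lakes), and `coherence_summary()` returns both views.

## Trends and responses

The probability of a warm phase is modelled as
$P(W \mid \text{year}) = \mathrm{logit}^{-1}(a + b\,\text{year})$ by a
binomial GLM, with the deviance reduction against the intercept-only model
and its 1-df χ² p-value. Thirty-odd binary observations flirt with
quasi-separation; the fitter detects it (fitted probabilities pinned at 0/1
or non-convergence) and flags the fit rather than reporting astronomically
scaled coefficients as converged. The overall trend of the yearly warm-phase
count (0–4) is tested by a hand-rolled Mann–Kendall test: Kendall's S with
tie-corrected variance, tau-b, and a normal-approximation p with continuity
correction.

Water-column stability is the Brunt–Väisälä frequency
$N = \sqrt{(g/\rho)\,\partial\rho/\partial z}$ with z positive downward,
from centred finite differences of freshwater density (Kell's polynomial,
maximum near 3.98 °C; salinity 0 throughout). Negative $N^2$ (unstable
layers) is clipped to zero and flagged. The summary statistic is the mean
of $N$ (s⁻¹) over the depth range — magnitudes like 0.025 s⁻¹ for a
stratified July column only make sense on the $N$ scale, not $N^2$ — but
the per-layer $N^2$ profile is returned as well. Phase-conditioned
responses (stability, biomass, any yearly series) are split by a phase's
C/W code and compared by Levene's test (median-centred) and a two-sided
Mann–Whitney U test, exact for small tie-free groups.

## The synthetic lake

`lake_scenario()` / `generate_lake()` produce multi-year daily profiles
with known ground truth so every stage is testable without external data.
The 3 m temperature is a logistic function of cumulative clear-sky
radiation at the scenario latitude — the same curves used by the transfer,
so latitude consistency between generator and transfer is structural, while
ground truth (threshold crossings and window means of the noise-free
closed-form curves) stays independent of the detection code.

Defaults are calibrated to the reference system: asymptote 21.048 °C;
midpoint 179.2 and scale 54.5 kJ cm⁻², chosen once so that the noise-free
reference lake crosses 4 °C homothermy on day 91 and 10 °C on day 121, its
long-term mean phase starts. (The midpoint/scale are *clear-sky* cumulative
units: an empirical sigmoid fitted against measured, cloud-attenuated
radiation has a much smaller midpoint, and the generator models no cloud
climatology.) The winter floor of 1 °C creates a detectable 3 °C crossing,
which emerges around day 82. The deep water follows the column between the
4 °C maximum-density floor and a 6 °C summer hypolimnion cap, with a
logistic thermocline (8 m deep, 1.5 m wide) normalised so the 3 m horizon
carries the driver exactly; this passes through the full dimictic cycle —
inverse winter stratification, homothermy at overturn, a two-layer summer,
fall cooling. Per-year offsets (±1.5 °C in the standard validation
scenario) impose warm/cold years; Gaussian observation noise (0.3 °C) and
weekly subsampling mimic field campaigns; a single seed fixes all
randomness.

What the generator does **not** emulate — and what passing tests therefore
cannot show about real data: cloud-driven weather variability within years,
wind-mixing events that transiently deepen the epilimnion, ice phenology
(ice-off is an input, never simulated), salinity stratification, and
hypolimnetic warming memory between years. Recovery rates on the synthetic
scenario (≥ 95 % of imposed codes at weekly sampling and 0.3 °C noise) are
an upper bound on what identically parameterised real monitoring would
give.

## Problem sizes and numerical choices

Validation uses a 36-year single-site scenario for code recovery, 100
replicated 36-year grids (four phase outcomes per year, pooled fit) for
logistic parameter recovery — median final-year probability error ≈ 0.05,
against the 0.1 requirement; a single 36-year phase series is genuinely too
short, giving 0.11–0.17 for any of the published coefficient sets — and a
six-site panel (20 years, weekly sampling) for the end-to-end pipeline,
which completes in seconds. Exact-test and rank kernels are verified
against enumeration oracles (N ≤ 40 tables, n ≤ 10 series); the stability
kernel against independent finite differences at 10⁻¹⁰.

Remaining conventions, fixed once: the calendar is 365 days with 29
February merged into day 59 (one day is below the method's resolution);
the phase-1 window always begins 1 January regardless of Δ; the phase-1
mean uses the 3 m horizon (the epilimnion reference depth of the input
format); sigmoid fits start from a self-starting logistic and fall back to
Levenberg–Marquardt before reporting failure.

## Known limitations

The radiation transfer is validated for 45–66 °N spring conditions only;
southern-hemisphere or polar use is out of scope. Thresholds are not
detrended, so a strong secular trend inside the reference period shifts
them. The two-category coding discards magnitude information by design —
that is what makes it robust across systems — and coherence statistics on
short series have wide confidence ranges, which is why the Fisher test and
both odds estimators are always reported together.
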