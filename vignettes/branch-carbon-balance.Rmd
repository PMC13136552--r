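---
title: "Methods: branch-level carbon balance along canopy light gradients"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: branch-level carbon balance along canopy light gradients}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(branchcarbon)
```

# The question and the model

Light within a tree crown declines from the top downwards; the fraction
reaching the lowest shade branches of mature trees typically lies between
5% and 40% of top-of-crown irradiance. Shade branches acclimate — thinner
leaves (higher SLA), lower dark respiration, slightly higher quantum
yield, a different leaf-area-to-twig-mass allocation — and the net outcome
for their carbon economy is not obvious a priori. This package implements
the bookkeeping needed to answer that question at the level of individual
current-year branches: how many days of assimilation pay back the carbon
in new leaves and twigs, and what fraction of lifetime uptake they
represent.

## Light response

Net photosynthesis is modelled as an exponential saturation curve,

$$P_N(I) = P_{gmax}\left(1 - e^{-\phi_0 I / P_{gmax}}\right) - R_d,$$

with $I$ the PPFD (µmol photons m⁻² s⁻¹), $P_{gmax}$ the asymptotic gross
rate, $R_d$ dark respiration (stored as a positive magnitude and
subtracted — one sign convention, applied everywhere) and $\phi_0$ the
quantum yield at $I = 0$. The model implies three exact identities used
throughout the tests: $P_N(0) = -R_d$, $P_g(0) = 0$, and
$P_N \to P_{gmax} - R_d$ as $I \to \infty$.

`fit_lrc()` estimates the triple per curve by Levenberg–Marquardt least
squares (via minpack.lm) with box bounds
$P_{gmax} \in (0, 100]$, $R_d \in [0, 20]$,
$\phi_0 \in (0, 0.2]$ (SI curve units) that keep the optimiser in a
physiological region; all three are arguments. Starting values are
$R_{d,0} = \max(0, -\min P_N)$, $P_{gmax,0} = \max P_N + R_{d,0}$ and
$\phi_{0,0}$ from the slope of the two lowest-light points — standard,
robust choices. Curves are always fitted individually; aggregation to
species × position means happens downstream. Non-convergence is flagged
in the returned object, never silent; fewer than three observations, or a
single light level, is an error.

A note on identifiability: with the common eight-level design
(0–1500 µmol) and observation noise of a few tenths of a µmol, $P_{gmax}$
is recovered to a couple of percent, but the information on $R_d$ comes
almost entirely from the lowest-light points. A Cramér–Rao calculation at
$(P_{gmax}, R_d, \phi_0) = (10, 1, 0.05)$ with noise SD 0.3 bounds the
median relative error of $R_d$ near 15% for *any* estimator; per-curve
$R_d$ estimates at this design should therefore be treated as noisy, and
averaging over curves (as the pipeline does) is essential.

## From light records to daily assimilation

Continuous 15-min irradiance series (lux loggers are converted with
PPFD = lux/120, the established relationship for pendant-type sensors)
drive the fitted curves. Two temperature corrections are applied:

* gross photosynthesis is multiplied by a piecewise-linear factor with a
  broad optimum — 0 at ≤ −2 °C, rising linearly to 1 at 10 °C, flat to
  30 °C, falling to 0 at 42 °C;
* dark respiration follows $R_d(T) = R_{d,ref}\,Q_{10}^{(T - T_{ref})/10}$
  with $Q_{10} = 2$.

$T_{ref}$ is 25 °C, the chamber setpoint at which the curves are measured;
it is the only defensible anchor for the reference rate and is
configurable. Hourly temperature is applied as a step function to the
four 15-min steps within each hour (interpolation would smooth nothing
that matters at a 2 °C diurnal gradient per hour, and the step function
keeps the mapping auditable). The same temperature series is used for
both crown positions: vertical temperature gradients within a crown are
negligible compared to the light gradient.

Net rates are summed over each complete calendar day and converted to
grams of carbon, $A_N = \sum \text{net} \times 900\,\text{s} \times 12
\times 10^{-6}$ (g C m⁻² d⁻¹). Winter days are legitimately negative.
Partial days at series edges are dropped with a warning — amortisation
counts whole days, and extrapolating part-days would bias the counts.
All series run in local standard time without DST shifts, so every day is
exactly 96 steps. Per species × crown position, the daily series from
each fitted curve × logger combination are averaged pointwise; branch
series are $A_{Branch} = \text{leaf area} \times A_N$.

## Costs, amortisation, RCC

The carbon cost of a tissue is simply the carbon in its dry biomass
(mass × C fraction). This deliberately excludes the respiration costs of
biosynthesis (roughly +25% across tissue types); because those costs are
nearly proportional to carbon content, the *comparison* between sun and
shade branches is unaffected, and an optional growth-respiration
multiplier would scale all results without reordering them.

Amortisation time counts days from 50% budbreak (the budbreak day itself
is day 1) until cumulative $A_{Branch}$ first reaches the cost — $C_F$
for foliage, $C_F + C_T$ for the whole branch. No sub-day interpolation:
results are integer days. Negative days enter the cumulative sum as they
stand. For evergreens the single-year series loops back to 1 January and
continues; a cap of 10 looped years guards against non-amortising
(carbon-negative) branches, which are flagged rather than looped forever.

RCC divides the cost by cumulative assimilation over the foliage
lifespan: for deciduous species the budbreak-to-discoloration window,
*endpoints inclusive* (a documented convention, tested); for evergreens,
`lifespan_years` full annual cycles of the looped series starting at
budbreak, so that for an annual-periodic series the denominator is
exactly lifespan × annual sum. Whether year 1 should instead contribute
only its post-budbreak remainder is genuinely open; full cycles were
chosen because a needle cohort assimilates through the winters *within*
its lifespan, and the convention is stated here rather than hidden.

## Sensitivity analysis

`run_sensitivity()` recomputes the shade branch's whole-branch RCC eight
times, each run replacing exactly one input with the sun-crown value:
incident light, $P_{gmax}$, $R_d$, $\phi_0$, SLA, LA:BDW, tissue C
concentration, season length. The full pipeline is re-run per
replacement — no shortcut formulas — and the result is
$(\text{RCC}_{new} - \text{RCC}_{init})/\text{RCC}_{init}$.
Replacements operate on species × position mean inputs, matching the
averaging that precedes the RCC calculation.

Two substitution semantics are underdetermined and fixed here
explicitly: SLA replacement holds *leaf mass* fixed (leaf area = mass ×
SLA, so leaf area and, through the fixed LA:BDW ratio, twig mass adjust);
LA:BDW replacement holds *leaf area* fixed (twig mass adjusts). For
evergreens, season-length replacement swaps only the budbreak date, since
no season end is defined for them. These conventions are recorded in the
result's metadata.

## Starch build-up costs

The carbon bound in the seasonal starch build-up is amplitude
(minimum-to-maximum concentration within the year) × tissue dry mass ×
0.4, the C fraction of starch. Conifers build starch in mature needles
in the weeks *before* budbreak; broadleaves refill branch wood during the
first half of the growing season after budbreak — the generator encodes
both phenologies. Because starch is measured in 3–5-year-old wood but
morphology in current-year branches, the broadleaf twig mass is upscaled
by $\sum_{i=1}^{5} i/2^{i-1} = 3.5625$, assuming constant annual biomass
increment and two new shoots per parent shoot; both the year count and
the shoot count are arguments, generalising the factor to
$\sum i/s^{i-1}$. Equal branching structure in both crown positions is
an assumption, not a measurement. The cost is expressed as % of
$A_{Branch}$ over the build-up window; for the pre-budbreak conifer
window the annual series is treated as periodic, so the window's calendar
days are drawn from the same single-year series, and the assimilating
leaf area is that of the 1-year-old needles. A window with non-positive
net uptake is flagged and reported with its sign, not clipped.

## The synthetic scenario generator

The generator produces every input the pipeline consumes, with known
ground truth, so that each stage can be validated against constructions
whose answers are known exactly. It emulates:

* **Light:** clear-sky PPFD proportional to the sine of solar elevation
  (declination from day of year, hour angle from time of day, latitude
  47.4° N by default), scaled by a top-of-crown maximum of
  1600 µmol m⁻² s⁻¹ — deliberately below the open-sky ~2000, folding
  sensor orientation and within-crown self-shading into one constant —
  and a per-day log-normal cloudiness multiplier (median 0.5, log-SD
  0.45, capped at 1) shared by both positions, which see the same sky.
  The shade series is RI × sun, optionally with multiplicative mean-1
  log-normal sensor noise (off by default, so the RI ratio is exact;
  the loggers' true noise structure is unknown, and these levels are free
  parameters, not site estimates). Night steps are exactly zero.
* **Temperature:** hourly; 9.6 °C annual mean (temperate-site
  climatology) with 9 °C seasonal and 4 °C diurnal half-amplitudes and
  iid Gaussian noise.
* **Traits:** a deciduous broadleaf (RI 0.30; sun/shade $P_{gmax}$ 14/10,
  $R_d$ 1.5/0.7, $\phi_0$ 0.045/0.055; SLA 10/25 m² kg⁻¹) and an
  evergreen conifer (RI 0.20; 10/7, 1.3/0.6, 0.040/0.050; SLA 4/6;
  5-year needle lifespan) — the canonical acclimation pattern of
  temperate trees, with conifers adjusting SLA much less than
  broadleaves. Per-tree records jitter leaf mass (CV 15%) and the SLA
  and LA:BDW ratios (CV 8%) log-normally and independently.
* **Starch:** amplitudes of 0.03 g g⁻¹ (broadleaf wood) and 0.10 g g⁻¹
  (conifer needles), 60- and 40-day build-up windows placed after and
  before budbreak respectively.

With these choices the scenario lands where temperate-canopy field
estimates land: broadleaf whole-branch amortisation within tens of days,
whole-branch RCC below ~10% in both positions, conifer amortisation of
one to three months, starch costs an order of magnitude higher in
conifers than broadleaves and always below concurrent uptake. The
calibration was fixed once, from those field-scale magnitudes, and is not
a fitting target.

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: sunflecks and any sub-15-min light
variation, VPD limitation of stomatal conductance (which would penalise
sun branches more), radiative-transfer canopy structure, inter-annual
transfer between the starch and assimilation years, and correlated
(weather-regime) temperature noise. Conclusions about those effects
require field data, not this generator.

Reproducibility: every generator draws from its own RNG substream derived
from the single scenario seed, so any stage can be regenerated
independently and bit-identically; the generators save and restore the
caller's RNG state.

## Numerical and testing choices

* `temperature_multiplier()` is linear interpolation over the four
  anchors with constant-zero extension — exact at the anchors by
  construction.
* Daily integration is a plain sum over 96 steps; an independent
  step-by-step oracle agrees to 10⁻¹² relative in the tests.
* Amortisation and window sums are validated against brute-force
  day-by-day scan oracles (100 randomized seasonal scenarios, exact
  integer agreement, including year-looping cases).
* Ties: a cumulative sum that reaches the cost exactly on day $n$ reports
  $n$ days; cost 0 reports 0 days.
* Degenerate inputs (non-positive masses, C fractions outside (0,1),
  unordered phenology, empty starch windows, single-level gas-exchange
  designs, negative PPFD) are rejected at construction, with row numbers
  for table inputs.
* Test problem sizes: full single-year series (35,040 15-min steps;
  8,760/8,784 hourly steps), two species × two positions × two curves,
  five trees per species; the Monte-Carlo recovery study uses 200
  replicates, and the deterministic oracle suites 50–100 randomized
  cases. These sizes exercise every code path, including leap years and
  conifer year-looping, while keeping the default suite fast.

## Known limitations

Beyond the generator's non-goals above: the carbon cost metric excludes
biosynthesis respiration (absolute RCCs are underestimates, position
contrasts are not); conifer needle lifespans enter as whole-year
assumptions; per-curve $R_d$ is weakly identified at typical designs (see
the Cramér–Rao note); and the pipeline requires same-scenario light,
temperature and starch series — it does not model carry-over between
years.
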