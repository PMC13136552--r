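# branchcarbon

Within a tree crown, light falls off steeply from the sun-exposed top to the
shaded lower branches. Whether that gradient translates into a worse
carbon economy for shade branches — longer payback times for the carbon
invested in leaves and twigs, a larger share of lifetime assimilation spent
on construction and starch storage — is the question this package is built
to answer quantitatively. It is aimed at plant ecophysiologists who have
(or want to simulate) branch-level gas-exchange, irradiance-logger,
morphology and phenology data and need a tested, reproducible
implementation of the branch carbon-balance bookkeeping.

## The model

**Light response.** Net photosynthesis of a leaf follows an exponential
saturation curve in PPFD *I*:

P<sub>N</sub>(I) = P<sub>gmax</sub> (1 − e<sup>−φ₀ I / P<sub>gmax</sub></sup>) − R<sub>d</sub>

with P<sub>gmax</sub> the asymptotic gross assimilation rate, R<sub>d</sub>
dark respiration and φ₀ the quantum yield at I = 0. Curves are fitted
individually by bounded Levenberg–Marquardt least squares.

**Assimilation.** Each fitted curve is driven by a 15-min irradiance logger
series (lux-based sensors are converted with PPFD = lux/120). Gross
photosynthesis is scaled by a piecewise-linear temperature multiplier
(broad optimum 10–30 °C, zero at −2 and +42 °C) and dark respiration by a
Q₁₀ = 2 law referenced to the 25 °C measurement chamber. Net rates are
summed over each day and converted to grams of carbon (×12 g mol⁻¹),
giving daily net assimilation A<sub>N</sub> (g C m⁻² d⁻¹), averaged per
species × crown position, and scaled by branch leaf area to
A<sub>Branch</sub> (g C branch⁻¹ d⁻¹).

**Costs.** A branch's carbon cost is the carbon in its current-year dry
biomass (foliage C<sub>F</sub>, twigs C<sub>T</sub>). Two summary
statistics relate cost to uptake: the *amortisation time* (days from 50%
budbreak until cumulative A<sub>Branch</sub> reaches the cost; evergreen
series may loop past 31 December) and the *relative carbon cost* (RCC,
cost as % of cumulative assimilation over the foliage lifespan —
budbreak-to-discoloration for deciduous species, 3–5 looped annual cycles
for conifers).

**Sensitivity.** The shade-branch RCC is recomputed eight times, each time
replacing one factor (incident light, P<sub>gmax</sub>, R<sub>d</sub>, φ₀,
SLA, LA:BDW, tissue C concentration, season length) with its sun-crown
value; reported as (RCC<sub>new</sub> − RCC<sub>init</sub>)/RCC<sub>init</sub>.

**Starch.** The seasonal starch build-up cost is amplitude × tissue dry
mass × 0.4 (the C fraction of starch), expressed as % of
A<sub>Branch</sub> summed over the build-up window. For broadleaves the
current-year twig mass is upscaled to the 5-year branch system by
Σᵢ i/2<sup>i−1</sup> = 3.5625 (constant yearly increment, two new shoots
per parent shoot).

A synthetic scenario generator (solar-elevation light model with
multiplicative shade attenuation, seasonal/diurnal temperature,
model-generated gas-exchange points, trait contrasts, starch phenology)
supplies every input with known ground truth.

## Worked example

```r
library(branchcarbon)

## fit a light-response curve from (noiseless) synthetic observations
obs <- generate_lrc_observations(lrc_params(10, 1, 0.05),
                                 c(0, 25, 50, 100, 250, 500, 1000, 1500), 0)
fit_lrc(obs)
#> Light-response curve parameters (exponential saturation model)
#>   Pgmax: 10.0000 umol CO2 m-2 s-1
#>   Rd:    1.0000 umol CO2 m-2 s-1
#>   phi0:  0.05000 umol CO2 / umol photons
#>   RSS: 0  converged: TRUE

## full pipeline on the calibrated two-species scenario
res <- run_pipeline(scenario_config(seed = 1))
aggregate(cbind(total_amortisation_days, total_rcc_pct) ~ species + position,
          res$costs, mean)
#>     species position total_amortisation_days total_rcc_pct
#> 1 broadleaf    shade                    14.4          7.78
#> 2   conifer    shade                    88.6          8.19
#> 3 broadleaf      sun                    16.8          8.70
#> 4   conifer      sun                    46.8          4.13
```

Broadleaf branches pay back their construction carbon within a couple of
weeks of budbreak and invest under 10% of their lifetime uptake in
current-year tissues, in both crown positions; conifers take one to three
months but spread the cost over a multi-year needle lifespan. The
sensitivity table shows what sustains that balance in the shade:

```r
subset(res$sensitivity, species == "broadleaf",
       c(factor, rcc_initial, rcc_replaced, rel_change))
#>                  factor rcc_initial rcc_replaced rel_change
#>          incident_light        7.33         4.04    -0.4479
#>                   pgmax        7.33         6.32    -0.1377
#>                      rd        7.33         8.96     0.2232
#>                    phi0        7.33         9.07     0.2377
#>                     sla        7.33        14.12     0.9268
#>                  la_bdw        7.33        10.13     0.3821
#>  tissue_c_concentration        7.33         7.45     0.0169
#>           season_length        7.33         7.16    -0.0228
```

Giving the shade branch the sun crown's light would nearly halve its RCC
(−45%), while imposing sun-type SLA or respiration raises it — the classic
signature of shade acclimation through thinner leaves and lower
maintenance costs. Starch build-up stays well below concurrent uptake
(`res$starch`: ≲ 0.7% for the broadleaf, 7–12% for the conifer whose
needles refill reserves before budbreak).

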