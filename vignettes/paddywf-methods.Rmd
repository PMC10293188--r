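---
title: "Methods: simulating paddy irrigation-drainage units and their water footprint"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating paddy irrigation-drainage units and their water footprint}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paddywf)
```

## Scope and model structure

`paddywf` simulates the daily water and nutrient balance of one
irrigation-drainage unit (IDU): a paddy field, a drainage/irrigation
ditch, and optionally a small pond, operated under one of four management
styles (TC, PD1, PD2, QD) that differ only in whether the pond sits in
the drainage path and whether local (ditch/pond) water is prioritized for
irrigation. Everything above the IDU — provincial style shares, dry-year
freshwater restriction, the redesign scenario ladder — is composition of
IDU-scale season runs.

The package is organized around two classed results: `simulate_idu()`
returns an `idu_sim` (one season, one unit, one parameter set) and
`run_ensemble()` a `wf_ensemble` (climate years x Monte-Carlo parameter
sets x styles, aggregated to a provincial mixture).

## Daily operation order

The within-day sequencing is not uniquely determined by the physics and
results depend on it, so it is fixed and documented:

1. rain falls on field, ditch and pond surfaces; ponded water first
   refills any root-zone soil deficit;
2. crop evapotranspiration ETc = Kc * ET0 is taken from ponded water,
   then from the soil store under the stress coefficient Ks; ditch and
   pond lose open-water evaporation at 1.05 * ET0;
3. field percolation (constant rate while ponded; ditch and pond are
   treated as lined/puddled with zero percolation, configurable);
4. irrigation: when the ponded depth has fallen below the stage trigger,
   refill to the stage target, drawing local storage first for PD1/QD
   (QD also the pond) and remote freshwater otherwise, subject to the
   seasonal remote cap;
5. drainage: depth above the stage maximum (or any depth during a
   scheduled drainage window) drains to the ditch; ditch overflow goes to
   the pond when the pond is in the drainage path, final overflow leaves
   the IDU over the outlet weir. There is no backflow into the IDU.

Putting irrigation before drainage means a refill decision never triggers
same-day drainage (target <= maximum by construction). Water mass is
conserved exactly by this bookkeeping; the test suite checks daily and
seasonal closure to 1e-6 relative on randomized configurations, and the
closure is in practice at machine precision.

## Field water-level scheme

"Normal management by farmers" is encoded as shallow continuous ponding:
per stage a lower irrigation-trigger depth (default 10 mm), an upper
refill target (40 mm) and a maximum depth before drainage (60 mm), with a
7-day mid-season drying window at the end of the development stage and a
10-day terminal drainage window. Stage lengths default to 30/30/40/30
days (initial/development/mid/late). All depths and dates are
configurable through `default_water_scheme()`.

The mid-season drying and terminal drainage produce a small, style-independent
baseline water stress in most years (the soil store TAW = 60 mm with
depletion fraction p = 0.2 carries the crop through the drying window
only partly unstressed). Because the scheme is identical across styles,
style comparisons are unaffected; in unrestricted years all styles
irrigate the same volume and differ only in its source.

## Crop water and yield response

ET0 is the standard FAO-56 daily Penman-Monteith computation: shortwave
radiation from sunshine duration via the Angstrom formula (a = 0.25,
b = 0.50), net longwave from temperature, humidity and relative sunshine,
psychrometric constant from station pressure at elevation, soil heat flux
zero at the daily step, and actual vapour pressure from daily mean
relative humidity (the generator produces a single daily RH; when RH
max/min are available their mean is the appropriate input). Crop
coefficients default to paddy-rice FAO-56 values 1.05/1.10/1.20/0.90.

Yield response to water stress uses stage-wise response factors
Ky = 1.0, 1.09, 1.32, 0.5 (initial, development, mid-season,
late-season): per stage `YL_i = Ky_i (1 - ETa_i/ETc_i)`, and the seasonal
relative yield is the product `Ya/Yx = prod(1 - YL_i)` — the CROPWAT
convention for combining stages; a stage-wise sum would overstate losses
when several stages are stressed. Stage losses are clamped to [0, 1].
Yield per unit area is identical across styles in unrestricted years
(sources differ, quantities do not); Ky-based losses apply only where
the remote freshwater cap binds.

## Nutrient dynamics

Field, ditch and pond are fully mixed. On fertilization days the field
concentration is reset to the event's initial concentrations (default
schedule: 25/15/10 mg/L N and 1.5/0.5/0.3 mg/L P at days 1, 25, 55 —
magnitudes typical of basal/tillering/panicle applications; these are
inputs, not predictions). Between events the field concentration declines
first-order at 0.15/day, an explicit stand-in for soil adsorption and
plant uptake. Ditches and ponds retain nutrients by spiraling-theory
areal uptake: mass removed per day is `vf * (C - EC0) * A`, with vf in
m/day and C in g/m^3, floored at zero when `C <= EC0` (net release is
disabled — small water bodies are treated as retention features; a
release term would require a sediment-pool state the model does not
carry) and capped so a single step cannot undercut the equilibrium
concentration.

Mass accounting routes every gram: runoff loads (outflow volume x
ditch-or-pond concentration), leaching loads (percolation x field
concentration), retention, and a field soil sink (infiltration, decay,
and residual mass when the field dries out). The seasonal budget
(fertilizer inputs = exports + retention + sinks + storage change) closes
exactly; the tests assert 1e-6 relative.

The four retention parameters are uncertain by an order of magnitude.
Literature ranges (vf_N 4.2-44 cm/d, vf_P 1.5-9.0 cm/d, ENC0 0.4-5.0
mg/L, EPC0 0.03-1.1 mg/L) are read as the 5th-95th percentiles (90%
central coverage, configurable) of lognormal distributions;
`fit_lognormal_from_range()` inverts the normal quantiles and
`sample_retention_params()` draws reproducible Monte-Carlo sets. Whether
spiraling retention should also act on the ponded field is not settled;
here it acts on ditch and pond only, with the field's first-order decline
standing in for field-side removal.

## Synthetic climate

The generator emulates the monsoonal structure that matters for this
analysis: month-specific wet-day occurrence as a first-order two-state
Markov chain (persistence 0.40 in the shipped presets, so wet and dry
spells clump realistically — essential for the no-rain-run and dry-event
analyses), gamma-distributed wet-day amounts (shape 0.5) whose mean
reproduces the monthly normals, a shared AR(1) temperature anomaly, and
sunshine reduced on wet days and capped at the astronomical day length.
Years are 365 days (no leap days) for alignment simplicity.

Three presets (NE, CJ, SE) are shipped as regional archetypes. Their
seasonal rain totals were calibrated once so that the growing-season
aridity index (seasonal ET0 / seasonal precipitation — the ratio
convention used throughout) exceeds 1 in roughly a quarter of years,
matching the dry-year frequency the dryness classes encode. The extreme
tail (index > 1.6) occurs in about 2% of synthetic years rather than 5%:
a single-site generator with one climatology has thinner inter-annual
tails than a multi-station historical ensemble, and we chose not to
inflate variance beyond plausible monsoon inter-annual variability.
Consequences: extreme-dry conditions are represented but rarer than in a
3-station 30-year archive. Boundary convention: an aridity index of
exactly 1.0 or 1.6 falls in the *less* dry class (strict inequalities).
A day counts as no-rain below 1 mm (a conventional trace cutoff,
configurable).

What the generator does not emulate: spatial correlation between
stations, typhoon-scale daily extremes, multi-decadal trends, and any
coupling between fertilization timing and weather. Tests passing on
synthetic climate therefore demonstrate the machinery and its internal
consistency (conservation, monotonicity, direction of style contrasts),
not agreement with any particular station record.

## Dry-year freshwater restriction

The guarantee probability PI (79% NE and southwest, 83% SE coastal, 87%
CJ) is interpreted on the within-ensemble dryness ranking: years whose
aridity rank exceeds PI lose the unlimited remote supply, and their
seasonal remote total is capped at the PI-quantile of the seasonal
irrigation-demand distribution (demand measured on an unrestricted
TC run). The exact quantitative rule behind "restricted beyond the supply
capability" is a design decision of this package, implemented on the
seasonal total rather than per event as the simplest defensible reading.
With short ensembles the cap binds weakly in wet samples; 30-year
ensembles (the scale the analysis was designed around) produce genuinely
binding restrictions.

## Scenarios and upscaling

Styles are aggregated to provincial results by deterministic share
weighting — the expectation of proportional random sampling, removing
needless Monte-Carlo variance; seeded random sampling remains available
(`aggregate = "sample"`). ISS is aggregated as the ratio of
share-weighted irrigation volumes, not the mean of ratios.

The redesign ladder: RI moves share mass TC -> PD1 and PD2 -> QD
proportionally until the recycling share reaches its target; PR moves the
pond-bearing fraction of PD1 into QD (only IDUs that actually possess an
isolated pond can be reconnected; that fraction is a profile input); PC
raises the pond area to the 8% combined-area cap, records the converted
field area, and connects ponds into the drainage path for every style
(TC -> PD2, PD1 -> QD). Treating construction as drainage connection
while leaving irrigation priority to the RI lever keeps the two
mechanisms separable; on the standard ladder PC follows RI, so all
constructed ponds end up in QD units anyway. Land occupation assumes all
new ponds are converted from paddy fields, with production falling in
proportion to the occupied field share.

## Numerical choices and degenerate inputs

- All stochastic functions take a seed and restore the caller's RNG
  state; ensembles derive fixed substream seeds for parameters and style
  sampling so modules are independently reproducible.
- Ditch/pond storages start the season half full (pre-season carry-over,
  configurable); initial ditch/pond concentrations default to the
  equilibrium concentrations of the parameter draw; the field starts
  nutrient-free until the first fertilization.
- ISS is defined as 0 when no irrigation was needed; gray WF errors on
  zero yield; the aridity index warns and returns `Inf` on zero seasonal
  precipitation; concentrations in near-empty compartments (< ~1 L) are
  treated as zero to avoid 0/0.
- Impact tables round half away from zero to one decimal, matching how
  such observation tables are conventionally presented.
- No groundwater P standard exists, so the P leaching term of the gray
  WF is excluded unless a standard is supplied.

## Problem sizes

The shipped tests and the acceptance script choose sizes that keep full
runs in minutes while preserving the contrasts of interest: the
style-comparison ensemble uses 30 synthetic years x 20 parameter sets
(600 matched draws per style; 30 years is the series length the dry-year
analysis was designed around), the scenario ladder 10 years x 6 sets per
rung, conservation suites 100 randomized configurations, and the
lognormal round-trip 1e5 draws. All sizes are arguments; nothing in the
code depends on them.

## Known limitations

- No groundwater table, canal hydraulics, or routing between IDUs; the
  outlet weir is a simple capacity threshold.
- No nitrogen speciation, sediment phosphorus pool, or greenhouse-gas
  fluxes; field-side nutrient processes are a calibrated stand-in.
- Yield responds to water stress only through the Ky mechanism; no
  temperature or pest effects, no water-logging damage (so the benefit of
  extra drainage storage in wet years is not quantified).
- Provincial profiles and climate presets are synthetic archetypes;
  reproducing any specific province's historical numbers requires that
  province's station data and survey shares.
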