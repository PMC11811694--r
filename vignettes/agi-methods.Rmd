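---
title: "Aerobic growth index habitat analysis: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Aerobic growth index habitat analysis: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agihabitat)
```

## The problem

Antarctic toothfish and its prey are ectothermic water breathers adapted to
the cold, oxygen-rich waters of the high-latitude Southern Ocean.  Ocean
warming raises their metabolic oxygen demand while subsurface deoxygenation
(driven by the southward shift of relatively warm, oxygen-poor Circumpolar
Deep Water) lowers the supply.  This package quantifies the joint effect
with the extended aerobic growth index (AGI): the ratio of the
environmental oxygen partial-pressure supply to a species-specific,
temperature-dependent demand.  Where the index exceeds a species' critical
value, that part of its contemporary three-dimensional habitat can sustain
a viable population; summing grid-cell volumes gives the viable habitat
volume $\Omega$ (km^3^), and intersecting a predator's and a prey's viable
cells gives the habitat overlap $\Phi$ (km^3^).  The pipeline then asks how
$\Omega$, $\Phi$, and prey richness change between a historical baseline
(1995--2014) and end-of-century conditions under four emission scenarios.

## The index

For a species $i$ with preferred temperature $T^{pref}_i$ (the
volume-weighted in-habitat median of monthly climatological in situ
temperature) and oxygen threshold $pO_2^{thr,i}$ (the volume-weighted
in-habitat 10th percentile of monthly climatological $pO_2$),

$$\mathrm{AGI}_i \;=\; \frac{pO_2}
{\,pO_2^{thr,i}\;\left(\tfrac{1}{3}\right)^{1-d}
\exp\!\left(\frac{j_2-j_1}{T^{pref}_{i,K}}-\frac{j_2-j_1}{T_K}\right)}$$

with $j_1 = 4500$ K and $j_2 = 8000$ K (anabolism and catabolism
activation energies over the Boltzmann constant), metabolic scaling
coefficient $d = 0.7$, and temperatures in Kelvin.  Three structural
properties anchor the implementation and its tests:

* at $(T^{pref}, pO_2^{thr})$ the index equals $3^{0.3} \approx 1.3904$
  for every species (closed form, machine precision);
* AGI is linear in $pO_2$ and strictly decreasing in temperature; and
* the ratio of future to historical AGI is species independent — all
  species parameters cancel — so the relative change
  $\mathrm{AGI}_{rel} = 100\,(\mathrm{AGI}_f/\mathrm{AGI}_h - 1)$ is a
  property of the water, not of the species.

The critical value $\mathrm{AGI}^{crit}_i$ is the volume-weighted 10th
percentile of monthly in-habitat AGI over the same climatology; viability
uses the strict inequality $\mathrm{AGI}_i > \mathrm{AGI}^{crit}_i$, so
boundary cells are excluded.

### The weighted percentile

All three thresholds use one primitive: the weighted empirical-CDF
percentile with a lower-value rule — the smallest sample value whose
cumulative normalised weight reaches the target fraction.  No
interpolation is performed, the result is always an actual sample value,
and the rule is exact on ties and independent of accumulation order after
a stable sort.  Each of the 12 climatological months contributes one
sample per habitat cell with the cell's volume as weight; months are
equally weighted (month lengths are not used).  A direct consequence,
used as an end-to-end test: on a climatology with no seasonal cycle the
viable fraction of any habitat equals $1 - 0.1 = 0.9$ of its volume to
within the largest single-cell volume fraction.

## Seawater thermodynamics

The model state is potential temperature, practical salinity and oxygen
concentration in mmol m^-3^; the index needs in situ temperature and
$pO_2$ in mbar.  Conversions are implemented from the standard published
formulas and validated against their published check values:

* pressure from depth and latitude (Saunders 1981);
* potential-to-in-situ temperature by Runge--Kutta integration of the
  adiabatic lapse rate, and in situ density from the EOS-80 international
  equation of state (Fofonoff & Millard 1983) — the classic `seawater`
  formulation; TEOS-10 differences are far below the analysis'
  sensitivity, and the conversion sits behind this module's interface so
  it can be swapped;
* oxygen solubility from the Garcia & Gordon (1992) Benson--Krause fit
  (µmol kg^-1^), water vapour pressure from Weiss & Price (1980);
* $pO_2 = (C/C_{sat})\, x_{O_2} (P_{atm} - p_{H_2O})$ with
  $x_{O_2} = 0.20946$ and $P_{atm} = 1013.25$ mbar.  Hydrostatic pressure
  is ignored in the partial pressure, as is conventional for metabolic
  indices; the ceiling at 0 °C and salinity 35 is ~211 mbar, against
  which the species thresholds of 116--166 mbar should be read.

## Habitat construction

Two-dimensional occurrence-probability maps are thresholded ("larger than
zero" is strict `> 0`, following the wording of the zero-threshold design;
positive thresholds such as 0.8 are inclusive, which keeps cells at
exactly a printed threshold), regridded to the model grid by
largest-area-fraction (majority) regridding on a plate-carrée area
approximation with cosine-latitude weighting, and extruded over the
species depth range.  Depth membership is by level centre within the
closed interval — a convention that avoids double counting at layer
edges.  Squid species use habitat-suitability surfaces with their
published species-specific thresholds (0.228, 0.281, 0.121) instead of
occurrence probabilities.  All habitats are intersected with the wet mask
and capped at 3185 m; map content north of 45°S is truncated (and the
truncated probability mass reported).

Volumes honour partial bottom cells: a layer's wet thickness is clipped at
the bathymetry, so $\Omega$ and $\Phi$ are not biased by all-or-nothing
bottom cells.  The continental shelf is the connected region of cells
shallower than 1000 m reachable from the southernmost wet row (flood fill
with longitude wrap), which excludes isolated shallow offshore banks.
The three management sectors are pure longitude bands (70°W--30°E,
30°E--150°E, 150°E--70°W) that partition the domain south of 45°S.

## Scenario analysis

Future viability is evaluated on annual-mean fields (a conservative
choice: monthly extremes would show larger change), while thresholds
always come from the monthly historical climatology; the historical
$\Omega$ baseline also uses the annual-mean historical field so the
comparison is like-for-like.  Derived fields of an annual mean are
recomputed from the annual-mean state variables rather than averaged, so
attribution identities hold exactly.

Future fields are drift-corrected by subtracting the control run's change
over the same interval, applied to in situ temperature and oxygen
concentration after conversion (the difference to correcting potential
temperature first is second order), after which $pO_2$ is recomputed.
Attribution keeps the other driver at historical levels: the
temperature-only mode pairs future temperature with the historical annual
$pO_2$; the oxygen-only mode recomputes $pO_2$ from future oxygen with
historical temperature and salinity.  Because the index is a product of a
supply factor and a temperature factor, the two single-driver AGI ratios
multiply exactly to the combined ratio when $pO_2$ is supplied directly.

Percent changes always use the historical value as denominator; strata
with zero historical volume are reported as undefined (`NA`), never as 0
or infinity.  Overlap changes are reported for the whole habitat, the
shelf, the four depth intervals 0--400/400--700/700--1000/1000--3500 m,
and the three sectors.  Prey richness is counted per cell of the
predator's viable mask and area-averaged per level (volumes would
double-weight thick deep layers in what is a per-level count).  When
comparing richness across periods the future count can be evaluated over
the *historical* predator viable mask (`within =`), so both periods
average the same region; without this, the conditional mean over a
shrinking future mask can rise even while prey are lost everywhere.

## The synthetic ocean

No ocean-model output ships with the package; a seeded generator provides
inputs with the statistical structure the analysis assumes, and its
defaults are the study conditions for all tests:

* grid: 90 × 16 × 20 (4° lon × ~2° lat, −78° to −45°S, depth edges at
  $3500\,f^{1.7}$ m so layers thicken with depth) — coarse enough for
  seconds-scale runs, fine enough that the 0--400/400--700/700--1000 m
  intervals contain distinct levels; a ~600 m shelf band along the
  southern boundary, a slope whose latitude wobbles with longitude, and a
  ~3400 m basin;
* climatology: cold southern surface (−1.5 °C) warming to ~5 °C at 45°S,
  a CDW-like subsurface temperature maximum near 500 m, salinity
  34--34.7, oxygen falling from ~330 mmol m^-3^ at the surface to a
  minimum near 600 m; a seasonal surface cycle (amplitude 1.5 °C)
  decaying by ~200 m; spatial noise (0.15 °C, 0.02, 6 mmol m^-3^) drawn
  once per cell and shared by all months — a long-term climatology's
  texture is spatial, so month-to-month variation is carried by the
  seasonal cycle alone and a zero-amplitude cycle makes every month equal
  the annual mean;
* scenarios: forcing scales 0.25/0.5/0.75/1.0 for the four emission
  pathways (chosen to give a monotone forcing ladder, not as a claim
  about real scenario spacing).  At full scale: surface-intensified
  warming with maximum amplitude 1.3 °C applied with a latitudinal shape
  (weak under-ice warming in the south, strongest at the northern edge,
  in-habitat surface maximum ~1.2 °C), a small deep warming bump; an
  oxygen perturbation specified in concentration units — a gain of
  12 mmol m^-3^ in the upper ocean and a loss of 18 mmol m^-3^ peaking at
  700 m — because converting concentration to $pO_2$ is precisely what
  the pipeline must do; and a linear control drift (+0.05 °C,
  −2 mmol m^-3^) carried by both the control and every scenario;
* species: a domain-spanning predator (0--2210 m, probability positive
  over every wet column) and seven prey archetypes spanning
  shallow-shelf, mid-shelf, krill-like, subsurface open-ocean,
  sector-restricted, deep, and suitability-thresholded squid-like
  distributions.

With these defaults the pipeline reproduces the qualitative change
surfaces of the real analysis: relative AGI gains in the top ~250 m
(oxygen gain outweighing warming-driven demand), losses of 5--10 % between
400 and 1200 m peaking near the deoxygenation maximum, oxygen dominating
the attribution, overlap losses concentrated at 400--1000 m for subsurface
prey, and monotone ordering across the scenario ladder.

What the generator does **not** emulate: mesoscale circulation and fronts,
sea-ice control of the seasonal cycle, interannual variability,
ice-shelf cavities (the bathymetry surface is the only floor), realistic
scenario spacing, and the observed magnitudes of habitat loss.  Because
the synthetic world has modest horizontal variance, viability collapses
more sharply at the worst-hit depth levels than the real fields show
(interval losses can approach 100 % where eddy-permitting projections
show 20--40 %).
Passing tests therefore demonstrate the correctness of the machinery and
the qualitative response patterns, not quantitative agreement with any
real projection.

## Numerical choices and degenerate inputs

* Percentile rule as above; the implementation tolerates cumulative-weight
  rounding at $10^{-12}$.
* Missing values: land and below-seafloor cells are `NA` end to end,
  never zero-filled; relative change where the baseline is zero is `NA`.
* Temperatures cross all interfaces in °C; the Kelvin conversion
  (+273.15) happens only inside the index evaluation.
* Inputs are validated against plausible oceanic ranges (−3 to 40 °C,
  salinity 0--42); the generator clips synthetic temperatures at the
  freezing point (−1.9 °C).
* Empty habitats, zero-weight samples, shape mismatches and missing file
  variables raise descriptive errors rather than propagating nonsense.

## Problem sizes

Default test and analysis runs use the 90 × 16 × 20 grid (25 168 wet
cells), 12 climatological months, 8 species and 4 scenarios; a full
pipeline run takes a few seconds on one CPU.  The weighted-percentile
oracle tests enumerate all weight patterns up to n = 8; regridding and
shelf-connectivity tests use brute-force area sampling and graph
components as independent oracles.

## Known limitations

The index considers temperature and oxygen only — no sea ice,
circulation, acidification, food-web dynamics, acclimation or adaptation —
and only contemporary habitat: it cannot create habitat beyond the
prescribed distribution bounds.  Thresholds inherit any bias of the input
fields.  The regridding is majority-vote on a regular lon-lat
approximation, not exact spherical polygon overlap.  The published
29-species table ships as a reference fixture; reproducing its threshold
values requires the eddy-permitting ocean-model fields it was derived
from, which are beyond desk scale.
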