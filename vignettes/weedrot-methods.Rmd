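---
title: "Density-structured rotation modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-structured rotation modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(weedrot)
```

## The problem

Black-grass (*Alopecurus myosuroides*) is the dominant herbicide-resistant
weed of northern-European cereal systems. Farmers facing it must choose
between continuing a profitable but resistance-promoting rotation
(business as usual, BAU: winter wheat, winter wheat, oilseed rape, repeated)
and switching to diversified mitigation (MIT) rotations that suppress the
weed through spring cropping, stale seedbeds and altered tillage, at a cost
in wheat area and often in profit. `weedrot` provides the machinery to make
that comparison quantitatively: a density-structured population model driven
by management, an economic layer with density-responsive wheat yield, and
scenario comparison through opportunity and productivity costs.

## State variable and classification

A field's weed burden is tracked as a **density distribution**: the
proportions of its survey grid cells in five ordinal states (absent, low,
medium, high, very high). Fields are classified from raw data in two
dichotomies:

* **Density**: the mean quadrat score is categorised with cut-offs 0.5 /
  1.5 / 2.5 / 3.5; `absent`--`medium` count as low density (LD), `high` and
  `very_high` as high density (HD), because only the two highest states
  carry a wheat-yield penalty. The boundary 0.5 belongs to `absent` and the
  other boundaries to the higher category, following the printed inequality
  directions of the source survey's category definitions.
* **Resistance**: the mean glasshouse assay mortality across two selective
  herbicides (mesosulfuron + iodosulfuron, and cycloxydim), dichotomised at
  72% mortality. Mortality is what the herbicide achieves, so **mortality at
  or above the threshold means low resistance**; the threshold itself is
  assigned to the low-resistance side. The assays are averaged unweighted;
  replicate counts are not modelled.

The combinations LD-LR, LD-HR and HD-HR are the initial conditions
strategies are designed for. HD with low resistance only arises under poor
management: it is reported flagged as anomalous rather than silently
dropped or coerced.

## The transition model

The population model is a proportional-odds cumulative-logit regression on
the ordinal next state:

$$P(s_{t+1} \le k \mid x) = \mathrm{logit}^{-1}(c_k - \eta), \qquad
\eta = x^\top\beta + u_{\text{crop transition}} + u_{\text{rotation}} +
u_{\text{field}},$$

with strictly increasing cutpoints $c_1<\dots<c_4$ and zero-mean Gaussian
random effects. Fixed effects cover the previous state (four indicator
terms), sowing window, tillage class, stale seedbed count, glyphosate and
selective application counts, relative seed rate, and the resistance level.
Numeric covariates are standardised internally (centre/scale stored with
the model) so coefficient magnitudes are comparable. The link is not named
by the originating analysis; the proportional-odds logit is the standard
choice for ordinal ecological state models and is adopted here.

Simulation is distribution-level Markov updating: for year $t$ the model
yields a $5\times5$ row-stochastic matrix $M_t$ (row $s$ = next-state
distribution given previous state $s$) and $p_t = p_{t-1} M_t$. Whether the
original analysis updated per quadrat or per distribution is not stated;
distribution-level updating is exact in expectation for exchangeable
quadrats and is what the economics consumes. Trajectories include year 0,
so "the distribution at year 6" reads at index 6. The transition into year
$t$ uses year $t$'s management and the crop transition from year $t-1$'s
crop; the first year assumes a preceding winter wheat (configurable).
Resistance is held fixed for a whole run: the model deliberately does not
let resistance evolve, and it does not decay (no consistent fitness costs).

### Estimation

The fitter maximises the penalised likelihood with ridge (Gaussian)
penalties on the three random-effect blocks, alternating BFGS optimisation
(analytic gradients) with moment updates of the random-effect standard
deviations, plus a very weak ridge (prior sd 100) on the fixed effects so
that design columns without variation stay well-posed. The build contract
preferred full posterior sampling as the default backend with penalised
likelihood as the fast mode; no MCMC backend is available in the target
environment, so penalised likelihood is the only backend. The contract is
on the returned coefficient sets, which are unchanged; optimizer status,
gradient norm and observed-information standard errors are exposed as
diagnostics. Parameter recovery on data simulated from a known model
(10,000 transitions) returns every coefficient within 0.15 of truth and
within its 95% Wald interval — this is asserted in the acceptance suite,
not merely claimed here.

### Multiple imputation for unseen crop transitions

Crop transitions never observed in training cannot have an estimated
effect. Following the documented interpretation of the original multiple
imputation (37 imputations), the fitted model carries `n_imputations`
coefficient sets; everything estimated from data is shared, and each
imputation draws an independent $u \sim N(0, \sigma^2_{\text{ct}})$ for
every unseen transition at simulation time, deterministically from the run
seed. With complete data the imputations coincide, so imputation "collapses"
as it should. The exact imputation mechanics of the original fit are in
unavailable supplementary material; the imputation count is configurable.
Proxy crop transitions can be supplied as an explicit map applied before
encoding; every applied proxy is recorded on the trajectory object.

## Strategies

BAU (ww-ww-osr repeated, late-autumn wheat drilling with one stale seedbed)
and CWW (six wheat years) are built in code from their printed definitions.
The 27 MIT strategies (3 density-resistance classes x 3 soils x 3 regions)
are **data**: a packaged CSV fixture, clearly labelled synthetic, built to
satisfy every qualitative constraint the published results state — at least
one spring crop, more stale seedbeds than BAU, fewer wheat years and up to
(exactly at most) three times BAU's glyphosate for high-resistance targets,
reduced total herbicide for LD-LR, four spring crops in the eastern HD-HR
rotation, heavier selective use on wheat where density is high. The real
strategy tables live in unavailable supplementary material and can replace
the fixture without code changes; `load_strategies()` validates any file
against the same rules. Two fixture choices were forced by those rules
interacting with the synthetic world: LD-LR wheat years carry two stale
seedbeds (LD-LR mitigation is the closest to integrated weed management,
increasing non-chemical control as herbicide is cut), and LD-LR strategies
stay on `min_till` rather than `no_till` so reduced herbicide is compensated
culturally. The eastern LD-LR rotation keeps BAU's four wheat crops but
swaps one oilseed rape year for a spring crop, satisfying both "same wheat
count as BAU in the east" and "every MIT rotation includes spring cropping".

## Economics

The economic layer is a gross-margin model: `gross profit = output − costs`
exactly, per year, with costs itemised as herbicide (dose x product cost),
operations (tillage, drilling, spray passes, stale seedbed passes; fuel and
labour) and other (fertiliser, seed, sundries). Only winter wheat responds
to weed density: `yield = base x sum_s p_s (1 − loss_s)` with zero loss for
the three lowest states. Default penalties are loss(high) = 0.15,
loss(very_high) = 0.35 with ±50% lower/upper limits for sensitivity
analysis — placeholders for the unavailable supplementary values, as are
all prices (2019 levels, chosen to avoid pandemic and war anomalies) and
base yields. No acceptance quantity depends on these fixture values. Mean
annual wheat yield is rotation total divided by rotation length, making
per-year figures comparable across scenarios with different wheat
frequencies. Gross profit is a gross margin: fixed and overhead costs,
subsidies and discounting are out of scope, as is crop abandonment from
harvest pollution.

## Comparison and scale-up

Opportunity cost is BAU's mean annual gross profit minus MIT's; productivity
cost the same for wheat yield; negative values favour switching. Worst-case
18-year sequences (BBB/BBM/BMM/MMM: three 6-year blocks, each BAU or MIT)
start from the stated worst-case distribution (0.1, 0.1, 0.2, 0.3, 0.3) —
70% of cells can still get worse — with resistance fixed high, and are
compared to continuous BAU (BBB) through cumulative year-by-year cost
series. National totals multiply per-hectare values by county cereal areas
and the county's observed category shares, selecting values by the county's
region and averaging unweighted over soils. The packaged county table
carries 13 counties; the extracted source caption lists only 12
abbreviations, so the 13th (Norfolk) and the county-to-region assignment
are labelled stand-ins. Percentages are rounded only at the reporting
layer.

One reported figure is internally inconsistent in the source: the year-6
damaging proportion is described as "60% lower" under MIT while the year-6
summary cells give a 68% reduction and the annual-mean cells give exactly
60%. The worked example implements the annual-mean reading; the discrepancy
is documented, not resolved. Similarly the LD-HR productivity cost is
printed as 1.638 where the printed inputs differ by 1.63; the footnote
attributing this to rounding is taken at face value.

## The synthetic world

The generator emulates the structure of the field data so the pipeline is
testable without downloads: 125 fields across the 13 counties, a 20 x 20
quadrat grid per field (grid dimensions are unstated in the source; 20 x 20
is small enough for fast tests and large enough for stable proportions),
category mix 14% / 56% / 30%, two-herbicide assay mortalities drawn from
Beta distributions with means 0.90 (susceptible) and 0.40 (resistant) at
concentration 50 — separable across the 0.72 threshold while exercising
boundary cases — and per-category quadrat-state distributions concentrated
low for LD and high for HD (stand-ins for unstated initial distributions).
Quadrat states are generated directly on the ordinal scale; the upstream
counts-per-quadrat protocol is below the analysis's level of abstraction.
Management histories follow a configurable crop-transition frequency table;
within a crop, tillage, stale seedbeds, herbicide programmes and seed rate
vary independently so the fitted model can separate their effects
(management fully determined by crop would confound fixed effects with the
crop-transition random effects). Withheld transitions are explicit
configuration, never random, so imputation tests are reproducible.

What the generator does **not** emulate: spatial autocorrelation within
grids, seed-bank dormancy, weather, resistance evolution, and any
correlation between management choices and current weed state (real farmers
respond to what they see). A green test therefore establishes that the
machinery is correct for the stated world, not that the fixture values
reproduce the original study's headline numbers — those depend on the real
survey data and unavailable supplementary tables, and are deliberately out
of reach at desk scale.

## Numerical choices

* Distributions must sum to 1 within 1e-9; simulation renormalises each
  year to stop round-off accumulating over 18-year runs.
* Cutpoints are parameterised as a base plus log-increments, so ordering is
  structural rather than constrained.
* Likelihood probabilities are floored at 1e-12 before logging.
* Random-effect standard deviations are floored at 0.05 (the moment update
  degenerates when the true variance is zero).
* The stage seed fan-out is `(seed mod 1000003) * 1009 + stage`, mod
  2^31 − 1, keeping every derived seed a valid 32-bit integer.

## Known limitations

The estimation backend is penalised likelihood only; between-imputation
variability reflects unseen-transition uncertainty, not posterior
uncertainty in estimated coefficients. Economic tables are stand-ins.
Sequence economics are compared on across-imputation mean series. No
statistical testing between scenarios is performed — like the source
analysis, ranges across regions, soils and subcategories are reported
instead.
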