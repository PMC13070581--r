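---
title: "The multi-mechanism niche model: structure, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The multi-mechanism niche model: structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mmniche)
```

## Overview

`mmniche` simulates the assembly of a sown grassland metacommunity on a
matrix of small contiguous plots spanning a soil-nitrogen gradient. Four
mechanisms act together: soil resource competition, dispersal and
colonisation, spatiotemporal niche differentiation, and species
differences in population growth rates. Each mechanism is built from
trait-based *attributes* — 11 in all — and every attribute can be
switched off independently. Switching off a trait-valued attribute
replaces the species-specific values with the unweighted community mean;
switching off a process attribute disables the process (between-plot
dispersal, the stochastic recruitment lottery, or the R* competitive
hierarchy). With all 11 attributes off the species are dynamically
identical: the model collapses to a neutral limit, which is the anchor
for several of the package's tests.

A year of simulated dynamics proceeds: seed arrival and recruitment at
the start of the season, 160 days of continuous-time competitive growth,
then an overwinter transition that routes the reproductive fraction of
biomass into next year's seed rain and exposes the rest to mortality.
Reported annual biomass is end-of-season (peak) biomass, before
overwintering — matching how field biomass is clipped at peak standing
crop. Year 0 is special only in that the "seed rain" is the sown seed
biomass added by the experimenter, which passes through the same
recruitment pathway as natural seed rain in later years.

## The submodels and their assumptions

### Arrival

Dispersal distance follows the WALD (inverse-Gaussian) kernel,
parameterised per species from seed-release height $h$, mean wind
velocity $w$ and seed terminal velocity $v$:
$\lambda = h^2/\sigma^2$, $\mu = h w / v$, with $\sigma^2 = 0.3$
describing turbulence above the canopy. The plot-to-plot dispersal
fraction array is estimated once per run by simulating $2 \times 10^4$
seeds per species and source plot: distances from the kernel (sampled
with the standard inverse-Gaussian transform sampler), directions
uniform on $[0^\circ, 360^\circ)$, start points uniform within the
source plot, landings assigned by point-in-rectangle test. Counting
guarantees the conservation identity
$\sum_k pd_{ijk} + \mathrm{loss}_{ij} = 1$ exactly.

Choices where the design was open:

* **Seed origins** are area-distributed (uniform within the source
  plot) rather than a plot-centre point source: plots are only 0.75 m
  wide and contiguous, so the within-plot origin matters for
  nearest-neighbour fractions. A `source = "centre"` option exists and
  is what the quadrature cross-check uses.
* **Boundaries absorb.** Seeds landing on walkways or outside the block
  array are lost, as in a weeded field margin. The alternative
  (reflecting or wrapping) has no field analogue here.
* **Wind velocity** is a single scalar parameter, default 3 m/s — a
  typical mid-latitude growing-season mean — configurable everywhere it
  matters.
* The array is computed once per run and reused across years: the
  kernel is time-invariant, so recomputing would only add Monte-Carlo
  noise. In the factorial scan it is additionally shared across
  scenarios within a replicate, because no switch alters the dispersal
  traits (the canopy-height attribute deliberately leaves seed-release
  height untouched).

Seed rain into plot $k$ is end-of-season biomass times the species'
fecundity $f_i$ times the dispersal fraction, summed over source plots,
and then *weeded*: arrivals of species never sown in $k$ are zeroed,
mirroring the experimental removal of non-target species.

### Recruitment (the lottery)

Arriving seed biomass converts to adult biomass at up to $1/f_i$ units
per unit of seed — the equilibrium conversion: if $B$ adults produce
$B f_i$ seed, then $x$ seed implies roughly $x/f_i$ adults. Conversion
is limited by a plot-level soil-N budget. Each species' establishable
nitrogen is

$$\mathrm{headroom}_N(i) = q_i \max\!\big(0,\; B^*_{ij} - b_{ij} -
\textstyle\sum_{i'} W_{ii'}\, b_{i'j}\big),$$

the growth-equation equilibrium headroom scaled by tissue N
concentration $q_i$. Using the same competition coefficients $W$ as the
growth ODE keeps recruitment and within-season dynamics mutually
consistent: a plot already at competitive equilibrium admits no
colonists. With the lottery on, seed packets (default $10^{-3}$ g, or
the species' measured per-seed mass when available) are drawn uniformly
without replacement and establish while their nitrogen demand fits the
species' remaining headroom; with it off, resources are divided
deterministically in proportion to seed biomass, capped at demand, with
unused shares redistributed to a fixed point. In the abundant-resource
limit both pathways give exactly $\mathrm{pool}_i/f_i$.

Two implementation notes. First, the sequential draw is accelerated
*exactly in distribution*: headrooms only decrease during recruitment,
so a species that cannot establish now never can again (its remaining
packets, all doomed, are discarded), and any batch of $m$ draws whose
worst-case total demand fits every current headroom is guaranteed to
establish in full, so only its species composition — a multivariate
hypergeometric draw — is needed, not its order. Second, the sub-packet
remainder of each species' pool is established at the end (random
order), so the abundant-limit conversion is exact rather than truncated
at packet resolution; sensitivity to packet mass is below Monte-Carlo
noise, which the test suite checks.

### Growth

Within a season each species relaxes toward its monoculture carrying
capacity at rate $RGR_{ij}$, discounted by competition from superior
resource competitors:

$$\frac{dB_i}{dt} = RGR_{ij}\Big(B^*_{ij} - B_i - \sum_{i':\,R^*_{i'} <
R^*_i} \frac{q_{i'}}{q_i}\,\mathrm{overlap}_{ii'}\; B_{i'}\Big).$$

Soil N modulates both parameters: $B^*_{ij} = \exp(a_i + b \log N_j)$
(log-log regression, species-specific intercepts, common slope) and
$RGR_{ij} = \max(0, c_i + d_i N_j)$ (linear, clamped at zero). The
four embedded assumptions: each species can access at most
$q_i B^*_{ij}$ of soil N per plot; superior competitors (lower $R^*$)
pre-empt that access; spatiotemporal niche differences partially shield
poorer competitors; and nitrogen is recycled instantly, so the growth
law depends only on current biomasses.

Overlap is asymmetric. The impact *of* $i'$ *on* $i$ is weighted by the
fraction of $i$'s rooting zone and canopy interval occupied by $i'$
(interval overlap from the ground up: $\min(x_i, x_{i'})/x_i$), averaged
into a spatial component, times the fraction of $i$'s active months
during which $i'$ is also active. Total overlap is the *product* of the
spatial and temporal components: competition requires being in the same
place *and* at the same time. (The arithmetic-mean alternative was
rejected because it would let temporally disjoint species compete at
half strength.) Phenology is resolved in whole months, the resolution of
the underlying trait data, and affects competition only through the
overlap weights — species grow over the full 160-day season. The
equations support this minimal reading; truncating each species' own
growth window would add a second, unparameterised phenology effect.

Numerical choices: fixed-step 4th-order Runge–Kutta with a 1-day step
(the system is linear and mildly stiff at most; accuracy against the
single-species closed form $B(t) = B^* - (B^* - B_0)e^{-RGR\,t}$ is
~10⁻¹⁰ relative at these rates, and the test suite enforces 0.1%).
Biomass is floored at zero after each step; a species driven to zero
stays at zero for the rest of the season, and a species starting a
season at zero cannot appear from nothing — arrival is the lottery's
job, not the ODE's. Ties in $R^*$ compete in neither direction (strict
inequality). With the $R^*$ attribute off, interspecific interaction
strength is set equal to intraspecific strength: every other species
competes with coefficient $\mathrm{overlap}_{ii'}$ (tissue-N ratio 1),
which is what makes the all-off neutral limit exact.

### Overwinter

$b_{ij}(y) = B_{ij}(y-1, 160)\,(1-m_i)\,(1-f_i)$: the reproductive
fraction $f_i$ leaves as seed (and is safe from winter mortality); the
remainder survives with probability $1-m_i$ in biomass terms.

## The factorial scan and evaluation

`run_factorial()` runs every scenario × replicate with a seed derived
deterministically from (master seed, scenario bit-code, replicate), so
results are independent of batch composition and execution order —
scenarios can be added, removed or parallelised without changing any
run. Deterministic configurations (lottery off) still execute all
requested replicates and simply produce identical results.

Prediction error is the B\*-scaled RMSE: residuals divided by the
species' monoculture carrying capacity in that plot, squared, averaged
within a group, rooted. Scaling removes the dependence of raw RMSE on
average biomass. Community-level error per plot is the arithmetic mean
of the sown species' errors. $R^2 = 1 - SS_{res}/SS_{tot}$ (variance
explained about the observed mean, not squared correlation) is computed
on log-transformed scaled biomass, $\log(y/B^* + 10^{-3})$; the offset
admits zeros and its exact value only matters for plots predicted or
observed empty. Importance analyses select the lowest-RMSE 5% of runs
per plot and complexity level (attributes on, 1–11, or mechanisms on,
1–4, where a mechanism counts as on when exactly — or at least — $k$ of
its attributes are on) and report per-attribute inclusion frequencies,
pairwise co-occurrence counts, and the collinearity of per-attribute
marginal effect vectors (mean error with the attribute off minus on,
per plot) — the last is a reconstruction, as the exact construction
behind the published collinearity summary is not specified; monocultures
are excluded from importance analyses by default.

PCA-based trait imputation (`impute_trait_pca()`, used for demographic
rates lacking direct estimates) standardises traits, seeds missing
cells with the trait mean, and iterates the
decompose-with-leading-components/reconstruct cycle to a fixed point
(components covering ≥ 90% of variance; tolerance $10^{-8}$). The
iteration matters: a single reconstruction pass leaves the mean-filled
cell's shrinkage in the species score — roughly $1/n_{\mathrm{traits}}$
relative error even for exactly low-rank trait matrices — whereas the
fixed point recovers low-rank structure to numerical precision.

## The synthetic-fixture generator

`fixture_spec()` defaults encode the emulated experiment: 5 grass
species; 10 blocks of 64 contiguous 0.75 m × 0.75 m plots (4 × 16, i.e.
3 m × 12 m blocks) separated by 1 m walkways; a monotone block-level
soil-N gradient of ~100–1200 mg/kg with 8% lognormal within-block
jitter; 43 sowing treatments spanning richness 1/2/3/5 and total
densities of 600, 3000 or 6000 seedlings/m² (constant across richness
— only the per-species ratio changes), with 1–4 replicates filling each
block. All monocultures occur at every density, since monoculture
behaviour anchors the B\* scaling. Seedling densities convert to sown
seed biomass via per-species per-seed mass (0.2–2 mg, typical of
temperate grasses); the published seeding-rate-to-biomass conversion is
not available, so the conversion is explicit and generated traits carry
a `seed_mass` column. Trait ranges (fecundity 0.05–0.4, mortality
0.1–0.6, heights 0.2–1.2 m, rooting depths 30–200 cm, phenology within
April–October, terminal velocities 0.3–3 m/s, tissue N 5–25 mg/g, B* of
roughly 60–220 g/m² at mid-gradient) are field-realistic for perennial
prairie grasses.

What the generator does *not* emulate: the original treatment
assignment table (only its marginal properties), species introduction
sequences, inter-annual climate variation, herbivory, and measurement
design details. Synthetic "observations" are full-model output times
lognormal noise — so tests against them demonstrate internal
consistency of the pipeline (the full model should, and does, rank best
against its own output), not predictive skill on real field data, which
requires the archived experimental observations.

## Problem sizes used in the packaged checks

The test suite runs the whole pipeline at a reduced scale chosen to keep
the checks sharp but quick: a 2-block fixture (128 plots, 5 species),
32 scenarios × 3 replicates × 6 seasons for the self-consistency scan,
2 × 10⁴ Monte-Carlo seeds wherever the dispersal array is quantitatively
compared against quadrature, and 10⁴ random instances for the
recruitment budget-conservation property. The full design (10 blocks,
2048 scenarios × 10 replicates) runs through exactly the same code
paths; only the loop counts differ.

## Known limitations

* Nitrogen is the only limiting resource; light competition enters only
  implicitly through canopy overlap weights.
* No seed bank or dispersal through time: seed not establishing in the
  year it arrives is lost.
* The competition ODE is linear; transgressive overyielding cannot
  emerge.
* Dispersal is isotropic with a single scalar wind speed.
* The deterministic recruitment route is an idealised proportional
  division; it matches the lottery's expectation exactly only when
  resources are abundant or species are exchangeable.
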