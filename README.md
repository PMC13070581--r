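# mmniche

A spatially explicit, stochastic metacommunity simulator for predicting
the composition of sown grassland communities from species traits, with a
factorial attribute-ablation framework for ranking model variants.

## The scientific problem

Community assembly is governed by several mechanisms at once — resource
competition, dispersal and colonisation, spatiotemporal niche
differentiation, and differences in population growth rates — yet most
predictive models encode only one or two of them. `mmniche` implements a
multi-mechanism niche model in which all four act simultaneously on a
matrix of experimental plots spanning a soil-nitrogen gradient, and in
which each of 11 trait-based *attributes* can be switched off
independently (replacing species-level differences with the community
mean, or disabling a process). Running the full 2^11 factorial of
attribute configurations and scoring each variant against observations
reveals which mechanisms carry predictive power.

## The model

Biomass of species *i* in plot *j* is tracked annually, *b~ij~(y)*, and
daily within a 160-day growing season, *B~ij~(y, t)*.

**Arrival.** Seed dispersal distance follows the WALD (inverse-Gaussian)
kernel with density

    ps(d) = sqrt(λ / (2π d³)) · exp( −λ (d − μ)² / (2 μ² d) ),

where λ = h²/σ² and μ = h·w/v (h seed-release height, w mean wind
velocity, v seed terminal velocity, σ² = 0.3). Plot-to-plot dispersal
fractions *pd~i,j,k~* are estimated by Monte-Carlo simulation of 2·10⁴
seeds per species and source plot (uniform directions, absorbing
walkways/margins). Seed rain is end-of-season biomass × fecundity *f~i~*
× dispersal fraction, and weeding restricts arrivals to the species sown
in each plot.

**Establishment.** Arriving seed converts to adult biomass through a
lottery: packets of seed are drawn uniformly without replacement, each
contributing up to 1/*f~i~* units of adult biomass while the plot's
soil-N headroom (q~i~ · equilibrium headroom, with q~i~ tissue N per unit
biomass) lasts. With the lottery attribute off, resources are divided
deterministically in proportion to seed biomass.

**Growth.** Within a season,

    dB_i/dt = RGR_ij · ( B*_ij − B_i − Σ_{i′: R*_i′ < R*_i} (q_i′/q_i) · overlap_ii′ · B_i′ ),

i.e. relaxation toward the soil-N-modulated monoculture carrying capacity
*B\*~ij~* = exp(a~i~ + b·log N~j~), discounted by competition from
superior resource competitors (lower *R\**), weighted by tissue-N ratio
and by asymmetric spatiotemporal overlap (rooting depth, canopy height,
phenology; total overlap = spatial × temporal). Between seasons,
*b~ij~(y)* = *B~ij~(y−1, 160)* · (1−m~i~) · (1−f~i~).

## Worked example

Generate a synthetic two-block experiment (128 plots, 5 grass species,
soil N ~100–1200 mg/kg), simulate six growing seasons under the full
model, then compare the full model, a resource-competition-ablated
variant and the neutral limit against synthetic observations:

```r
library(mmniche)
spec   <- fixture_spec(n_blocks = 2)
traits <- make_traits(spec, seed = 1)
plots  <- make_design(spec, traits, seed = 2)

sim <- run_simulation(traits, plots, switch_config(), years = 6, seed = 3)
sim
#> mmniche_sim: 5 species x 128 plots, 6 growing seasons
#>   attributes on: 11/11; seed: 3
#>   final-year mean biomass by species (g/m^2):
#>   sp1   sp2   sp3   sp4   sp5
#> 82.75 37.48 42.93  5.33  8.08

obs  <- make_observations(traits, plots, noise_sd = 0.2, seed = 4, years = 6)
mk   <- function(cfg) { d <- as.data.frame(t(unclass(cfg)))
                        d$scenario_code <- scenario_code(cfg); d }
scen <- rbind(mk(switch_config()),                               # full model
              mk(switch_config(b_star = FALSE, r_star = FALSE)), # no resource competition
              mk(switch_config(.default = FALSE)))               # neutral limit
scan <- run_factorial(traits, plots, scen, replicates = 2, years = 6,
                      master_seed = 5)
ev   <- evaluate_scan(scan, obs, traits, plots)
aggregate(rmse ~ scenario_code, data = ev[ev$richness > 1, ], FUN = mean)
#>   scenario_code       rmse
#> 1             0 0.56614880
#> 2          2044 0.53951161
#> 3          2047 0.08514519
```

The `rmse` column is the community-level B\*-scaled error averaged over
polyculture plots: the full model (code 2047) fits its own noisy
observations about six times better than variants lacking the
resource-competition attributes (2044) or all attributes (0), which is
the expected ranking when the observations were generated by the full
model.

The 11 attributes, their four-mechanism grouping
(`mechanism_groups()`), scenario enumeration (`enumerate_scenarios()`),
overlap components (`total_overlap()`), top-model inclusion frequencies
(`top_models()`) and attribute co-occurrence (`pair_cooccurrence()`) are
all exported; `inst/cli/mmniche.R` wraps the pipeline for shell use
(`synth`, `simulate`, `scan`, `evaluate`, `report`).

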