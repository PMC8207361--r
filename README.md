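# fishscape

An individual-based model of an age-structured fish population on a
two-dimensional landscape, built to ask a question that matters for spatial
fisheries management: **when size-selective fishing truncates a population's
age structure, does its spatial distribution become more aggregated — and
what controls how strongly?**

The answer the model probes is the interplay of three things:

* **age-specific habitat preference** (ontogenetic niche shift) — different
  age classes prefer different habitats, so removing the old ages empties
  "their" habitats;
* **carrying capacity** — when it is small, density dependence pushes fish
  off their preferred habitats and blurs the age-habitat association;
* **landscape structure** — a smooth habitat gradient lets fish follow local
  cues to their global optimum, a fragmented landscape traps them at local
  optima.

The package is aimed at quantitative ecologists and fisheries scientists who
want a fast, fully reproducible re-implementation of this simulation design
for exploration, teaching, or extension.

## The model

**Landscape.** An 11 × 11 lattice with a closed boundary. Each cell carries
an intrinsic habitat index *H* ∈ {0, 0.1, …, 1}; each of the 11 levels
occupies exactly 11 cells, arranged either as a column-wise **gradient** or
as a uniformly random (**fragmented**) permutation. All cells share one
carrying capacity *K* ∈ {5, 10, 20, 40, 80, 160}.

**Fish.** Nine age classes. Each fish of age *i* holds a preference value
*Z* drawn from its age's niche curve, a symmetric Beta(1.2, 1.2) rescaled to
an age-specific interval. Strong preference: niche centres 0.2 → 0.8, width
0.4; weak preference: centres 0.4 → 0.6, width 0.8. Both tile [0, 1].

**Movement** (40 synchronous steps per year). A fish evaluates the realized
suitability of its cell *c*,

> *R*(*c*, *i*) = 1 − |*H<sub>c</sub>* − *Z<sub>i</sub>*| − *N<sub>c</sub>* / *K*,

draws one random Moore neighbour, and moves there iff that cell's realized
suitability is strictly higher — a locally sensing, density-dependent
approximation to the ideal free distribution (basin model).

**Demography** (once per year, after the last movement step). Each fish of
age *i* spawns one recruit with probability *R<sub>i</sub>* (0.53, 0.50,
then 0.01; newborn survival is 1, placed in the mother's cell), then
survives with probability 1 − *M<sub>i</sub>* − *F<sub>i</sub>* (natural
mortality 0.10/0.10/0.40…/1.00; fishing mortality *F* ∈ {0, 0.1, …, 0.5} on
ages 4–8). Survivors age and redraw *Z*. The corresponding Leslie matrix has
unfished growth rate λ ≈ 0.9998 (≈ 0.9956 at *F* = 0.5) and a right-skewed
stable age distribution.

**Outputs.** Per year, abundance by (cell, age class), snapshotted after the
final movement step. Over the analysis window (years 5–15) the package
computes **Shannon age diversity** H′ = −Σ *p<sub>i</sub>* ln *p<sub>i</sub>*
(age truncation ⇒ low H′) and the **spatial CV** of per-cell totals
(aggregation ⇒ high CV), then regresses CV on H′ within each
(preference, landscape, *K*) combination across all fishing levels. A
negative slope means age truncation elevates spatial variability.

## Worked example

```r
library(fishscape)

# Leslie demography across the six fishing levels
sapply(fishing_mortality_schedule(),
       function(Fv) growth_rate(build_leslie(make_vital_rates(Fv))))
#> 0.9998 0.9985 0.9974 0.9967 0.9961 0.9956

round(stable_age_distribution(build_leslie(make_vital_rates(0))), 3)
#> 0.258 0.233 0.209 0.126 0.075 0.045 0.027 0.016 0.010

# One run: strong preference, heavy fishing, gradient landscape
out <- run_simulation(sim_config("strong", F = 0.4, landscape = "gradient",
                                 K = 40, seed = 2024))
summarize_replicate(out)
#>   mean_shannon  mean_cv mean_popsize n_years
#> 1     1.462125 1.079451     340.9091      11

# A small factorial: all six fishing levels, 5 replicates
sm <- run_scenario_grid(scenario_grid(preference = "strong",
                                      landscape = "gradient", K = 40),
                        replicates = 5, master_seed = 11)
fit_cv_vs_shannon(sm)
#>    slope    se intercept r_squared  n
#> 1 -0.355 0.027      1.59      0.86 30
```

The growth rates show the designed near-stationarity (λ just below 1,
declining with fishing pressure); the stable age distribution is
right-skewed, as in most exploited fish stocks. In the single run, fishing
at 40% pushes mean age diversity down to ≈ 1.46 (the unfished maximum is
ln 9 ≈ 2.20) while the spatial CV rises above 1. The factorial fit makes
the headline pattern quantitative: the slope of spatial CV on age diversity
is clearly negative (−0.36 ± 0.03) — age truncation elevates spatial
variability.

Larger designs run through `run_scenario_grid()` directly or via the thin
CLI in `inst/cli/fishscape.R` (`run`, `grid` and `analyze` subcommands with
YAML configuration; see `?load_config`).

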