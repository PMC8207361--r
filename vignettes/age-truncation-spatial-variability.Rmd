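---
title: "Age truncation and spatial variability: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Age truncation and spatial variability: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fishscape)
```

# The question and the model

Exploited fish stocks lose their old age classes first: size-selective
fishing truncates the age structure. Because many species shift habitat as
they age (ontogenetic niche shift), truncation can empty the habitats the
old fish occupied and leave the population more spatially aggregated — a
distribution pattern associated with lower resilience. `fishscape`
implements an individual-based model designed to isolate this mechanism and
to ask how its strength depends on the degree of age-specific habitat
preference, on the environment's carrying capacity, and on landscape
structure.

The model couples three ingredients, each deliberately minimal:

1. **A lattice landscape.** 11 × 11 cells with a closed boundary. Each cell
   has a fixed intrinsic habitat index $H_c \in \{0, 0.1, \dots, 1\}$; the
   11 levels partition the 121 cells into 11 groups of 11, arranged either
   as a smooth column-wise gradient or as a uniform random permutation
   (fragmented). A single carrying capacity $K$ is shared by all cells and
   is deliberately independent of $H$.

2. **Age-structured fish with age-specific preference.** Nine age classes;
   each individual of age $i$ carries a preference $Z_i$ drawn from its
   age's niche curve — a symmetric $\mathrm{Beta}(1.2, 1.2)$ rescaled onto
   an age-specific interval. The *strong* mode (centres 0.2–0.8, width 0.4)
   gives narrow, well-separated niches; the *weak* mode (centres 0.4–0.6,
   width 0.8) gives broad, heavily overlapping ones. In both modes the
   union of intervals is exactly $[0,1]$, so preference strength is varied
   without changing the population's potential range.

3. **Density-dependent habitat selection.** The realized suitability of
   cell $c$ for a fish of age $i$ is the basin-model rule
   $$R(c,i) = 1 - |H_c - Z_i| - N_c / K,$$
   declining with both habitat mismatch and local crowding. Fish sense only
   locally: at each of 40 synchronous steps per year a fish draws *one*
   uniformly random Moore neighbour and moves there iff that cell's $R$
   strictly exceeds its current cell's. This randomized, strictly-improving
   local search approximates an ideal free distribution without assuming
   fish can sense gradients at a distance; 40 steps suffice for essentially
   all fish to reach a nearest-preference cell when $K$ is effectively
   infinite (the package's reachability check yields ≥ 99% under both
   preference modes).

The annual cycle is: 40 movement steps → snapshot → reproduction →
survival/ageing. Reproduction is one recruit per mother with probability
$R_i$ (0.53, 0.50, then 0.01 for ages 3–9), the recruit entering at age 1
in the mother's cell with survival 1. Survival is a single Bernoulli with
total mortality $M_i + F_i$ (natural mortality 0.10, 0.10, 0.40 × 6, 1.00;
fishing mortality $F \in \{0, 0.1, \dots, 0.5\}$ added to ages 4–8 only).
Survivors age and redraw $Z$ from the new age's curve. The matching Leslie
matrix (fecundities $R_i$ on the first row, survivals on the subdiagonal)
has unfished growth rate $\lambda \approx 0.9998$, falling to $\approx
0.9956$ at $F = 0.5$, with a right-skewed stable age distribution — a
demography tuned so that fishing changes age *structure* much more than
population *size*, keeping the two influences on spatial pattern apart.

# Summary statistics and regression design

Each year's snapshot (taken after the last movement step, before
demography) yields two indices:

* **Shannon age diversity** $H' = -\sum_i p_i \ln p_i$ over the
  landscape-wide age-class proportions. Low $H'$ = strong truncation.
  Natural logarithm; the base only rescales both axes of the regression and
  cannot change a slope's sign.
* **Spatial CV**: standard deviation over mean of the 121 per-cell total
  abundances. The sample ($n-1$) standard deviation is the default, with a
  population-variant switch (`spatial_cv(..., type = "population")`); the
  two differ by the fixed factor $\sqrt{120/121}$ and cannot reorder any
  comparison.

Both are averaged over the analysis window, years 5–15 (11 years),
excluding the initial transient: started from 100 fish in each of the nine
classes (900 total), the population needs about five years to relax from
the uniform to the right-skewed quasi-stable age structure, during which
total abundance declines to its quasi-stationary level (about 420 under the
deterministic projection). After year 5 the trajectory changes by well
under 1% per year.

One replicate contributes one (mean $H'$, mean CV) point per scenario. The
response of spatial variability to age truncation is the OLS slope of mean
CV on mean $H'$ within each (preference, landscape, $K$) combination,
pooled across all six fishing levels. The full-design model adds the
three-way interaction $H' \times \text{preference} \times K$ per landscape;
$K$ enters on the $\log_2$ scale by default because the design's levels
(5–160) are geometric, with a categorical-$K$ alternative exposed
(`factorial_model(..., K_coding = "factor")`).

# Numerical and design choices

Several points are genuinely open in this model family; the package fixes
them as follows.

**Self-counting in the movement rule.** With synchronous updating, both the
current and the candidate cell's suitability are evaluated on the occupancy
snapshot taken at step start. The mover is part of its current cell's
count; the candidate cell is evaluated with the crowding *already present
there*, i.e. without adding the mover. The alternative — counting the fish
at both locations — adds a constant $1/K$ penalty to every potential move,
which is negligible at large $K$ but at $K = 5$ freezes the population into
equal-density configurations and suppresses the density-driven churn the
basin model is meant to express; under that convention the low-$K$
weak-preference scenarios cease to show the negative CV–diversity
relationship that every other scenario shows. The chosen convention lets a
lone fish drift between equally good cells — a harmless random walk
consistent with the model's explicitly randomized direction choice.

**Strictness and ties.** A fish moves only on a *strict* suitability
improvement, so exact ties (equal $H$, equal snapshot density) keep the
fish in place. Candidate neighbours are drawn uniformly from the available
3, 5 or 8 cells at corners, edges and interior respectively; no re-draw
toward eight, which is the simplest reading of a random direction choice
under a closed boundary.

**Preference updating.** When a fish ages, its $Z$ is redrawn
independently from the new age's niche curve. The alternative of preserving
the individual's quantile across ages would correlate an individual's
successive habitats; nothing in the model's specification requires it, and
independent redrawing keeps the age classes' preference distributions
exactly at their defining Beta laws.

**Reproduction as Bernoulli.** Offspring are at most one per mother per
year, with probability $R_i$. Since all $R_i \le 0.53$, a Bernoulli draw
reproduces the stated rates exactly; a Poisson alternative would differ
only in allowing multiple births, which the rates make rare anyway.

**Fragmented layouts per replicate.** Each replicate of a fragmented
scenario draws its own random layout from its own stream. Averaging over
layouts removes the idiosyncrasy of any single permutation, which is what a
60-replicate design is for; the layout is part of the replicate's seed and
therefore exactly reproducible.

**Random streams.** Every run is driven by a single integer seed; grid runs
derive one child seed per (scenario, replicate) from the master seed by a
deterministic 32-bit hash (`derive_seed()`), so any replicate can be rerun
in isolation and match the grid run bit for bit.

**Extinction.** At high fishing and small populations extinction is
possible in principle; remaining years are then recorded as zero abundance
and the output flagged (`extinct_year`), with the replicate's indices
treated as missing for the extinct years. Under the study's parameter
ranges extinction does not occur in the 15-year horizon.

# What the simulations show — and at what size

The package's tests and acceptance script reproduce the design's result
structure at reduced replication: both preference modes and landscapes,
$K \in \{5, 40, 160\}$ (the ends and middle of the geometric schedule), all
six fishing levels, 10 replicates — 720 runs, about half a minute on one
CPU. The full design (144 scenarios × 60 replicates) runs in well under an
hour through `run_scenario_grid()` and is exposed via the CLI, but the
reduced grid already resolves the qualitative structure: all
CV–diversity slopes negative; strong preference steeper than weak at every
matched landscape × $K$; the strong-preference response weakening sharply
as $K$ falls on the gradient landscape while the weak response changes
little (hence a clear three-way interaction there); both responses
weakening on the fragmented landscape. With only three $K$ levels and 10
replicates the *fragmented* three-way term is not reliably non-significant
— a power artefact of the reduced design — so the tests assert the robust
contrast (three-way evidence orders of magnitude stronger on the gradient)
rather than a hard significance threshold on the fragmented side.

# What the generator does and does not emulate

The simulator *is* the study system: a closed, single-species population
with habitat-independent vital rates, no movement constraints beyond local
sensing, equal niche widths across ages, and one shared carrying capacity.
Passing its tests therefore demonstrates internal consistency of the
mechanism — age truncation concentrating a preference-structured population
— not a forecast for any real stock. Real populations add habitat-dependent
recruitment, size-dependent movement ability, schooling and site fidelity,
age-dependent (usually widening) niche widths, spatially varying carrying
capacity, and open boundaries; each of these is a deliberate omission here,
and several (wider old-age niches especially) would be expected to weaken
the simulated effect.

# Session info

```{r}
sessionInfo()
```
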