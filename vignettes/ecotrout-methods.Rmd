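---
title: "The ecotrout model: structure, assumptions and numerical choices"
author: "ecotrout authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The ecotrout model: structure, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# What the model is

`ecotrout` is a daily-timestep, spatially explicit eco-genetic individual-based
model (IBM) of a resident stream brown-trout (*Salmo trutta*) population, with
a recreational-angling module and a harvest-regulation scenario experiment on
top. The population, its age and size structure, and its genetic composition
emerge from the growth, survival and reproduction of individual fish
interacting through a size-based dominance hierarchy in a shared, flow-driven
habitat. The angling module converts an exploitation-rate target into a fixed
seasonal fishing pressure, generates Poisson capture events per fish with
length-dependent catchability, and applies minimum-length (MLL) and
harvest-slot (HS) regulations with voluntary catch-and-release, noncompliance
and hooking mortality. The statistics layer implements the analysis battery
such experiments are evaluated with: baseline endpoint comparisons
(Welch t-tests), Mann-Kendall trend tests, balanced factorial ANOVA with a
variance decomposition, and the spawning potential ratio (SPR).

# The daily schedule

Each simulated day, in fixed order:

1. **Environment.** Reach temperature and flow are read from the (synthetic)
   daily series; each cell's depth, velocity and food production are updated
   from flow through per-cell hydraulic-geometry power laws.
2. **Habitat selection.** Trout are ranked by dominance (length, then weight,
   then id) and, in that order, each claims the cell maximizing its short-term
   fitness measure. Food already claimed by more dominant occupants is gone,
   which makes crowded cells unattractive and creates emergent density
   dependence in growth.
3. **Growth.** Net energy = realized intake x food energy density -
   respiration (weight-, temperature- and velocity-dependent). Weight may
   drop; length only grows, and only while the fish is at or above the
   healthy weight for its length.
4. **Natural mortality.** Six daily survival probabilities — high temperature,
   high velocity (relative to the fish's maximum sustainable swim speed),
   stranding (depth relative to body length), starvation (condition factor),
   terrestrial predation (length, buffered by depth and cover) and piscivory
   (length, scaled by piscivore density) — evaluated as sequential Bernoulli
   draws in that fixed order; the first failure is the recorded cause.
5. **Angling** (inside the April-October season, after the burn-in). Captures
   per fish are Poisson with mean `pressure x q(length)`; events are processed
   sequentially and stop at death. Legal-size captures are kept with
   probability 0.4 (60% voluntary release); non-legal captures are illegally
   kept with probability 0.05; every release kills with probability 0.2
   (hooking mortality).
6. **Spawning** (November-December). Ready females (length at or above the
   expressed threshold, condition at least 0.95, suitable temperature and
   flow, not yet spawned) create a redd fertilized by the largest mature male
   plus a Poisson(1.5) draw of smaller mature males.
7. **Redds.** Daily egg mortality (temperature extremes, dewatering,
   scouring, background) and degree-day development; after 430 degree-days
   the survivors hatch (10% per day, rounded up), each inheriting genotypes
   from the mother and one uniformly drawn contributing male.
8. **Recorders.** Population outputs on September 1; spawner/egg outputs at
   the end of the spawning season; fishery counters at the end of the angling
   season.

# Quantitative genetics

Three trait groups are heritable under the infinitesimal model: genotypic size
at emergence, sex-specific genotypic maturity-length thresholds (every fish
carries both; only the own-sex one is expressed), and a neutral trait used to
separate drift from selection. Offspring genotypic values are
`Normal(midparent, VA/2 + Vmut)` per trait, independent across traits, with
`VA` fixed over the run; phenotypes add `Normal(0, VE)`. Defaults give
heritability `h^2 = VA/(VA+VE) = 0.2` for every trait (female threshold mean
17 cm, `VA = 0.8 cm^2`; male 15 cm; emergence 2.8 cm, `VA = 0.02 cm^2`;
neutral 0, `VA = 1`), a canonical salmonid life-history heritability;
`Vmut = 0.001 VA` keeps long runs from degenerating. Negative draws are floored
at 10% of the initial trait mean, a numerical guard that keeps lengths
positive. In the no-evolution control, offspring genotypes are instead drawn
from the initial trait distributions `Normal(initial mean, VA)`, severing the
parent-offspring link while leaving every other process untouched.

# The fitness measure

A fish evaluates a cell as
`(product of the six daily survivals)^H x min(1, projectedLength(H)/threshold)`
with horizon `H = 90` days; the projection extrapolates the day's growth in
that cell through the length-weight inverse. The survival factor dominates for
mature fish ("stay alive"); the size factor pushes immature fish toward growth
("reach the maturity threshold"). In the implementation the argmax over cells
drops factors constant across cells (temperature, starvation and piscivory
survival), which cannot change the selected cell; the exported
`fitness_measure()` reports the full quantity.

# Synthetic study system

Observed gauge records and field habitat surveys are replaced by generators, so the whole
artifact runs from seeds alone:

* **Climate.** Water temperature = annual sinusoid (mean 9.5 C, amplitude
  7.5 C, peak end of July) + AR(1) noise (rho 0.9, SD 0.8 C), truncated at
  0 C. Log flow = seasonal cosine (median 1 m^3/s, amplitude 0.45, winter
  peak) + AR(1) noise (rho 0.85, SD 0.30): lognormal flows with winter-spring
  spates. These reproduce the seasonality and autocorrelation the IBM's
  mechanisms need (spawning windows, degree-day development, spate scouring,
  summer growth), not any particular gauge record.
* **Reach.** 1 km x 6 m mean width of cells whose depth/velocity power-law
  coefficients, cover and areas are drawn from configured ranges. The default
  reach uses 20 cells: enough spatial heterogeneity for refuge-seeking and
  food competition to matter, while keeping a 40-year run in the tens of
  seconds. Cell food per day = drift (proportional to velocity x area) plus a
  stationary search-food floor.
* **One site, many replicates.** The reach and the climate series are drawn
  from their own dedicated seeds, fixed across all scenarios and replicates
  of an experiment — replicates differ only in demographic, genetic and
  fishing randomness, the way field replicates of a single stream would.
  Without this, habitat differences between "replicates" dominate the
  between-arm variance and the endpoint statistics lose their meaning. The
  default site seed was chosen by screening candidate reaches on their
  *unfished* demography against the calibration benchmarks above (graded age
  structure, spawner density near 150-250 per hectare, baseline piscivore
  density near the predation reference); the screening never looked at
  fished outcomes.
* **Initial population.** Age-structured densities (age-0 2000/ha down to
  15/ha at age 5), normal lengths per age, founder genotypes from the initial
  trait distributions. The first 10 simulated years are a fishing-free
  burn-in, because a synthetic initial population needs to equilibrate before
  regulations start.

# Parameterization and calibration

Bioenergetic and survival parameters are not site measurements; they were set
once, by pattern-oriented calibration of the *unfished* model against
standard brown-trout stream benchmarks: September age-0 around 6-8 cm, age-1
13-15 cm, age-2 16-19 cm, age-3+ around 20 cm and 150-400 g asymptote;
age-0 densities of a few hundred to a couple thousand per hectare with
strong, stabilizing density dependence; winter feeding near maintenance;
annual adult natural mortality around 40-60%. Two calibration choices carry
the model's density-dependent compensation and deserve emphasis:

* Maximum consumption `cmax = 0.053 W^0.65 f(T)` (dome-shaped `f`, optimum
  14 C) crosses respiration `40 W^0.8 e^(0.064 T) (1 + v)` J/day near 350 g,
  so adult growth saturates at a realistic size instead of running away when
  competition is released.
* Piscivory is the dominant mortality of small fish (daily survival 0.97 at
  3 cm under the reference piscivore density of 150 fish/ha at or above
  18 cm, approaching 1 by 12 cm, scaled linearly below the reference
  density). Because the piscivores are exactly the harvestable size classes,
  angling releases fry from predation — the mechanism behind the
  compensatory age-0 response to exploitation.

The two-point-anchor convention makes every survival curve testable: each
logistic passes exactly through two configured (driver, survival) points.

# Fishing-pressure conversion

Seasonal pressure is the closed form
`anglePressure = ExpR x harvestableStock x anglingEfficiency / (reachLength x seasonLength)`
(angler-h km^-1 day^-1), computed once on the first day of each season from
the harvestable stock — fish of legal size plus fish projected (at that day's
growth in their cell) to reach the minimum-length limit by season's end — and
held fixed. Catchability `q(L)` is a saturating logistic through 10% of its
plateau at 10 cm and 90% at 25 cm; the plateau (0.0025 captures per fish per
angler-h km) was set so that realized exploitation approximately matches the
target at intermediate rates with the default efficiency of 5 angler-h per
kept trout. The Poisson capture process makes realized exploitation saturate
below the target at the highest rates (kept fish cannot be caught again, and
hooking deaths remove fish before they can be kept), so realized rates
deviate from targets by some tens of percent at the extremes while remaining
strictly increasing — the forward projection of the stock is the other
recognized source of that deviation.

Whether the harvestable stock should exclude fish above the maximum-length
limit under a slot regulation is genuinely ambiguous; the pressure formula is
written in terms of the minimum limit only, and that is what
`estimate_harvestable_stock()` implements. Hooking mortality applies equally
to sub-minimum and slot-protected fish.

# Scenario experiment and analyses

The full factorial grid is 5 exploitation rates (5-65%) x 5 minimum limits
(17-21 cm) x 6 maximum limits (25-100 cm; 100 = plain MLL) = 150 scenarios
plus a no-fishing baseline. The desk-scale default is 40 years, a 1-km reach,
the reduced grid {5, 35, 65}% x {17, 19, 21} cm x {25, 100} cm and 4
replicates; the full 100-year experiment is a configuration choice, not the
default. Replicate seeds are derived deterministically and never shared
between scenarios. An ExpR = 0 scenario follows a code path that consumes no
fishing randomness, so it reproduces the baseline bit for bit under a shared
seed — a structural regression test.

Endpoint analyses use per-replicate means over the final 15 years for
100-year runs, scaled to the final 15% (at least 3 years) for shorter runs.
The variance decomposition reports each ANOVA term's share of the total sum
of squares; on the balanced grid this is exact and orthogonal and coincides
with averaging-over-orderings relative-importance measures, which only differ
under collinearity. Welch's unequal-variance t-test is used for the pairwise
baseline comparisons; no multiple-testing correction is applied (per-output
alpha = 0.05). The Mann-Kendall implementation uses the tie-corrected
variance and the +-1 continuity correction; replicate window means are the
analysis units throughout.

# What passing desk-scale tests does and does not show

The synthetic generators emulate seasonal forcing, heritable variation and an
age-structured population, but not: observed gauge series (no multi-year
droughts or climate trends), real habitat maps, size-dependent maternal
effects on egg size beyond the genotype link, superimposition of redds,
angler-behavior dynamics, or density-dependent catchability. Directional
results at 40 years and 0.6 ha — threshold evolution toward earlier
maturation under exploitation, its amplification by smaller minimum limits,
population truncation, compensatory age-0 responses, reduced total fecundity,
and the superiority of the evolving stock over the no-evolution control in
spawner density and SPR — are therefore statements about the model's
mechanisms, not quantitative predictions for any real fishery; effect
magnitudes at desk scale are smaller than century-scale ones because the
threshold trait is still evolving when the run ends.

One desk-scale finding deserves explicit caution. In this parameterization the
no-evolution control does *not* collapse under heavy exploitation: plastic
maturation (the environmental spread of the threshold phenotype around a mean
near the minimum-length limit) together with competitive and predation release
keeps recruitment high with or without genetic transmission. Evolution still
pays — the evolving stock holds more spawners, more spawner biomass and higher
total fecundity than the control — but because its recruitment is also higher,
its spawning biomass *per recruit* is not, and the population it produces is
more juvenescent (a lower adult:juvenile ratio). Systems in which plasticity
alone cannot avert recruitment overfishing would need weaker compensatory
recruitment or later-maturing phenotypes than this synthetic site has.

# Degenerate inputs and numerical conventions

Zero variance components are legal everywhere and make the corresponding draw
exact (used heavily in tests). Zero noise SDs give deterministic climate.
Flow must be strictly positive; temperature is truncated at 0 C. An empty
population or an extinct run is not an error: recorders emit zeros (ratios
NA). Ties in dominance are broken by weight then id; ties in habitat
selection by the lowest cell id; all season windows are closed date
intervals. The simulation calendar uses 365-day years; ages increment on
January 1. Poisson draws with mean 0 are skipped, keeping RNG streams aligned
between fished and unfished runs. All randomness flows through R's RNG, so a
run is a pure function of (configuration, seed).
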