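---
title: "Modelling clostridial strain degeneration: simulation, filtering and fitness statistics"
author: "degeneR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling clostridial strain degeneration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(degeneR)
```

# The problem

Repeated subculture of solventogenic clostridia selects for mutants of the
sporulation/solventogenesis master regulator Spo0A. Because committing to
sporulation removes cells from the growing population, a Spo0A-null mutant
enjoys a large growth advantage under frequent transfers, sweeps the
culture, and the population loses solvent production — strain
degeneration. `degeneR` provides (i) a population simulator that generates
degenerating cultures under configurable transfer regimes, (ii) a
synthetic pooled-sequencing layer, (iii) the variant-filtering cascade
used to read low-frequency allele trajectories out of ultra-deep
population sequencing, and (iv) mutation-spectrum, hotspot-enrichment and
relative-fitness statistics.

# The population model

## Growth, sporulation, transfer

One transfer cycle is modelled discretely:

1. **(Heat shock, optional.)** The transfer aliquot is heated; vegetative
   cells die and spores germinate with probability
   `germinationEfficiency` (default 0.8).
2. **Dilution.** Every class's vegetative and spore counts are thinned
   binomially at `dilutionFactor` (default 1/10). Binomial thinning is
   frequency-unbiased, so the bottleneck adds drift but no systematic
   change in composition.
3. **Germination.** Spores carried into fresh medium germinate at
   `germinationEfficiency` and rejoin the vegetative pool. This
   fresh-medium germination step is a modelling choice the experimental
   description leaves open; without it a sporulating wild type would lose
   90% of its propagules every cycle in *all* regimes and could never be
   stabilized by longer transfer intervals. With it, the three regimes
   separate exactly as observed: 24 h transfers favour non-sporulating
   mutants, while heat-shock and 72 h regimes retain the wild type.
4. **Growth.** The inoculum (*N*~0~ cells) regrows to carrying capacity
   *K* (default 10^8^ CFU/ml) over *g* = log~2~(*K*/*N*~0~) ≈ 3.3
   Wright–Fisher generations — five transfers therefore give ≈ 16.6
   generations, matching the experimental accounting. Each generation is
   a multinomial resampling with per-class weight
   *x~i~* · *w~i~*(*x*), where the realized fitness
   *w~i~*(*x*) = `baselineFitness` · (1 − `freqDependence` · *x~i~*)
   declines linearly with the class's own frequency. The linear form is
   the simplest shape consistent with the observed monotone decline of
   competition-assay fitness with initial mutant frequency; the
   experiments report the phenomenon but no functional form.
5. **Sporulation.** Each class converts `sporulationFraction` of its
   vegetative cells to spores (binomially), once per cycle at the end of
   growth. The wild-type default of 0.9 reproduces the observed one-log
   drop of vegetative counts (10^8^ → 10^7^ CFU/ml) at sporulation onset.
6. **Post-24 h decay.** For transfer intervals beyond 24 h, vegetative
   cells survive each extra hour with probability `post24hViability`.
   Spo0A-null classes default to 0.953/h, i.e. ~90% viability loss
   between 24 h and 72 h — the decline is reported qualitatively, the
   rate is this package's choice.

Solvent and acid outputs are frequency-weighted sums of pure-culture class
yields at the end of growth; no mechanistic metabolic or pH model is
attempted (a documented non-goal), and no within-cycle continuous-time
dynamics are modelled.

## Default genotype classes and mutation templates

The wild type (`RD` morphotype) has fitness 1, sporulation 0.9, solvent
yield 7.2 g/L and acid yield 1.95 g/L (the observed subculture-1 values).
Mutations spawn new classes from region templates
(`defaultRegionTemplates()`):

* **spo0A region** → Spo0A-null: `baselineFitness` 1.9,
  `freqDependence` 0.6, no sporulation, no solvents, `FW` morphotype.
  Over one 3.3-generation cycle, 1.9 per generation compounds to ≈ 8.5 —
  the upper range of measured 24 h relative fitness at low mutant
  frequency — and the linear decline puts the fitness crossover
  (*w* = 1) at own-frequency (1 − 1/1.9)/0.6 ≈ 0.79, matching the observed
  "around 80%" crossover.
* **sensor-kinase and hybrid-kinase hotspots** → reduced sporulation with
  mild fitness effects (`RD`/`DCOG` morphotypes).
* **abrB/intergenic hotspot** → partial solvent loss (`CIC` morphotype),
  able to hold *w* > 1 to higher own-frequency, as observed for
  partial-activity Spo0A mutants.
* **non-hotspot regions** → neutral carrier lineages: they hitchhike with
  their background, which is how carrier mutations reach visible
  frequencies in real trajectories.

Mutation events arrive as Poisson(`mutationRate` × births per cycle) and
pick a region by `defaultTargetWeights()` (≈ 65% of hits in the four
hotspots) and a type from `defaultSpectrum()` (87% of SNPs in the
G:C→T:A transversion class, plus the observed indel proportions).
`mutationRate` (default 10^−6^ per cell per generation) is the rate of
*tracked, phenotype-relevant lineage-founding events*, not a genomic
per-base rate: it is calibrated so that degeneration under the 24 h
regime is essentially universal by subculture 15, as observed across all
replicate series in the motivating experiments. At this rate a typical
15-subculture series spawns on the order of 10^3^ lineages, of which a
handful establish.

**Limitation.** Because the simulator tracks lineage-founding events, the
per-isolate mutation count of a sampled colony equals the length of its
lineage's template chain; the experimentally observed ~3.16 mutations per
isolate includes passenger SNPs accumulated at the genomic per-base rate,
which the class-level model does not enumerate.

## Randomness and determinism

`simulateSeries()` seeds R's RNG once and draws in a fixed documented
order (heat shock, dilution, germination, one multinomial per generation,
sporulation, decay, Poisson mutation count, per-event draws), so a seed
fully determines the output. Monte-Carlo tests compare means against
analytic or enumerated oracles within three Monte-Carlo standard errors.

# The sequencing model

Each (variant, subculture) pair yields one pileup site: total depth is
negative binomial with mean 368 (the study-scale median) and size 27
(coefficient of variation ≈ 0.2, mimicking real coverage
overdispersion); reads split between *first-forward* and *first-reverse*
orientation strata binomially at 0.5; alternate reads are binomial with
success probability *q* = AF(1 − ε) + (1 − AF)ε/3, ε = 0.001 by default.
The two orientations are abstract read strata — the filter only needs two
independent sources of support, so read-pair semantics, alignment and
mapping quality are out of scope, as are indel sequencing errors (the
hotspot signal is SNP-dominated). Background sites with AF = 0 can be
added to exercise false-positive behaviour.

# The filtering cascade

Site-level rules (each failure appends a label; calls are never dropped):

* **Criterion A** (`low_qual`): Phred score
  −10·log~10~ P(X ≥ alt | depth, ε/3) ≥ 100, i.e. the alternate count
  must be inexplicable by sequencing error alone. Capped at 1000.
* **Criterion B** (`no_consensus`): combined AF ≥ 0.005 and a Fisher
  exact strand-exactness screen (p ≥ 0.001). A and B together re-specify
  the original workflow's two-caller consensus as two internal,
  documented criteria on the same pileup — the package implements the
  consensus *logic* rather than invoking external callers.
* **Orientation** (`low_orientation_af`, `low_reads`): AF strictly
  above 0.04 in both strata; at least 4 reads per stratum (the
  conservative reading of a minimum-read threshold — a total-count
  alternative is selectable); mean base quality ≥ 20.

Trajectory-level rules, applied per (replicate, variant) to variants that
pass the site rules in at least one subculture:

* **Recurrence** (`insufficient_recurrence`): AF strictly above 0.08 in
  at least 3 subcultures. Missing AFs (below detection) count as 0. The
  subcultures need not be consecutive (a consecutive-run flag is
  provided; the non-consecutive reading is the default since transient
  dips below threshold are common in real trajectories).
* **Exclusion regions** (`rrna`): BED intervals (0-based half-open,
  converted to the internal 1-based inclusive convention at the
  boundary).
* **Starter background** (`starter_background`): subculture-0 AF ≤ 0.5,
  applied per replicate.
* **Depth artifact** (`depth_artifact`): |Spearman ρ(AF, depth)| < 0.8
  across ≥ 6 subcultures. This generalizes a manual single-position
  removal into a reusable screen. Note the rule's resolution limit: with
  exactly six subcultures, a genuinely rising trajectory coincides with a
  random depth ranking at |ρ| ≥ 0.8 a few percent of the time; the screen
  can be disabled (`depthScreen = FALSE`) or its threshold raised when
  series are short.

Thresholds follow the source wording exactly: strict inequality for
"above 0.04" and "AF > 0.08", non-strict for the score ≥ 100. Because
every rule only appends labels, the cascade's keep-set equals the
conjunction of independently evaluated rules — a property the test suite
checks against a brute-force oracle on random panels.

# Mutation statistics

Substitution classes are strand-collapsed (G→T ≡ C→A, reported as
G:C>T:A), with fractions over SNPs only. Hotspot enrichment uses an exact
binomial upper tail against the length-proportional uniform null with
Benjamini–Hochberg correction at FDR 0.05 — the package's own definition,
chosen as the simplest defensible length-aware null since the original
report states hotspots without naming a statistic (a Poisson variant is
available behind `method = "poisson"`). Intergenic mutations are assigned
to named regions keyed by flanking gene ids, mirroring how the
abrB-adjacent intergenic hotspot is described. Multi-hit positions count
once per record; no per-site deduplication. Because the binomial count
statistic is discrete, its null p-values are super-uniform rather than
exactly uniform; the FDR calibration simulation in the test suite
verifies the property that matters (family-wise false-positive rate at
q ≤ 0.05 stays at or below the nominal level).

# Fitness statistics

`relativeFitness()` implements the odds-ratio statistic
*w* = [*x*~2~(1 − *x*~1~)]/[*x*~1~(1 − *x*~2~)]. Boundary proportions
(a competitor below plating detection) return flagged `NA`s, never silent
infinities, since only interior points are interpretable.
`frequencyDependence()` declares negative frequency dependence iff the
Spearman correlation of *w* against *x*~1~ is negative at α = 0.05, and
estimates the crossover frequency by antitonic (monotone non-increasing)
regression of per-*x*~1~ median *w*, linearly interpolated at *w* = 1 —
an interpolation rather than a parametric fit, because only "around 80%"
is reported. Competition assays at different timepoints are analysed
stratified (pooling is the caller's choice). `simulateCompetition()`
reproduces the assay in silico without sporulation, since plate counts
enumerate colony-forming units of each morphotype.

# Problem sizes and numerical choices

The shipped tests and the acceptance script use: 10^8^ CFU/ml carrying
capacity; 10 000 Monte-Carlo sites for detection-limit estimates; 1 000
random pileup sites for oracle-equivalence; 400–1 000 simulated
catalogues of 225 mutations over a synthetic 6 Mb genome of 5 000 equal
genes for FDR calibration; 100–200 seeded competition experiments of
n = 30 observations; and 30–60 seeded series per transfer regime. These
sizes keep Monte-Carlo standard errors well inside the asserted margins.
The hotspot-recovery fixture places its 90 background mutations at most
one per gene so that "exactly the four constructed hotspots" is a
deterministic outcome of the construction rather than a seed-dependent
one. Phred scores are computed from `pbinom(..., log.p = TRUE)` to avoid
underflow and capped at 1000; ε = 0 therefore yields the cap for any
alternate support. Multinomial weights are floored at 10^−12^ so a class
at the frequency where its realized fitness would cross zero is removed
by sampling, not by a negative weight.

# What passing tests do and do not show

The synthetic generator reproduces the *structure* of the experimental
data — bottlenecked selection dynamics with realistic drift, overdispersed
coverage with orientation strata and miscalls, hotspot-concentrated
catalogues with the observed substitution bias — but not its full
complexity: no strand-specific error profiles, no alignment or mapping
artifacts, no indel errors, no metabolic feedback between acids and
growth, and lineage-level rather than per-base mutation accumulation.
Green tests therefore certify the statistical machinery and its
calibration under the modelled conditions, not performance on arbitrary
real sequencing runs.
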