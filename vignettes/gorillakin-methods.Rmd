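---
title: "Methods: relatedness, parentage and dispersal inference in gorillakin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: relatedness, parentage and dispersal inference in gorillakin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gorillakin` analyses codominant microsatellite genotypes from small,
socially structured primate populations: one-male breeding groups with a
single silverback, several adult females and their offspring, plus solitary
males, sampled across sites tens of kilometres apart. This vignette is the
package's own account of each method, its assumptions, the tunable
parameters, and the numerical choices made where the design was open.

## Data model

A `GenotypeTable` holds two integer allele-size matrices (individuals ×
loci; the unordered genotype is stored sorted) plus metadata (`sex`,
`age_class`, `role`, `group`, `country`). Missingness is whole-locus only:
a genotype is either two alleles or absent, which is what "number of valid
markers" filtering counts. `filterIndividuals()` defaults to 7 valid loci,
i.e. "more than six" on a ten-locus panel. Allele sizes are carried exactly
as read; no binning is applied.

Allele frequencies (`alleleFrequencies()`) are direct counts over a stated
reference set — by default every successfully typed individual, with a
predicate argument (e.g. adults only) because the right reference is a
study-design decision, not something the software should guess. The
frequency object records the per-locus typed gene count `n`; expected
heterozygosity uses Nei's unbiased `n/(n-1) (1 - Σ p²)` by default (the raw
Gini–Simpson form is selectable, and is used automatically for population
frequencies where `n` is not applicable). The multilocus probability of
identity is `Π_l [Σ_i p_i⁴ + Σ_{i<j} (2 p_i p_j)²]`.

## Relatedness estimators

Three estimators, all method-of-moments against reference frequencies:

* **Queller–Goodnight (QG)** — per locus, with reference individual
  carrying alleles *a,b* and partner *c,d*:
  numerator `½(δ_ac+δ_ad+δ_bc+δ_bd) − p_a − p_b`, denominator
  `1 + δ_ab − p_a − p_b`. The multilocus value is the **ratio of sums**
  (the estimator's published form; it avoids locus-level 0/0), and the
  reported value is the arithmetic mean of the two reference orientations,
  making `r(x,y) = r(y,x)` exact.
* **Lynch–Ritland (LR)** — locus value
  `[p_a(δ_bc+δ_bd) + p_b(δ_ac+δ_ad) − 4 p_a p_b] /
  [(1+δ_ab)(p_a+p_b) − 4 p_a p_b]` with the published locus weights
  `w = den/(2 p_a p_b)`; multilocus value `Σ w r / Σ w`; symmetrised the
  same way.
* **Loiselle kinship** — `Σ_l Σ_a (x_a−p_a)(y_a−p_a) / Σ_l Σ_a p_a(1−p_a)`
  where `x_a` is the half-dosage of allele *a*; the small-sample correction
  `Σ_a p_a(1−p_a)/(n−1)` is added per locus when the frequency table
  carries a finite gene count. Expectation is half the relatedness
  coefficient (0.25 for parent–offspring).

Loci with a zero denominator for an orientation contribute to neither sum
for that orientation. Pairs sharing fewer than `minSharedLoci` (default 5)
typed loci are flagged undefined rather than estimated.

Pair significance uses a frequency-model null: at each locus typed in both
members, both genotypes are redrawn from the reference pool
(frequency-weighted, with replacement — chosen for exchangeability with the
frequency model under which the estimators are defined), the estimator is
recomputed `nPerm` times, and `p = #{null ≥ observed}/nPerm` (one-tailed,
"more related than random"). A two-tailed variant doubles the smaller tail.

## Parentage

Likelihoods use Mendelian transmission with a single-parameter error model:
with probability *e* (default 0.01) a recorded genotype is an independent
Hardy–Weinberg draw. Because an errored genotype is marginally still HWE,
all mixtures stay closed-form. LODs are natural-log ratios of
candidate-parent versus unrelated-individual likelihoods, with the error
mixture applied to the offspring genotype; with a known other parent the
baseline is "known parent plus random mate". At `e = 0` a
Mendelian-incompatible locus drives the LOD to −∞ (flagged); mismatch
counts always ignore error.

Confidence follows the simulated-Δ procedure: `nSim` offspring (default
10,000) are generated from the frequencies, candidate pools contain the
true parent with probability `propSampled` (default 0.5) plus unrelated
HWE individuals, error is injected into every simulated genotype, and
Δ = LOD(best) − LOD(second best) is recorded together with whether the best
candidate is the true parent. The threshold for a confidence level (relaxed
0.80, strict 0.95) is the smallest Δ\* such that the proportion of correct
top candidates among simulations with Δ ≥ Δ\* (tie-inclusive) reaches the
level; unreachable levels give +∞ with a warning. Exact top ties count as
no assignment (Δ = 0), and Δ = +∞ (the runner-up outright excluded) is kept
as infinite separation rather than collapsed. `assignParentage()` runs the
exhaustive parent-pair search first and falls back to separate maternity
and paternity analyses when no pair reaches relaxed confidence.

Dyadic relationship tests compute `P(g_x, g_y | R)` under IBD-coefficient
vectors (k₀,k₁,k₂): parent–offspring (0,1,0), full sib (¼,½,¼), half sib
(½,½,0), unrelated (1,0,0). With the error model, the exact per-locus
likelihood is `(1−e)² P_R + (1−(1−e)²) P₀`, since conditional on any error
the joint factorises into the HWE product. Likelihood ratios against the
unrelated model are flagged significant above 10.

## Kin-structure permutation tests

All tests share the convention `p = #{null ≥ observed}/nPerm` (an optional
`(+1)/(n+1)` correction never returns zero) and a mandatory seed for
reproducibility. Undefined pairs are excluded from observed and null means
alike, keeping the two comparable.

* `groupMeanRelatednessTest()` — observed within-group mean pairwise
  relatedness per group; null from group-size-preserving reshuffles of
  individuals among groups (a permutation, not a bootstrap).
* `partitionRelatednessTest()` — the same machinery on a coarser partition
  (country/region) after restricting to one sex, for sex-biased dispersal
  inference.
* `focalMaleRelatednessTest()` — observed mean relatedness of each female
  to her own breeding male; the null redraws, for each female
  independently, a male uniformly from the pool. This independent-redraw
  null is the normative choice here (a label-permutation alternative would
  couple females sharing a male); the two-tailed p is also reported since
  both kin-avoidance and kin-preference are of interest.

## Spatial structure

Distances are haversine great-circle distances on the WGS84 mean radius
(6371.0088 km), between group home-range centres; solitary males inherit
the host group whose range they use. A supplied distance matrix overrides
coordinates — the canonical path when published between-site distances
should be used verbatim instead of possibly inconsistent coordinates.

R_ST is estimated by allele-size variance components: per locus, a one-way
ANOVA of allele sizes with gene copies as observations yields
among-population (σ²_b) and within-population (σ²_w) components;
multilocus `R_ST = Σσ²_b / Σ(σ²_b+σ²_w)`. Negative among components are
truncated at zero per locus, so identical-composition populations give
exactly 0 (and fixation for different alleles gives exactly 1); the
estimator is invariant under global allele-size translation. Global
significance permutes individuals among populations.

Isolation by distance regresses `R_ST/(1−R_ST)` on the **natural** log of
distance (the base only rescales the slope; the choice is recorded in the
output). Significance permutes the location assignment of populations,
keeping the R_ST table fixed and recomputing distances — equivalent to a
Mantel test; one-tailed for a positive slope. Pairs at `R_ST = 1`
(infinite transform) are excluded with a warning.

## Behavioural proximity

Scan records in three distance categories (0–5 m, 6–10 m, ≥10 m) are pooled
over both focal directions of each dyad; a scan whose distance was not
recorded counts as ≥10 m. "Near" means <10 m, i.e. the 0–5 m and 6–10 m
categories together, so the three labels partition the outcomes. The index
is near scans per focal hour (dyad-pooled hours). The proximity–relatedness
association uses Spearman's rank correlation with average-rank ties; the
exact p-value is used for n ≤ 10 without ties, the large-sample
approximation otherwise.

## The synthetic-data generator

`simulationConfig()` encodes the study conditions the package targets:

* ten loci, seven founder alleles per locus with Dirichlet(1.5)
  frequencies. Founder expected heterozygosity is 0.78; after the residual
  drift of the forward model the final census measures He ≈ 0.75 and ~6.4
  observed alleles per locus, the diversity regime the package is meant
  for.
* four groups (two per region) with between-group distances 2–62 km
  (nearest neighbours ~2 and ~9 km, between regions ~57–62 km); one
  silverback and five adult females per group, seven immatures per group
  in the census, four solitary males.
* extragroup paternity 2/27 ≈ 0.074 per offspring, sired by a random
  outside male (another silverback or a solitary).
* universal female natal dispersal with a distance-biased kernel (70% to
  the nearest group, remainder ∝ 1/distance); breeding-male slots filled
  from the population-wide son pool with probability 0.8 (male-biased
  dispersal); stepwise ±1 mutation at 5×10⁻⁴ per transmitted allele with
  reflecting bounds.
* `backgroundImmigrationRate = 0.25`: each recruited adult slot may be
  filled from the wider unsampled population (an HWE draw at founder
  frequencies). The sampled groups are embedded in a continuous
  population; a fully closed four-group world would drift far below the
  target diversity within ten generations. Closed-population scenarios
  (pure drift, stepping-stone differentiation) set this to 0.
* genotyping artefacts (HWE-replacement error, allelic dropout, per-locus
  missingness) injected at configurable rates; 1% error matches the
  parentage model's default.

The generator reproduces the *statistical* structure the analyses need —
Mendelian pedigrees, dispersal-limited spatial structure, polygynous
paternity — but not primate demography: generations are non-overlapping,
census sizes fixed, no interbirth intervals, group formation or
disintegration, and no coalescent-scale history. Passing tests therefore
validate the estimators and tests under a faithful genetic model, not the
ecological realism of any particular field system.

## Validation problem sizes and numerical choices

The test suite and the reproduction script use these scales, chosen to pin
each property well inside Monte-Carlo error: 10,000 dyads per relationship
class for estimator recovery (±0.02 band); 1,000 replicates at 200
permutations each for the null calibration of the four permutation tests
(0.05 ± 0.02 band); 1,000 simulated offspring with 10 candidate fathers for
paternity recovery (≥95%); 1,000 full-sib and 1,000 unrelated dyads for
likelihood-ratio separation; 100 replicates of a closed stepping-stone
scenario (8 demes on a line, 15 females per deme, dispersal rate 0.35 with
95% of moves to the nearest neighbour, 5% global male pool, 25 generations)
for isolation-by-distance power, a regime chosen by a design-time pilot to
represent clearly restricted dispersal (≥80% detection required, ~95%
measured). Fewer demes make the location-permutation test
coarse — with six locations the Mantel null has only 720 arrangements and
deme-level drift noise erodes power — which is why the power scenario uses
eight.

Other numerical decisions: exact LOD ties leave offspring unassigned;
permutation p-values use the plain `#{≥}/n` convention to match the tests'
published descriptions, with the `(+1)/(n+1)` correction available;
degenerate inputs (empty reference sets, monomorphic panels, single
partitions, zero observation hours) raise errors naming the offending unit
rather than returning silent NAs.

## Known limitations

Relatedness estimators treat reference frequencies as known; with very
small reference samples the usual downward bias of within-sample estimates
applies. The parentage error model is the single-parameter HWE-replacement
class — allele-specific dropout is simulated by the generator but not
modelled in the likelihood. R_ST assumes strict stepwise mutation scaling
of allele-size variance. The pipeline is single-threaded; at the package's
intended scale (tens of individuals, ten loci) every analysis runs in
seconds to minutes.
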