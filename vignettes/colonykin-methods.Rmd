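---
title: "Methods: colony-level kinship and mating-system inference in colonykin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony-level kinship and mating-system inference in colonykin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(colonykin)
```

## Scope and model organism

`colonykin` analyses the colony-level genetics of haplodiploid social
insects (ants, bees, wasps) genotyped at codominant microsatellite-style
markers.  In haplodiploids, females (queens, workers) are diploid and
males are haploid: a worker receives one of her mother's two alleles and
her father's single allele at every locus.  Full sisters therefore share
their father's entire genome and have expected relatedness r = 0.75;
mother and daughter have r = 0.5.  These Mendelian anchors are the basis
of everything the package computes:

* reconstruction of queen and mate genotypes from worker genotypes, and
  classification of each colony's mating system (monogyny/monandry,
  polyandry, alien workers, multiple queens);
* pairwise relatedness with the Queller–Goodnight (QG) moment estimator
  and a maximum-likelihood (ML) estimator over identity-by-descent
  modes;
* Weir–Cockerham F-statistics with the customary low / medium / high /
  very-high differentiation bands for pairwise F~ST~;
* a one-sided two-sample Kolmogorov–Smirnov (KS) test asking whether
  queens are more related to their actual mates than to the pool of
  available males (non-random mating);
* a seeded simulator that generates whole studies with known truth, so
  every stage is testable without any external data.

## The synthetic world

`makePopulationModel()` fixes per-locus allele frequencies.  Defaults
describe the kind of marker panel used in regional ant studies: 12
unlinked loci; high allelic richness (the default 20 equifrequent
alleles matches the panel average of ~19.7, and the documented per-locus
counts 9–28 can be passed directly); allele labels are even integers
from 102 upward, mimicking fragment sizes, but identity is the integer
label, not a repeat length.

Multi-site divergence uses a Balding–Nichols perturbation: site
frequencies are drawn from Dirichlet((1 − F)/F · p~ancestral~) with
F = `divergence`, independently per site and locus.  This choice is the
package's own (the original field study used real genotypes, not
simulations); its virtue is an analytic handle: the expected
Weir–Cockerham θ̂ between two sites equals F, which the test suite
exploits (bias |mean θ̂ − F| < 0.02 at F = 0.1).

`simulateColony()` draws a queen (two draws from site frequencies per
locus) and one haploid father per mate; workers get a uniformly chosen
queen allele plus their father's allele, with fathers per worker drawn
by the paternity weights.  Alien workers — strayed foragers from
another nest — are simulated as offspring of an independent monandrous
queen × male from the same site, not as bare frequency draws.  Missing
data are masked independently per (individual, locus); there is no
locus-level dropout, mutation or genotyping-error model (deliberate
non-goals).  Colony defaults (8 workers, one queen, one mate, no
aliens, no missing data) are the canonical colony of a strictly
monogynous, predominantly monandrous species, and the 8-worker sample
mirrors the common genotyping design; how real studies choose the 8
workers from a larger colony is unstated in the field literature, so
sampling is uniform at random here.

A green test on this world establishes that the algorithms are correct
*under Mendelian inheritance with known frequencies and independent
loci*.  It does not establish robustness to null alleles, stutter,
allele dropout, linkage, or population substructure within a site —
real-data QC for those belongs upstream of this package.

## Genotype tables and conventions

`GenotypeTable` stores an individuals × loci matrix pair of integer
allele calls with colony/site/caste/ploidy metadata.  Conventions:

* missing code is `0` in CSV files and zeros in Genepop (that format's
  convention); internally `NA`;
* haploid males keep true ploidy in the native table and CSV dialects
  (a single label, never "a/a"), and are expanded to homozygous
  pseudo-diploids wherever a diploid-oriented method needs them
  (Genepop export, both relatedness estimators) — explicit and
  reversible;
* individuals typed at fewer than 10 of 12 loci (configurable) are
  *flagged*, not dropped; a hard filter is opt-in.  Real studies
  re-genotype to reach 10 loci, synthetic data may carry more
  missingness, so flag-only is the default;
* all missing-data handling downstream is pairwise-complete per locus.

## Queen and mate reconstruction

The central algorithm generalises the manual procedure used in colony
studies: at each locus, two alleles shared by all workers are assigned
to the queen, the unassigned alleles to fathers, iterated over loci to
a minimal pedigree.  `reconstructColony()` makes that exact:

1. **Queen candidates per locus** (`candidateQueenGenotypes()`): all
   allele pairs {a, b} over the colony's observed alleles such that
   every non-missing worker carries a or b; {a, wildcard} is admitted
   when a alone covers all workers (the queen's second allele may be
   unobserved).  Wildcards are reported distinctly and never silently
   concretised.
2. **Father minimisation**: for a fixed worker set, the minimal number
   of patrilines such that, at every locus, some queen candidate gives
   every patriline a common paternal allele after subtracting a queen
   allele from each worker.  The search is an exact depth-first
   enumeration of worker partitions with constraint propagation
   (paternal-candidate sets are bitmasks over the colony's alleles;
   partial infeasibility prunes).  Loci are independent given the
   partition, which keeps the search exact and fast for the 8–16-worker
   colonies this design targets.
3. **Objective**: queens are minimised first — a single-queen
   explanation always beats a two-queen one.  Among single-queen
   explanations, candidates are compared by (fathers, aliens): a worker
   may only be excluded as alien if, at ≥ 2 loci (configurable), it
   shares no allele with *any* covering queen pair of the remaining
   workers.  This guard is the crux: a minority patriline carries the
   queen's alleles everywhere (0 conflict loci) and so can never be
   explained away as alien — a 14:2 double-mating colony is called
   polyandrous; a strayed forager conflicts at many loci and is
   excluded — 15 sisters + 1 alien is called monandrous-with-alien.
   A naive lexicographic order with aliens before fathers fails here,
   because any monandrous colony plus an alien admits a degenerate
   0-alien "explanation" (per-locus queen = {father allele, one alien
   allele}, every sister reinterpreted as her own patriline); the
   (fathers, aliens) comparison with the conflict guard reproduces the
   published manual calls on both sides.
4. **Two queens** are a fallback when no single-queen explanation
   exists: exhaustive bipartition for ≤ 12 workers, a deterministic
   sampled search above that (the result is then marked `heuristic`).
5. **Ties**: all co-optimal queen pairs per locus are retained;
   reporting order is lexicographic by allele label; patrilines are
   ordered by size (majority first).  Missing worker calls are
   unconstraining (no imputation).

`verifyAgainstQueen()` compares an empirically genotyped queen with the
inferred solutions per locus (match / ambiguous / mismatch; a wildcard
matches anything), mirroring the validation step of genotyping a subset
of queens.  `paternityPartition()` returns per-father worker counts and
fractions (a 14:2 split is 87.5% / 12.5%).

## Relatedness

**Queller–Goodnight.**  `qgPair()` implements the symmetrized
multilocus ratio-of-sums form: per locus and direction x→y the
numerator sums, over x's two allele positions, the frequency of that
allele within y's genotype minus its population frequency; the
denominator does the same within x's own genotype.  Numerators and
denominators are summed over loci and both directions before dividing
(ratio-of-sums stabilises low-information loci, and is the standard
multilocus form).  A direction skips a locus where its denominator is
undefined (focal individual homozygous for a fixed allele); a zero
total denominator yields an explicit undefined result, never a crash.
Self-relatedness is exactly 1; with true frequencies the estimator is
centred: unrelated pairs average 0, full sisters 0.75, mother–daughter
0.5.

**Allele frequencies** are a logged, configurable choice because field
papers rarely state the reference set: `"all"` individuals,
`"one-per-colony"` (one random worker per colony — the pipeline
default, mirroring a population-level genotyping design), an explicit
id set, or the simulator's true frequencies.  Alleles that appear in
analysed genotypes but not in the reference are floored at 1/(2N + 1)
and renormalised so every analysed genotype has positive likelihood.
No focal-pair exclusion bias correction is applied by default, matching
the common spreadsheet-tool behaviour field studies rely on.

**Maximum likelihood.**  `mlPair()` maximises
∏~loci~ (k₀P₀ + k₁P₁ + k₂P₂) over the simplex of IBD-mode weights,
with the standard non-inbred genotype-pair probabilities (no inbreeding
modes — the 3-mode model, not the 9-coefficient one — appropriate for
populations at Hardy–Weinberg equilibrium, and matching the common
ML-relatedness tools).  r̂ = k₂ + k₁/2 is nonnegative by construction,
the practical reason field studies report ML alongside QG.
Optimisation is a dense simplex grid (step 0.02) followed by EM
refinement; EM is monotone in likelihood, so the refined optimum never
falls below the best grid point (and the code falls back to the grid
point in the numerically impossible case it would).  Deterministic, no
randomness.

## Population statistics

`heterozygosity()` reports Ho (fraction heterozygous among non-missing
diploid calls) and the unbiased expected heterozygosity
He = (2n/(2n − 1))(1 − Σp²).  `fStatistics()` implements the
Weir–Cockerham (1984) variance components a (among populations), b
(among individuals within populations) and c (within individuals),
summed over alleles and loci before forming θ̂ = Σa/Σ(a + b + c) and
f̂ = 1 − Σc/Σ(b + c) — ratio-of-sums, as Genepop combines loci, which
is why these estimators were chosen over Nei's.  Negative estimates are
reported as computed.  Haploids are excluded (they would distort the
within-individual component).  Pairwise F~ST~ restricts to each
population pair; classification uses the exact published bands:
low [0, 0.05), medium [0.05, 0.15), high [0.15, 0.25], very high
(> 0.25), with negative values classed as 0 (logged).  The test suite
checks the implementation against an independent mean-squares (ANOVA)
formulation of the same estimators and against the simulator's drift
parameter.

`oneSampleTTest()` is the standard t = (mean − μ)/(SD/√n) with a
two-sided p on n − 1 df, used to compare mean nestmate relatedness with
0.75.  One degenerate case is defined rather than an error: all values
exactly equal to μ gives t = 0, p = 1; zero SD off-target errors.  A
note for readers of the field literature: a published value t = 0.333
(p = 0.741, df = 28) is not reproducible from the accompanying summary
statistics (mean 0.77, SD 0.06, n = 29 give t ≈ 1.79 under this
formula, though the printed p does match t = 0.333 at 28 df); the
package provides the standard test and leaves the discrepancy to the
reader.

## The mating test

`buildPairSets()` takes the reconstructions of monogynous, monandrous
colonies (polyandrous, multi-queen and undetermined colonies are
excluded) and forms one observed (queen, own mate) relatedness value
per colony, plus the *exhaustive* cross-pair null: every ordered
(queen of colony i, male of colony j ≠ i) value — n² − n pairs, which
for 26 colonies is exactly 650.  The exhaustive cross set is the
package's reading of "random pairs of queens and males" whose count
equals 650; it is logged prominently.  Wildcard or ambiguous loci in
reconstructed genotypes are treated as missing; males enter as
homozygous pseudo-diploids.

`ksOneSided()` tests "observed stochastically greater than null" via
D = sup~t~ [F~null~(t) − F~obs~(t)], evaluated over the pooled support
and its left limits (both ECDFs only move there, which handles ties
exactly).  Two p-values are reported: the asymptotic one-sided bound
exp(−2D²n₁n₂/(n₁ + n₂)), and a permutation p (group labels resampled
over the pooled values, seeded, (1 + hits)/(B + 1)).  The permutation p
is the recommended headline at small n.  Dependence among null pairs
(each queen appears n − 1 times) is acknowledged; the permutation is at
the pair-value level, mirroring how the KS test is used in the field; a
colony-level block permutation would be stricter and is a known
limitation.  The opposite direction is available by flag.

## Pipeline and reproducibility

`runPipeline()` chains the stages (input or simulation → validation →
reconstruction → nestmate relatedness + t-test vs 0.75 → F-statistics →
mating test) with fail-fast, stage-named errors, and writes a
machine-readable JSON report plus a per-colony CSV.  All randomness
fans out from one master seed by a counter-based scheme
(seed~i~ = (7919·master + 1000003·i) mod (2³¹ − 1)), so inserting or
reordering stages does not silently reshuffle downstream draws, and
rerunning the same config gives byte-identical reports.  Configs are
JSON (this package avoids a YAML dependency).  A thin command-line
front end ships in `inst/cli/colonykin.R` (simulate / convert /
reconstruct / run).

With a single colony the mating test is skipped with an explicit
"insufficient colonies" note while the other stages complete.

## Numerical and design choices, in brief

* Allele labels: positive integers; frequencies keyed by the label
  string.
* QG denominator skip rule and undefined-result signalling as above;
  tolerance for "frequency 1" is 1 − 10⁻¹².
* ML grid step 0.02, EM to a 10⁻¹² step tolerance, likelihood floors at
  10⁻³⁰⁰ to avoid log(0).
* Reconstruction tie-breaks are deterministic (lexicographic by allele
  label; patrilines by size); the two-queen heuristic above 12 workers
  uses a fixed internal seed.
* The alien conflict guard treats a wildcard queen allele as
  non-matching (a wildcard means "never transmitted to the core
  workers", so it should not absorb an alien's alleles);
  `verifyAgainstQueen()` keeps wildcard-matches-anything semantics, as
  its question — could the observed queen be the inferred one? — is the
  permissive direction.
* Missing data: pairwise-complete everywhere; no imputation.

## Known limitations

* No genotyping-error model inside the reconstruction search; the
  conflict guard absorbs single-locus artifacts but two bad loci on one
  individual could mis-flag an alien.
* Power to detect polyandry with 8 workers is limited for very skewed
  paternity (a 12% minority patriline is missed whenever no minority
  worker is sampled, about 0.88⁸ ≈ 36% of the time); the 16-worker
  design used for irregular colonies is the remedy, not a software
  setting.
* The ML estimator ignores inbreeding; QG uses no small-sample bias
  correction for the frequency reference.
* The KS null treats cross pairs as exchangeable values; block
  structure is only addressed by permutation at the value level.
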