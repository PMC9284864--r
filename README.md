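# colonykin

Colony-level kinship, mating system and population structure for
haplodiploid social insects genotyped at codominant
(microsatellite-style) markers.

Field studies of ants and other social Hymenoptera routinely genotype a
handful of workers per colony at ~12 polymorphic loci and then ask:
how many queens does each colony have, how many males did each queen
mate with, are any sampled workers strays from other nests, how related
are nestmates, are populations differentiated, and do queens mate with
males more related to them than expected by chance?  `colonykin` turns
that workflow — usually spread across spreadsheets and several
single-purpose programs — into one tested, scriptable R package, and
bundles a haplodiploid colony simulator with known ground truth so
every stage is verifiable without any external dataset.

## The science in brief

In haplodiploids, females are diploid and males haploid, so a worker
carries one maternal allele plus her father's whole haploid genotype,
and full sisters have expected relatedness r = 3/4.

* **Pedigree reconstruction** (`reconstructColony`): at each locus the
  queen is an allele pair {a, b} covering all workers; fathers are the
  residual alleles.  The package finds the minimal explanation exactly —
  queens first, then fathers, with workers excludable as aliens only
  when they conflict with every covering queen pair at ≥ 2 loci — and
  classifies each colony (monandrous / polyandrous / multi-queen /
  undetermined), retaining all co-optimal queen solutions and wildcard
  (unobserved) alleles explicitly.
* **Relatedness**: the Queller–Goodnight estimator in its symmetrized
  multilocus ratio-of-sums form,
  r = Σ<sub>loci,dir</sub>(p<sub>within partner</sub> − p) /
  Σ<sub>loci,dir</sub>(p<sub>within self</sub> − p),
  and a maximum-likelihood estimator maximizing
  ∏<sub>loci</sub>(k₀P₀ + k₁P₁ + k₂P₂) over IBD-mode weights,
  r̂ = k₂ + k₁/2 ≥ 0.
* **F-statistics**: Weir–Cockerham (1984) variance components,
  θ̂ = Σa / Σ(a+b+c) (pairwise F<sub>ST</sub> with the standard
  low/medium/high/very-high bands) and f̂ = 1 − Σc/Σ(b+c)
  (F<sub>IS</sub>).
* **Non-random mating**: queen-to-own-mate relatedness versus the
  exhaustive cross-pair null (n² − n ordered queen × foreign-male
  pairs), compared with a one-sided two-sample Kolmogorov–Smirnov test
  D = sup<sub>t</sub>[F<sub>null</sub>(t) − F<sub>obs</sub>(t)], with
  asymptotic and permutation p-values.
* **Simulator**: seeded colonies (queen × mates, paternity skew, alien
  workers, second queens, missing data) across sites diverged by a
  Balding–Nichols Dirichlet model whose drift parameter F is the
  expected θ̂ — the analytic handle the test suite leans on.

See `vignettes/colonykin-methods.Rmd` for assumptions, parameter
defaults, numerical choices and known limitations.

## Worked example

Simulate a two-site study of 13 colonies (8 workers each) in which one
colony is secretly sired by two males at 7:1 paternity skew, then run
the whole analysis:

```r
library(colonykin)

report <- runPipeline(list(
  seed = 21,
  simulation = list(
    model = list(nLoci = 12, allelesPerLocus = 20, nSites = 2),
    sites = c(10, 3),
    overrides = list(site1c04 = list(nWorkers = 16, nFathersPerQueen = 2,
                                     paternityWeights = c(0.875, 0.125)))),
  matingTest = list(nPermutations = 1000)))
report
#> StudyReport: 13 colonies
#>   12/13 monandrous, 1 polyandrous, 0 multi-queen, 0 undetermined
#>   nestmate relatedness: mean of colony means = 0.714 (SD 0.062, SE 0.017, 13 colonies)
#>   vs 0.75: t = -2.950, df = 11, p = 0.013
#>   F_IS = -0.045, multilocus F_ST = 0.066
#>   mating test (QG): D = 0.348, asymptotic p = 0.0691, permutation p = 0.0589
#>   mating test (ML): D = 0.091, asymptotic p = 0.8338, permutation p = 0.5015
```

The planted polyandrous colony is found and its paternity split
recovered (this seed happened to sample 15 majority- and 1
minority-patriline worker):

```r
model <- makePopulationModel(nLoci = 12, allelesPerLocus = 20,
                             nSites = 2, seed = 11)
study <- simulateStudy(model, c(10, 3),
  overrides = list(site1c04 = colonyConfig(nWorkers = 16,
    nFathersPerQueen = 2, paternityWeights = c(0.875, 0.125))),
  seed = 21)
rec <- reconstructColony(study@table, colony = "site1c04")
rec
#> ColonyReconstruction site1c04 -> monogyne_polyandrous
#>   queens: 1  fathers: 2  aliens: 0
paternityPartition(rec)
#>   queen father nWorkers fraction
#> 1     1      1       15   0.9375
#> 2     1      2        1   0.0625
```

Reading the report: the 12/13 monandrous count is the mating-frequency
classification; nestmate relatedness is the mean of per-colony mean QG
relatedness among workers, tested against the full-sister expectation
0.75; F<sub>IS</sub> near 0 indicates Hardy–Weinberg equilibrium within
sites; the mating test compares queen–own-mate relatedness with the
12² − 12 cross pairs of the 12 monandrous colonies (here, with random
mating simulated, the QG p hovers near 0.06 and ML finds nothing, as it
should under the null).

Genotype tables round-trip through CSV (wide/long) and Genepop:

```r
writeGenotypeTable(study@table, "study.csv", "csv-wide")
exportGenepop(study@table, "study.gen")   # haploids become homozygotes
```

A thin CLI over the same functions ships in `inst/cli/colonykin.R`
(`simulate`, `convert`, `reconstruct`, `run`).

## Acceptance script

`scripts/acceptance.R` recomputes the package's headline calibration
from scratch — it simulates 200 monogynous, monandrous colonies (8
workers, 12 loci × 20 equifrequent alleles), computes QG relatedness
for all within-colony worker pairs under the true allele frequencies,
and reports the grand mean, which theory fixes at the haplodiploid
full-sister value:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The JSON maps each target id to its recomputed value and problem size.
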