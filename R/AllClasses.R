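#' @import methods
#' @importFrom stats pt rgamma runif sd setNames
#' @importFrom utils read.csv combn packageVersion
NULL

## Central containers. Allele calls live in two integer matrices
## (individuals x loci): a1/a2 for diploids (stored with a1 <= a2),
## a1 only for haploids (a2 is NA by invariant), both NA when missing.

#' GenotypeTable: multilocus codominant genotypes with colony metadata
#'
#' The lingua franca of the package: an individuals-by-loci table of
#' integer allele calls plus per-individual metadata (colony, site, caste,
#' ploidy).  Haploid individuals (males) carry a single allele per locus;
#' diploids carry an unordered pair; missing calls are `NA`.
#'
#' @slot a1 integer matrix (individuals x loci), first allele (the smaller
#'   of the pair for diploids), `NA` when the call is missing.
#' @slot a2 integer matrix, second allele; `NA` for haploids and missing
#'   calls.
#' @slot info data.frame with one row per individual (rownames = ids) and
#'   columns `colony`, `site`, `caste` (worker/queen/male), `ploidy`
#'   (1 or 2), and after validation `typedLoci` and `flagged`.
#' @exportClass GenotypeTable
setClass("GenotypeTable",
  slots = c(a1 = "matrix", a2 = "matrix", info = "data.frame"))

setValidity("GenotypeTable", function(object) {
  msg <- character()
  if (!identical(dim(object@a1), dim(object@a2)))
    msg <- c(msg, "a1 and a2 must have identical dimensions")
  if (nrow(object@a1) != nrow(object@info))
    msg <- c(msg, "info must have one row per individual")
  if (!all(c("colony", "site", "caste", "ploidy") %in% names(object@info)))
    msg <- c(msg, "info needs columns colony, site, caste, ploidy")
  else {
    if (!all(object@info$ploidy %in% c(1L, 2L)))
      msg <- c(msg, "ploidy must be 1 or 2")
    if (!all(object@info$caste %in% c("worker", "queen", "male")))
      msg <- c(msg, "caste must be worker, queen or male")
    hap <- object@info$ploidy == 1L
    if (any(hap) && any(!is.na(object@a2[hap, , drop = FALSE])))
      msg <- c(msg, "haploid individuals must not carry a second allele")
    di <- object@info$ploidy == 2L
    if (any(di)) {
      bad <- is.na(object@a1[di, , drop = FALSE]) !=
        is.na(object@a2[di, , drop = FALSE])
      if (any(bad))
        msg <- c(msg, "diploid calls must have both alleles or neither")
    }
  }
  if ((nrow(object@a1) > 0 && is.null(rownames(object@a1))) ||
      (ncol(object@a1) > 0 && is.null(colnames(object@a1))))
    msg <- c(msg, "a1 needs individual rownames and locus colnames")
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeTable
#'
#' @param a1,a2 integer matrices of allele calls (see class doc).
#' @param info data.frame of per-individual metadata; rownames are the
#'   individual identifiers and must match `rownames(a1)`.
#' @return a validated [GenotypeTable-class] object with diploid calls
#'   stored in sorted order.
#' @export
GenotypeTable <- function(a1, a2, info) {
  storage.mode(a1) <- "integer"
  storage.mode(a2) <- "integer"
  rownames(info) <- rownames(a1)
  ## canonical order: a1 <= a2 for diploid calls
  both <- !is.na(a1) & !is.na(a2)
  lo <- pmin(a1, a2)
  hi <- pmax(a1, a2)
  a1[both] <- lo[both]
  a2[both] <- hi[both]
  new("GenotypeTable", a1 = a1, a2 = a2, info = info)
}

setMethod("show", "GenotypeTable", function(object) {
  cat("GenotypeTable:", nrow(object@a1), "individuals x",
      ncol(object@a1), "loci\n")
  cat("  colonies:", length(unique(object@info$colony)),
      " sites:", length(unique(object@info$site)), "\n")
  cat("  castes:", paste(sprintf("%s=%d", names(table(object@info$caste)),
                                 table(object@info$caste)), collapse = ", "),
      "\n")
  miss <- mean(is.na(object@a1))
  cat(sprintf("  missing calls: %.1f%%\n", 100 * miss))
})

#' AlleleFreqs: per-locus allele frequency tables
#'
#' @slot freqs named list (per locus) of named numeric vectors mapping
#'   allele label to frequency; each vector sums to 1.
#' @slot provenance character description of the reference individual set
#'   (e.g. "all individuals", "one random worker per colony",
#'   "true (simulation)").
#' @exportClass AlleleFreqs
setClass("AlleleFreqs", slots = c(freqs = "list", provenance = "character"))

setValidity("AlleleFreqs", function(object) {
  s <- vapply(object@freqs, sum, numeric(1))
  if (any(abs(s - 1) > 1e-9))
    return("per-locus frequencies must sum to 1 (tol 1e-9)")
  if (any(vapply(object@freqs, function(p) any(p <= 0), logical(1))))
    return("all frequencies must be strictly positive (floor rule)")
  TRUE
})

setMethod("show", "AlleleFreqs", function(object) {
  k <- vapply(object@freqs, length, integer(1))
  cat("AlleleFreqs:", length(object@freqs), "loci,",
      "alleles per locus", paste(range(k), collapse = "-"), "\n")
  cat("  reference:", object@provenance, "\n")
})

#' PopulationModel: allele-frequency world for the colony simulator
#'
#' Ancestral per-locus allele frequencies plus per-site frequencies
#' obtained by a Balding-Nichols Dirichlet perturbation with drift
#' parameter F = `divergence` (divergence 0 means all sites share the
#' ancestral frequencies exactly).
#'
#' @slot loci character vector of locus names.
#' @slot allelesPerLocus integer vector, alleles per locus.
#' @slot scheme "uniform" or "dirichlet" ancestral frequency scheme.
#' @slot nSites number of sites.
#' @slot divergence Balding-Nichols F in [0, 1).
#' @slot ancestral list per locus of named ancestral frequencies.
#' @slot siteFreqs list per site of per-locus named frequencies.
#' @slot seed integer seed used to build the model (NA if none given).
#' @exportClass PopulationModel
setClass("PopulationModel",
  slots = c(loci = "character", allelesPerLocus = "integer",
            scheme = "character", nSites = "integer", divergence = "numeric",
            ancestral = "list", siteFreqs = "list", seed = "integer"))

setValidity("PopulationModel", function(object) {
  if (any(object@allelesPerLocus < 1L))
    return("alleles_per_locus must be >= 1")
  if (object@divergence < 0 || object@divergence >= 1)
    return("divergence must be in [0, 1)")
  for (s in object@siteFreqs) {
    sums <- vapply(s, sum, numeric(1))
    if (any(abs(sums - 1) > 1e-12))
      return("site frequencies must sum to 1 (tol 1e-12)")
  }
  TRUE
})

setMethod("show", "PopulationModel", function(object) {
  cat("PopulationModel:", length(object@loci), "loci,",
      object@nSites, "site(s), scheme =", object@scheme,
      ", divergence F =", object@divergence, "\n")
  cat("  alleles per locus:", paste(object@allelesPerLocus, collapse = ", "),
      "\n")
})

#' ColonyConfig: composition of one simulated colony
#'
#' @slot nWorkers number of workers sampled (including aliens).
#' @slot nQueens 1 or 2 resident queens.
#' @slot nFathersPerQueen mates per queen.
#' @slot paternityWeights list (per queen) of nonnegative weights summing
#'   to 1, length `nFathersPerQueen`.
#' @slot nAliens workers that are offspring of a foreign queen x male.
#' @slot missingRate probability a call is masked, per individual x locus.
#' @slot includeQueenGenotype emit the queen's own genotype row(s).
#' @exportClass ColonyConfig
setClass("ColonyConfig",
  slots = c(nWorkers = "integer", nQueens = "integer",
            nFathersPerQueen = "integer", paternityWeights = "list",
            nAliens = "integer", missingRate = "numeric",
            includeQueenGenotype = "logical"))

setValidity("ColonyConfig", function(object) {
  if (object@nWorkers < 1L) return("n_workers must be positive")
  if (!object@nQueens %in% c(1L, 2L)) return("n_queens must be 1 or 2")
  if (object@nFathersPerQueen < 1L)
    return("n_fathers_per_queen must be positive")
  if (length(object@paternityWeights) != object@nQueens)
    return("one paternity weight vector per queen")
  for (w in object@paternityWeights) {
    if (length(w) != object@nFathersPerQueen)
      return("paternity_weights length must equal n_fathers_per_queen")
    if (any(w < 0) || abs(sum(w) - 1) > 1e-9)
      return("paternity_weights must be nonnegative and sum to 1")
  }
  if (object@nAliens < 0L || object@nAliens >= object@nWorkers)
    return("n_aliens must satisfy 0 <= n_aliens < n_workers")
  if (object@missingRate < 0 || object@missingRate > 1)
    return("missing_rate must be in [0, 1]")
  TRUE
})

#' Construct a ColonyConfig
#'
#' Defaults describe the species' canonical colony: one queen mated to a
#' single male, eight genotyped workers, no aliens, no missing data.
#'
#' @param nWorkers workers sampled per colony (default 8).
#' @param nQueens 1 or 2.
#' @param nFathersPerQueen mates per queen (default 1 = monandry).
#' @param paternityWeights numeric vector (recycled per queen) or list per
#'   queen; default equal shares.
#' @param nAliens number of alien workers among `nWorkers`.
#' @param missingRate per-(individual, locus) masking probability.
#' @param includeQueenGenotype also emit the mother queen genotype row(s).
#' @return a [ColonyConfig-class] object.
#' @export
colonyConfig <- function(nWorkers = 8, nQueens = 1, nFathersPerQueen = 1,
                         paternityWeights = NULL, nAliens = 0,
                         missingRate = 0, includeQueenGenotype = FALSE) {
  if (is.null(paternityWeights))
    paternityWeights <- rep(1 / nFathersPerQueen, nFathersPerQueen)
  if (!is.list(paternityWeights))
    paternityWeights <- rep(list(as.numeric(paternityWeights)), nQueens)
  new("ColonyConfig", nWorkers = as.integer(nWorkers),
      nQueens = as.integer(nQueens),
      nFathersPerQueen = as.integer(nFathersPerQueen),
      paternityWeights = paternityWeights, nAliens = as.integer(nAliens),
      missingRate = as.numeric(missingRate),
      includeQueenGenotype = isTRUE(includeQueenGenotype))
}

#' SyntheticStudy: simulated multi-site study with its truth registry
#'
#' @slot table the combined [GenotypeTable-class].
#' @slot truth named list (per colony) of ground-truth records: queen and
#'   father genotypes, per-worker maternity/paternity, alien ids.
#' @slot model the [PopulationModel-class] used.
#' @slot seed master seed.
#' @exportClass SyntheticStudy
setClass("SyntheticStudy",
  slots = c(table = "GenotypeTable", truth = "list",
            model = "PopulationModel", seed = "integer"))

setMethod("show", "SyntheticStudy", function(object) {
  cat("SyntheticStudy:", length(object@truth), "colonies,",
      nrow(object@table@a1), "individuals, seed =", object@seed, "\n")
})

#' ColonyReconstruction: inferred pedigree of one colony
#'
#' Result of [reconstructColony()]: the minimal (queens, aliens, fathers)
#' explanation of the worker genotypes.
#'
#' @slot colony colony identifier.
#' @slot loci locus names.
#' @slot nQueens,nFathers,nAliens objective counts (nFathers totalled over
#'   queens).
#' @slot classification one of "monogyne_monandrous",
#'   "monogyne_polyandrous", "multi_queen", "undetermined".
#' @slot queens list per queen with elements `genotype` (2 x loci matrix,
#'   NA = wildcard/unobserved second allele) and `solutions` (per locus, a
#'   2-column matrix of all co-optimal queen allele pairs, NA = wildcard).
#' @slot fathers list per queen of fathers; each father is a list with
#'   `genotype` (length-loci vector, NA where ambiguous) and `candidates`
#'   (per locus, the vector of feasible paternal alleles).
#' @slot assignment data.frame: id, queen index, father index (within
#'   queen), alien flag; aliens carry NA queen/father.
#' @slot heuristic TRUE when the search fell back to a non-exhaustive
#'   strategy (two-queen tier above the exhaustive limit).
#' @slot notes character vector of diagnostics (ambiguities etc.).
#' @exportClass ColonyReconstruction
setClass("ColonyReconstruction",
  slots = c(colony = "character", loci = "character", nQueens = "integer",
            nFathers = "integer", nAliens = "integer",
            classification = "character", queens = "list", fathers = "list",
            assignment = "data.frame", heuristic = "logical",
            notes = "character"))

setValidity("ColonyReconstruction", function(object) {
  ok <- c("monogyne_monandrous", "monogyne_polyandrous", "multi_queen",
          "undetermined")
  if (!object@classification %in% ok)
    return("unknown classification")
  if (object@classification != "undetermined") {
    if (object@nAliens != sum(object@assignment$alien))
      return("nAliens inconsistent with assignment")
    cls <- if (object@nQueens >= 2L) "multi_queen"
           else if (object@nFathers >= 2L) "monogyne_polyandrous"
           else "monogyne_monandrous"
    if (cls != object@classification)
      return("classification inconsistent with counts")
  }
  TRUE
})

setMethod("show", "ColonyReconstruction", function(object) {
  cat("ColonyReconstruction", object@colony, "->", object@classification,
      "\n")
  cat("  queens:", object@nQueens, " fathers:", object@nFathers,
      " aliens:", object@nAliens,
      if (object@heuristic) " [heuristic]" else "", "\n")
  if (length(object@notes))
    cat("  notes:", paste(object@notes, collapse = "; "), "\n")
})
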