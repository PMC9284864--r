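## One-command orchestration of the full analysis flow on a genotype
## table (read from disk or simulated): reconstruct colonies -> classify
## mating -> nestmate relatedness with t-test vs 0.75 -> F-statistics ->
## mating test -> structured report.

#' Read a study configuration file (JSON)
#'
#' @param path JSON file; see [runPipeline()] for the recognised fields.
#' @return a config list.
#' @export
readStudyConfig <- function(path) {
  jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyDataFrame = FALSE,
                     simplifyMatrix = FALSE)
}

.defaultConfig <- function() {
  list(seed = 1,
       freqReference = "one-per-colony",
       reconstruction = list(maxAliens = 1, allowTwoQueens = TRUE,
                             minConflictLoci = 2),
       matingTest = list(nPermutations = 1000))
}

#' Run the full colony-genetics pipeline
#'
#' Stages, in order: (1) load or simulate the genotype table; (2)
#' validate (minimum-typed-loci rule); (3) reconstruct every colony and
#' classify its mating system; (4) nestmate relatedness per colony and a
#' one-sample t-test of the monandrous-colony means against the
#' haplodiploid full-sister expectation 0.75; (5) heterozygosity and
#' Weir-Cockerham F-statistics (pairwise F_ST with classification when
#' several sites are present); (6) the queen-mate non-random-mating KS
#' test (QG and ML variants) when >= 2 eligible colonies exist,
#' otherwise an explicit "insufficient colonies" note.  All stochastic
#' stages are seeded from `config$seed` by a counter-based fan-out, so
#' rerunning the same config gives a byte-identical report.
#'
#' @param config list (or path to a JSON file) with fields:
#'   \describe{
#'     \item{seed}{master seed (default 1).}
#'     \item{genotypes / dialect}{path + dialect of an input table, OR}
#'     \item{simulation}{list(model = list(nLoci, allelesPerLocus,
#'       frequencyScheme, nSites, divergence), sites = colonies per
#'       site, workersPerColony, and optional overrides named by colony
#'       id with fields of [colonyConfig()]).}
#'     \item{freqReference}{"one-per-colony" (default), "all" or "true"
#'       (simulation only).}
#'     \item{reconstruction}{maxAliens, allowTwoQueens, minConflictLoci.}
#'     \item{matingTest}{nPermutations.}
#'   }
#' @param outDir optional directory; when given, writes report.json and
#'   colonies.csv there.
#' @return object of class "StudyReport" (a list; see its print method).
#' @export
runPipeline <- function(config, outDir = NULL) {
  if (is.character(config)) config <- readStudyConfig(config)
  cfg <- utils::modifyList(.defaultConfig(), config)
  seed <- as.integer(cfg$seed)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "': ", conditionMessage(e),
           call. = FALSE))
  }
  ## stage 1: input
  truth <- NULL; model <- NULL
  table <- stage("input", {
    if (!is.null(cfg$genotypes)) {
      readGenotypeTable(cfg$genotypes,
                        dialect = if (is.null(cfg$dialect)) "csv-wide"
                                  else cfg$dialect)
    } else if (!is.null(cfg$simulation)) {
      sim <- cfg$simulation
      mArgs <- sim$model
      model <- do.call(makePopulationModel,
                       c(mArgs, list(seed = .subSeed(seed, 1))))
      defaults <- sim[names(sim) %in% c("workersPerColony")]
      dcfg <- colonyConfig(
        nWorkers = if (is.null(sim$workersPerColony)) 8
                   else sim$workersPerColony)
      overrides <- lapply(sim$overrides, function(o) do.call(colonyConfig, o))
      study <- simulateStudy(model, unlist(sim$sites), config = dcfg,
                             overrides = overrides,
                             seed = .subSeed(seed, 2))
      truth <- study@truth
      validateGenotypes(study@table)
    } else stop("config needs either 'genotypes' or 'simulation'")
  })
  ## stage 2: frequencies
  freqs <- stage("frequencies", {
    if (identical(cfg$freqReference, "true")) {
      if (is.null(model)) stop("freqReference 'true' needs a simulation")
      trueFreqs(model, 1)
    } else {
      estimateAlleleFreqs(table, reference = cfg$freqReference,
                          seed = .subSeed(seed, 3))
    }
  })
  ## stage 3: reconstruction
  recons <- stage("reconstruction",
    reconstructAllColonies(table,
      maxAliens = cfg$reconstruction$maxAliens,
      allowTwoQueens = cfg$reconstruction$allowTwoQueens,
      minConflictLoci = cfg$reconstruction$minConflictLoci))
  colSummary <- do.call(rbind, lapply(recons, function(r)
    data.frame(colony = r@colony, nQueens = r@nQueens,
               nFathers = r@nFathers, nAliens = r@nAliens,
               classification = classification(r),
               stringsAsFactors = FALSE)))
  rownames(colSummary) <- NULL
  counts <- base::table(factor(colSummary$classification,
                         levels = c("monogyne_monandrous",
                                    "monogyne_polyandrous", "multi_queen",
                                    "undetermined")))
  ## stage 4: nestmate relatedness + t-test vs 0.75
  nestmate <- stage("nestmate-relatedness",
    meanGroupRelatedness(table, freqs))
  monand <- colSummary$colony[colSummary$classification ==
                                "monogyne_monandrous"]
  tt <- stage("t-test", {
    vals <- nestmate$meanR[nestmate$group %in% monand]
    if (length(vals) >= 2 && sd(vals) > 0) oneSampleTTest(vals, mu = 0.75)
    else NULL
  })
  ## stage 5: F-statistics
  info <- indivData(table)
  popstats <- stage("popgen-stats", {
    enough <- all(base::table(info$site[info$ploidy == 2L]) >= 2)
    if (enough) fStatistics(table, pops = "site") else NULL
  })
  ## stage 6: mating test
  matingNote <- NULL
  mating <- stage("mating-test", {
    if (sum(colSummary$classification == "monogyne_monandrous") >= 2) {
      lapply(setNames(nm = c("qg", "ml")), function(est) {
        ps <- buildPairSets(recons, freqs, estimator = est)
        ks <- ksOneSided(ps$mate, ps$null,
                         nPermutations = cfg$matingTest$nPermutations,
                         seed = .subSeed(seed, 4))
        list(pairSets = ps, ks = ks)
      })
    } else {
      matingNote <- "insufficient colonies for the mating test"
      NULL
    }
  })
  report <- structure(list(
    colonies = colSummary,
    classificationCounts = as.list(counts),
    nestmate = nestmate,
    nestmateOverall = attr(nestmate, "overall"),
    tTestVs075 = tt,
    popstats = popstats,
    mating = mating,
    matingNote = matingNote,
    truthAvailable = !is.null(truth),
    provenance = list(config = cfg, seed = seed,
                      freqReference = freqs@provenance,
                      package = "colonykin",
                      version = as.character(packageVersion("colonykin")))),
    class = "StudyReport")
  if (!is.null(outDir)) writeStudyReport(report, outDir)
  report
}

#' Write a StudyReport to disk
#'
#' Emits `report.json` (machine-readable, byte-stable for a fixed config
#' and seed) and `colonies.csv`.
#'
#' @param report a StudyReport from [runPipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeStudyReport <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  json <- list(
    classificationCounts = report$classificationCounts,
    nestmateOverall = report$nestmateOverall,
    tTestVs075 = if (!is.null(report$tTestVs075))
      unclass(report$tTestVs075),
    fst = if (!is.null(report$popstats)) report$popstats$fst,
    fis = if (!is.null(report$popstats)) report$popstats$fis,
    fisPerPop = if (!is.null(report$popstats))
      as.list(report$popstats$fisPerPop),
    pairwiseFst = if (!is.null(report$popstats))
      report$popstats$pairwiseFst,
    mating = if (!is.null(report$mating)) lapply(report$mating, function(m)
      list(D = m$ks$D, pAsymptotic = m$ks$pAsymptotic,
           pPermutation = m$ks$pPermutation, n1 = m$ks$n1, n2 = m$ks$n2)),
    matingNote = report$matingNote,
    provenance = report$provenance)
  jsonlite::write_json(json, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null", na = "null")
  utils::write.csv(report$colonies, file.path(dir, "colonies.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' @export
print.StudyReport <- function(x, ...) {
  cc <- x$classificationCounts
  n <- sum(unlist(cc))
  cat("StudyReport:", n, "colonies\n")
  cat(sprintf("  %d/%d monandrous, %d polyandrous, %d multi-queen, %d undetermined\n",
              cc$monogyne_monandrous, n, cc$monogyne_polyandrous,
              cc$multi_queen, cc$undetermined))
  ov <- x$nestmateOverall
  cat(sprintf("  nestmate relatedness: mean of colony means = %.3f (SD %.3f, SE %.3f, %d colonies)\n",
              ov$mean, ov$sd, ov$se, ov$nGroups))
  if (!is.null(x$tTestVs075))
    cat(sprintf("  vs 0.75: t = %.3f, df = %d, p = %.3f\n",
                x$tTestVs075$t, x$tTestVs075$df, x$tTestVs075$p))
  if (!is.null(x$popstats))
    cat(sprintf("  F_IS = %.3f%s\n", x$popstats$fis,
                if (!is.na(x$popstats$fst))
                  sprintf(", multilocus F_ST = %.3f", x$popstats$fst)
                else ""))
  if (!is.null(x$mating)) {
    for (est in names(x$mating)) {
      ks <- x$mating[[est]]$ks
      cat(sprintf("  mating test (%s): D = %.3f, asymptotic p = %.4f, permutation p = %s\n",
                  toupper(est), ks$D, ks$pAsymptotic,
                  ifelse(is.na(ks$pPermutation), "not run",
                         sprintf("%.4f", ks$pPermutation))))
    }
  } else if (!is.null(x$matingNote)) cat("  mating test:", x$matingNote, "\n")
  invisible(x)
}
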