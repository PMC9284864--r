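## Haplodiploid colony simulator: the ground-truth generator for every
## downstream stage.  Females are diploid, males haploid; a worker
## receives one uniformly chosen allele of her mother plus her father's
## single allele at every locus.

#' Build a population model of allele frequencies
#'
#' Creates per-locus ancestral allele frequencies and, for multi-site
#' models, per-site frequencies drawn by a Balding-Nichols perturbation:
#' site frequencies ~ Dirichlet((1 - F)/F * p_ancestral) with
#' F = `divergence`, independently per site and locus.  `divergence = 0`
#' gives every site the ancestral frequencies exactly, so the analytic
#' handle is: the expected Weir-Cockerham theta between two sites is F.
#'
#' Allele labels are microsatellite-style even integers starting at 102;
#' identity is the integer label, not a repeat length.
#'
#' @param nLoci number of loci (default 12, the study design).
#' @param allelesPerLocus integer scalar or vector (recycled to `nLoci`);
#'   the study's markers carried 9-28 alleles each.
#' @param frequencyScheme "uniform" (equifrequent) or "dirichlet"
#'   (ancestral frequencies drawn from a symmetric Dirichlet).
#' @param dirichletAlpha concentration for `frequencyScheme = "dirichlet"`.
#' @param nSites number of sites.
#' @param divergence Balding-Nichols drift parameter F in [0, 1).
#' @param seed integer seed (optional but recommended).
#' @param loci optional locus names (default L01, L02, ...).
#' @return a [PopulationModel-class].
#' @examples
#' m <- makePopulationModel(nLoci = 12, allelesPerLocus = 20, seed = 1)
#' @export
makePopulationModel <- function(nLoci = 12, allelesPerLocus = 20,
                                frequencyScheme = c("uniform", "dirichlet"),
                                dirichletAlpha = 1, nSites = 1,
                                divergence = 0, seed = NULL, loci = NULL) {
  frequencyScheme <- match.arg(frequencyScheme)
  if (nLoci < 1) stop("nLoci must be positive")
  if (any(allelesPerLocus < 1)) stop("allelesPerLocus must be positive")
  if (nSites < 1) stop("nSites must be positive")
  if (divergence < 0 || divergence >= 1)
    stop("divergence must be in [0, 1)")
  k <- as.integer(rep_len(allelesPerLocus, nLoci))
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(nLoci))
  if (!is.null(seed)) set.seed(as.integer(seed))
  labels <- lapply(k, function(ki) as.character(100L + 2L * seq_len(ki)))
  ancestral <- vector("list", nLoci)
  names(ancestral) <- loci
  for (l in seq_len(nLoci)) {
    p <- if (frequencyScheme == "uniform") rep(1 / k[l], k[l])
         else {
           g <- rgamma(k[l], shape = dirichletAlpha)
           g / sum(g)
         }
    ancestral[[l]] <- setNames(p / sum(p), labels[[l]])
  }
  siteFreqs <- vector("list", nSites)
  names(siteFreqs) <- sprintf("site%d", seq_len(nSites))
  for (s in seq_len(nSites)) {
    if (divergence == 0) {
      siteFreqs[[s]] <- ancestral
    } else {
      conc <- (1 - divergence) / divergence
      siteFreqs[[s]] <- lapply(ancestral, function(p) {
        g <- rgamma(length(p), shape = conc * p)
        ## guard against all-zero draws at tiny concentrations
        if (sum(g) == 0) g[sample.int(length(g), 1)] <- 1
        setNames(g / sum(g), names(p))
      })
    }
  }
  new("PopulationModel", loci = loci, allelesPerLocus = k,
      scheme = frequencyScheme, nSites = as.integer(nSites),
      divergence = as.numeric(divergence), ancestral = ancestral,
      siteFreqs = siteFreqs, seed = if (is.null(seed)) NA_integer_
                                    else as.integer(seed))
}

#' True allele frequencies of a model site
#'
#' @param model a [PopulationModel-class].
#' @param site site index (default 1).
#' @return an [AlleleFreqs-class] with provenance "true (simulation)".
#' @export
trueFreqs <- function(model, site = 1) {
  new("AlleleFreqs", freqs = model@siteFreqs[[site]],
      provenance = "true (simulation)")
}

## one multilocus haploid draw from site frequencies
.drawHaploid <- function(freqs) {
  vapply(freqs, function(p)
    as.integer(names(p))[sample.int(length(p), 1, prob = p)], integer(1))
}

## diploid draw: two independent haploid draws, rows = the two alleles
.drawDiploid <- function(freqs) {
  rbind(.drawHaploid(freqs), .drawHaploid(freqs))
}

#' Simulate one colony
#'
#' The queen is sampled as two independent draws from the site
#' frequencies per locus; each father is one draw per locus.  Every
#' non-alien worker receives one uniformly chosen queen allele plus the
#' allele of a father chosen by the paternity weights.  Aliens are
#' simulated as offspring of an independent monandrous queen x male from
#' the same site (a stray forager from another nest, not a bare
#' frequency draw).  Missing entries are masked independently per
#' (individual, locus).
#'
#' @param model a [PopulationModel-class].
#' @param site site index.
#' @param config a [ColonyConfig-class].
#' @param colonyId colony identifier used in ids and metadata.
#' @param seed optional integer seed.
#' @return list with `table` (a [GenotypeTable-class] of workers, plus
#'   queen rows when requested) and `truth` (queen/father genotypes,
#'   per-worker maternity and patriline, alien ids).
#' @examples
#' m <- makePopulationModel(seed = 1)
#' sim <- simulateColony(m, config = colonyConfig(nWorkers = 8), seed = 2)
#' @export
simulateColony <- function(model, site = 1, config = colonyConfig(),
                           colonyId = "colony1", seed = NULL) {
  validObject(config)
  if (!is.null(seed)) set.seed(as.integer(seed))
  freqs <- model@siteFreqs[[site]]
  L <- length(model@loci)
  nQ <- config@nQueens
  nF <- config@nFathersPerQueen
  queens <- lapply(seq_len(nQ), function(q) {
    g <- .drawDiploid(freqs)
    colnames(g) <- model@loci
    g
  })
  fathers <- lapply(seq_len(nQ), function(q)
    lapply(seq_len(nF), function(f) setNames(.drawHaploid(freqs), model@loci)))
  nW <- config@nWorkers
  nA <- config@nAliens
  alienIdx <- if (nA > 0) sort(sample.int(nW, nA)) else integer(0)
  ids <- sprintf("%s_w%02d", colonyId, seq_len(nW))
  a1 <- matrix(NA_integer_, nW, L, dimnames = list(ids, model@loci))
  a2 <- a1
  maternity <- rep(NA_integer_, nW)
  patriline <- rep(NA_integer_, nW)
  alienParents <- list()
  for (w in seq_len(nW)) {
    if (w %in% alienIdx) {
      aq <- .drawDiploid(freqs)
      am <- .drawHaploid(freqs)
      mat <- aq[cbind(sample.int(2, L, replace = TRUE), seq_len(L))]
      a1[w, ] <- mat
      a2[w, ] <- am
      alienParents[[ids[w]]] <- list(queen = aq, male = am)
    } else {
      q <- if (nQ == 1) 1L else sample.int(nQ, 1)
      f <- sample.int(nF, 1, prob = config@paternityWeights[[q]])
      maternity[w] <- q
      patriline[w] <- f
      mat <- queens[[q]][cbind(sample.int(2, L, replace = TRUE), seq_len(L))]
      a1[w, ] <- mat
      a2[w, ] <- fathers[[q]][[f]]
    }
  }
  info <- data.frame(colony = rep(colonyId, nW),
                     site = rep(names(model@siteFreqs)[site], nW),
                     caste = rep("worker", nW), ploidy = rep(2L, nW),
                     row.names = ids, stringsAsFactors = FALSE)
  if (config@includeQueenGenotype) {
    qids <- sprintf("%s_q%d", colonyId, seq_len(nQ))
    qa1 <- t(vapply(queens, function(g) pmin(g[1, ], g[2, ]), integer(L)))
    qa2 <- t(vapply(queens, function(g) pmax(g[1, ], g[2, ]), integer(L)))
    rownames(qa1) <- rownames(qa2) <- qids
    a1 <- rbind(a1, qa1)
    a2 <- rbind(a2, qa2)
    info <- rbind(info, data.frame(colony = rep(colonyId, nQ),
                                   site = rep(names(model@siteFreqs)[site], nQ),
                                   caste = rep("queen", nQ),
                                   ploidy = rep(2L, nQ),
                                   row.names = qids,
                                   stringsAsFactors = FALSE))
  }
  if (config@missingRate > 0) {
    mask <- matrix(runif(length(a1)) < config@missingRate, nrow(a1))
    a1[mask] <- NA_integer_
    a2[mask] <- NA_integer_
  }
  tab <- GenotypeTable(a1, a2, info)
  truth <- list(colony = colonyId, site = names(model@siteFreqs)[site],
                queens = queens, fathers = fathers,
                workerIds = ids, maternity = setNames(maternity, ids),
                patriline = setNames(patriline, ids),
                aliens = ids[alienIdx], alienParents = alienParents)
  list(table = tab, truth = truth)
}

## counter-based sub-seed fan-out: stage order changes do not reshuffle
## randomness; kept below 2^31 (R integers are 32-bit)
.subSeed <- function(master, index) {
  as.integer((as.double(master) * 7919 + 1000003 * index) %% 2147483647)
}

#' Simulate a whole multi-site study
#'
#' Wraps [simulateColony()] over a design of sites x colonies, fanning a
#' single master seed out to one sub-seed per colony (counter-based, so
#' the randomness of colony i does not depend on how many colonies
#' precede it in other sites).
#'
#' @param model a [PopulationModel-class].
#' @param nColoniesPerSite integer vector, colonies per site (length
#'   `nSites` of the model, or shorter to use fewer sites).
#' @param config default [ColonyConfig-class] applied to every colony.
#' @param overrides named list (by colony id, e.g. "site1c03") of
#'   [ColonyConfig-class] objects replacing the default.
#' @param seed master seed (required for reproducibility).
#' @return a [SyntheticStudy-class].
#' @examples
#' m <- makePopulationModel(nSites = 2, seed = 1)
#' st <- simulateStudy(m, c(3, 2), seed = 9)
#' @export
simulateStudy <- function(model, nColoniesPerSite,
                          config = colonyConfig(), overrides = list(),
                          seed = 1) {
  if (length(nColoniesPerSite) < 1 || any(nColoniesPerSite < 1))
    stop("at least one colony per requested site")
  if (length(nColoniesPerSite) > model@nSites)
    stop("more sites requested than the model has")
  tabs <- list()
  truth <- list()
  idx <- 0L
  for (s in seq_along(nColoniesPerSite)) {
    for (j in seq_len(nColoniesPerSite[s])) {
      idx <- idx + 1L
      cid <- sprintf("site%dc%02d", s, j)
      cfg <- if (cid %in% names(overrides)) overrides[[cid]] else config
      sim <- simulateColony(model, site = s, config = cfg, colonyId = cid,
                            seed = .subSeed(seed, idx))
      tabs[[cid]] <- sim$table
      truth[[cid]] <- sim$truth
    }
  }
  new("SyntheticStudy", table = combineGenotypeTables(tabs), truth = truth,
      model = model, seed = as.integer(seed))
}

#' Check Mendelian consistency of a simulated colony against its truth
#'
#' Every non-alien worker allele pair must equal {one maternal allele,
#' the paternal allele} of its recorded parents at every unmasked locus.
#' Used by the test suite; exported because it documents the invariant.
#'
#' @param sim result of [simulateColony()].
#' @return TRUE, or a character vector of violations.
#' @export
checkMendelian <- function(sim) {
  tab <- sim$table
  tr <- sim$truth
  bad <- character()
  for (id in setdiff(tr$workerIds, tr$aliens)) {
    q <- tr$queens[[tr$maternity[[id]]]]
    f <- tr$fathers[[tr$maternity[[id]]]][[tr$patriline[[id]]]]
    for (l in seq_along(lociNames(tab))) {
      w1 <- tab@a1[id, l]; w2 <- tab@a2[id, l]
      if (is.na(w1)) next
      obs <- sort(c(w1, w2))
      ok <- identical(sort(as.integer(c(q[1, l], f[l]))), as.integer(obs)) ||
            identical(sort(as.integer(c(q[2, l], f[l]))), as.integer(obs))
      if (!ok) bad <- c(bad, sprintf("%s locus %d", id, l))
    }
  }
  if (length(bad)) bad else TRUE
}
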