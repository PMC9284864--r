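## Queen/father pedigree reconstruction from worker genotypes.
##
## A colony explanation is searched in lexicographic objective order
## (n_queens, n_aliens, n_fathers): (i) one queen, no aliens; (ii) one
## queen with up to max_aliens workers excluded; (iii) two queens.  The
## father count for a fixed worker set is found by exact search over
## worker partitions: a patriline is feasible iff at every locus the
## workers share a paternal allele after subtracting a queen allele, for
## some per-locus queen genotype common to all patrilines.

#' Candidate queen genotypes at one locus
#'
#' All unordered allele pairs {a, b} (a = b allowed) over the alleles
#' observed in the colony such that every non-missing worker call
#' carries a or b; additionally {a, wildcard} whenever the single allele
#' a covers all workers (queen possibly homozygous or carrying an
#' unobserved second allele).  Wildcards are encoded as NA.
#'
#' @param calls 2-column matrix of worker calls at one locus (one row
#'   per worker, NA rows = missing).
#' @return 2-column integer matrix of candidate pairs, lexicographically
#'   ordered ({a,a} before {a,wildcard} before {a,b}); zero rows when no
#'   single-queen explanation exists at this locus.
#' @export
candidateQueenGenotypes <- function(calls) {
  calls <- calls[!is.na(calls[, 1]), , drop = FALSE]
  if (nrow(calls) == 0)
    return(matrix(NA_integer_, 1, 2))  # unconstraining locus
  alleles <- sort(unique(as.integer(calls)))
  covers <- function(a, b) all(calls[, 1] == a | calls[, 2] == a |
                               calls[, 1] == b | calls[, 2] == b)
  out <- list()
  for (i in seq_along(alleles)) {
    a <- alleles[i]
    if (covers(a, a)) {
      out[[length(out) + 1L]] <- c(a, a)
      out[[length(out) + 1L]] <- c(a, NA_integer_)  # wildcard second allele
    }
    for (j in seq_along(alleles)) {
      if (j <= i) next
      b <- alleles[j]
      if (covers(a, b)) out[[length(out) + 1L]] <- c(a, b)
    }
  }
  if (length(out) == 0) return(matrix(NA_integer_, 0, 2))
  m <- unique(do.call(rbind, out))
  key2 <- ifelse(is.na(m[, 2]), m[, 1] + 0.5, m[, 2])
  m[order(m[, 1], key2), , drop = FALSE]
}

## paternal allele candidates of one worker call under a queen pair
## (NULL = unconstraining missing call; integer(0) = incompatible)
.paternalCand <- function(w1, w2, q) {
  if (is.na(w1)) return(NULL)
  qs <- q[!is.na(q)]
  if (length(qs) == 0) return(NULL)  # fully wildcard locus
  cand <- integer(0)
  if (w1 %in% qs) cand <- c(cand, w2)
  if (w2 %in% qs) cand <- c(cand, w1)
  unique(cand)
}

## Precompute per-locus queen candidates and paternal candidate sets for
## a worker subset.  Paternal candidate sets are stored as integer
## bitmasks over the locus' colony alleles (missing call = all-ones),
## so a patriline's joint constraint is a chain of bitwAnd operations.
## Returns NULL if some locus has no candidate (no single-queen
## explanation).
.queenStructure <- function(w1, w2) {
  L <- ncol(w1)
  qc <- vector("list", L)
  pcMask <- vector("list", L)
  alleles <- vector("list", L)
  for (l in seq_len(L)) {
    cands <- candidateQueenGenotypes(cbind(w1[, l], w2[, l]))
    if (nrow(cands) == 0) return(NULL)
    qc[[l]] <- cands
    al <- sort(unique(as.integer(stats::na.omit(c(w1[, l], w2[, l])))))
    alleles[[l]] <- al
    full <- if (length(al)) as.integer(2^length(al) - 1) else 1L
    toMask <- function(x) {
      if (is.null(x)) return(full)
      if (length(x) == 0) return(0L)
      as.integer(sum(2^(match(x, al) - 1)))
    }
    M <- matrix(0L, nrow(cands), nrow(w1))
    for (qi in seq_len(nrow(cands)))
      for (w in seq_len(nrow(w1)))
        M[qi, w] <- toMask(.paternalCand(w1[w, l], w2[w, l], cands[qi, ]))
    pcMask[[l]] <- M
  }
  list(qc = qc, pcMask = pcMask, alleles = alleles, L = L, n = nrow(w1))
}

## reduced paternal mask of a group (vector over queen candidates)
.groupMask <- function(M, g) {
  red <- M[, g[1]]
  for (j in g[-1]) red <- bitwAnd(red, M[, j])
  red
}

## is a grouping (list of worker index vectors) feasible at every locus?
.groupsFeasible <- function(qs, groups) {
  groups <- groups[lengths(groups) > 0]
  for (l in seq_len(qs$L)) {
    viable <- rep(TRUE, nrow(qs$qc[[l]]))
    M <- qs$pcMask[[l]]
    for (g in groups) {
      viable <- viable & (.groupMask(M, g) != 0L)
      if (!any(viable)) return(FALSE)
    }
  }
  TRUE
}

## Exact minimal-father search over worker partitions (restricted-growth
## DFS with partial-feasibility pruning).  Returns NULL when even
## singleton patrilines fail (never happens once .queenStructure is
## non-NULL), else list(k, partitions = all co-optimal groupings).
.minFathers <- function(qs, kCap = Inf) {
  n <- qs$n
  best <- Inf
  solutions <- list()
  assign <- integer(n)
  recurse <- function(i, nGroups) {
    if (nGroups > min(best, kCap)) return()
    groups <- lapply(seq_len(nGroups), function(g) which(assign[seq_len(i - 1)] == g))
    if (i > 1 && !.groupsFeasible(qs, groups)) return()
    if (i > n) {
      if (nGroups < best) { best <<- nGroups; solutions <<- list() }
      if (nGroups == best)
        solutions[[length(solutions) + 1L]] <<- groups
      return()
    }
    for (g in seq_len(min(nGroups + 1L, n))) {
      assign[i] <<- g
      recurse(i + 1L, max(nGroups, g))
      assign[i] <<- 0L
    }
    invisible()
  }
  recurse(1L, 0L)
  if (!is.finite(best)) return(NULL)
  list(k = best, partitions = solutions)
}

## co-optimal queen pairs per locus for one grouping (indices + matrix)
.viableQueens <- function(qs, groups, l) {
  groups <- groups[lengths(groups) > 0]
  viable <- rep(TRUE, nrow(qs$qc[[l]]))
  M <- qs$pcMask[[l]]
  for (g in groups) viable <- viable & (.groupMask(M, g) != 0L)
  which(viable)
}

.queenSolutionsFor <- function(qs, groups) {
  lapply(seq_len(qs$L), function(l)
    qs$qc[[l]][.viableQueens(qs, groups, l), , drop = FALSE])
}

.maskToAlleles <- function(mask, al) {
  if (length(al) == 0) return(integer(0))
  al[bitwAnd(mask, as.integer(2^(seq_along(al) - 1))) != 0L]
}

## assemble queen genotype, father genotypes and ambiguity info for the
## primary (first viable) queen solution of one grouping
.assembleQueenFathers <- function(qs, groups, loci) {
  viable <- lapply(seq_len(qs$L), function(l) .viableQueens(qs, groups, l))
  sols <- lapply(seq_len(qs$L), function(l)
    qs$qc[[l]][viable[[l]], , drop = FALSE])
  genotype <- vapply(seq_len(qs$L), function(l)
    as.integer(sols[[l]][1, ]), integer(2))  # 2 x L
  colnames(genotype) <- loci
  fathers <- lapply(groups, function(g) {
    cand <- lapply(seq_len(qs$L), function(l) {
      qi <- viable[[l]][1]
      red <- .groupMask(qs$pcMask[[l]], g)[qi]
      .maskToAlleles(red, qs$alleles[[l]])
    })
    geno <- vapply(cand, function(x)
      if (length(x) == 1) as.integer(x) else NA_integer_, integer(1))
    names(geno) <- loci
    list(genotype = geno, candidates = setNames(cand, loci))
  })
  list(solutions = setNames(sols, loci), genotype = genotype,
       fathers = fathers)
}

## conflict loci of worker e against a worker subset: loci where e
## shares no allele with any single-queen covering pair of the subset
## (wildcard alleles do not absorb e's alleles).  This is the alien
## guard: a foreign queen's offspring conflicts at many loci, a
## minority patriline at none (it carries the queen's alleles).
.coverConflicts <- function(w1, w2, e, sub) {
  sum(vapply(seq_len(ncol(w1)), function(l) {
    if (is.na(w1[e, l])) return(FALSE)
    cands <- candidateQueenGenotypes(cbind(w1[sub, l], w2[sub, l]))
    alleles <- unique(as.integer(cands))
    alleles <- alleles[!is.na(alleles)]
    if (length(alleles) == 0) return(FALSE)
    !(w1[e, l] %in% alleles || w2[e, l] %in% alleles)
  }, logical(1)))
}

#' Reconstruct the queen/father pedigree of one colony
#'
#' Infers the minimal explanation of the worker genotypes.  Queens are
#' minimized first (a single-queen explanation always beats a two-queen
#' one); among single-queen explanations, candidates are compared by
#' (number of fathers, number of alien workers), and a worker may only
#' be excluded as alien when it conflicts with the resulting queen
#' solution at >= `minConflictLoci` loci.  The guard is what separates a
#' true alien (a foreign queen's offspring, conflicting at many loci)
#' from a minority patriline (which conflicts at none, so polyandry is
#' never explained away as an alien) and protects against single-locus
#' genotyping artifacts.  The father count for a fixed worker set is
#' found by exact partition search; ties retain all co-optimal queen
#' solutions.
#'
#' @param table a [GenotypeTable-class].
#' @param colony colony id (default: the single colony in `table`).
#' @param maxAliens maximum workers excludable as aliens (default 1).
#' @param allowTwoQueens try a two-queen explanation when single-queen
#'   tiers fail (default TRUE).
#' @param minConflictLoci minimum conflicting loci to call a worker alien
#'   (default 2).
#' @param exhaustiveLimit maximum workers for the exhaustive two-queen
#'   bipartition search (default 12; above it a deterministic seeded
#'   sample of bipartitions is used and the result is marked heuristic).
#' @return a [ColonyReconstruction-class].
#' @examples
#' m <- makePopulationModel(seed = 1)
#' sim <- simulateColony(m, config = colonyConfig(nWorkers = 8), seed = 3)
#' reconstructColony(sim$table)
#' @export
reconstructColony <- function(table, colony = NULL, maxAliens = 1,
                              allowTwoQueens = TRUE, minConflictLoci = 2,
                              exhaustiveLimit = 12) {
  info <- indivData(table)
  if (is.null(colony)) {
    colony <- unique(info$colony[info$caste == "worker"])
    if (length(colony) != 1)
      stop("table holds several colonies; give `colony`")
  }
  keep <- info$colony == colony & info$caste == "worker"
  ids <- individuals(table)[keep]
  if (length(ids) < 2) stop("need >= 2 workers with usable genotypes")
  w1 <- table@a1[ids, , drop = FALSE]
  w2 <- table@a2[ids, , drop = FALSE]
  loci <- lociNames(table)
  notes <- character()
  finish <- function(nQ, nA, queens, fathers, assignment, heuristic = FALSE) {
    nF <- sum(vapply(fathers, length, integer(1)))
    cls <- if (nQ >= 2L) "multi_queen"
           else if (nF >= 2L) "monogyne_polyandrous"
           else "monogyne_monandrous"
    new("ColonyReconstruction", colony = colony, loci = loci,
        nQueens = as.integer(nQ), nFathers = as.integer(nF),
        nAliens = as.integer(nA), classification = cls, queens = queens,
        fathers = fathers, assignment = assignment,
        heuristic = heuristic, notes = notes)
  }
  orderGroups <- function(groups, idsSub) {
    ## majority patriline first; deterministic tie-break by first id
    ord <- order(-vapply(groups, length, integer(1)),
                 vapply(groups, function(g) min(idsSub[g]), character(1)))
    groups[ord]
  }
  buildSingleQueen <- function(idsSub, qsSub, mf, alienIds) {
    groups <- orderGroups(mf$partitions[[1]], idsSub)
    asm <- .assembleQueenFathers(qsSub, groups, loci)
    if (length(mf$partitions) > 1) {
      notes <<- c(notes, sprintf("%d co-optimal worker partitions",
                                 length(mf$partitions)))
      ## retain the union of queen solutions over co-optimal partitions
      allSols <- lapply(mf$partitions, function(p)
        .queenSolutionsFor(qsSub, p))
      asm$solutions <- setNames(lapply(seq_along(loci), function(l)
        unique(do.call(rbind, lapply(allSols, function(s) s[[l]])))), loci)
    }
    fa <- rep(NA_integer_, length(ids)); names(fa) <- ids
    for (fi in seq_along(groups)) fa[idsSub[groups[[fi]]]] <- fi
    assignment <- data.frame(id = ids,
                             queen = ifelse(ids %in% alienIds, NA_integer_, 1L),
                             father = fa[ids],
                             alien = ids %in% alienIds,
                             stringsAsFactors = FALSE, row.names = NULL)
    finish(1L, length(alienIds),
           queens = list(list(genotype = asm$genotype,
                              solutions = asm$solutions)),
           fathers = list(asm$fathers), assignment)
  }

  ## --- single-queen tiers ---------------------------------------------
  ## The 0-alien explanation and guarded alien-exclusion explanations
  ## are compared by (n_fathers, n_aliens); only workers passing the
  ## conflict guard are ever considered for exclusion, so a minority
  ## patriline (0 conflict loci) can never be explained away as alien.
  n <- length(ids)
  bestAlien <- NULL
  if (maxAliens >= 1 && n >= 3) {
    conflQ <- vapply(seq_len(n), function(e)
      .coverConflicts(w1, w2, e, setdiff(seq_len(n), e)), numeric(1))
    suspicious <- which(conflQ >= minConflictLoci)
    if (length(suspicious)) {
      kCap <- Inf
      for (s in seq_len(min(maxAliens, length(suspicious), n - 2))) {
        subsets <- combn(suspicious, s)
        for (ci in seq_len(ncol(subsets))) {
          ex <- subsets[, ci]
          sub <- setdiff(seq_len(n), ex)
          if (s > 1) {  # re-check the guard against the joint remainder
            confl <- vapply(ex, function(e)
              .coverConflicts(w1, w2, e, sub), numeric(1))
            if (!all(confl >= minConflictLoci)) next
          } else confl <- conflQ[ex]
          qsS <- .queenStructure(w1[sub, , drop = FALSE],
                                 w2[sub, , drop = FALSE])
          if (is.null(qsS)) next
          mfS <- .minFathers(qsS, kCap = kCap)
          if (is.null(mfS)) next
          if (is.null(bestAlien) || mfS$k < bestAlien$k) {
            bestAlien <- list(k = mfS$k, s = s, ex = ex, sub = sub,
                              qs = qsS, mf = mfS, confl = confl)
            kCap <- mfS$k - 1  # later candidates must strictly improve
          }
        }
      }
    }
  }
  ## 0-alien explanation, capped so it is only built when it is at
  ## least as good (fewest fathers; ties go to fewer aliens)
  qs <- .queenStructure(w1, w2)
  if (!is.null(qs)) {
    mf <- .minFathers(qs, kCap = if (is.null(bestAlien)) Inf
                                 else bestAlien$k)
    if (!is.null(mf))
      return(buildSingleQueen(ids, qs, mf, character(0)))
  }
  if (!is.null(bestAlien)) {
    notes <- c(notes, sprintf("alien(s) %s conflict at %s loci",
                              paste(ids[bestAlien$ex], collapse = ","),
                              paste(bestAlien$confl, collapse = ",")))
    return(buildSingleQueen(ids[bestAlien$sub], bestAlien$qs,
                            bestAlien$mf, ids[bestAlien$ex]))
  }

  ## --- tier (iii): two queens, no aliens ------------------------------
  if (allowTwoQueens && length(ids) >= 2) {
    n <- length(ids)
    bip <- list()
    if (n <= exhaustiveLimit) {
      for (code in seq_len(2^(n - 1) - 1)) {
        inB <- c(FALSE, as.logical(bitwAnd(code,
                  2^(seq_len(n - 1) - 1)) > 0))
        bip[[length(bip) + 1L]] <- inB
      }
      heuristic <- FALSE
    } else {
      set.seed(.subSeed(20240101, n))  # deterministic heuristic sample
      bip <- lapply(seq_len(200), function(i)
        sample(c(TRUE, FALSE), n, replace = TRUE))
      bip <- Filter(function(b) any(b) && !all(b), bip)
      heuristic <- TRUE
    }
    bestK <- Inf; bestSol <- NULL
    for (inB in bip) {
      A <- which(!inB); B <- which(inB)
      qsA <- .queenStructure(w1[A, , drop = FALSE], w2[A, , drop = FALSE])
      if (is.null(qsA)) next
      qsB <- .queenStructure(w1[B, , drop = FALSE], w2[B, , drop = FALSE])
      if (is.null(qsB)) next
      mfA <- .minFathers(qsA); mfB <- .minFathers(qsB)
      if (mfA$k + mfB$k < bestK) {
        bestK <- mfA$k + mfB$k
        bestSol <- list(A = A, B = B, qsA = qsA, qsB = qsB,
                        mfA = mfA, mfB = mfB)
      }
    }
    if (!is.null(bestSol)) {
      gA <- orderGroups(bestSol$mfA$partitions[[1]], ids[bestSol$A])
      gB <- orderGroups(bestSol$mfB$partitions[[1]], ids[bestSol$B])
      asmA <- .assembleQueenFathers(bestSol$qsA, gA, loci)
      asmB <- .assembleQueenFathers(bestSol$qsB, gB, loci)
      qn <- rep(NA_integer_, length(ids)); names(qn) <- ids
      fa <- rep(NA_integer_, length(ids)); names(fa) <- ids
      qn[ids[bestSol$A]] <- 1L; qn[ids[bestSol$B]] <- 2L
      for (fi in seq_along(gA)) fa[ids[bestSol$A][gA[[fi]]]] <- fi
      for (fi in seq_along(gB)) fa[ids[bestSol$B][gB[[fi]]]] <- fi
      assignment <- data.frame(id = ids, queen = qn[ids], father = fa[ids],
                               alien = FALSE, stringsAsFactors = FALSE,
                               row.names = NULL)
      return(finish(2L, 0L,
                    queens = list(list(genotype = asmA$genotype,
                                       solutions = asmA$solutions),
                                  list(genotype = asmB$genotype,
                                       solutions = asmB$solutions)),
                    fathers = list(asmA$fathers, asmB$fathers),
                    assignment, heuristic = heuristic))
    }
  }

  ## --- undetermined ----------------------------------------------------
  assignment <- data.frame(id = ids, queen = NA_integer_,
                           father = NA_integer_, alien = FALSE,
                           stringsAsFactors = FALSE, row.names = NULL)
  new("ColonyReconstruction", colony = colony, loci = loci,
      nQueens = 0L, nFathers = 0L, nAliens = 0L,
      classification = "undetermined", queens = list(), fathers = list(),
      assignment = assignment, heuristic = FALSE,
      notes = c(notes, "no explanation within the search tiers"))
}

#' Reconstruct every colony of a table
#'
#' @param table a [GenotypeTable-class].
#' @param ... passed to [reconstructColony()].
#' @return named list of [ColonyReconstruction-class] objects.
#' @export
reconstructAllColonies <- function(table, ...) {
  info <- indivData(table)
  cols <- unique(info$colony[info$caste == "worker"])
  out <- lapply(cols, function(cid) {
    tryCatch(reconstructColony(table, colony = cid, ...),
             error = function(e)
               stop("colony ", cid, ": ", conditionMessage(e),
                    call. = FALSE))
  })
  setNames(out, cols)
}

#' Paternity partition of a reconstruction
#'
#' @param recon a [ColonyReconstruction-class].
#' @return data.frame: queen, father, nWorkers, fraction (fractions sum
#'   to 1 over non-alien workers; invariant under father relabeling).
#' @export
paternityPartition <- function(recon) {
  if (classification(recon) == "undetermined")
    stop("paternity partition undefined for an undetermined reconstruction")
  a <- recon@assignment
  a <- a[!a$alien, ]
  tab <- as.data.frame(table(queen = a$queen, father = a$father),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0, ]
  data.frame(queen = as.integer(tab$queen),
             father = as.integer(tab$father),
             nWorkers = tab$Freq,
             fraction = tab$Freq / sum(tab$Freq),
             row.names = NULL)
}

#' Compare a reconstruction with an observed queen genotype
#'
#' Per locus: "mismatch" when no co-optimal queen solution contains the
#' observed allele pair (a wildcard allele matches anything); "match"
#' when the solution is unique (or all solutions agree with the observed
#' pair); "ambiguous" when only some of several co-optimal solutions
#' match.
#'
#' @param recon a [ColonyReconstruction-class] with one queen.
#' @param observed 2 x loci matrix (or a 2-row genotype) of the
#'   empirically genotyped queen; NA = untyped locus (status "untyped").
#' @param queen queen index (default 1).
#' @return data.frame: locus, status.
#' @export
verifyAgainstQueen <- function(recon, observed, queen = 1) {
  sols <- recon@queens[[queen]]$solutions
  loci <- recon@loci
  status <- vapply(seq_along(loci), function(l) {
    o <- sort(observed[, l])
    if (anyNA(o)) return("untyped")
    s <- sols[[l]]
    matches <- apply(s, 1, function(q) {
      conc <- q[!is.na(q)]
      if (length(conc) == 2) identical(as.integer(sort(conc)),
                                       as.integer(o))
      else if (length(conc) == 1) conc %in% o  # wildcard matches anything
      else TRUE                                # fully wildcard locus
    })
    if (!any(matches)) "mismatch"
    else if (all(matches) || nrow(s) == 1) "match"
    else "ambiguous"
  }, character(1))
  data.frame(locus = loci, status = status, stringsAsFactors = FALSE,
             row.names = NULL)
}
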