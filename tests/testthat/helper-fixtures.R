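## Shared fixtures and independent oracles for the test suite.
## Everything here is deliberately written WITHOUT reusing package
## internals, so package results are checked against an independent
## route.

## -- small constructors ------------------------------------------------

mkFreqs <- function(...) {
  ## mkFreqs(L1 = c("102" = .5, "104" = .5), ...)
  new("AlleleFreqs", freqs = list(...), provenance = "manual")
}

mkTable <- function(a1, a2, colony = "c1", site = "s1",
                    caste = "worker", ploidy = 2L, ids = NULL) {
  ## a1, a2: matrices individuals x loci (a2 NA rows for haploids)
  n <- nrow(a1)
  if (is.null(ids)) ids <- sprintf("i%02d", seq_len(n))
  if (is.null(colnames(a1)))
    colnames(a1) <- colnames(a2) <- sprintf("L%02d", seq_len(ncol(a1)))
  rownames(a1) <- rownames(a2) <- ids
  info <- data.frame(colony = rep_len(colony, n), site = rep_len(site, n),
                     caste = rep_len(caste, n),
                     ploidy = rep_len(as.integer(ploidy), n),
                     row.names = ids, stringsAsFactors = FALSE)
  GenotypeTable(a1, a2, info)
}

g2 <- function(...) {
  ## genotype matrix for qgPair/mlPair: g2(c(1,2), c(3,3)) -> 2 x 2
  m <- matrix(as.integer(unlist(list(...))), nrow = 2)
  colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  m
}

## Build a colony table with an exact patriline split from explicit
## parents (used where the expectation assumes an exact 14:2 etc.).
mkColonyFromParents <- function(queen, fathers, patriline,
                                colony = "c1", site = "s1") {
  L <- ncol(queen)
  n <- length(patriline)
  a1 <- matrix(NA_integer_, n, L)
  a2 <- matrix(NA_integer_, n, L)
  for (w in seq_len(n)) {
    mat <- queen[cbind(sample.int(2, L, replace = TRUE), seq_len(L))]
    a1[w, ] <- mat
    a2[w, ] <- fathers[[patriline[w]]]
  }
  colnames(a1) <- colnames(a2) <- colnames(queen)
  mkTable(a1, a2, colony = colony, site = site)
}

drawQueen <- function(freqs) {
  g <- vapply(freqs@freqs, function(p)
    as.integer(names(p))[sample.int(length(p), 2, replace = TRUE,
                                    prob = p)], integer(2))
  colnames(g) <- names(freqs@freqs)
  g
}

drawMale <- function(freqs) {
  vapply(freqs@freqs, function(p)
    as.integer(names(p))[sample.int(length(p), 1, prob = p)], integer(1))
}

## -- independent IBD-mode genotype-pair probabilities ------------------
## Standard published table for the non-inbred modes, written directly
## case by case (independent of the package's derivation).
refModeProbs <- function(x, y, p) {
  x <- sort(x); y <- sort(y)
  pA <- function(a) unname(p[as.character(a)])
  pg <- function(g) if (g[1] == g[2]) pA(g[1])^2 else 2 * pA(g[1]) * pA(g[2])
  P0 <- pg(x) * pg(y)
  P2 <- if (identical(x, y)) pg(x) else 0
  P1 <- {
    if (x[1] == x[2] && y[1] == y[2]) {            # AA, BB (or AA, AA)
      if (x[1] == y[1]) pA(x[1])^3 else 0
    } else if (x[1] == x[2]) {                     # AA, BC
      if (x[1] %in% y) pA(x[1])^2 * pA(setdiff2(y, x[1])) else 0
    } else if (y[1] == y[2]) {                     # AB, CC
      if (y[1] %in% x) pA(y[1])^2 * pA(setdiff2(x, y[1])) else 0
    } else {                                       # AB vs CD/AC/AB
      shared <- intersect(x, y)
      if (length(shared) == 2) pA(x[1]) * pA(x[2]) * (pA(x[1]) + pA(x[2]))
      else if (length(shared) == 1)
        pA(shared) * pA(setdiff2(x, shared)) * pA(setdiff2(y, shared))
      else 0
    }
  }
  c(P0 = P0, P1 = P1, P2 = P2)
}
setdiff2 <- function(g, a) {
  ## multiset removal of one copy of a
  i <- match(a, g)
  g[-i]
}

## independent grid maximizer of the pair likelihood
refMlGrid <- function(gx, gy, freqs, step = 0.02) {
  L <- ncol(gx)
  P <- t(vapply(seq_len(L), function(l)
    refModeProbs(gx[, l], gy[, l], freqs@freqs[[l]]), numeric(3)))
  best <- -Inf; bk <- c(1, 0, 0)
  for (k1 in seq(0, 1, by = step)) for (k2 in seq(0, 1 - k1, by = step)) {
    k <- c(1 - k1 - k2, k1, k2)
    ll <- sum(log(pmax(P %*% k, 1e-300)))
    if (ll > best) { best <- ll; bk <- k }
  }
  list(k = bk, logLik = best)
}

## -- independent brute-force colony reconstruction oracle --------------
## Enumerates every explanation and applies the same decision rule the
## package documents: queens minimized first; single-queen candidates
## compared by (n_fathers, n_aliens) with the conflict guard on aliens;
## two queens only when no single-queen explanation exists.

oracleCoverPairs <- function(w1, w2) {
  ## all covering queen pairs (incl. wildcard = NA) at one locus
  keep <- !is.na(w1)
  if (!any(keep)) return(list(c(NA_integer_, NA_integer_)))
  w1 <- w1[keep]; w2 <- w2[keep]
  al <- sort(unique(c(w1, w2)))
  out <- list()
  for (a in al) for (b in al) {
    if (b < a) next
    if (all(w1 == a | w2 == a | w1 == b | w2 == b))
      out[[length(out) + 1]] <- c(a, b)
  }
  for (a in al)
    if (all(w1 == a | w2 == a))
      out[[length(out) + 1]] <- c(a, NA_integer_)
  out
}

oracleGroupFeasible <- function(w1, w2, groups) {
  ## single queen, given patriline grouping: feasible iff at each locus
  ## some covering pair admits a common father allele per group
  L <- ncol(w1)
  for (l in seq_len(L)) {
    pairs <- oracleCoverPairs(w1[, l], w2[, l])
    if (length(pairs) == 0) return(FALSE)
    okAny <- FALSE
    for (q in pairs) {
      qs <- q[!is.na(q)]
      ok <- TRUE
      for (g in groups) {
        cands <- NULL
        for (w in g) {
          if (is.na(w1[w, l])) next
          cw <- integer(0)
          if (length(qs) == 0) cw <- c(w1[w, l], w2[w, l])
          else {
            if (w1[w, l] %in% qs) cw <- c(cw, w2[w, l])
            if (w2[w, l] %in% qs) cw <- c(cw, w1[w, l])
          }
          cw <- unique(cw)
          cands <- if (is.null(cands)) cw else intersect(cands, cw)
          if (length(cands) == 0) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) { okAny <- TRUE; break }
    }
    if (!okAny) return(FALSE)
  }
  TRUE
}

oraclePartitions <- function(n) {
  ## all set partitions of 1..n via restricted growth strings
  out <- list()
  rec <- function(i, assign, m) {
    if (i > n) { out[[length(out) + 1]] <<- split(seq_len(n), assign); return() }
    for (g in seq_len(m + 1)) {
      assign[i] <- g
      rec(i + 1, assign, max(m, g))
    }
  }
  rec(1, integer(n), 0)
  out
}

oracleMinFathers <- function(w1, w2) {
  best <- Inf
  for (p in oraclePartitions(nrow(w1))) {
    if (length(p) >= best) next
    if (oracleGroupFeasible(w1, w2, p)) best <- length(p)
  }
  if (is.finite(best)) best else NA_integer_
}

oracleConflicts <- function(w1, w2, e, sub) {
  sum(vapply(seq_len(ncol(w1)), function(l) {
    if (is.na(w1[e, l])) return(FALSE)
    pairs <- oracleCoverPairs(w1[sub, l], w2[sub, l])
    al <- unique(unlist(pairs))
    al <- al[!is.na(al)]
    if (length(al) == 0) return(FALSE)
    !(w1[e, l] %in% al || w2[e, l] %in% al)
  }, logical(1)))
}

oracleReconstruct <- function(w1, w2, maxAliens = 1, minConflictLoci = 2) {
  ## returns c(nQueens, nAliens, nFathers) under the documented rule
  n <- nrow(w1)
  ## single-queen candidates: (fathers, aliens) lexicographic
  best <- NULL
  k0 <- oracleMinFathers(w1, w2)
  if (!is.na(k0)) best <- c(k0, 0)
  if (maxAliens >= 1 && n >= 3) {
    for (s in seq_len(min(maxAliens, n - 2))) {
      for (ex in asplit(combn(n, s), 2)) {
        sub <- setdiff(seq_len(n), ex)
        confl <- vapply(ex, function(e) oracleConflicts(w1, w2, e, sub),
                        numeric(1))
        if (!all(confl >= minConflictLoci)) next
        k <- oracleMinFathers(w1[sub, , drop = FALSE],
                              w2[sub, , drop = FALSE])
        if (is.na(k)) next
        if (is.null(best) || k < best[1]) best <- c(k, s)
      }
    }
  }
  if (!is.null(best)) return(c(1L, best[2], best[1]))
  ## two queens
  if (n >= 2) {
    bestK <- Inf
    for (code in seq_len(2^(n - 1) - 1)) {
      inB <- c(FALSE, as.logical(bitwAnd(code, 2^(seq_len(n - 1) - 1)) > 0))
      A <- which(!inB); B <- which(inB)
      kA <- oracleMinFathers(w1[A, , drop = FALSE], w2[A, , drop = FALSE])
      kB <- oracleMinFathers(w1[B, , drop = FALSE], w2[B, , drop = FALSE])
      if (!is.na(kA) && !is.na(kB)) bestK <- min(bestK, kA + kB)
    }
    if (is.finite(bestK)) return(c(2L, 0L, bestK))
  }
  c(NA_integer_, NA_integer_, NA_integer_)
}

## random small colony generator for oracle comparisons: a mix of true
## family structure and noise workers
randomOracleColony <- function(nWorkers, nLoci, nAlleles = 5,
                               family = TRUE) {
  al <- 100L + 2L * seq_len(nAlleles)
  if (family) {
    q <- matrix(sample(al, 2 * nLoci, replace = TRUE), 2, nLoci)
    f1 <- sample(al, nLoci, replace = TRUE)
    f2 <- sample(al, nLoci, replace = TRUE)
    a1 <- matrix(NA_integer_, nWorkers, nLoci)
    a2 <- a1
    for (w in seq_len(nWorkers)) {
      if (runif(1) < 0.2) {  # noise worker
        a1[w, ] <- sample(al, nLoci, replace = TRUE)
        a2[w, ] <- sample(al, nLoci, replace = TRUE)
      } else {
        f <- if (runif(1) < 0.3) f2 else f1
        a1[w, ] <- q[cbind(sample.int(2, nLoci, replace = TRUE),
                           seq_len(nLoci))]
        a2[w, ] <- f
      }
    }
  } else {
    a1 <- matrix(sample(al, nWorkers * nLoci, replace = TRUE),
                 nWorkers, nLoci)
    a2 <- matrix(sample(al, nWorkers * nLoci, replace = TRUE),
                 nWorkers, nLoci)
  }
  ## sprinkle missing calls
  miss <- matrix(runif(nWorkers * nLoci) < 0.05, nWorkers, nLoci)
  a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
  lo <- pmin(a1, a2); hi <- pmax(a1, a2)
  list(a1 = lo, a2 = hi)
}
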