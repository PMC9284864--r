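## Pairwise relatedness: the Queller-Goodnight moment estimator
## (symmetrized ratio-of-sums across loci) and a maximum-likelihood
## (k0, k1, k2) estimator over the three non-inbred IBD modes.

#' Estimate allele frequencies from a genotype table
#'
#' Per-locus counts over non-missing calls; haploids contribute one
#' allele copy, diploids two.  Alleles that appear somewhere in the
#' analysed table but not in the reference set are floored at
#' 1/(2N + 1) (N = number of reference individuals) and the vector is
#' renormalized, so every analysed genotype has positive likelihood.
#'
#' @param table a [GenotypeTable-class].
#' @param reference "all" (every individual), "one-per-colony" (one
#'   random worker per colony, the pipeline default mirroring a
#'   population-level genotyping design), or "ids" with `ids` given.
#' @param ids explicit individual ids when `reference = "ids"`.
#' @param seed seed for the "one-per-colony" draw.
#' @return an [AlleleFreqs-class].
#' @export
estimateAlleleFreqs <- function(table,
                                reference = c("all", "one-per-colony", "ids"),
                                ids = NULL, seed = NULL) {
  reference <- match.arg(reference)
  info <- indivData(table)
  sel <- switch(reference,
    "all" = individuals(table),
    "one-per-colony" = {
      if (!is.null(seed)) set.seed(as.integer(seed))
      workers <- individuals(table)[info$caste == "worker"]
      byCol <- split(workers, info[workers, "colony"])
      vapply(byCol, function(w) w[sample.int(length(w), 1)], character(1))
    },
    "ids" = {
      if (is.null(ids)) stop("reference = 'ids' needs ids")
      ids
    })
  ref <- table[sel, ]
  loci <- lociNames(table)
  N <- length(sel)
  freqs <- vector("list", length(loci))
  names(freqs) <- loci
  for (l in seq_along(loci)) {
    pl <- ref@info$ploidy
    copies <- c(ref@a1[, l],
                ref@a2[pl == 2L, l])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0)
      stop("locus with zero non-missing calls in reference set: ", loci[l])
    cnt <- base::table(copies)
    p <- setNames(as.numeric(cnt) / sum(cnt), names(cnt))
    ## floor unseen-but-analysed alleles
    seen <- unique(stats::na.omit(c(table@a1[, l], table@a2[, l])))
    unseen <- setdiff(as.character(seen), names(p))
    if (length(unseen)) {
      floor <- 1 / (2 * N + 1)
      p <- c(p, setNames(rep(floor, length(unseen)), unseen))
      p <- p / sum(p)
    }
    ord <- order(as.integer(names(p)))
    freqs[[l]] <- p[ord]
  }
  prov <- switch(reference, all = "all individuals",
                 "one-per-colony" = "one random worker per colony",
                 ids = sprintf("%d explicit individuals", N))
  new("AlleleFreqs", freqs = freqs, provenance = prov)
}

## Pull the pseudo-diploid 2 x L genotype matrix of one individual
## (haploids duplicated into homozygotes -- the only convention
## compatible with the diploid estimators).
.pseudoDiploid <- function(table, id) {
  a1 <- table@a1[id, ]
  a2 <- table@a2[id, ]
  if (indivData(table)[id, "ploidy"] == 1L) a2 <- a1
  rbind(a1, a2)
}

#' Queller-Goodnight relatedness of one genotype pair
#'
#' The symmetrized multilocus ratio-of-sums form.  For direction x->y
#' and locus l, the numerator is the sum over x's two allele positions of
#' (frequency of that allele within y's genotype - population frequency),
#' and the denominator is the same sum with frequencies within x's own
#' genotype; r = (sum num(x->y) + sum num(y->x)) / (sum den(x->y) +
#' sum den(y->x)), summed over loci before dividing.  A direction skips a
#' locus when its denominator term is undefined (focal individual
#' homozygous for an allele at frequency 1).
#'
#' @param gx,gy 2 x loci genotype matrices (pseudo-diploid; see
#'   [asPairGenotype()] helpers), NA = missing locus.
#' @param freqs an [AlleleFreqs-class].
#' @return list with `r` (NA with `undefined = TRUE` when the summed
#'   denominator is zero), `lociUsed`, and per-locus numerator and
#'   denominator contributions for both directions.
#' @export
qgPair <- function(gx, gy, freqs) {
  loci <- lociNames(freqs)
  numxy <- denxy <- numyx <- denyx <- rep(NA_real_, length(loci))
  for (l in seq_along(loci)) {
    x <- gx[, l]; y <- gy[, l]
    if (any(is.na(x)) || any(is.na(y))) next
    p <- freqs@freqs[[l]]
    px <- p[as.character(x)]
    py <- p[as.character(y)]
    if (any(is.na(px)) || any(is.na(py)))
      stop("allele absent from frequency table at locus ", loci[l])
    fw <- function(a, g) (sum(g == a)) / 2
    ## x -> y direction (x focal for the denominator)
    if (!(x[1] == x[2] && px[1] >= 1 - 1e-12)) {
      numxy[l] <- sum(vapply(seq_len(2), function(i)
        fw(x[i], y) - px[i], numeric(1)))
      denxy[l] <- sum(vapply(seq_len(2), function(i)
        fw(x[i], x) - px[i], numeric(1)))
    }
    if (!(y[1] == y[2] && py[1] >= 1 - 1e-12)) {
      numyx[l] <- sum(vapply(seq_len(2), function(i)
        fw(y[i], x) - py[i], numeric(1)))
      denyx[l] <- sum(vapply(seq_len(2), function(i)
        fw(y[i], y) - py[i], numeric(1)))
    }
  }
  den <- sum(denxy, na.rm = TRUE) + sum(denyx, na.rm = TRUE)
  num <- sum(numxy, na.rm = TRUE) + sum(numyx, na.rm = TRUE)
  used <- sum(!is.na(denxy) | !is.na(denyx))
  if (used == 0 || abs(den) < 1e-300)
    return(list(r = NA_real_, undefined = TRUE, lociUsed = used,
                num = cbind(xy = numxy, yx = numyx),
                den = cbind(xy = denxy, yx = denyx)))
  list(r = num / den, undefined = FALSE, lociUsed = used,
       num = cbind(xy = numxy, yx = numyx),
       den = cbind(xy = denxy, yx = denyx))
}

.buildPairs <- function(table, pairs) {
  info <- indivData(table)
  if (is.matrix(pairs) || is.data.frame(pairs)) {
    as.matrix(pairs)
  } else if (identical(pairs, "within-colony")) {
    workers <- individuals(table)[info$caste == "worker"]
    byCol <- split(workers, info[workers, "colony"])
    do.call(rbind, lapply(byCol, function(w) {
      if (length(w) < 2) return(NULL)
      t(combn(w, 2))
    }))
  } else if (identical(pairs, "all")) {
    t(combn(individuals(table), 2))
  } else stop("pairs must be 'within-colony', 'all' or an id matrix")
}

#' Pairwise Queller-Goodnight relatedness over a table
#'
#' @param table a [GenotypeTable-class]; haploids enter as homozygous
#'   pseudo-diploids.
#' @param freqs an [AlleleFreqs-class] (population reference; see
#'   [estimateAlleleFreqs()] or [trueFreqs()]).
#' @param pairs "within-colony" (default), "all", or a 2-column matrix of
#'   individual ids.
#' @return data.frame: id1, id2, r, lociUsed, undefined.
#' @export
qgRelatedness <- function(table, freqs, pairs = "within-colony") {
  pm <- .buildPairs(table, pairs)
  if (is.null(pm) || nrow(pm) == 0) stop("no eligible pairs")
  res <- data.frame(id1 = pm[, 1], id2 = pm[, 2], r = NA_real_,
                    lociUsed = NA_integer_, undefined = FALSE,
                    stringsAsFactors = FALSE, row.names = NULL)
  geno <- lapply(setNames(nm = unique(c(pm))), function(id)
    .pseudoDiploid(table, id))
  for (i in seq_len(nrow(pm))) {
    q <- qgPair(geno[[pm[i, 1]]], geno[[pm[i, 2]]], freqs)
    res$r[i] <- q$r
    res$lociUsed[i] <- q$lociUsed
    res$undefined[i] <- q$undefined
  }
  res
}

#' Mean within-group relatedness
#'
#' Mean Queller-Goodnight relatedness over all unordered member pairs of
#' each group (default: colony nestmates).  Undefined pairs are excluded
#' and counted.
#'
#' @param table a [GenotypeTable-class].
#' @param freqs an [AlleleFreqs-class].
#' @param groupBy metadata column defining groups (default "colony").
#' @param caste restrict to this caste (default "worker").
#' @return data.frame per group: group, n (members), nPairs, meanR, sdR,
#'   nUndefined; the attribute "overall" holds the grand mean, SD and SE
#'   over group means.
#' @export
meanGroupRelatedness <- function(table, freqs, groupBy = "colony",
                                 caste = "worker") {
  info <- indivData(table)
  keep <- info$caste %in% caste
  members <- split(individuals(table)[keep], info[keep, groupBy])
  members <- Filter(function(w) length(w) >= 2, members)
  if (length(members) == 0)
    stop("no group with >= 2 usable members")
  rows <- lapply(names(members), function(g) {
    w <- members[[g]]
    pr <- qgRelatedness(table, freqs, pairs = t(combn(w, 2)))
    ok <- !pr$undefined & !is.na(pr$r)
    data.frame(group = g, n = length(w), nPairs = sum(ok),
               meanR = mean(pr$r[ok]), sdR = sd(pr$r[ok]),
               nUndefined = sum(!ok), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  m <- out$meanR[!is.na(out$meanR)]
  attr(out, "overall") <- list(mean = mean(m), sd = sd(m),
                               se = sd(m) / sqrt(length(m)),
                               nGroups = length(m))
  out
}

## Genotype-pair probabilities for m = 0, 1, 2 alleles IBD (non-inbred
## modes).  P0 = P(gx) P(gy); P1 = P(gx) * average over x's alleles of
## the chance that y = {that allele, one random draw}; P2 = P(gx) when
## the unordered genotypes coincide.
.ibdModeProbs <- function(x, y, p) {
  pg <- function(g) if (g[1] == g[2]) p[as.character(g[1])]^2
                    else 2 * p[as.character(g[1])] * p[as.character(g[2])]
  u <- function(e) {  # P(y | one allele of y is IBD copy e)
    if (y[1] == y[2]) (e == y[1]) * p[as.character(y[1])]
    else (e == y[1]) * p[as.character(y[2])] +
         (e == y[2]) * p[as.character(y[1])]
  }
  P0 <- pg(x) * pg(y)
  P1 <- pg(x) * 0.5 * (u(x[1]) + u(x[2]))
  P2 <- pg(x) * as.numeric(identical(sort(x), sort(y)))
  c(P0, P1, P2)
}

#' Maximum-likelihood pairwise relatedness (k0, k1, k2)
#'
#' Maximizes prod over loci of (k0 P0 + k1 P1 + k2 P2) over the IBD-mode
#' simplex, with the standard non-inbred genotype-pair probabilities.
#' Optimization is a dense simplex grid (step `gridStep`) followed by EM
#' refinement, which is monotone in likelihood, so the refined optimum
#' never falls below the best grid point.  r-hat = k2 + k1/2 is
#' nonnegative by construction.
#'
#' @param gx,gy 2 x loci pseudo-diploid genotype matrices.
#' @param freqs an [AlleleFreqs-class].
#' @param gridStep simplex grid spacing (default 0.02).
#' @param emIter EM refinement iterations (default 300).
#' @return list: k0, k1, k2, r, logLik, lociUsed.
#' @export
mlPair <- function(gx, gy, freqs, gridStep = 0.02, emIter = 300) {
  loci <- lociNames(freqs)
  P <- matrix(NA_real_, 0, 3)
  for (l in seq_along(loci)) {
    x <- gx[, l]; y <- gy[, l]
    if (any(is.na(x)) || any(is.na(y))) next
    p <- freqs@freqs[[l]]
    if (any(is.na(p[as.character(c(x, y))])))
      stop("allele absent from frequency table at locus ", loci[l])
    row <- .ibdModeProbs(x, y, p)
    if (all(row <= 0))
      stop("degenerate likelihood (all IBD-mode probabilities zero) at locus ",
           loci[l])
    P <- rbind(P, row)
  }
  if (nrow(P) == 0) stop("no locus where both genotypes are non-missing")
  ll <- function(k) sum(log(pmax(P %*% k, 1e-300)))
  ## dense simplex grid
  ks <- seq(0, 1, by = gridStep)
  grid <- expand.grid(k1 = ks, k2 = ks)
  grid <- grid[grid$k1 + grid$k2 <= 1 + 1e-12, ]
  K <- rbind(1 - grid$k1 - grid$k2, grid$k1, grid$k2)
  lls <- colSums(log(pmax(P %*% K, 1e-300)))
  best <- which.max(lls)
  kGrid <- K[, best]
  llGrid <- lls[best]
  ## EM refinement from the (interior-nudged) grid optimum
  k <- pmax(kGrid, 1e-6)
  k <- k / sum(k)
  for (it in seq_len(emIter)) {
    w <- P * rep(k, each = nrow(P))
    w <- w / rowSums(w)
    kNew <- colMeans(w)
    if (max(abs(kNew - k)) < 1e-12) { k <- kNew; break }
    k <- kNew
  }
  if (ll(k) < llGrid) k <- kGrid  # never fall below the grid optimum
  k <- k / sum(k)
  list(k0 = k[1], k1 = k[2], k2 = k[3], r = k[3] + k[2] / 2,
       logLik = ll(k), lociUsed = nrow(P))
}

#' Pairwise maximum-likelihood relatedness over a table
#'
#' @inheritParams qgRelatedness
#' @param gridStep,emIter passed to [mlPair()].
#' @return data.frame: id1, id2, k0, k1, k2, r, logLik, lociUsed.
#' @export
mlRelatedness <- function(table, freqs, pairs = "within-colony",
                          gridStep = 0.02, emIter = 300) {
  pm <- .buildPairs(table, pairs)
  if (is.null(pm) || nrow(pm) == 0) stop("no eligible pairs")
  geno <- lapply(setNames(nm = unique(c(pm))), function(id)
    .pseudoDiploid(table, id))
  rows <- lapply(seq_len(nrow(pm)), function(i) {
    m <- mlPair(geno[[pm[i, 1]]], geno[[pm[i, 2]]], freqs,
                gridStep = gridStep, emIter = emIter)
    data.frame(id1 = pm[i, 1], id2 = pm[i, 2], k0 = m$k0, k1 = m$k1,
               k2 = m$k2, r = m$r, logLik = m$logLik,
               lociUsed = m$lociUsed, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Build a pseudo-diploid genotype matrix from allele vectors
#'
#' Convenience for tests and for queen/male genotypes produced by the
#' reconstruction: a haploid vector becomes a homozygous pseudo-diploid.
#'
#' @param a1 allele vector (length = loci).
#' @param a2 second allele vector, or NULL for a haploid.
#' @param loci locus names.
#' @return 2 x loci integer matrix.
#' @export
asPairGenotype <- function(a1, a2 = NULL, loci = names(a1)) {
  if (is.null(a2)) a2 <- a1
  g <- rbind(as.integer(a1), as.integer(a2))
  colnames(g) <- loci
  g
}
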