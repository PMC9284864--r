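## Population-level statistics: heterozygosity, Weir & Cockerham (1984)
## variance-component F-statistics (the estimators behind Genepop's
## F-statistics), the standard differentiation classification, and the
## one-sample t-test used for nestmate relatedness.

#' Observed and unbiased expected heterozygosity
#'
#' Ho = fraction heterozygous among non-missing diploid calls;
#' He = (2n/(2n - 1)) (1 - sum p^2), the unbiased (Nei) expected
#' heterozygosity from the same individuals.
#'
#' @param table a [GenotypeTable-class].
#' @param ids optional subset of individual ids (default: all diploids).
#' @return data.frame per locus: locus, n (diploid individuals typed),
#'   Ho, He; the attribute "overall" holds unweighted means across loci.
#'   Loci with zero diploid calls are omitted with a warning.
#' @export
heterozygosity <- function(table, ids = NULL) {
  info <- indivData(table)
  if (is.null(ids)) ids <- individuals(table)[info$ploidy == 2L]
  ids <- ids[info[ids, "ploidy"] == 2L]
  loci <- lociNames(table)
  rows <- lapply(seq_along(loci), function(l) {
    a1 <- table@a1[ids, l]; a2 <- table@a2[ids, l]
    ok <- !is.na(a1)
    n <- sum(ok)
    if (n == 0) return(NULL)
    ho <- mean(a1[ok] != a2[ok])
    p <- as.numeric(base::table(c(a1[ok], a2[ok])))
    p <- p / sum(p)
    he <- (2 * n / (2 * n - 1)) * (1 - sum(p^2))
    data.frame(locus = loci[l], n = n, Ho = ho, He = he,
               stringsAsFactors = FALSE)
  })
  drop <- vapply(rows, is.null, logical(1))
  if (any(drop))
    warning("loci with zero diploid calls omitted: ",
            paste(loci[drop], collapse = ", "))
  out <- do.call(rbind, rows[!drop])
  attr(out, "overall") <- c(Ho = mean(out$Ho), He = mean(out$He))
  out
}

## Weir & Cockerham (1984) per-allele variance components for one locus.
## geno: 2-column matrix of diploid calls; pop: population factor.
## Returns matrix with columns a, b, c (one row per allele).
.wcComponents <- function(a1, a2, pop) {
  ok <- !is.na(a1) & !is.na(pop)
  a1 <- a1[ok]; a2 <- a2[ok]; pop <- factor(pop[ok])
  r <- nlevels(pop)
  if (r < 1 || length(a1) == 0) return(NULL)
  ni <- as.numeric(table(pop))
  if (any(ni < 1)) return(NULL)
  nbar <- mean(ni)
  alleles <- sort(unique(c(a1, a2)))
  nc <- if (r > 1) (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1) else NA_real_
  out <- matrix(NA_real_, length(alleles), 3,
                dimnames = list(alleles, c("a", "b", "c")))
  for (k in seq_along(alleles)) {
    al <- alleles[k]
    cnt <- (a1 == al) + (a2 == al)
    het <- (a1 == al) != (a2 == al)
    pi <- tapply(cnt, pop, sum) / (2 * ni)
    hi <- tapply(het, pop, mean)
    pbar <- sum(ni * pi) / (r * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    s2 <- if (r > 1) sum(ni * (pi - pbar)^2) / ((r - 1) * nbar) else 0
    if (r > 1) {
      aC <- (nbar / nc) *
        (s2 - (1 / (nbar - 1)) *
           (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
      bC <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
           ((2 * nbar - 1) / (4 * nbar)) * hbar)
    } else {
      aC <- 0
      bC <- (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - ((2 * nbar - 1) / (4 * nbar)) * hbar)
    }
    out[k, ] <- c(aC, bC, hbar / 2)
  }
  out
}

#' Weir-Cockerham F-statistics
#'
#' Multilocus theta-hat (F_ST) = sum(a) / sum(a + b + c) and
#' f-hat (F_IS) = 1 - sum(c) / sum(b + c), the a/b/c variance components
#' of Weir & Cockerham (1984) summed over alleles and loci
#' (ratio-of-sums, as Genepop combines them).  Negative estimates are
#' reported as computed.  Missing calls are handled pairwise-complete
#' (each locus uses its non-missing individuals); haploids are excluded
#' with a warning.
#'
#' @param table a [GenotypeTable-class].
#' @param pops metadata column defining populations (default "site"), or
#'   a vector of population labels along `individuals(table)`.
#' @return object of class "PopStats": list with `fst`, `fis`, `fit`
#'   (multilocus), `perLocus` data.frame of summed components, `fisPerPop`,
#'   `pairwiseFst` (symmetric matrix, NA diagonal), `pairwiseClass`
#'   (classification of each pair, negatives classed as 0), and
#'   `sampleSizes`.
#' @export
fStatistics <- function(table, pops = "site") {
  info <- indivData(table)
  labels <- if (length(pops) == 1 && pops %in% names(info))
    info[[pops]] else as.character(pops)
  dip <- info$ploidy == 2L
  if (any(!dip))
    warning(sum(!dip), " haploid individual(s) excluded from F-statistics")
  a1 <- table@a1[dip, , drop = FALSE]
  a2 <- table@a2[dip, , drop = FALSE]
  labels <- labels[dip]
  loci <- lociNames(table)
  popLevels <- unique(labels)
  ## at least 2 individuals somewhere per population
  for (p in popLevels)
    if (sum(labels == p) < 2)
      stop("population ", p, " has < 2 diploid individuals")
  sums <- function(a1, a2, lab) {
    tot <- c(a = 0, b = 0, cc = 0)
    perLocus <- list()
    for (l in seq_along(loci)) {
      comp <- .wcComponents(a1[, l], a2[, l], lab)
      if (is.null(comp)) next
      s <- colSums(comp)
      perLocus[[loci[l]]] <- s
      tot <- tot + c(s["a"], s["b"], s["c"])
    }
    list(tot = tot, perLocus = perLocus)
  }
  all <- sums(a1, a2, labels)
  tot <- all$tot
  fst <- if (length(popLevels) > 1)
    unname(tot[1] / sum(tot)) else NA_real_
  fis <- unname(1 - tot[3] / (tot[2] + tot[3]))
  fit <- if (length(popLevels) > 1)
    unname(1 - tot[3] / sum(tot)) else NA_real_
  perLocus <- do.call(rbind, all$perLocus)
  perLocus <- data.frame(locus = rownames(perLocus), perLocus,
                         row.names = NULL, stringsAsFactors = FALSE)
  ## per-population F_IS (single-population variance components)
  fisPerPop <- vapply(popLevels, function(p) {
    keep <- labels == p
    s <- sums(a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
              labels[keep])$tot
    unname(1 - s[3] / (s[2] + s[3]))
  }, numeric(1))
  ## pairwise F_ST
  np <- length(popLevels)
  pw <- matrix(NA_real_, np, np, dimnames = list(popLevels, popLevels))
  if (np > 1) {
    for (i in seq_len(np - 1)) for (j in (i + 1):np) {
      keep <- labels %in% popLevels[c(i, j)]
      s <- sums(a1[keep, , drop = FALSE], a2[keep, , drop = FALSE],
                labels[keep])$tot
      pw[i, j] <- pw[j, i] <- unname(s[1] / sum(s))
    }
  }
  cls <- pw
  cls[] <- NA_character_
  cls[!is.na(pw)] <- classifyFst(pw[!is.na(pw)])
  structure(list(fst = fst, fis = fis, fit = fit, perLocus = perLocus,
                 fisPerPop = fisPerPop, pairwiseFst = pw,
                 pairwiseClass = cls,
                 sampleSizes = base::table(labels)),
            class = "PopStats")
}

#' @export
print.PopStats <- function(x, ...) {
  cat("Weir-Cockerham F-statistics\n")
  cat(sprintf("  multilocus: F_ST = %s, F_IS = %.3f\n",
              ifelse(is.na(x$fst), "NA (single population)",
                     sprintf("%.3f", x$fst)), x$fis))
  if (!all(is.na(x$pairwiseFst))) {
    cat("  pairwise F_ST:\n")
    print(round(x$pairwiseFst, 3))
  }
  invisible(x)
}

#' Classify a pairwise F_ST value
#'
#' Standard bands: low (0 <= F_ST < 0.05), medium (0.05 <= F_ST < 0.15),
#' high (0.15 <= F_ST <= 0.25), very high (F_ST > 0.25).  Negative
#' estimates are treated as 0 for classification (with a message).
#'
#' @param value numeric vector of F_ST values.
#' @return character vector in {"low", "medium", "high", "very_high"}.
#' @examples
#' classifyFst(c(0.02, 0.10, 0.25, 0.2500001))
#' @export
classifyFst <- function(value) {
  if (any(value < 0, na.rm = TRUE))
    message("negative F_ST value(s) treated as 0 for classification")
  v <- pmax(value, 0)
  ifelse(v < 0.05, "low",
    ifelse(v < 0.15, "medium",
      ifelse(v <= 0.25, "high", "very_high")))
}

#' One-sample t-test
#'
#' t = (mean - mu) / (SD / sqrt(n)) with a two-sided p from the t
#' distribution on n - 1 degrees of freedom.  Used to compare mean
#' nestmate relatedness with the haplodiploid full-sister expectation
#' of 0.75.
#'
#' @param values numeric vector (n >= 2, finite).
#' @param mu hypothesized mean (default 0.75).
#' @return object of class "TTestResult": list with mean, sd, se, n, mu,
#'   t, df, p.
#' @export
oneSampleTTest <- function(values, mu = 0.75) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 2) stop("need n >= 2 finite values")
  s <- sd(values)
  if (s == 0) {
    ## degenerate but well-defined case: every value equals mu
    if (mean(values) == mu)
      return(structure(list(mean = mu, sd = 0, se = 0, n = n, mu = mu,
                            t = 0, df = n - 1, p = 1),
                       class = "TTestResult"))
    stop("zero standard deviation: t statistic undefined")
  }
  t <- (mean(values) - mu) / (s / sqrt(n))
  structure(list(mean = mean(values), sd = s, se = s / sqrt(n), n = n,
                 mu = mu, t = t, df = n - 1,
                 p = 2 * pt(-abs(t), df = n - 1)),
            class = "TTestResult")
}

#' @export
print.TTestResult <- function(x, ...) {
  cat(sprintf(
    "one-sample t-test: mean = %.3f (SD %.3f, SE %.3f, n = %d) vs mu = %g\n",
    x$mean, x$sd, x$se, x$n, x$mu))
  cat(sprintf("  t = %.3f, df = %d, two-sided p = %.3f\n", x$t, x$df, x$p))
  invisible(x)
}
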