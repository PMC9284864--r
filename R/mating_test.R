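## Non-random-mating analysis: relatedness of queens to their own mates
## versus the exhaustive cross-pair null (every queen x every other
## colony's male), compared with a one-sided two-sample
## Kolmogorov-Smirnov test.

#' Build observed-mate and cross-pair null relatedness sets
#'
#' Eligible colonies are reconstructed monogynous, monandrous colonies.
#' The observed set holds one (queen, own mate) relatedness value per
#' colony; the null holds the relatedness of every ordered (queen of
#' colony i, male of colony j != i) combination - for n colonies that is
#' n^2 - n values (26 colonies give 650).  Queen and male genotypes come
#' from the reconstruction (wildcard or ambiguous loci treated as
#' missing); males enter as homozygous pseudo-diploids.
#'
#' @param recons list of [ColonyReconstruction-class] objects (e.g. from
#'   [reconstructAllColonies()]).
#' @param freqs an [AlleleFreqs-class].
#' @param estimator "qg" or "ml".
#' @return list: `mate` (named numeric per colony), `null` (numeric),
#'   `nColonies`, `nMatePairs`, `nNullPairs`, `excluded` (ids of
#'   ineligible colonies).
#' @export
buildPairSets <- function(recons, freqs, estimator = c("qg", "ml")) {
  estimator <- match.arg(estimator)
  eligible <- Filter(function(r)
    classification(r) == "monogyne_monandrous", recons)
  excluded <- setdiff(names(recons), names(eligible))
  if (length(eligible) < 2)
    stop("need >= 2 eligible (monogynous, monandrous) colonies")
  loci <- eligible[[1]]@loci
  queens <- lapply(eligible, function(r) {
    g <- queenGenotype(r)
    g  # 2 x L, NA wildcards act as missing loci
  })
  males <- lapply(eligible, function(r) {
    f <- fatherGenotypes(r)[[1]]
    asPairGenotype(f, loci = loci)  # pseudo-diploid, NA ambiguous loci
  })
  rel <- function(gq, gm) {
    if (estimator == "qg") qgPair(gq, gm, freqs)$r
    else mlPair(gq, gm, freqs)$r
  }
  n <- length(eligible)
  mate <- vapply(seq_len(n), function(i)
    rel(queens[[i]], males[[i]]), numeric(1))
  names(mate) <- names(eligible)
  null <- numeric(0)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    null <- c(null, rel(queens[[i]], males[[j]]))
  }
  list(mate = mate, null = null, nColonies = n,
       nMatePairs = length(mate), nNullPairs = length(null),
       excluded = excluded)
}

## one-sided KS statistic: sup_t [F_null(t) - F_obs(t)], evaluated at
## the pooled support and its left limits (both step functions only
## move there)
.ksD <- function(obs, null) {
  so <- sort(obs); sn <- sort(null)
  v <- sort(unique(c(so, sn)))
  Fo <- findInterval(v, so) / length(so)
  Fn <- findInterval(v, sn) / length(sn)
  FoL <- (findInterval(v, so, left.open = TRUE)) / length(so)
  FnL <- (findInterval(v, sn, left.open = TRUE)) / length(sn)
  max(Fn - Fo, FnL - FoL, 0)
}

#' One-sided two-sample Kolmogorov-Smirnov test
#'
#' For the alternative "observed stochastically greater than null"
#' (mated pairs more related than random cross pairs), the statistic is
#' D = sup_t [F_null(t) - F_obs(t)].  The asymptotic one-sided p is the
#' large-sample bound exp(-2 D^2 n1 n2 / (n1 + n2)); a permutation p
#' (group labels resampled over the pooled values) is computed alongside
#' when `nPermutations > 0` and is the recommended headline number at
#' small n.
#'
#' @param observed numeric sample (the mated-pair relatedness values).
#' @param null numeric sample (the cross-pair null).
#' @param alternative "observed_greater" (default) or "observed_less".
#' @param nPermutations permutation replicates (0 = asymptotic only).
#' @param seed seed for the permutation resampling.
#' @return object of class "KSResult": list with D, alternative,
#'   pAsymptotic, pPermutation (NA if not run), nPermutations, n1, n2,
#'   seed.
#' @examples
#' ksOneSided(c(0.2, 0.3, 0.4), c(0.1, 0.2, 0.3))
#' @export
ksOneSided <- function(observed, null,
                       alternative = c("observed_greater", "observed_less"),
                       nPermutations = 0, seed = NULL) {
  alternative <- match.arg(alternative)
  observed <- observed[is.finite(observed)]
  null <- null[is.finite(null)]
  if (length(observed) == 0 || length(null) == 0)
    stop("both samples must be nonempty")
  stat <- function(o, u)
    if (alternative == "observed_greater") .ksD(o, u) else .ksD(u, o)
  D <- stat(observed, null)
  n1 <- length(observed); n2 <- length(null)
  pAsym <- min(1, exp(-2 * D^2 * n1 * n2 / (n1 + n2)))
  pPerm <- NA_real_
  if (nPermutations > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    pool <- c(observed, null)
    hits <- 0L
    for (b in seq_len(nPermutations)) {
      idx <- sample.int(n1 + n2, n1)
      if (stat(pool[idx], pool[-idx]) >= D - 1e-12) hits <- hits + 1L
    }
    pPerm <- (1 + hits) / (nPermutations + 1)
  }
  structure(list(D = D, alternative = alternative, pAsymptotic = pAsym,
                 pPermutation = pPerm, nPermutations = nPermutations,
                 n1 = n1, n2 = n2,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "KSResult")
}

#' @export
print.KSResult <- function(x, ...) {
  cat(sprintf("one-sided two-sample KS test (%s)\n", x$alternative))
  cat(sprintf("  D = %.3f (n1 = %d, n2 = %d)\n", x$D, x$n1, x$n2))
  cat(sprintf("  asymptotic p = %.4f", x$pAsymptotic))
  if (!is.na(x$pPermutation))
    cat(sprintf(", permutation p = %.4f (%d permutations)",
                x$pPermutation, x$nPermutations))
  cat("\n")
  invisible(x)
}
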