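test_that("allele frequencies count copies, floor unseen alleles, and fail on empty loci", {
  ## two diploids {A,A},{A,B}: p(A) = 0.75, p(B) = 0.25
  tab <- mkTable(matrix(c(102L, 102L)), matrix(c(102L, 104L)))
  f <- estimateAlleleFreqs(tab)
  expect_equal(unname(f@freqs$L01), c(0.75, 0.25))
  ## haploid male {A} + diploid {B,B}: copy counting with mixed ploidy
  tab2 <- mkTable(matrix(c(102L, 104L)), matrix(c(NA, 104L)),
                  ploidy = c(1L, 2L), caste = c("male", "worker"))
  f2 <- estimateAlleleFreqs(tab2)
  expect_equal(unname(f2@freqs$L01[c("102", "104")]), c(1, 2) / 3)
  ## allele analysed but unseen in the reference set: floored at 1/(2N+1)
  tab3 <- mkTable(matrix(c(102L, 102L, 106L)), matrix(c(102L, 104L, 106L)))
  f3 <- estimateAlleleFreqs(tab3, reference = "ids", ids = c("i01", "i02"))
  expect_true("106" %in% names(f3@freqs$L01))
  expect_equal(unname(f3@freqs$L01["106"]), 0.2 / 1.2)
  expect_lt(abs(sum(f3@freqs$L01) - 1), 1e-12)
  ## a locus with zero non-missing reference calls errors by name
  tab4 <- mkTable(matrix(c(102L, NA), 1, 2), matrix(c(104L, NA), 1, 2))
  expect_error(estimateAlleleFreqs(tab4), "L02")
})

test_that("Queller-Goodnight matches hand-evaluated cases and is symmetric", {
  f <- mkFreqs(L01 = c("1" = 0.5, "2" = 0.25, "3" = 0.25))
  ## x = y = {A,B}: the symmetrized estimator returns exactly 1
  expect_equal(qgPair(g2(c(1, 2)), g2(c(1, 2)), f)$r, 1)
  ## x = {A,B}, y = {A,C}: hand evaluation gives -1
  expect_equal(qgPair(g2(c(1, 2)), g2(c(1, 3)), f)$r, -1)
  ## symmetry is exact for arbitrary pairs
  set.seed(42)
  f12 <- mkFreqs(L01 = setNames(rep(0.1, 10), 101:110),
                 L02 = setNames(rep(0.1, 10), 201:210))
  for (i in 1:25) {
    gx <- g2(sample(101:110, 2, TRUE), sample(201:210, 2, TRUE))
    gy <- g2(sample(101:110, 2, TRUE), sample(201:210, 2, TRUE))
    expect_identical(qgPair(gx, gy, f12)$r, qgPair(gy, gx, f12)$r)
  }
  ## zero total denominator is an undefined-result signal, not a crash
  f1 <- mkFreqs(L01 = c("5" = 1))
  q <- qgPair(g2(c(5, 5)), g2(c(5, 5)), f1)
  expect_true(q$undefined)
  expect_true(is.na(q$r))
})

test_that("QG calibrates to Mendelian expectations on simulated kin", {
  m <- makePopulationModel(nLoci = 12, allelesPerLocus = 20, seed = 1)
  f <- trueFreqs(m)
  ## full sisters -> 0.75, queen-daughter -> 0.5 (smaller-n check here;
  ## the full-scale calibration is an acceptance test)
  rs <- qd <- numeric(0)
  for (s in 1:40) {
    sim <- simulateColony(m, config = colonyConfig(
      nWorkers = 4, includeQueenGenotype = TRUE), seed = s)
    pr <- qgRelatedness(sim$table, f, pairs = "within-colony")
    rs <- c(rs, pr$r)
    qid <- individuals(sim$table)[indivData(sim$table)$caste == "queen"]
    wid <- individuals(sim$table)[indivData(sim$table)$caste == "worker"]
    qd <- c(qd, qgRelatedness(sim$table, f,
                              pairs = cbind(qid, wid))$r)
  }
  expect_lt(abs(mean(rs) - 0.75), 0.03)
  expect_lt(abs(mean(qd) - 0.5), 0.03)
})

test_that("mean within-group relatedness follows pair-counting expectations", {
  ## two identical heterozygotes -> mean r = 1
  f <- mkFreqs(L01 = c("102" = 0.5, "104" = 0.25, "106" = 0.25))
  tab <- mkTable(matrix(c(102L, 102L)), matrix(c(104L, 104L)))
  g <- meanGroupRelatedness(tab, f)
  expect_equal(g$meanR, 1)
  expect_equal(g$nPairs, 1L)
  ## 16 workers split 14:2 between two fathers: expected mean
  ## (92 * 0.75 + 28 * 0.25) / 120 = 0.6333
  m <- makePopulationModel(nLoci = 12, allelesPerLocus = 20, seed = 2)
  ft <- trueFreqs(m)
  set.seed(99)
  means <- vapply(1:60, function(i) {
    tab <- mkColonyFromParents(drawQueen(ft),
                               list(drawMale(ft), drawMale(ft)),
                               patriline = rep(c(1, 2), c(14, 2)))
    meanGroupRelatedness(tab, ft)$meanR
  }, numeric(1))
  expect_lt(abs(mean(means) - 0.6333), 0.02)
  ## < 2 usable members is an error
  one <- mkTable(matrix(102L), matrix(104L))
  expect_error(meanGroupRelatedness(one, f), ">= 2")
})

test_that("IBD-mode probabilities match the published table", {
  p <- c("1" = 0.5, "2" = 0.3, "3" = 0.2)
  cases <- list(list(c(1, 1), c(1, 1)), list(c(1, 1), c(1, 2)),
                list(c(1, 2), c(1, 2)), list(c(1, 1), c(2, 2)),
                list(c(1, 2), c(1, 3)), list(c(1, 2), c(3, 3)),
                list(c(1, 3), c(2, 3)))
  for (cs in cases) {
    ours <- colonykin:::.ibdModeProbs(cs[[1]], cs[[2]], p)
    ref <- refModeProbs(cs[[1]], cs[[2]], p)
    expect_equal(unname(ours), unname(ref), tolerance = 1e-12,
                 label = paste(cs[[1]], collapse = "/"))
  }
})

test_that("ML relatedness recovers the forced IBD modes", {
  ## no allele shared anywhere: only the k0 mode has positive likelihood
  f <- mkFreqs(L01 = setNames(rep(0.25, 4), 101:104),
               L02 = setNames(rep(0.25, 4), 201:204),
               L03 = setNames(rep(0.25, 4), 301:304))
  m0 <- mlPair(g2(c(101, 102), c(201, 202), c(301, 302)),
               g2(c(103, 104), c(203, 204), c(303, 304)), f)
  expect_gt(m0$k0, 0.999)
  expect_lt(m0$r, 1e-3)
  ## identical rare homozygotes at many loci force a k2-dominant fit
  fr <- do.call(mkFreqs, setNames(lapply(1:10, function(l)
    setNames(rep(0.05, 20), 100 + 2 * 1:20)), sprintf("L%02d", 1:10)))
  g <- g2(rep(c(102, 102), 10))[, 1:10]
  colnames(g) <- sprintf("L%02d", 1:10)
  mh <- mlPair(g, g, fr)
  expect_gte(mh$r, 0.9)
  ## impossible allele -> error naming the locus
  expect_error(mlPair(g2(c(999, 999)), g2(c(101, 102)),
                      mkFreqs(L01 = c("101" = 0.5, "102" = 0.5))),
               "L01")
})

test_that("ML estimates live on the simplex and dominate the grid oracle", {
  m <- makePopulationModel(nLoci = 10, allelesPerLocus = 10, seed = 5)
  f <- trueFreqs(m)
  set.seed(7)
  for (i in 1:15) {
    gx <- drawQueen(f)
    gy <- if (i %% 3 == 0) gx else drawQueen(f)
    res <- mlPair(gx, gy, f)
    expect_gte(res$r, 0)
    expect_lte(res$r, 1)
    expect_lt(abs(res$k0 + res$k1 + res$k2 - 1), 1e-9)
    ## refined likelihood never falls below the independent grid optimum
    ref <- refMlGrid(gx, gy, f, step = 0.1)
    expect_gte(res$logLik, ref$logLik - 1e-9)
  }
})

test_that("haploid males enter the estimators as homozygous pseudo-diploids", {
  f <- mkFreqs(L01 = c("102" = 0.5, "104" = 0.3, "106" = 0.2))
  tabH <- mkTable(matrix(c(102L, 102L)), matrix(c(104L, NA)),
                  ploidy = c(2L, 1L), caste = c("worker", "male"))
  tabD <- mkTable(matrix(c(102L, 102L)), matrix(c(104L, 102L)))
  rH <- qgRelatedness(tabH, f, pairs = cbind("i01", "i02"))
  rD <- qgRelatedness(tabD, f, pairs = cbind("i01", "i02"))
  expect_equal(rH$r, rD$r)
})
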