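## independent Weir-Cockerham oracle via the mean-squares (ANOVA)
## formulation, algebraically equivalent to the a/b/c components route
refWC <- function(a1, a2, pop) {
  pop <- factor(pop)
  r <- nlevels(pop)
  ni <- as.numeric(table(pop))
  s1 <- sum(ni)
  nc <- (s1 - sum(ni^2) / s1) / (r - 1)
  alleles <- sort(unique(c(a1, a2)))
  A <- B <- W <- 0
  for (al in alleles) {
    cnt <- (a1 == al) + (a2 == al)
    het <- (a1 == al) != (a2 == al)
    pij <- cnt / 2
    pi <- tapply(cnt, pop, sum) / (2 * ni)
    pbar <- sum(ni * pi) / s1
    MSP <- sum(2 * ni * (pi - pbar)^2) / (r - 1)
    MSI <- sum(2 * (pij - pi[pop])^2) / (s1 - r)
    MSG <- sum(het / 2) / s1
    A <- A + (MSP - MSI) / (2 * nc)
    B <- B + (MSI - MSG) / 2
    W <- W + MSG
  }
  c(fst = A / (A + B + W), fis = 1 - W / (B + W))
}

test_that("heterozygosity follows its closed forms", {
  ## all homozygotes -> Ho = 0
  tab <- mkTable(matrix(c(102L, 104L)), matrix(c(102L, 104L)))
  h <- heterozygosity(tab)
  expect_equal(h$Ho, 0)
  ## single heterozygote, n = 1: Ho = 1 and unbiased He = 1
  tab1 <- mkTable(matrix(102L), matrix(104L))
  h1 <- heterozygosity(tab1)
  expect_equal(h1$Ho, 1)
  expect_equal(h1$He, 1)
  ## k equifrequent alleles: He -> 1 - 1/k in a large sample
  m <- makePopulationModel(nLoci = 6, allelesPerLocus = 10, seed = 1)
  st <- simulateStudy(m, 80, config = colonyConfig(nWorkers = 1), seed = 2)
  h2 <- heterozygosity(st@table)
  expect_lt(max(abs(h2$He - 0.9)), 0.03)
})

test_that("Weir-Cockerham estimates agree with the independent mean-squares route", {
  set.seed(31)
  for (i in 1:10) {
    n1 <- sample(8:15, 1); n2 <- sample(8:15, 1)
    al <- 100L + 2L * seq_len(4)
    a1 <- sample(al, n1 + n2, TRUE); a2 <- sample(al, n1 + n2, TRUE)
    pop <- rep(c("P1", "P2"), c(n1, n2))
    tab <- mkTable(cbind(pmin(a1, a2)), cbind(pmax(a1, a2)),
                   colony = sprintf("c%d", seq_along(a1)), site = pop)
    fs <- fStatistics(tab)
    ref <- refWC(pmin(a1, a2), pmax(a1, a2), pop)
    expect_equal(fs$fst, unname(ref["fst"]), tolerance = 1e-10)
    expect_equal(fs$fis, unname(ref["fis"]), tolerance = 1e-10)
  }
})

test_that("theta is near zero without divergence and recovers the drift parameter", {
  ## identical source frequencies -> theta ~ 0
  th0 <- vapply(1:8, function(r) {
    m <- makePopulationModel(nLoci = 12, allelesPerLocus = 20,
                             nSites = 2, divergence = 0, seed = 300 + r)
    st <- simulateStudy(m, c(40, 40), config = colonyConfig(nWorkers = 1),
                        seed = r)
    fStatistics(st@table)$fst
  }, numeric(1))
  expect_lt(abs(mean(th0)), 0.01)
  ## random mating -> f ~ 0
  m <- makePopulationModel(nLoci = 12, allelesPerLocus = 20, seed = 9)
  st <- simulateStudy(m, 60, config = colonyConfig(nWorkers = 1), seed = 10)
  expect_lt(abs(fStatistics(st@table)$fis), 0.03)
  ## theta rises monotonically with the simulator's divergence
  mth <- vapply(c(0.02, 0.05, 0.1, 0.2), function(F) {
    mean(vapply(1:6, function(r) {
      m <- makePopulationModel(nLoci = 12, allelesPerLocus = 20,
                               nSites = 2, divergence = F,
                               seed = round(1000 * F) + r)
      st <- simulateStudy(m, c(40, 40), config = colonyConfig(nWorkers = 1),
                          seed = r)
      fStatistics(st@table)$fst
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mth) > 0))
})

test_that("inbreeding shows up as positive f and an Ho deficit", {
  ## autozygosity mixture with F = 0.3: E[f-hat] = 0.3
  set.seed(5)
  al <- 100L + 2L * seq_len(10)
  n <- 300
  a1 <- a2 <- integer(n)
  inb <- runif(n) < 0.3
  a1 <- sample(al, n, TRUE)
  a2 <- ifelse(inb, a1, sample(al, n, TRUE))
  tab <- mkTable(cbind(pmin(a1, a2)), cbind(pmax(a1, a2)),
                 colony = sprintf("c%d", 1:n))
  fs <- fStatistics(tab)
  expect_gt(fs$fis, 0.15)
  expect_lt(abs(fs$fis - 0.3), 0.1)
  h <- heterozygosity(tab)
  expect_gt(h$He, h$Ho)
})

test_that("F_ST classification uses the exact band boundaries", {
  expect_identical(classifyFst(0.02), "low")
  expect_identical(classifyFst(0.049999), "low")
  expect_identical(classifyFst(0.05), "medium")
  expect_identical(classifyFst(0.10), "medium")
  expect_identical(classifyFst(0.15), "high")
  expect_identical(classifyFst(0.25), "high")
  expect_identical(classifyFst(0.2500001), "very_high")
  expect_message(v <- classifyFst(-0.02), "negative")
  expect_identical(v, "low")
})

test_that("the one-sample t-test matches the t distribution", {
  ## symmetric values around mu -> t = 0, p = 1
  tt <- oneSampleTTest(c(0.70, 0.75, 0.80), mu = 0.75)
  expect_equal(tt$t, 0)
  expect_equal(tt$p, 1)
  ## all values equal to mu is the degenerate t = 0 case
  t0 <- oneSampleTTest(rep(0.75, 5), mu = 0.75)
  expect_equal(t0$t, 0)
  expect_equal(t0$p, 1)
  ## but zero SD off-target is an error
  expect_error(oneSampleTTest(rep(0.8, 5), mu = 0.75), "zero standard")
  ## t = 0.333 on 28 df gives the two-sided p ~ 0.741
  base <- scale(rnorm(29))[, 1]           # mean 0, sd 1
  vals <- 0.75 + 0.06 * base + 0.333 * 0.06 / sqrt(29)
  tt2 <- oneSampleTTest(vals, mu = 0.75)
  expect_equal(tt2$t, 0.333, tolerance = 1e-6)
  expect_equal(tt2$df, 28)
  expect_equal(tt2$p, 0.7416, tolerance = 1e-3)
  ## agreement with the reference implementation
  ref <- t.test(vals, mu = 0.75)
  expect_equal(tt2$t, unname(ref$statistic), tolerance = 1e-10)
  expect_equal(tt2$p, ref$p.value, tolerance = 1e-10)
  ## haploids are excluded from F-statistics with a warning
  tabH <- mkTable(matrix(c(102L, 102L, 104L)), matrix(c(104L, 102L, NA)),
                  ploidy = c(2L, 2L, 1L),
                  caste = c("worker", "worker", "male"),
                  colony = c("c1", "c2", "c3"))
  expect_warning(fStatistics(tabH), "haploid")
})
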