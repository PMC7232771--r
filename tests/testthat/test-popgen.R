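test_that("allele frequencies count alt dosages over called alleles", {
  gd <- toy_dataset(
    A = matrix(c(0, 0, 0,
                 1, 1, NA,
                 2, 1, 0), nrow = 3, byrow = TRUE),
    B = matrix(c(1, 1,
                 2, 2,
                 NA, NA), nrow = 3, byrow = TRUE))
  fa <- alleleFreqs(gd, "A")
  expect_equal(fa$p_alt[1], 0)
  expect_equal(fa$p_alt[2], 0.5)        # {1, 1, NA} -> 2/4
  expect_equal(fa$n_alleles[2], 4L)
  expect_equal(fa$p_alt[3], 0.5)        # {2, 1, 0} -> 3/6
  expect_equal(fa$n_alleles[3], 6L)
  fb <- alleleFreqs(gd, "B")
  expect_equal(fb$p_alt[1], 0.5)        # {1, 1} -> 2/4
  expect_true(fb$all_missing[3])
  expect_true(is.na(fb$p_alt[3]))
  expect_error(alleleFreqs(gd, "Z"), "unknown site")
})

test_that("diversity uses the unbiased He and averages FIS over polymorphic loci", {
  # 10 individuals, all heterozygous at locus 2; locus 1 monomorphic
  g <- rbind(rep(0, 10), rep(1, 10))
  gd <- toy_dataset(A = g)
  d <- siteDiversity(gd)
  heUnbiased <- (20 / 19) * 0.5
  expect_equal(d$He, (0 + heUnbiased) / 2)
  expect_equal(d$Ho, 0.5)
  expect_equal(d$FIS, 1 - 1 / heUnbiased)  # about -0.9, heterozygote excess

  # exact HWE proportions: FIS is 1/(2n), essentially zero at large n
  hwe <- c(rep(0, 25), rep(1, 50), rep(2, 25))
  dh <- siteDiversity(toy_dataset(A = matrix(hwe, nrow = 1)))
  expect_equal(dh$FIS, 1 / (2 * 100))
  expect_lt(abs(dh$FIS), 0.01)

  expect_error(siteDiversity(toy_dataset(A = g, B = matrix(c(0, 1), 2, 1))),
               "fewer than 2")
})

test_that("pairwise FST matches the nested-ANOVA oracle and its fixed points", {
  # fixed for alternate alleles: theta = 1
  g1 <- matrix(0L, 5, 8); g2 <- matrix(2L, 5, 8)
  gd <- toy_dataset(A = g1, B = g2)
  expect_equal(pairwiseFst(gd)$fst["A", "B"], 1)

  # identical samples: essentially no differentiation
  set.seed(21)
  gg <- matrix(sample(0:2, 60, TRUE), 6, 10)
  gd2 <- toy_dataset(A = gg, B = gg)
  expect_lte(pairwiseFst(gd2)$fst["A", "B"], 0.01)

  # toy table against the brute-force variance-components oracle
  set.seed(22)
  ga <- matrix(sample(c(0:2, NA), 120, TRUE, prob = c(.35, .3, .25, .1)), 15, 8)
  gb <- matrix(sample(c(0:2, NA), 90, TRUE, prob = c(.2, .3, .4, .1)), 15, 6)
  gd3 <- toy_dataset(A = ga, B = gb)
  res <- pairwiseFst(gd3)
  expect_equal(res$fst["A", "B"], oracle_wc_theta(ga, gb), tolerance = 1e-10)
  expect_equal(res$fst, t(res$fst))
  expect_equal(diag(res$fst), c(A = 0, B = 0))

  # relabeling individuals within a site changes nothing
  gd4 <- toy_dataset(A = ga[, sample(8)], B = gb)
  expect_equal(pairwiseFst(gd4)$fst, res$fst)

  expect_error(pairwiseFst(toy_dataset(A = ga)), "at least 2 sites")
  # no shared polymorphic loci
  gd5 <- toy_dataset(A = matrix(0L, 3, 4), B = matrix(0L, 3, 4))
  expect_error(pairwiseFst(gd5), "polymorphic")
})

test_that("genic exact tests match hypergeometric enumeration and combine by Fisher", {
  # identical allele counts 5/5 vs 5/5 -> p = 1
  gA <- matrix(c(0, 0, 1, 1, 1, 2, 1, 0, 1, 2), 2, 5, byrow = TRUE)
  gd <- toy_dataset(A = gA, B = gA)
  gt <- genicTest(gd, "A", "B")
  expect_true(all(gt$perLocus$p == 1))
  expect_equal(gt$combinedP, 1)

  # 10 ref alleles vs 10 alt alleles: p = 2 / choose(20, 10)
  g1 <- matrix(0L, 1, 5); g2 <- matrix(2L, 1, 5)
  gt2 <- genicTest(toy_dataset(A = g1, B = g2), "A", "B")
  pOracle <- sum(vapply(0:10, function(k) {
    pk <- dhyper(k, 10, 10, 10)
    if (pk <= dhyper(0, 10, 10, 10) + 1e-12) pk else 0
  }, numeric(1)))
  expect_equal(gt2$perLocus$p, pOracle, tolerance = 1e-12)
  expect_equal(pOracle, 2 / choose(20, 10), tolerance = 1e-12)

  # monomorphic-everywhere loci are skipped
  gm <- rbind(rep(0, 4), c(0, 1, 2, 1))
  gt3 <- genicTest(toy_dataset(A = gm, B = gm), "A", "B")
  expect_equal(nrow(gt3$perLocus), 1L)
})

test_that("IBS distances follow the dosage-sharing definition", {
  a <- matrix(c(0, 2, 1), 3, 1)
  gd <- toy_dataset(A = cbind(a, a), B = matrix(c(2, 0, 1), 3, 1))
  d <- ibsDistance(gd)
  expect_equal(unname(d[1, 2]), 0)           # identical genotypes
  expect_equal(unname(d[1, 3]), 2 / 3)       # two opposite homs, one match
  gdo <- toy_dataset(A = matrix(c(0, 0), 2, 1), B = matrix(c(2, 2), 2, 1))
  expect_equal(unname(ibsDistance(gdo)[1, 2]), 1)
  # het vs hom at a single locus: distance 0.5
  gh <- toy_dataset(A = matrix(1, 1, 1), B = matrix(2, 1, 1))
  expect_equal(unname(ibsDistance(gh)[1, 2]), 0.5)
})

test_that("metric MDS reproduces classical scaling up to axis sign", {
  # collinear points: one axis explains everything
  x <- c(0, 1, 3)
  d <- as.matrix(dist(x))
  fit <- suppressWarnings(metricMDS(d, k = 2))
  expect_gt(fit$varExplained[1], 0.999)

  z <- matrix(0, 3, 3)
  fitz <- suppressWarnings(metricMDS(z, k = 2))
  expect_true(all(fitz$points == 0))

  set.seed(30)
  pts <- matrix(rnorm(8), 4, 2)
  d4 <- as.matrix(dist(pts))
  fit4 <- metricMDS(d4, k = 2)
  oracle <- oracle_cmds(d4, 2)
  expect_equal(abs(unname(fit4$points)), abs(oracle), tolerance = 1e-10)

  expect_warning(metricMDS(d4, k = 4), "truncated|positive")
})
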