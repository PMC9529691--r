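test_that("score equals the oriented weighted allele sum", {
  # all dosages zero, no missing -> weights with beta < 0 count the effect
  # allele (dosage 0); beta > 0 flips to 2 - d
  ins <- makeInstruments(c(-0.5, -0.2))
  g0 <- matrix(0, 3, 2, dimnames = list(NULL, c("s01", "s02")))
  expect_equal(as.numeric(computeGRS(g0, ins)), c(0, 0, 0))

  # one SNP, |w| = 0.5, oriented dosages 0/1/2 -> scores 0 / 0.5 / 1.0
  ins1 <- makeInstruments(-0.5)
  g1 <- matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "s01"))
  expect_equal(as.numeric(computeGRS(g1, ins1)), c(0, 0.5, 1.0))

  # 5-SNP, 4-individual worked fixture vs a spreadsheet-style oracle
  betas <- c(0.5, -0.3, 0.2, -0.1, 0.4)
  eaf <- c(0.2, 0.4, 0.6, 0.3, 0.5)
  ins5 <- makeInstruments(betas, eaf = eaf)
  set.seed(11)
  g5 <- matrix(sample(0:2, 20, replace = TRUE), 4, 5,
               dimnames = list(NULL, sprintf("s%02d", 1:5)))
  oracle <- numeric(4)
  for (i in 1:4) {
    acc <- 0
    for (j in 1:5) {
      d <- g5[i, j]
      if (betas[j] > 0) d <- 2 - d     # count the ANM-decreasing allele
      acc <- acc + abs(betas[j]) * d
    }
    oracle[i] <- acc
  }
  expect_equal(as.numeric(computeGRS(g5, ins5)), oracle)
})

test_that("score is invariant to allele-representation flips", {
  betas <- c(0.5, -0.3, 0.2)
  eaf <- c(0.2, 0.4, 0.6)
  ins <- makeInstruments(betas, eaf = eaf)
  g <- makeGenotypes(50, eaf, seed = 2)
  base <- as.numeric(computeGRS(g, ins))
  # swap (effect, other), negate the weight, complement dosage and eaf
  s <- as.data.frame(ins)
  s$beta <- -s$beta
  s$eaf <- 1 - s$eaf
  tmp <- s$effect_allele; s$effect_allele <- s$other_allele
  s$other_allele <- tmp
  insFlip <- new("InstrumentSet", snps = s)
  gFlip <- 2 - g
  expect_equal(as.numeric(computeGRS(gFlip, insFlip)), base)
})

test_that("missing dosages follow the declared policy", {
  ins <- makeInstruments(c(-0.5, 0.4), eaf = c(0.3, 0.8))
  g <- matrix(c(1, NA, 2, 0), 2, 2, dimnames = list(NULL, c("s01", "s02")))
  # s01: oriented freq 0.3 -> impute 0.6; s02 flips, oriented freq 0.2
  sc <- computeGRS(g, ins)
  expect_equal(as.numeric(sc), c(0.5 * 1 + 0.4 * (2 - 2),
                                 0.5 * (2 * 0.3) + 0.4 * (2 - 0)))
  scc <- computeGRS(g, ins, missingPolicy = "complete")
  expect_true(is.na(as.numeric(scc)[2]))
  expect_false(is.na(as.numeric(scc)[1]))
})

test_that("bad genotype input is rejected with named errors", {
  ins <- makeInstruments(c(-0.5, 0.4))
  g <- matrix(0, 2, 1, dimnames = list(NULL, "s01"))
  expect_error(computeGRS(g, ins), "s02")
  gBad <- matrix(c(0, 3), 1, 2, dimnames = list(NULL, c("s01", "s02")))
  expect_error(computeGRS(gBad, ins), "\\[0, 2\\]")
})

test_that("pruning applies the window and r2 rules greedily by rank", {
  # two SNPs 5,000 kb apart on one chromosome: better-ranked survives
  ins2 <- makeInstruments(c(-0.5, -0.3), chrom = c("1", "1"),
                          pos = c(1e6, 6e6), pval = c(1e-20, 1e-10))
  g2 <- makeGenotypes(500, c(0.3, 0.3), seed = 4)
  kept <- pruneInstruments(ins2, g2, windowBp = 1e7, r2Max = 0.5)
  expect_equal(snpIds(kept), "s01")

  # distinct chromosomes, independent draws, permissive r2 -> identity
  ins3 <- makeInstruments(c(-0.5, -0.3, 0.2), pval = c(1e-9, 1e-8, 1e-7))
  g3 <- makeGenotypes(2000, rep(0.3, 3), seed = 5)
  expect_equal(snpIds(pruneInstruments(ins3, g3, r2Max = 0.05)),
               snpIds(ins3))

  # r2Max = 1 and window 0 is the identity
  expect_equal(snpIds(pruneInstruments(ins3, g3, windowBp = 0, r2Max = 1)),
               snpIds(ins3))
})

test_that("pruning matches an exhaustive greedy oracle on a correlated block", {
  cfg <- simConfig(nIndividuals = 2000, nSnps = 20, ldBlockSize = 5L,
                   ldBlockR = 0.6, seed = 13)
  sim <- simulateCohort(cfg)
  g <- genotypes(sim$cohort)
  s <- as.data.frame(sim$instruments)
  windowBp <- 2.5e6; r2Max <- 0.05
  # brute-force greedy reimplementation
  ord <- order(s$pval, s$snp)
  kept <- integer(0)
  for (i in ord) {
    drop <- FALSE
    for (k in kept) {
      sameChromClose <- s$chrom[i] == s$chrom[k] &&
        abs(s$pos[i] - s$pos[k]) < windowBp
      r2 <- cor(g[, s$snp[i]], g[, s$snp[k]])^2
      if (sameChromClose || r2 >= r2Max) { drop <- TRUE; break }
    }
    if (!drop) kept <- c(kept, i)
  }
  oracle <- sort(s$snp[kept])
  pruned <- pruneInstruments(sim$instruments, g, windowBp = windowBp,
                             r2Max = r2Max)
  expect_equal(sort(snpIds(pruned)), oracle)
  expect_true(all(snpIds(pruned) %in% snpIds(sim$instruments)))
  expect_lt(nInstruments(pruned), nInstruments(sim$instruments))
})

test_that("stratification partitions the annotated instruments", {
  ann <- c(rep("DDR", 104), rep("non-DDR", 163))
  ins <- makeInstruments(rep(c(-0.2, 0.3), length.out = 267),
                         chrom = rep(1:22, length.out = 267),
                         pos = seq_len(267) * 1e5, annotation = ann)
  ddr <- stratifyInstruments(ins, "DDR")
  non <- stratifyInstruments(ins, "non-DDR")
  expect_equal(nInstruments(ddr), 104L)
  expect_equal(nInstruments(non), 163L)
  expect_equal(sort(c(snpIds(ddr), snpIds(non))), sort(snpIds(ins)))

  allDDR <- makeInstruments(c(-0.1, -0.2), annotation = c("DDR", "DDR"))
  expect_equal(nInstruments(stratifyInstruments(allDDR, "DDR")), 2L)
  expect_warning(empty <- stratifyInstruments(allDDR, "non-DDR"),
                 "no instruments")
  expect_equal(nInstruments(empty), 0L)
  expect_error(stratifyInstruments(allDDR, "other"))
})

test_that("instrument strength matches the closed form and flags degeneracy", {
  withr::with_seed(30, {
    n <- 20000
    score <- rnorm(n)
    expo <- sqrt(0.073) * scale(score)[, 1] + sqrt(1 - 0.073) * rnorm(n)
    st <- instrumentStrength(score, expo)
    # independent oracle: F reported by summary.lm
    fit <- summary(lm(expo ~ score))
    expect_equal(st$r_squared, fit$r.squared, tolerance = 1e-12)
    expect_equal(st$f_statistic, unname(fit$fstatistic["value"]),
                 tolerance = 1e-6)
    # k-regressor form shrinks F accordingly
    stk <- instrumentStrength(score, expo, nRegressors = 2L)
    expect_lt(stk$f_statistic, st$f_statistic)
  })
  # exact linear relation -> R2 = 1, F = +Inf
  sc <- 1:10
  stInf <- instrumentStrength(sc, 2 * sc + 3)
  expect_equal(stInf$r_squared, 1)
  expect_equal(stInf$f_statistic, Inf)
  expect_error(instrumentStrength(rep(1, 10), rnorm(10)), "degenerate")
})
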