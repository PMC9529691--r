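gwasTab <- function(snp, ea, oa, eaf, beta, se = 0.01) {
  data.frame(snp = snp, effect_allele = ea, other_allele = oa, eaf = eaf,
             beta = beta, se = se, stringsAsFactors = FALSE)
}

test_that("harmonization aligns alleles and logs exclusions", {
  ex <- gwasTab(c("a", "b", "c", "d", "e"),
                ea = c("A", "A", "A", "A", "A"),
                oa = c("G", "G", "G", "T", "C"),
                eaf = c(0.3, 0.3, 0.3, 0.2, 0.3),
                beta = c(0.1, 0.1, 0.1, 0.1, 0.1))
  ou <- gwasTab(c("a", "b", "c", "d", "f"),
                ea = c("A", "G", "T", "A", "A"),
                oa = c("G", "A", "C", "T", "G"),
                eaf = c(0.3, 0.7, 0.7, 0.5, 0.3),
                beta = c(0.05, -0.05, 0.05, 0.02, 0.1))
  h <- harmonizeSumstats(ex, ou)
  # a: identical labels pass through
  expect_equal(h$pairs$beta_y[h$pairs$snp == "a"], 0.05)
  # b: swapped labels flip the sign back
  expect_equal(h$pairs$beta_y[h$pairs$snp == "b"], 0.05)
  # c: strand complement (A/G vs T/C), same orientation
  expect_equal(h$pairs$beta_y[h$pairs$snp == "c"], 0.05)
  # d: palindromic with outcome eaf 0.5 -> ambiguous
  reasons <- setNames(h$exclusions$reason, h$exclusions$snp)
  expect_equal(unname(reasons["d"]), "palindromic_ambiguous")
  expect_equal(unname(reasons["e"]), "unmatched_in_outcome")
  expect_equal(unname(reasons["f"]), "unmatched_in_exposure")
  expect_setequal(h$pairs$snp, c("a", "b", "c"))

  # palindromic outside the ambiguity band orients by frequency
  ex2 <- gwasTab("p1", "A", "T", eaf = 0.1, beta = 0.1)
  ou2 <- gwasTab("p1", "A", "T", eaf = 0.9, beta = 0.04)  # opposite strand
  h2 <- harmonizeSumstats(ex2, ou2)
  expect_equal(h2$pairs$beta_y, -0.04)
  # non-complementary mismatch excluded with reason
  ex3 <- gwasTab("m1", "A", "G", eaf = 0.3, beta = 0.1)
  ou3 <- gwasTab("m1", "A", "C", eaf = 0.3, beta = 0.1)
  expect_equal(harmonizeSumstats(ex3, ou3)$exclusions$reason,
               "allele_mismatch")
})

test_that("IVW matches hand arithmetic and the WLS oracle", {
  # collinear printed fixture: slope exactly 0.1
  pairs3 <- data.frame(beta_x = c(0.5, 0.3, 0.2), se_x = 0.01,
                       beta_y = c(0.05, 0.03, 0.02), se_y = 0.01)
  est <- mrIVW(pairs3, sign = "increase")
  expect_equal(est@estimate, 0.1, tolerance = 1e-12)
  expect_equal(est@extra$Q, 0, tolerance = 1e-20)

  # all beta_y zero -> estimate zero
  pairs0 <- transform(pairs3, beta_y = 0)
  expect_equal(mrIVW(pairs0, sign = "increase")@estimate, 0)

  # single pair delegates to the Wald ratio
  single <- data.frame(beta_x = 0.5, se_x = 0.01, beta_y = 0.05,
                       se_y = 0.01)
  w <- mrIVW(single, sign = "increase")
  expect_equal(w@method, "Wald ratio")
  expect_equal(w@estimate, 0.1)
  expect_equal(w@se, 0.02)

  # seeded tables: equality with weighted-least-squares through origin
  for (s in 1:20) {
    p <- makePairs(25, seed = s, trueEffect = 0.05, pleioSD = 0.01)
    est <- mrIVW(p, sign = "increase")
    fit <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
    expect_equal(est@estimate, unname(coef(fit)), tolerance = 1e-8)
  }
})

test_that("Egger matches the WLS oracle and a zero intercept recovers IVW", {
  for (s in 1:10) {
    p <- makePairs(25, seed = s, trueEffect = 0.05, pleioMean = 0.005,
                   pleioSD = 0.01)
    eg <- mrEgger(p, sign = "increase")
    fit <- lm(beta_y ~ beta_x, data = p, weights = 1 / p$se_y^2)
    expect_equal(eg@estimate, unname(coef(fit)["beta_x"]),
                 tolerance = 1e-8)
    expect_equal(eg@intercept, unname(coef(fit)["(Intercept)"]),
                 tolerance = 1e-8)
    # constraining the intercept to zero is exactly fixed-effect IVW
    fit0 <- lm(beta_y ~ 0 + beta_x, data = p, weights = 1 / p$se_y^2)
    ivwF <- mrIVW(p, randomEffects = FALSE, sign = "increase")
    expect_equal(unname(coef(fit0)), ivwF@estimate, tolerance = 1e-10)
  }
  expect_error(mrEgger(makePairs(2), sign = "increase"), "at least 3")
})

test_that("weighted median interpolates the cumulative-weight crossing", {
  # equal weights, odd count -> ordinary median of ratios
  p <- data.frame(beta_x = rep(1, 5), se_x = 0.01,
                  beta_y = c(0.5, 0.1, 0.3, 0.2, 0.4), se_y = 0.01)
  est <- mrWeightedMedian(p, nBoot = 50, seed = 2, sign = "increase")
  expect_equal(est@estimate, 0.3)

  # one SNP carrying > 50% of the weight returns its ratio
  pDom <- data.frame(beta_x = c(1, 1, 1), se_x = 0.01,
                     beta_y = c(0.1, 0.2, 0.5),
                     se_y = c(0.001, 0.5, 0.5))
  estDom <- mrWeightedMedian(pDom, nBoot = 50, seed = 2, sign = "increase")
  expect_equal(estDom@estimate, 0.1, tolerance = 1e-4)

  # 5-pair fixture vs an exhaustive interpolation oracle
  p5 <- makePairs(5, seed = 40, trueEffect = 0.08, pleioSD = 0.02)
  r <- p5$beta_y / p5$beta_x
  w <- (abs(p5$beta_x) / p5$se_y)^2
  ord <- order(r)
  r <- r[ord]; w <- w[ord]
  cw <- (cumsum(w) - w / 2) / sum(w)
  oracle <- approx(cw, r, xout = 0.5)$y
  est5 <- mrWeightedMedian(p5, nBoot = 50, seed = 2, sign = "increase")
  expect_equal(est5@estimate, oracle, tolerance = 1e-10)
  # beta_x = 0 SNPs are excluded with a message
  p0 <- rbind(p5, data.frame(snp = NA, eaf = 0.5, beta_x = 0, se_x = 0.01,
                             beta_y = 0.1, se_y = 0.01))
  expect_message(est0 <- mrWeightedMedian(p0, nBoot = 50, seed = 2,
                                          sign = "increase"),
                 "beta_x = 0")
  expect_equal(est0@estimate, est5@estimate)
})

test_that("mode estimators find the dominant ratio cluster", {
  # all ratios identical -> that value
  pSame <- data.frame(beta_x = c(1, 2, 4), se_x = 0.01,
                      beta_y = c(0.1, 0.2, 0.4), se_y = 0.01)
  expect_equal(mrMode(pSame, nBoot = 30, sign = "increase")@estimate, 0.1)

  # bimodal fixture: 7 ratios near 0.1, 3 near 0.5 -> mode in the 0.1 cluster
  withr::with_seed(61, {
    ratios <- c(0.1 + rnorm(7, 0, 0.005), 0.5 + rnorm(3, 0, 0.005))
    pBi <- data.frame(beta_x = rep(1, 10), se_x = 0.01,
                      beta_y = ratios, se_y = 0.01)
  })
  estBi <- mrMode(pBi, nBoot = 30, seed = 5, sign = "increase")
  expect_lt(abs(estBi@estimate - 0.1), 0.05)
  # grid-search density oracle with the same bandwidth rule
  r <- sort(ratios)
  h <- 0.9 * min(sd(r), mad(r)) * 10^(-1 / 5)
  grid <- seq(min(r) - 3 * h, max(r) + 3 * h, length.out = 4001)
  dens <- vapply(grid, function(x) sum(dnorm((x - r) / h)), 0)
  expect_lt(abs(estBi@estimate - grid[which.max(dens)]), 1e-2)

  # uniform weights make the weighted mode equal the simple mode
  pU <- data.frame(beta_x = rep(1, 6), se_x = 0.01,
                   beta_y = c(0.1, 0.12, 0.11, 0.3, 0.09, 0.1),
                   se_y = 0.01)
  expect_equal(mrMode(pU, weighted = TRUE, nBoot = 30,
                      sign = "increase")@estimate,
               mrMode(pU, weighted = FALSE, nBoot = 30,
                      sign = "increase")@estimate)
})

test_that("Wald ratio arithmetic and its bootstrap agreement hold", {
  p <- data.frame(beta_x = 0.5, se_x = 1e-6, beta_y = 0.05, se_y = 0.01)
  est <- mrWaldRatio(p, sign = "increase")
  expect_equal(est@estimate, 0.1)
  expect_equal(est@se, 0.02)
  expect_equal(mrWaldRatio(transform(p, beta_y = 0),
                           sign = "increase")@estimate, 0)
  expect_error(mrWaldRatio(transform(p, beta_x = 0), sign = "increase"),
               "beta_x = 0")
  # delta-method SE vs a large parametric bootstrap (negligible se_x)
  withr::with_seed(71, {
    boots <- replicate(20000, {
      (0.05 + rnorm(1, 0, 0.01)) / 0.5
    })
  })
  expect_lt(abs(sd(boots) - est@se) / est@se, 0.05)
})

test_that("estimators are equivariant under joint per-SNP sign flips", {
  p <- makePairs(20, seed = 81, trueEffect = 0.06, pleioSD = 0.01)
  withr::with_seed(81, flip <- sample(c(TRUE, FALSE), 20, replace = TRUE))
  pf <- p
  pf$beta_x[flip] <- -pf$beta_x[flip]
  pf$beta_y[flip] <- -pf$beta_y[flip]
  expect_equal(mrIVW(pf, sign = "increase")@estimate,
               mrIVW(p, sign = "increase")@estimate, tolerance = 1e-12)
  expect_equal(mrEgger(pf, sign = "increase")@estimate,
               mrEgger(p, sign = "increase")@estimate, tolerance = 1e-12)
  expect_equal(mrWeightedMedian(pf, nBoot = 10, sign = "increase")@estimate,
               mrWeightedMedian(p, nBoot = 10, sign = "increase")@estimate,
               tolerance = 1e-12)
  expect_equal(mrMode(pf, nBoot = 10, sign = "increase")@estimate,
               mrMode(p, nBoot = 10, sign = "increase")@estimate,
               tolerance = 1e-9)
  # the decrease-scale report is the negated increase-scale estimate
  expect_equal(mrIVW(p, sign = "decrease")@estimate,
               -mrIVW(p, sign = "increase")@estimate)
})

test_that("under no pleiotropy all estimators agree on the planted effect", {
  sim <- simulateCohort(simConfig(nIndividuals = 100, nSnps = 100,
                                  seed = 91))
  ss <- simulateSummaryStats(sim$instruments, trueEffect = 0.05,
                             nExposure = 5e5, nOutcome = 5e5, seed = 91)
  suite <- mrSuite(ss$pairs, nBoot = 200, seed = 3, sign = "increase")
  expect_true(all(abs(suite$estimate - 0.05) < 3 * suite$se))
  expect_lt(max(suite$estimate) - min(suite$estimate), 0.02)
})
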