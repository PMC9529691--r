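test_that("auto type resolution follows the rule table", {
  cases <- list(
    list(v = c(0, 1, 0, 1), expect = "binary"),
    list(v = c("yes", "no", "yes"), expect = "binary"),
    list(v = rnorm(100), expect = "continuous"),
    list(v = rep(0:3, 10), expect = "ordered_categorical"),
    list(v = rep(1:19, 3), expect = "ordered_categorical"),
    list(v = rep(1:20, 2), expect = "continuous"),
    list(v = rep(c("a", "b", "c"), 5), expect = "unordered_categorical"))
  for (cs in cases)
    expect_equal(resolveTraitType(cs$v), cs$expect)

  # declared types validate, then pass through
  expect_equal(resolveTraitType(rnorm(30),
                                list(declared_type = "continuous")),
               "continuous")
  expect_error(resolveTraitType(c(1, 2, 3),
                                list(declared_type = "binary")),
               "declared binary")
  expect_error(resolveTraitType(rep(5, 10)), class = "mrphewas_skip")
})

test_that("inverse normal transform maps ranks to the right quantiles", {
  expect_equal(inverseNormalTransform(c(1, 2, 3)),
               qnorm(c(1, 3, 5) / 6))
  expect_equal(round(inverseNormalTransform(c(1, 2, 3)), 4),
               c(-0.9674, 0, 0.9674))
  # any strictly increasing input of length m transforms like 1..m
  withr::with_seed(1, {
    x <- sort(rexp(25))
    expect_equal(inverseNormalTransform(x),
                 inverseNormalTransform(seq_len(25)))
  })
  # two tied minima among 4 share the average-rank quantile
  out <- inverseNormalTransform(c(5, 5, 7, 9))
  expect_equal(out[1], qnorm((1.5 - 0.5) / 4))
  expect_equal(out[1], out[2])
  # missing stays missing, transform is monotone
  out2 <- inverseNormalTransform(c(3, NA, 1, 2))
  expect_true(is.na(out2[2]))
  expect_equal(order(out2[-2]), order(c(3, 1, 2)))
  expect_error(inverseNormalTransform(rep(2, 5)), class = "mrphewas_skip")
})

test_that("the linear branch agrees with a normal-equations oracle", {
  n <- 800
  cov <- makeCovariates(n, seed = 9)
  withr::with_seed(9, {
    score <- rnorm(n)
    y <- 0.15 * score + rnorm(n)
  })
  phen <- data.frame(y = y)
  res <- runPhenomeScan(score, phen, covariates = cov)
  # oracle: explicit least squares on the transformed outcome
  yt <- inverseNormalTransform(y)
  X <- cbind(1, score, as.matrix(cov[, c("age", paste0("PC", 1:10))]))
  bh <- solve(crossprod(X), crossprod(X, yt))
  expect_equal(res$estimate, bh[2], tolerance = 1e-10)
  expect_equal(res$model, "linear")
  expect_equal(res$resolved_type, "continuous")
})

test_that("linear-branch p-values are invariant to monotone transforms", {
  n <- 500
  cov <- makeCovariates(n, seed = 12)
  withr::with_seed(12, {
    score <- rnorm(n)
    y <- 0.2 * score + rnorm(n)
  })
  p1 <- runPhenomeScan(score, data.frame(y = y), covariates = cov)$pvalue
  p2 <- runPhenomeScan(score, data.frame(y = exp(y) + 5),
                       covariates = cov)$pvalue
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("each variable type routes to its model, with one p per field", {
  cfg <- simConfig(nIndividuals = 4000, nSnps = 20, seed = 19)
  sim <- simulateCohort(cfg)
  grs <- computeGRS(genotypes(sim$cohort), sim$instruments)
  res <- runPhenomeScan(grs, phenome(sim$cohort), phenomeMeta(sim$cohort),
                        covariates(sim$cohort))
  models <- setNames(res$model, res$resolved_type)
  expect_equal(unname(models["continuous"]), "linear")
  expect_equal(unname(models["binary"]), "logistic")
  expect_equal(unname(models["ordered_categorical"]), "ordered_logistic")
  expect_equal(unname(models["unordered_categorical"]), "multinomial")
  expect_true(all(res$pvalue >= 0 & res$pvalue <= 1))
  expect_true(all(res$se[res$converged] > 0))
  expect_equal(res$n_cases[res$field_id == "breast_cancer"],
               sum(phenome(sim$cohort)$breast_cancer))

  # multinomial p equals a manual likelihood-ratio oracle
  dat <- data.frame(y = factor(phenome(sim$cohort)$diet_group),
                    score = as.numeric(grs),
                    covariates(sim$cohort))
  covs <- paste(c("age", paste0("PC", 1:10)), collapse = " + ")
  f1 <- nnet::multinom(as.formula(paste("y ~ score +", covs)),
                       data = dat, trace = FALSE, maxit = 200)
  f0 <- nnet::multinom(as.formula(paste("y ~", covs)),
                       data = dat, trace = FALSE, maxit = 200)
  pOracle <- pchisq(f0$deviance - f1$deviance,
                    df = length(levels(dat$y)) - 1, lower.tail = FALSE)
  expect_equal(res$pvalue[res$field_id == "diet_group"], pOracle,
               tolerance = 1e-6)
})

test_that("fields are skipped with logged reasons, never silently dropped", {
  n <- 300
  cov <- makeCovariates(n, seed = 3)
  withr::with_seed(3, {
    phen <- data.frame(
      constant = rep(1, n),
      rare = c(rep(1, 3), rep(0, n - 3)),   # 3 cases < 10
      fine = rnorm(n))
    score <- rnorm(n)
  })
  res <- runPhenomeScan(score, phen, covariates = cov)
  skipped <- attr(res, "skipped")
  expect_equal(nrow(res) + nrow(skipped), 3L)
  expect_setequal(skipped$field_id, c("constant", "rare"))
  expect_match(skipped$reason[skipped$field_id == "constant"],
               "single distinct")
  expect_match(skipped$reason[skipped$field_id == "rare"], "cases")
  expect_false("constant" %in% res$field_id)
})

test_that("permuting the score destroys a planted association", {
  n <- 2000
  cov <- makeCovariates(n, seed = 23)
  withr::with_seed(23, {
    score <- rnorm(n)
    y <- 0.3 * score + rnorm(n)
    perm <- sample(score)
  })
  pPlanted <- runPhenomeScan(score, data.frame(y = y),
                             covariates = cov)$pvalue
  pPermuted <- runPhenomeScan(perm, data.frame(y = y),
                              covariates = cov)$pvalue
  expect_lt(pPlanted, 1e-10)
  expect_gt(pPermuted, 0.001)
})

test_that("misaligned or incomplete inputs are rejected", {
  cov <- makeCovariates(10)
  expect_error(runPhenomeScan(rnorm(5), data.frame(y = rnorm(10)),
                              covariates = cov), "row-aligned")
  badCov <- cov[, setdiff(colnames(cov), "PC7")]
  expect_error(runPhenomeScan(rnorm(10), data.frame(y = rnorm(10)),
                              covariates = badCov), "PC7")
})
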